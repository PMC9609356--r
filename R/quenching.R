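#' Construct a fluorescence quenching titration series
#'
#' An ordered tryptophan-quenching titration of a protein (e.g.
#' holo-transferrin) with increasing quencher concentrations, either as
#' peak intensities or as full emission spectra per titration point. The
#' series must contain exactly one point at zero quencher, which defines
#' the unquenched intensity \eqn{F_0}. Concentrations are supplied in uM
#' and held internally in mol/L; the unquenched fluorophore lifetime
#' \eqn{\tau_0} is supplied in ns (default 2.5 ns, the usual tryptophan
#' value for serum transferrin).
#'
#' @param Q_uM Strictly increasing non-negative quencher concentrations in
#'   uM, including one zero.
#' @param intensities Positive peak intensities (a.u.) at the common
#'   emission maximum, one per concentration. Ignored when `spectra` is
#'   given.
#' @param spectra Optional list of [emission_spectrum] objects, one per
#'   concentration, on a common grid; peak intensities are then read at the
#'   emission maximum of the zero-quencher spectrum.
#' @param tau0_ns Unquenched fluorophore lifetime in ns.
#' @param protein_uM Protein concentration in uM (metadata).
#' @param excitation_nm Excitation wavelength in nm (metadata).
#' @param quencher Label of the quencher/ligand.
#' @param V0_L,added_volumes_L Optional initial cuvette volume and
#'   cumulative added titrant volume per point (L) for
#'   [correct_dilution()].
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(Q_uM, intensities = NULL, spectra = NULL,
                             tau0_ns = 2.5, protein_uM = NA_real_,
                             excitation_nm = 295, quencher = "quencher",
                             V0_L = NULL, added_volumes_L = NULL) {
  Q_uM <- as.numeric(Q_uM)
  if (any(Q_uM < 0))
    stop_memfluor("quencher concentrations must be non-negative", "invalid_data")
  if (any(diff(Q_uM) <= 0))
    stop_memfluor("quencher concentrations must be strictly increasing",
                  "invalid_data")
  if (sum(Q_uM == 0) != 1L)
    stop_memfluor("exactly one zero-quencher point (F0) is required",
                  "missing_F0")
  if (!is_number(tau0_ns) || tau0_ns <= 0)
    stop_memfluor("tau0 must be positive", "invalid_parameter")
  lambda_max <- NA_real_
  if (!is.null(spectra)) {
    if (!is.list(spectra) || length(spectra) != length(Q_uM))
      stop_memfluor("one spectrum per titration point is required", "invalid_data")
    ref <- spectra[[which(Q_uM == 0)]]
    for (sp in spectra)
      if (!inherits(sp, "emission_spectrum") || !same_grid(ref, sp))
        stop_memfluor("spectra must share one wavelength grid", "grid_mismatch")
    pk <- peak_emission(ref)
    lambda_max <- pk$lambda_max
    idx <- which.min(abs(ref$wavelengths - lambda_max))
    intensities <- vapply(spectra, function(sp) sp$intensities[idx], numeric(1L))
  }
  if (is.null(intensities) || length(intensities) != length(Q_uM))
    stop_memfluor("one intensity per titration point is required", "invalid_data")
  if (any(intensities <= 0))
    stop_memfluor("intensities must be positive", "invalid_data")
  structure(
    list(Q_uM = Q_uM, Q_M = Q_uM * 1e-6, intensity = as.numeric(intensities),
         spectra = spectra, lambda_max = lambda_max,
         tau0_ns = tau0_ns, tau0_s = tau0_ns * 1e-9,
         protein_uM = protein_uM, excitation_nm = excitation_nm,
         quencher = quencher, V0_L = V0_L, added_volumes_L = added_volumes_L),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series '%s': %d points, Q = %g-%g uM, tau0 = %g ns",
              x$quencher, length(x$Q_uM), min(x$Q_uM), max(x$Q_uM), x$tau0_ns))
  if (!is.null(x$spectra)) cat(sprintf(", spectra (peak %g nm)", x$lambda_max))
  cat("\n")
  invisible(x)
}

#' Relative fluorescence intensity along a titration
#'
#' \eqn{F/F_0} at each quencher concentration, with \eqn{F_0} the intensity
#' of the zero-quencher point. A non-monotone ratio sequence triggers a
#' data-quality warning (not an error), since assay noise can locally
#' invert the trend.
#'
#' @param series A [titration_series].
#' @return Data frame with columns `Q_uM` and `F_over_F0`.
#' @export
relative_intensity <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  F0 <- series$intensity[series$Q_uM == 0]
  r <- series$intensity / F0
  if (any(diff(r) > 1e-12))
    warn_memfluor("F/F0 is not monotonically decreasing in Q", "non_monotone")
  data.frame(Q_uM = series$Q_uM, F_over_F0 = r)
}

#' Smooth the spectra of a titration series
#'
#' Applies the conventional 5-point moving-average smoothing (see
#' [smooth_moving_average()]) to every spectrum of the series and re-reads
#' the peak intensities from the smoothed zero-quencher spectrum. Smoothing
#' is linear, so in the absence of noise and peak drift it leaves every
#' \eqn{F/F_0} ratio exactly unchanged while suppressing per-point
#' acquisition noise.
#'
#' @param series A [titration_series] carrying full spectra.
#' @param window Odd smoothing window (default 5).
#' @return The smoothed [titration_series]; its `preprocessing` field
#'   records the applied steps.
#' @export
smooth_titration <- function(series, window = 5L) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$spectra))
    stop_memfluor("series carries no spectra to smooth", "invalid_parameter")
  out <- titration_series(
    series$Q_uM,
    spectra = lapply(series$spectra, smooth_moving_average, window = window),
    tau0_ns = series$tau0_ns, protein_uM = series$protein_uM,
    excitation_nm = series$excitation_nm, quencher = series$quencher,
    V0_L = series$V0_L, added_volumes_L = series$added_volumes_L)
  out$preprocessing <- c(series$preprocessing,
                         sprintf("moving_average_%d", as.integer(window)))
  out
}

#' Modified Stern-Volmer (accessible-fraction) fit
#'
#' Ordinary least squares on the modified Stern-Volmer linearisation
#' \deqn{\frac{F_0}{F_0 - F} = \frac{1}{f_a K_{SV}} \cdot \frac{1}{[Q]} +
#'   \frac{1}{f_a},}
#' i.e. \eqn{y = F_0/(F_0 - F)} regressed on \eqn{x = 1/[Q]}. The accessible
#' fraction is \eqn{f_a = 1/\mathrm{intercept}} and the Stern-Volmer
#' constant \eqn{K_{SV} = \mathrm{intercept}/\mathrm{slope}} (in 1/M). The
#' bimolecular quenching rate constant \eqn{K_q = K_{SV}/\tau_0} follows
#' exactly, and the quenching mechanism is classified against the
#' diffusion-limited bound (see [classify_mechanism()]). The zero-quencher
#' point supplies \eqn{F_0} only, and points with \eqn{F \ge F_0} are
#' excluded (counted in `n_excluded`): both transforms are undefined there.
#' The reported `R` is the Pearson correlation of the transformed scatter.
#'
#' The transformed ordinate is strongly heteroscedastic under the usual
#' multiplicative intensity-noise model: by the delta method
#' \eqn{\mathrm{SD}(y_i) \approx (y_i^2 F_i / F_0)\, \sigma}, an
#' amplification of up to an order of magnitude between the least- and
#' most-quenched points. The default `weights = "model"` therefore applies
#' inverse-variance weights \eqn{w_i = (F_0 / (y_i^2 F_i))^2} in the
#' regression; `weights = "none"` gives the plain unweighted fit of the
#' graphical plot. At zero noise both are exact and identical.
#'
#' @param series A [titration_series].
#' @param weights `"model"` (inverse-variance, default) or `"none"`.
#' @return Object of class `sv_fit` with components `f_a`, `K_SV` (1/M),
#'   `K_q` (1/(M s)), `mechanism`, `slope`, `intercept`, `R`,
#'   `n_points_used`, `n_excluded`, `F0`, `tau0_ns` and the underlying
#'   `lm` fit.
#' @export
stern_volmer_fit <- function(series, weights = c("model", "none")) {
  stopifnot(inherits(series, "titration_series"))
  weights <- match.arg(weights)
  F0 <- series$intensity[series$Q_uM == 0]
  use <- series$Q_uM > 0 & series$intensity < F0
  n_excluded <- sum(series$Q_uM > 0) - sum(use)
  if (sum(use) < 3L)
    stop_memfluor("fewer than 3 usable titration points (Q > 0, F < F0)",
                  "insufficient_data")
  x <- 1 / series$Q_M[use]
  Fi <- series$intensity[use]
  y <- F0 / (F0 - Fi)
  w <- if (weights == "model") (F0 / (y^2 * Fi))^2 else rep(1, length(y))
  fit <- lm(y ~ x, weights = w)
  b <- unname(coef(fit))
  intercept <- b[1L]; slope <- b[2L]
  if (!is.finite(intercept) || !is.finite(slope) || intercept <= 0 || slope <= 0) {
    cond <- errorCondition(
      "non-physical Stern-Volmer regression (non-positive slope or intercept)",
      class = c("non_physical_fit", "memfluor_error"))
    cond$regression <- list(slope = slope, intercept = intercept, lm = fit)
    stop(cond)
  }
  f_a <- 1 / intercept
  K_SV <- intercept / slope
  K_q <- bimolecular_quenching_constant(K_SV, series$tau0_ns)
  if (f_a > 1 + 0.1)
    warn_memfluor(sprintf("accessible fraction f_a = %.3f exceeds 1 beyond regression noise",
                          f_a), "data_quality")
  structure(
    list(f_a = f_a, K_SV = K_SV, K_q = unname(K_q),
         mechanism = as.character(classify_mechanism(K_q)),
         slope = slope, intercept = intercept,
         R = stats::cor(x, y), n_points_used = sum(use),
         n_excluded = n_excluded, F0 = F0, tau0_ns = series$tau0_ns,
         weights = weights, quencher = series$quencher, lm = fit,
         x = x, y = y),
    class = "sv_fit"
  )
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Modified Stern-Volmer fit ('%s')\n", x$quencher))
  cat(sprintf("  K_SV = %s 1/M,  f_a = %.3f,  R = %.4f (n = %d, excluded %d)\n",
              fmt_sci(x$K_SV), x$f_a, x$R, x$n_points_used, x$n_excluded))
  cat(sprintf("  K_q = K_SV/tau0 = %s 1/(M s) (tau0 = %g ns) -> %s quenching\n",
              fmt_sci(x$K_q), x$tau0_ns, x$mechanism))
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) object

#' @export
coef.sv_fit <- function(object, ...) {
  c(f_a = object$f_a, K_SV = object$K_SV, K_q = object$K_q)
}

#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  Q_M <- if (is.null(newdata)) 1 / object$x
         else if (is.data.frame(newdata)) newdata$Q_uM * 1e-6
         else as.numeric(newdata)
  unname((1 - object$f_a) + object$f_a / (1 + object$K_SV * Q_M))
}

#' @export
plot.sv_fit <- function(x, ..., xlab = "1/[Q] (1/M)",
                        ylab = expression(F[0] / (F[0] - F))) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 16, ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' \eqn{K_q = K_{SV} / \tau_0}, with the lifetime supplied in ns (Table-style
#' convention) and converted to seconds internally.
#'
#' @param K_SV Stern-Volmer quenching constant (1/M).
#' @param tau0_ns Unquenched fluorophore lifetime in ns (default 2.5).
#' @return \eqn{K_q} in 1/(M s).
#' @export
#' @examples
#' bimolecular_quenching_constant(1.70e4, 2.5)  # 6.8e12
bimolecular_quenching_constant <- function(K_SV, tau0_ns = 2.5) {
  if (any(tau0_ns <= 0))
    stop_memfluor("tau0 must be positive", "invalid_parameter")
  K_SV / (tau0_ns * 1e-9)
}

#' Classify the quenching mechanism
#'
#' Compares the bimolecular quenching rate constant against the maximum
#' scatter-collision (diffusion-limited) rate constant of dynamic quenching,
#' \eqn{2 \times 10^{10}} 1/(M s): values strictly above the bound indicate
#' static (complex-forming) quenching, values at or below it dynamic
#' quenching. The ratio \eqn{K_q / \mathrm{threshold}} is attached as the
#' `margin` attribute.
#'
#' @param K_q Non-negative bimolecular quenching rate constant(s), 1/(M s).
#' @param threshold Diffusion-limited bound (default `2e10`).
#' @return Character vector (`"static"`/`"dynamic"`) with attribute
#'   `margin`.
#' @export
#' @examples
#' classify_mechanism(6.8e12)  # static
classify_mechanism <- function(K_q, threshold = 2e10) {
  if (any(K_q < 0))
    stop_memfluor("K_q must be non-negative", "invalid_parameter")
  out <- ifelse(K_q > threshold, "static", "dynamic")
  attr(out, "margin") <- K_q / threshold
  out
}

#' Scatchard double-logarithmic binding fit
#'
#' Ordinary least squares on the double-log form of static-quenching
#' binding,
#' \deqn{\log_{10}\!\left(\frac{F_0}{F} - 1\right) = \log_{10} K_a +
#'   n \log_{10} [Q],}
#' yielding the binding constant \eqn{K_a = 10^{\mathrm{intercept}}} (1/M)
#' and the number of binding sites per protein molecule
#' \eqn{n = \mathrm{slope}}. Points with \eqn{F_0/F - 1 \le 0} (no net
#' quenching) are excluded and counted.
#'
#' Under multiplicative intensity noise the log ordinate has
#' \eqn{\mathrm{SD}(y_i) \propto F_0 / (F_0 - F_i)} (delta method), so the
#' default `weights = "model"` uses inverse-variance weights
#' \eqn{w_i = ((F_0 - F_i)/F_0)^2}; `weights = "none"` reproduces the plain
#' graphical regression. Note that \eqn{K_a} extrapolates the fitted line
#' to \eqn{[Q] = 1} M — several decades outside a micromolar titration —
#' so its sampling error is inherently about an order of magnitude larger
#' (relatively) than the slope's.
#'
#' @param series A [titration_series].
#' @param weights `"model"` (inverse-variance, default) or `"none"`.
#' @return Object of class `scatchard_fit` with components `K_a` (1/M),
#'   `n`, `R` (Pearson correlation of the log-log scatter),
#'   `n_points_used`, `n_excluded` and the underlying `lm` fit.
#' @export
scatchard_fit <- function(series, weights = c("model", "none")) {
  stopifnot(inherits(series, "titration_series"))
  weights <- match.arg(weights)
  F0 <- series$intensity[series$Q_uM == 0]
  ratio <- F0 / series$intensity - 1
  use <- series$Q_uM > 0 & ratio > 0
  n_excluded <- sum(series$Q_uM > 0) - sum(use)
  if (sum(use) < 3L)
    stop_memfluor("fewer than 3 usable titration points (Q > 0, F0/F - 1 > 0)",
                  "insufficient_data")
  x <- log10(series$Q_M[use])
  y <- log10(ratio[use])
  w <- if (weights == "model") ((F0 - series$intensity[use]) / F0)^2
       else rep(1, length(y))
  fit <- lm(y ~ x, weights = w)
  b <- unname(coef(fit))
  structure(
    list(K_a = 10^b[1L], n = b[2L], R = stats::cor(x, y),
         intercept = b[1L], slope = b[2L],
         n_points_used = sum(use), n_excluded = n_excluded,
         weights = weights, quencher = series$quencher, lm = fit,
         x = x, y = y),
    class = "scatchard_fit"
  )
}

#' @export
print.scatchard_fit <- function(x, ...) {
  cat(sprintf("Scatchard double-log fit ('%s')\n", x$quencher))
  cat(sprintf("  K_a = %s 1/M,  n = %.3f sites,  R = %.4f (n = %d, excluded %d)\n",
              fmt_sci(x$K_a), x$n, x$R, x$n_points_used, x$n_excluded))
  invisible(x)
}

#' @export
coef.scatchard_fit <- function(object, ...) c(K_a = object$K_a, n = object$n)

#' @export
plot.scatchard_fit <- function(x, ..., xlab = "log10 [Q] (M)",
                               ylab = expression(log[10](F[0]/F - 1))) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 16, ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Direct nonlinear Stern-Volmer fit (cross-check)
#'
#' Nonlinear least-squares fit of the untransformed accessible-fraction
#' quenching model \eqn{F(Q) = F_0 [(1 - f_a) + f_a / (1 + K_{SV} Q)]}
#' with \eqn{F_0} fixed at the measured zero-quencher intensity. This is an
#' independent route to \eqn{(f_a, K_{SV})} used to cross-check the
#' linearised fit of [stern_volmer_fit()]; the linearised fit remains the
#' default analysis because it mirrors the conventional transformed plots.
#'
#' @param series A [titration_series].
#' @return Named list with `f_a` and `K_SV` (1/M).
#' @export
stern_volmer_fit_nls <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  F0 <- series$intensity[series$Q_uM == 0]
  d <- data.frame(Q = series$Q_M[series$Q_uM > 0],
                  F = series$intensity[series$Q_uM > 0])
  if (nrow(d) < 3L)
    stop_memfluor("fewer than 3 titration points with Q > 0", "insufficient_data")
  fit <- minpack.lm::nlsLM(
    F ~ F0 * ((1 - fa) + fa / (1 + K * Q)), data = d,
    start = list(fa = 0.9, K = 1 / stats::median(d$Q)),
    lower = c(fa = 1e-6, K = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  list(f_a = unname(cf["fa"]), K_SV = unname(cf["K"]))
}

#' Emission-maximum shift along a titration
#'
#' Maximum displacement of the emission maximum across titration points
#' relative to the zero-quencher spectrum. A shift beyond the tolerance
#' (default 2 nm, about twice the acquisition step) suggests a change in
#' the fluorophore microenvironment or protein conformation; its absence
#' supports pure proximity quenching.
#'
#' @param series A [titration_series] carrying full spectra. An
#'   intensity-only series yields a not-applicable result (not an error).
#' @param tolerance_nm Shift tolerance in nm (default 2).
#' @return List with `applicable`, `max_shift_nm`, `shifted`, and the
#'   per-point `lambda_max` values (nm) when applicable.
#' @export
detect_emission_shift <- function(series, tolerance_nm = 2) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$spectra))
    return(list(applicable = FALSE, max_shift_nm = NA_real_, shifted = NA))
  lam <- vapply(series$spectra, function(sp) peak_emission(sp)$lambda_max,
                numeric(1L))
  lam0 <- lam[series$Q_uM == 0]
  max_shift <- max(abs(lam - lam0))
  list(applicable = TRUE, max_shift_nm = max_shift,
       shifted = max_shift > tolerance_nm, lambda_max = lam)
}

#' Inner-filter risk check from molar absorption coefficients
#'
#' Ratio of the protein's molar absorption coefficient at the excitation
#' wavelength to the compound's. A large ratio (the default guard is 10)
#' means the titrant absorbs negligibly at the excitation wavelength and
#' the apparent quenching is not an inner-filter artefact.
#'
#' @param epsilon_protein,epsilon_compound Positive molar absorption
#'   coefficients, 1/(M cm), at the excitation wavelength.
#' @param warn_below Flag threshold on the ratio (default 10).
#' @return List with `ratio` and logical `warning` (TRUE when the ratio is
#'   below `warn_below`, i.e. possible inner-filter contamination).
#' @export
absorption_ratio_check <- function(epsilon_protein, epsilon_compound,
                                   warn_below = 10) {
  if (any(epsilon_protein <= 0) || any(epsilon_compound <= 0))
    stop_memfluor("molar absorption coefficients must be positive",
                  "invalid_parameter")
  ratio <- epsilon_protein / epsilon_compound
  list(ratio = ratio, warning = ratio < warn_below)
}

#' Dilution correction of titration intensities
#'
#' Rescales intensities by \eqn{(V_0 + V_{added}) / V_0} to undo the
#' concentration decrease caused by titrant addition. Off by default in all
#' fits: in the manual-titration protocol emulated here dilution is small
#' and conventionally treated as part of measurement error.
#'
#' @param series A [titration_series] constructed with `V0_L` and
#'   `added_volumes_L`.
#' @return A corrected [titration_series].
#' @export
correct_dilution <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$V0_L) || is.null(series$added_volumes_L))
    stop_memfluor("series carries no volume information", "invalid_parameter")
  if (length(series$added_volumes_L) != length(series$Q_uM))
    stop_memfluor("one cumulative added volume per point is required",
                  "invalid_data")
  factor <- (series$V0_L + series$added_volumes_L) / series$V0_L
  series$intensity <- series$intensity * factor
  series
}

#' Inner-filter correction of titration intensities
#'
#' Applies the standard absorbance-based correction
#' \eqn{F_{corr} = F \cdot 10^{(A_{ex} + A_{em})/2}} per titration point.
#' Off by default in all fits; use [absorption_ratio_check()] to decide
#' whether it is needed.
#'
#' @param series A [titration_series].
#' @param A_ex,A_em Absorbances at the excitation and emission wavelengths,
#'   one per titration point (scalars are recycled).
#' @return A corrected [titration_series].
#' @export
correct_inner_filter <- function(series, A_ex, A_em = 0) {
  stopifnot(inherits(series, "titration_series"))
  if (any(A_ex < 0) || any(A_em < 0))
    stop_memfluor("absorbances must be non-negative", "invalid_data")
  series$intensity <- series$intensity * 10^((A_ex + A_em) / 2)
  series
}
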