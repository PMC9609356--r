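# Seedable forward-model generators. Every generator/analyzer pair is an
# exact round trip at zero noise; all randomness is confined to `seed`.

#' Simulate a tryptophan-quenching titration
#'
#' Forward model of the accessible-fraction (modified Stern-Volmer)
#' quenching law,
#' \deqn{F(Q) = F_0 [(1 - f_a) + f_a / (1 + K_{SV} Q)],}
#' rendered as single-band emission spectra: a Gaussian band (default
#' centre 328 nm, SD 25 nm — the tryptophan band of serum transferrin
#' excited at 295 nm) on the 310-500 nm, 1 nm grid, scaled to \eqn{F(Q)}.
#' Multiplicative Gaussian noise is applied per grid point and per raw
#' scan; each emitted spectrum is the average of `n_scans` raw scans
#' (default 3, the conventional acquisition), recorded in
#' `n_scans_averaged`. An optional linear peak drift (reaching
#' `peak_drift_nm` at the highest Q) emulates a polarity change of the
#' fluorophore environment.
#'
#' @param f_a Accessible fraction, in (0, 1].
#' @param K_SV Stern-Volmer constant, 1/M, positive.
#' @param F0_level Unquenched peak intensity (a.u.).
#' @param Q_uM Quencher grid in uM including 0 (default 0-50 in steps of 5,
#'   the conventional titration design).
#' @param band_center_nm,band_sd_nm Gaussian band centre and width (nm).
#' @param peak_drift_nm Band-centre displacement at the highest Q (nm).
#' @param noise_sd Per-scan multiplicative noise SD as a fraction
#'   (default 0.01).
#' @param n_scans Raw scans averaged per titration point (default 3).
#' @param tau0_ns Lifetime metadata passed to the series (default 2.5 ns).
#' @param spectra If `FALSE`, return peak intensities only.
#' @param seed Optional RNG seed.
#' @param quencher Label for the series.
#' @return A [titration_series].
#' @export
#' @examples
#' ts <- simulate_titration(f_a = 1, K_SV = 2e4, Q_uM = c(0, 50), noise_sd = 0)
#' relative_intensity(ts)$F_over_F0[2]  # 0.5
simulate_titration <- function(f_a = 1, K_SV = 2.5e4, F0_level = 1000,
                               Q_uM = seq(0, 50, by = 5),
                               band_center_nm = 328, band_sd_nm = 25,
                               peak_drift_nm = 0, noise_sd = 0.01,
                               n_scans = 3L, tau0_ns = 2.5, spectra = TRUE,
                               seed = NULL, quencher = "compound") {
  if (!is_number(f_a) || f_a < 0 || f_a > 1)
    stop_memfluor("f_a must lie in [0, 1]", "invalid_parameter")
  if (!is_number(K_SV) || K_SV <= 0)
    stop_memfluor("K_SV must be positive", "invalid_parameter")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_memfluor("noise_sd must be non-negative", "invalid_parameter")
  if (!is_number(n_scans) || n_scans < 1)
    stop_memfluor("n_scans must be a positive count", "invalid_parameter")
  n_scans <- as.integer(n_scans)
  Q_M <- Q_uM * 1e-6
  Fq <- F0_level * ((1 - f_a) + f_a / (1 + K_SV * Q_M))
  # mean of n_scans independent multiplicative noise draws
  scan_noise <- function(npts) {
    if (noise_sd == 0) return(rep(1, npts))
    1 + rowMeans(matrix(rnorm(npts * n_scans, sd = noise_sd),
                        nrow = npts, ncol = n_scans))
  }
  with_seed(seed, {
    if (spectra) {
      wl <- seq(310, 500, by = 1)
      drift <- if (max(Q_uM) > 0) peak_drift_nm * Q_uM / max(Q_uM)
               else rep(0, length(Q_uM))
      sps <- lapply(seq_along(Q_uM), function(i) {
        centre <- band_center_nm + drift[i]
        y <- Fq[i] * exp(-((wl - centre)^2) / (2 * band_sd_nm^2))
        y <- y * scan_noise(length(y))
        emission_spectrum(wl, y, excitation_nm = 295,
                          n_scans_averaged = n_scans)
      })
      titration_series(Q_uM, spectra = sps, tau0_ns = tau0_ns,
                       quencher = quencher)
    } else {
      y <- Fq * scan_noise(length(Fq))
      titration_series(Q_uM, intensities = y, tau0_ns = tau0_ns,
                       quencher = quencher)
    }
  })
}

#' Simulate a polarized-intensity reading
#'
#' Inverts the anisotropy definition: for true anisotropy `A_true` and
#' total intensity \eqn{I_T = I_\parallel + 2 G I_\perp},
#' \eqn{I_\parallel = I_T (1 + 2 A) / 3} and
#' \eqn{I_\perp = I_T (1 - A) / (3 G)}, plus multiplicative channel noise.
#' At zero noise [anisotropy()] recovers `A_true` exactly.
#'
#' @param A_true True anisotropy in \eqn{[-0.5, 1]}.
#' @param total_intensity Total intensity \eqn{I_T} (a.u.).
#' @param G Apparatus constant (> 0).
#' @param noise_sd Multiplicative noise SD (fraction).
#' @param n Number of replicate readings.
#' @param seed Optional RNG seed.
#' @return List with numeric vectors `I_parallel`, `I_perpendicular` and
#'   scalar `G`.
#' @export
simulate_polarized <- function(A_true, total_intensity = 1000, G = 1,
                               noise_sd = 0, n = 1L, seed = NULL) {
  if (!is_number(A_true) || A_true < -0.5 || A_true > 1)
    stop_memfluor("A_true must lie in [-0.5, 1]", "invalid_parameter")
  if (!is_number(G) || G <= 0)
    stop_memfluor("G must be positive", "invalid_parameter")
  Ipar <- total_intensity * (1 + 2 * A_true) / 3
  Iperp <- total_intensity * (1 - A_true) / (3 * G)
  with_seed(seed, {
    noise1 <- if (noise_sd > 0) 1 + rnorm(n, sd = noise_sd) else rep(1, n)
    noise2 <- if (noise_sd > 0) 1 + rnorm(n, sd = noise_sd) else rep(1, n)
    list(I_parallel = pmax(Ipar * noise1, 0),
         I_perpendicular = pmax(Iperp * noise2, 0), G = G)
  })
}

#' Simulate a Laurdan two-channel reading
#'
#' Inverts the GP definition: \eqn{I_b = I_T (1 + GP)/2},
#' \eqn{I_r = I_T (1 - GP)/2}, plus multiplicative channel noise. At zero
#' noise [generalized_polarization()] recovers `GP_true` exactly.
#'
#' @param GP_true True generalized polarization in \eqn{[-1, 1]}.
#' @param total_intensity Total intensity \eqn{I_b + I_r} (a.u.).
#' @param noise_sd Multiplicative noise SD (fraction).
#' @param n Number of replicate readings.
#' @param seed Optional RNG seed.
#' @return List with numeric vectors `I_440` and `I_490`.
#' @export
simulate_gp <- function(GP_true, total_intensity = 1000, noise_sd = 0,
                        n = 1L, seed = NULL) {
  if (!is_number(GP_true) || GP_true < -1 || GP_true > 1)
    stop_memfluor("GP_true must lie in [-1, 1]", "invalid_parameter")
  Ib <- total_intensity * (1 + GP_true) / 2
  Ir <- total_intensity * (1 - GP_true) / 2
  with_seed(seed, {
    noise1 <- if (noise_sd > 0) 1 + rnorm(n, sd = noise_sd) else rep(1, n)
    noise2 <- if (noise_sd > 0) 1 + rnorm(n, sd = noise_sd) else rep(1, n)
    list(I_440 = pmax(Ib * noise1, 0), I_490 = pmax(Ir * noise2, 0))
  })
}

#' Simulate an osmotic-fragility curve
#'
#' Decreasing logistic hemolysis-versus-NaCl law
#' \eqn{H(c) = 100 / (1 + \exp((c - c_{50})/s))} with additive Gaussian
#' noise (percentage points), clamped to \eqn{[0, 100]}. Defaults emulate
#' the conventional assay design: NaCl 0.5-0.9% w/v in 0.05 steps, three
#' replicates, 2 percentage-point noise.
#'
#' @param c50 Midpoint NaCl concentration (% w/v).
#' @param steepness Logistic scale `s` (> 0, % NaCl).
#' @param nacl_grid NaCl grid (% w/v), within (0, 2].
#' @param replicates Replicates per NaCl level.
#' @param noise_sd Additive noise SD in percentage points.
#' @param seed Optional RNG seed.
#' @param treatment,concentration_uM Metadata for the curve.
#' @return A [fragility_curve].
#' @export
simulate_fragility <- function(c50 = 0.65, steepness = 0.03,
                               nacl_grid = seq(0.5, 0.9, by = 0.05),
                               replicates = 3L, noise_sd = 2, seed = NULL,
                               treatment = "treated",
                               concentration_uM = NA_real_) {
  if (!is_number(steepness) || steepness <= 0)
    stop_memfluor("steepness must be positive", "invalid_parameter")
  if (any(nacl_grid <= 0 | nacl_grid > 2))
    stop_memfluor("NaCl grid must lie in (0, 2] % w/v", "invalid_parameter")
  H <- 100 / (1 + exp((nacl_grid - c50) / steepness))
  with_seed(seed, {
    d <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      h <- H
      if (noise_sd > 0) h <- h + rnorm(length(h), sd = noise_sd)
      data.frame(nacl_percent = nacl_grid, replicate = r,
                 hemolysis_percent = pmin(pmax(h, 0), 100))
    }))
    fragility_curve(d, treatment = treatment,
                    concentration_uM = concentration_uM)
  })
}

#' Simulate an erythrocyte shape-count table
#'
#' Multinomial counts over the eight Bessis-Brecher shape categories for
#' each replicate (default total about 500 cells, the usual population
#' counted per micrograph set). The default proportions describe a healthy
#' control population: predominantly discocytes with a small echinocytic
#' tail and negligible (<2%) shares of the remaining forms.
#'
#' @param proportions Numeric vector of length 8 (or named over
#'   [SHAPE_CATEGORIES]) summing to 1 within 1e-9.
#' @param total Cells counted per replicate.
#' @param replicates Number of replicates.
#' @param seed Optional RNG seed.
#' @param treatment Treatment label.
#' @return A [morphology_table].
#' @export
simulate_morphology <- function(proportions = c(D = 0.88, SS = 0.005,
                                                S = 0.005, DS = 0.003,
                                                DE = 0.06, E = 0.03,
                                                SE = 0.015, ES = 0.002),
                                total = 500L, replicates = 3L, seed = NULL,
                                treatment = "treated") {
  if (!is.null(names(proportions))) {
    if (!setequal(names(proportions), SHAPE_CATEGORIES))
      stop_memfluor("proportion names must be the 8 shape categories",
                    "invalid_parameter")
    proportions <- proportions[SHAPE_CATEGORIES]
  }
  if (length(proportions) != length(SHAPE_CATEGORIES))
    stop_memfluor("8 category proportions are required", "invalid_parameter")
  if (any(proportions < 0))
    stop_memfluor("proportions must be non-negative", "invalid_parameter")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_memfluor("proportions must sum to 1 (tolerance 1e-9)",
                  "invalid_parameter")
  with_seed(seed, {
    counts <- rmultinom(replicates, size = total, prob = proportions)
    d <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(replicate = r, category = SHAPE_CATEGORIES,
                 count = counts[, r], stringsAsFactors = FALSE)
    }))
    morphology_table(d, treatment = treatment)
  })
}
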