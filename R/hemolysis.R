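#' Percent hemolysis from 540 nm absorbance
#'
#' Hemoglobin released into the supernatant, expressed as a percentage of
#' the hemoglobin of totally hemolysed cells:
#' \eqn{100 \cdot A_{540}^{sample} / A_{540}^{total}}. Values marginally
#' outside \eqn{[0, 100]} (assay noise) are clamped with an `out_of_range`
#' attribute flag rather than rejected.
#'
#' @param A540_sample Non-negative absorbance of the sample supernatant.
#' @param A540_total Positive absorbance of the fully hemolysed reference.
#' @return Numeric vector of hemolysis percentages in \eqn{[0, 100]}, with
#'   attribute `out_of_range` marking clamped entries.
#' @export
#' @examples
#' percent_hemolysis(0.27, 0.90)  # 30
percent_hemolysis <- function(A540_sample, A540_total) {
  if (any(A540_total <= 0))
    stop_memfluor("reference absorbance A540_total must be positive",
                  "reference_error")
  if (any(A540_sample < 0))
    stop_memfluor("absorbances must be non-negative", "invalid_data")
  h <- 100 * A540_sample / A540_total
  oor <- h < 0 | h > 100
  h <- pmin(pmax(h, 0), 100)
  attr(h, "out_of_range") <- oor
  h
}

#' Construct an osmotic-fragility curve
#'
#' Holds replicate hemolysis percentages over a series of NaCl
#' concentrations (w/v %) for one treatment, the raw material of an osmotic
#' fragility experiment (typically NaCl 0.5-0.9%, three replicates).
#' Hemolysis values up to 2 percentage points outside \eqn{[0, 100]} are
#' clamped (assay noise); larger excursions are rejected.
#'
#' @param data Data frame with columns `nacl_percent`, `replicate`,
#'   `hemolysis_percent`.
#' @param treatment Treatment label.
#' @param concentration_uM Compound concentration in uM (metadata).
#' @return Object of class `fragility_curve`: the replicate `data`, a
#'   per-NaCl `summary` (mean, sd, n) sorted by decreasing NaCl, and
#'   metadata.
#' @export
fragility_curve <- function(data, treatment = "treated",
                            concentration_uM = NA_real_) {
  stopifnot(is.data.frame(data))
  req <- c("nacl_percent", "replicate", "hemolysis_percent")
  if (!all(req %in% names(data)))
    stop_memfluor("data needs columns nacl_percent, replicate, hemolysis_percent",
                  "invalid_data")
  if (any(data$nacl_percent <= 0 | data$nacl_percent > 2))
    stop_memfluor("NaCl concentrations must lie in (0, 2] % w/v", "invalid_data")
  h <- data$hemolysis_percent
  if (any(h < -2 | h > 102))
    stop_memfluor("hemolysis percentages outside [-2, 102] are not plausible assay noise",
                  "invalid_data")
  clamped <- h < 0 | h > 100
  data$hemolysis_percent <- pmin(pmax(h, 0), 100)
  summ <- do.call(rbind, lapply(split(data, data$nacl_percent), function(d) {
    data.frame(nacl_percent = d$nacl_percent[1L], n = nrow(d),
               mean = mean(d$hemolysis_percent),
               sd = if (nrow(d) > 1L) sd(d$hemolysis_percent) else NA_real_)
  }))
  summ <- summ[order(summ$nacl_percent, decreasing = TRUE), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(data = data, summary = summ, treatment = treatment,
                 concentration_uM = concentration_uM,
                 clamped = any(clamped)),
            class = "fragility_curve")
}

#' @export
print.fragility_curve <- function(x, ...) {
  cat(sprintf("Osmotic fragility curve: '%s'", x$treatment))
  if (is.finite(x$concentration_uM))
    cat(sprintf(" at %g uM", x$concentration_uM))
  cat(sprintf(", %d NaCl levels\n", nrow(x$summary)))
  s <- x$summary; s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fragility_curve <- function(x, ..., xlab = "NaCl (% w/v)",
                                 ylab = "Hemolysis (%)") {
  s <- x$summary
  plot(s$nacl_percent, s$mean, type = "b", pch = 16, ylim = c(0, 100),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Fit the midpoint (C50) of an osmotic-fragility curve
#'
#' Least-squares fit of the two-parameter decreasing logistic
#' \deqn{H(c) = 100 / (1 + \exp((c - c_{50}) / s)), \quad s > 0,}
#' to replicate hemolysis data. `c50` is the NaCl concentration (% w/v) at
#' 50% hemolysis — the standard osmotic fragility index — and `s` the
#' transition steepness. The fit requires at least 4 NaCl levels whose mean
#' hemolysis spans both the low (<20%) and high (>80%) plateaus, otherwise
#' the midpoint is not identifiable.
#'
#' @param curve A [fragility_curve].
#' @return Object of class `fragility_fit` with components `coefficients`
#'   (`c50`, `s`), `fitted`, `residuals`, `data`, and the underlying
#'   [minpack.lm::nlsLM] fit.
#' @export
fit_c50 <- function(curve) {
  stopifnot(inherits(curve, "fragility_curve"))
  s <- curve$summary
  if (nrow(s) < 4L)
    stop_memfluor("at least 4 NaCl levels are required", "insufficient_data")
  if (!any(s$mean < 20) || !any(s$mean > 80))
    stop_memfluor("curve must span both <20% and >80% hemolysis for an identifiable C50",
                  "non_identifiable")
  d <- curve$data
  # start values: interpolate the 50% crossing of the per-NaCl means
  o <- order(s$nacl_percent)
  c50_0 <- stats::approx(s$mean[o], s$nacl_percent[o], xout = 50,
                         ties = "ordered")$y
  if (is.na(c50_0)) c50_0 <- mean(range(s$nacl_percent))
  s_0 <- diff(range(s$nacl_percent)) / 10
  fit <- minpack.lm::nlsLM(
    hemolysis_percent ~ 100 / (1 + exp((nacl_percent - c50) / s)),
    data = d, start = list(c50 = c50_0, s = s_0),
    lower = c(c50 = 0, s = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  structure(list(coefficients = c(c50 = unname(cf["c50"]), s = unname(cf["s"])),
                 fitted = fitted(fit), residuals = residuals(fit),
                 data = d, nls = fit, treatment = curve$treatment),
            class = "fragility_fit")
}

#' @export
print.fragility_fit <- function(x, ...) {
  cat(sprintf("Logistic fragility fit ('%s'): C50 = %.4f %% NaCl, steepness s = %.4f\n",
              x$treatment, x$coefficients["c50"], x$coefficients["s"]))
  invisible(x)
}

#' @export
coef.fragility_fit <- function(object, ...) object$coefficients

#' @export
predict.fragility_fit <- function(object, newdata = NULL, ...) {
  c50 <- object$coefficients["c50"]; s <- object$coefficients["s"]
  cc <- if (is.null(newdata)) object$data$nacl_percent else
    if (is.data.frame(newdata)) newdata$nacl_percent else newdata
  unname(100 / (1 + exp((cc - c50) / s)))
}

#' @export
residuals.fragility_fit <- function(object, ...) object$residuals

#' Compare osmotic resistance of treated cells against control
#'
#' At each NaCl concentration present in both curves, replicate hemolysis
#' values are compared two-sidedly (the many-to-one machinery of
#' [dunnett_many_to_one()], which for a single treated group is the pooled
#' t-test). If any matched point is significant at `alpha`, the overall
#' classification follows the sign of \eqn{c_{50}(treated) -
#' c_{50}(control)}: a left-shifted curve (lower C50) means increased
#' osmotic resistance, a right shift decreased; with no significant point
#' the curves are declared `unchanged` regardless of the C50 sign.
#'
#' @param treated,control [fragility_curve] objects with overlapping NaCl
#'   grids and replicate data.
#' @param alpha Per-comparison significance level (default 0.05).
#' @return Object of class `resistance_comparison`: per-NaCl table
#'   (difference of means, adjusted p, significance), fitted C50s, and the
#'   overall `classification` (`"increased"`, `"decreased"`, `"unchanged"`).
#' @export
compare_resistance <- function(treated, control, alpha = 0.05) {
  stopifnot(inherits(treated, "fragility_curve"),
            inherits(control, "fragility_curve"))
  shared <- intersect(unique(treated$data$nacl_percent),
                      unique(control$data$nacl_percent))
  if (length(shared) == 0L)
    stop_memfluor("fragility curves have disjoint NaCl grids", "comparison_error")
  per <- do.call(rbind, lapply(sort(shared, decreasing = TRUE), function(cc) {
    ht <- treated$data$hemolysis_percent[treated$data$nacl_percent == cc]
    hc <- control$data$hemolysis_percent[control$data$nacl_percent == cc]
    dt <- dunnett_many_to_one(c(hc, ht),
                              rep(c("control", "treated"), c(length(hc), length(ht))),
                              control = "control", alpha = alpha)
    data.frame(nacl_percent = cc,
               diff = dt$comparisons$estimate,
               p_adjusted = dt$comparisons$p_adjusted,
               significant = dt$comparisons$significant)
  }))
  rownames(per) <- NULL
  c50_t <- coef(fit_c50(treated))["c50"]
  c50_c <- coef(fit_c50(control))["c50"]
  classification <- if (!any(per$significant)) "unchanged"
    else if (c50_t < c50_c) "increased" else "decreased"
  structure(list(per_nacl = per, alpha = alpha,
                 c50_treated = unname(c50_t), c50_control = unname(c50_c),
                 classification = classification,
                 treated = treated$treatment, control = control$treatment),
            class = "resistance_comparison")
}

#' @export
print.resistance_comparison <- function(x, ...) {
  cat(sprintf("Osmotic resistance of '%s' vs '%s': %s\n", x$treated,
              x$control, x$classification))
  cat(sprintf("  C50 treated = %.4f, control = %.4f %% NaCl (alpha = %g)\n",
              x$c50_treated, x$c50_control, x$alpha))
  p <- x$per_nacl
  p$diff <- round(p$diff, 2); p$p_adjusted <- signif(p$p_adjusted, 3)
  print(p, row.names = FALSE)
  invisible(x)
}
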