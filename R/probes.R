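#' DPH fluorescence anisotropy
#'
#' Steady-state fluorescence anisotropy from polarized intensities,
#' \deqn{A = (I_\parallel - G I_\perp) / (I_\parallel + 2 G I_\perp),}
#' where `G` is the apparatus (grating) correction factor at the emission
#' wavelength. For the membrane probe DPH, higher anisotropy means lower
#' fluidity of the hydrocarbon-chain region. Values are range-checked
#' against the one-photon physical bounds \eqn{[-0.5, 1]}; out-of-range
#' values raise a data-quality warning, not an error.
#'
#' @param I_parallel,I_perpendicular Non-negative fluorescence intensities
#'   parallel and perpendicular to the excitation polarization (a.u.);
#'   vectors are recycled in the usual way.
#' @param G Apparatus constant, strictly positive (default 1).
#' @return Numeric vector of anisotropies.
#' @export
#' @examples
#' anisotropy(2, 1, G = 1)  # 0.25
anisotropy <- function(I_parallel, I_perpendicular, G = 1) {
  if (any(I_parallel < 0) || any(I_perpendicular < 0))
    stop_memfluor("polarized intensities must be non-negative", "invalid_data")
  if (any(G <= 0))
    stop_memfluor("apparatus constant G must be positive", "invalid_parameter")
  denom <- I_parallel + 2 * G * I_perpendicular
  if (any(denom <= 0))
    stop_memfluor("total intensity I_parallel + 2 G I_perpendicular must be positive",
                  "degenerate_signal")
  A <- (I_parallel - G * I_perpendicular) / denom
  if (any(A < -0.5 - 1e-12 | A > 1 + 1e-12))
    warn_memfluor("anisotropy outside the physical range [-0.5, 1]",
                  "data_quality")
  A
}

#' Laurdan generalized polarization
#'
#' Generalized polarization of the Laurdan probe,
#' \deqn{GP = (I_b - I_r) / (I_b + I_r),}
#' from the blue (440 nm) and red (490 nm) emission channels. GP reports
#' packing/hydration of the lipid head-group region: higher GP means a more
#' ordered, less hydrated interface.
#'
#' @param I_blue,I_red Non-negative intensities at 440 nm and 490 nm (a.u.).
#' @return Numeric vector of GP values in \eqn{[-1, 1]}.
#' @export
#' @examples
#' generalized_polarization(3, 1)  # 0.5
generalized_polarization <- function(I_blue, I_red) {
  if (any(I_blue < 0) || any(I_red < 0))
    stop_memfluor("channel intensities must be non-negative", "invalid_data")
  s <- I_blue + I_red
  if (any(s <= 0))
    stop_memfluor("I_blue + I_red must be positive", "degenerate_signal")
  (I_blue - I_red) / s
}

#' Assemble a concentration-response table of a probe metric
#'
#' Computes the chosen probe metric per replicate reading and summarises it
#' per (treatment, concentration) cell as mean and sample standard
#' deviation, cells ordered by concentration. This is the tabular backbone
#' of membrane dose-response experiments (typical design: compound
#' concentrations 5-30 uM, three replicates, one DMSO control).
#'
#' @param readings Data frame of replicate readings with columns
#'   `treatment`, `concentration_uM`, `replicate`, and either
#'   `I_parallel`, `I_perpendicular` (optionally `G`) for anisotropy,
#'   `I_440`, `I_490` for GP, or a precomputed `value` column.
#' @param metric One of `"anisotropy"`, `"GP"`, or `"value"` (precomputed).
#' @param control Treatment label of the control group (default
#'   `"control"`).
#' @return Object of class `dose_response`: list with the per-replicate
#'   `data` (long format with a `value` column), the per-cell `summary`
#'   (`n`, `mean`, `sd`), the metric name and control label.
#' @export
build_dose_response <- function(readings,
                                metric = c("anisotropy", "GP", "value"),
                                control = "control") {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(readings))
  if (nrow(readings) == 0L)
    stop_memfluor("no readings supplied", "empty_input")
  req <- c("treatment", "concentration_uM")
  if (!all(req %in% names(readings)))
    stop_memfluor("readings need columns treatment and concentration_uM",
                  "invalid_data")
  if (any(readings$concentration_uM < 0))
    stop_memfluor("concentrations must be non-negative", "invalid_data")
  value <- switch(metric,
    anisotropy = {
      G <- if ("G" %in% names(readings)) readings$G else 1
      anisotropy(readings$I_parallel, readings$I_perpendicular, G)
    },
    GP = generalized_polarization(readings$I_440, readings$I_490),
    value = readings$value
  )
  data <- data.frame(
    treatment = as.character(readings$treatment),
    concentration_uM = readings$concentration_uM,
    replicate = if ("replicate" %in% names(readings)) readings$replicate
                else seq_len(nrow(readings)),
    value = value, stringsAsFactors = FALSE
  )
  cell <- interaction(data$treatment, data$concentration_uM, drop = TRUE)
  summ <- do.call(rbind, lapply(split(data, cell), function(d) {
    data.frame(treatment = d$treatment[1L],
               concentration_uM = d$concentration_uM[1L],
               n = nrow(d), mean = mean(d$value),
               sd = if (nrow(d) > 1L) sd(d$value) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$treatment, summ$concentration_uM), , drop = FALSE]
  rownames(summ) <- NULL
  if (any(summ$n < 2L))
    warn_memfluor("some cells have a single replicate: SD undefined",
                  "single_replicate")
  structure(list(data = data, summary = summ, metric = metric,
                 control = control),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response table (%s), control = '%s'\n", x$metric, x$control))
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sd <- signif(s$sd, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dose_response <- function(x, ..., xlab = "Concentration (uM)",
                               ylab = x$metric) {
  s <- x$summary
  trts <- unique(s$treatment)
  cols <- seq_along(trts)
  plot(range(s$concentration_uM), range(c(s$mean - s$sd, s$mean + s$sd),
                                        na.rm = TRUE),
       type = "n", xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(trts)) {
    d <- s[s$treatment == trts[i], ]
    lines(d$concentration_uM, d$mean, col = cols[i], type = "b", pch = 16)
  }
  legend("topleft", legend = trts, col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' @rdname dunnett_many_to_one
#' @param alpha Familywise significance level (0.05 or 0.01 by convention).
#' @export
dunnett_many_to_one.dose_response <- function(x, alpha = 0.05, ...) {
  d <- x$data
  is_ctrl <- d$treatment == x$control
  if (!any(is_ctrl))
    stop_memfluor(sprintf("control group '%s' not present", x$control),
                  "missing_control")
  cell <- ifelse(is_ctrl, x$control,
                 paste0(d$treatment, ":", d$concentration_uM))
  dunnett_many_to_one(d$value, cell, control = x$control, alpha = alpha)
}
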