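#' Dunnett many-to-one comparison against a control
#'
#' Two-sided many-to-one comparison of several treated groups against one
#' shared control with familywise error control, as used throughout the
#' dose-response, fragility and morphology stages. The joint null
#' distribution of the comparison t statistics is multivariate t with the
#' usual product correlation structure
#' \eqn{\rho_{ij} = \sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}}; adjusted
#' p-values and the critical constant are computed from that distribution
#' ([mvtnorm::pmvt()] / [mvtnorm::qmvt()]). With a single treated group the
#' procedure reduces exactly to the two-sample pooled t-test.
#'
#' @param group Factor (or coercible) of group labels, same length as the
#'   observations.
#' @param control Label of the control group. Defaults to the first level.
#' @param alpha Familywise significance level, conventionally 0.05 or 0.01.
#' @return An object of class `dunnett_test`: a list with the per-comparison
#'   table (`comparisons`: estimate, t, adjusted p, decision, flag), the
#'   pooled degrees of freedom, the critical constant at `alpha`, and the
#'   significance flag convention (`**` at 0.01, `*` at 0.05).
#' @export
#' @param x For the default method, a numeric vector of observations; other
#'   methods exist for the package's table classes (see
#'   [build_dose_response()]).
#' @param ... Passed between methods.
#' @examples
#' set.seed(1)
#' g <- rep(c("control", "A", "B"), each = 4)
#' x <- rnorm(12) + (g == "B") * 3
#' dunnett_many_to_one(x, g, control = "control")
dunnett_many_to_one <- function(x, ...) UseMethod("dunnett_many_to_one")

#' @rdname dunnett_many_to_one
#' @export
dunnett_many_to_one.default <- function(x, group, control = NULL,
                                        alpha = 0.05, ...) {
  values <- as.numeric(x)
  group <- as.factor(group)
  if (length(values) != length(group))
    stop_memfluor("values and group lengths differ", "invalid_data")
  if (!alpha %in% c(0.05, 0.01) && !(is_number(alpha) && alpha > 0 && alpha < 1))
    stop_memfluor("alpha must be in (0, 1)", "invalid_parameter")
  lev <- levels(droplevels(group))
  if (is.null(control)) control <- lev[1L]
  if (!control %in% lev)
    stop_memfluor(sprintf("control group '%s' not present", control),
                  "missing_control")
  group <- droplevels(group)
  ns <- table(group)
  if (any(ns < 2L))
    stop_memfluor("every group needs at least 2 replicates", "insufficient_data")
  treated <- setdiff(lev, control)
  k <- length(treated)
  if (k < 1L)
    stop_memfluor("no treated groups to compare", "invalid_data")

  means <- tapply(values, group, mean)
  N <- length(values)
  df <- N - (k + 1L)
  s2 <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / df
  n0 <- ns[[control]]
  ni <- as.numeric(ns[treated])
  est <- as.numeric(means[treated] - means[[control]])
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- est / se

  b <- sqrt(ni / (ni + n0))
  corr <- outer(b, b)
  diag(corr) <- 1

  padj <- dunnett_p_adjust(abs(tstat), corr, df)
  crit <- dunnett_critical(k, corr, df, alpha)

  comparisons <- data.frame(
    group = treated,
    estimate = est,
    se = se,
    t = tstat,
    p_adjusted = padj,
    significant = padj <= alpha,
    flag = ifelse(padj <= 0.01, "**", ifelse(padj <= 0.05, "*", "")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(comparisons = comparisons, control = control, alpha = alpha,
         df = df, pooled_sd = sqrt(s2), critical = crit,
         n = c(setNames(n0, control), setNames(ni, treated))),
    class = "dunnett_test"
  )
}

# Two-sided max-|T| adjusted p-values under the many-to-one multivariate t.
# The quasi-Monte-Carlo integration in mvtnorm is run under a fixed local
# seed so repeated analyses of the same data give identical reports.
dunnett_p_adjust <- function(abs_t, corr, df) {
  k <- nrow(corr)
  if (k == 1L) return(2 * pt(-abs_t, df))
  with_seed(20260923, vapply(abs_t, function(ti) {
    1 - mvtnorm::pmvt(lower = rep(-ti, k), upper = rep(ti, k),
                      df = df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1]
  }, numeric(1L)))
}

# Critical constant c with P(max_i |T_i| <= c) = 1 - alpha.
dunnett_critical <- function(k, corr, df, alpha) {
  if (is_number(corr)) {  # scalar rho shortcut for balanced designs
    rho <- corr
    corr <- matrix(rho, k, k); diag(corr) <- 1
  }
  if (k == 1L) return(qt(1 - alpha / 2, df))
  with_seed(20260923,
    mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = corr,
                  algorithm = mvtnorm::GenzBretz(abseps = 1e-5))$quantile)
}

#' @export
print.dunnett_test <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one comparison vs control '%s' (alpha = %g)\n",
              x$control, x$alpha))
  cat(sprintf("  pooled df = %d, critical |t| = %.4f\n", x$df, x$critical))
  tab <- x$comparisons
  tab$estimate <- signif(tab$estimate, 4)
  tab$t <- signif(tab$t, 4)
  tab$p_adjusted <- signif(tab$p_adjusted, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dunnett_test <- function(object, ...) object

#' Familywise error rate of the Dunnett procedure under the global null
#'
#' Monte-Carlo calibration utility: simulates balanced one-way layouts with
#' all groups drawn from the same normal distribution and reports the
#' fraction of replicates in which any comparison is (wrongly) declared
#' significant. The per-replicate decision rule is the same max-|t| versus
#' critical-constant rule used by [dunnett_many_to_one()].
#'
#' @param k Number of treated groups (the control is additional).
#' @param n Replicates per group.
#' @param alpha Familywise significance level.
#' @param reps Number of simulated replicates.
#' @param seed Optional seed for reproducibility.
#' @return List with the estimated familywise error `fwer`, its Monte-Carlo
#'   standard error `se`, and the critical constant used.
#' @export
simulate_dunnett_fwer <- function(k = 4, n = 3, alpha = 0.05, reps = 5000,
                                  seed = NULL) {
  stopifnot(k >= 1, n >= 2, reps >= 1)
  df <- (k + 1L) * (n - 1L)
  crit <- dunnett_critical(k, 0.5, df, alpha)
  rej <- with_seed(seed, vapply(seq_len(reps), function(r) {
    x <- matrix(rnorm((k + 1L) * n), nrow = n)
    m <- colMeans(x)
    s2 <- sum((x - rep(m, each = n))^2) / df
    tmax <- max(abs(m[-1L] - m[1L])) / sqrt(s2 * 2 / n)
    tmax > crit
  }, logical(1L)))
  fwer <- mean(rej)
  list(fwer = fwer, se = sqrt(fwer * (1 - fwer) / reps), critical = crit,
       reps = reps, alpha = alpha)
}
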