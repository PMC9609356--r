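#' Erythrocyte shape categories
#'
#' The fixed, ordered label set of the Bessis-Brecher shape scale used
#' throughout the morphology stage: discocytes (D), spherocytes (SS),
#' stomatocytes (S), discostomatocytes (DS), discoechinocytes (DE),
#' echinocytes (E), spheroechinocytes (SE), and spherocytes arising from
#' spheroechinocyte transformation (ES).
#'
#' @export
SHAPE_CATEGORIES <- c("D", "SS", "S", "DS", "DE", "E", "SE", "ES")

#' Construct an erythrocyte shape-count table
#'
#' Per-replicate counts of cells in each of the eight shape categories for
#' one treatment; population totals of roughly 500 cells per replicate are
#' typical. Categories absent from the input get a zero count.
#'
#' @param counts Data frame with columns `replicate`, `category`, `count`
#'   (non-negative integers; `category` drawn from [SHAPE_CATEGORIES]).
#' @param treatment Treatment label.
#' @return Object of class `morphology_table`: a replicate-by-category count
#'   matrix, per-replicate totals, and the treatment label.
#' @export
morphology_table <- function(counts, treatment = "treated") {
  stopifnot(is.data.frame(counts))
  req <- c("replicate", "category", "count")
  if (!all(req %in% names(counts)))
    stop_memfluor("counts needs columns replicate, category, count", "invalid_data")
  if (!all(counts$category %in% SHAPE_CATEGORIES))
    stop_memfluor(paste("unknown shape category; allowed:",
                        paste(SHAPE_CATEGORIES, collapse = ", ")),
                  "invalid_data")
  ct <- counts$count
  if (any(ct < 0) || any(ct != round(ct)))
    stop_memfluor("counts must be non-negative integers", "invalid_data")
  reps <- unique(counts$replicate)
  mat <- matrix(0L, nrow = length(reps), ncol = length(SHAPE_CATEGORIES),
                dimnames = list(as.character(reps), SHAPE_CATEGORIES))
  for (i in seq_len(nrow(counts)))
    mat[as.character(counts$replicate[i]), counts$category[i]] <-
      mat[as.character(counts$replicate[i]), counts$category[i]] +
      as.integer(counts$count[i])
  totals <- rowSums(mat)
  structure(list(counts = mat, totals = totals, treatment = treatment),
            class = "morphology_table")
}

#' @export
print.morphology_table <- function(x, ...) {
  cat(sprintf("Shape-count table '%s': %d replicate(s), totals %s cells\n",
              x$treatment, nrow(x$counts),
              paste(x$totals, collapse = "/")))
  print(x$counts)
  invisible(x)
}

#' Per-category percentage shares of a shape population
#'
#' Converts per-replicate counts to percentage shares (each replicate's
#' shares sum to 100) and summarises them as mean and sample SD per
#' category over replicates.
#'
#' @param table A [morphology_table]; every replicate total must be
#'   positive.
#' @return Object of class `shape_shares`: the replicate-by-category share
#'   matrix (`shares`, in percent) and a per-category `summary` data frame
#'   (`mean`, `sd`, `n`).
#' @export
shape_shares <- function(table) {
  stopifnot(inherits(table, "morphology_table"))
  if (any(table$totals <= 0))
    stop_memfluor("every replicate must contain at least one counted cell",
                  "invalid_data")
  shares <- 100 * sweep(table$counts, 1, table$totals, "/")
  summ <- data.frame(
    category = SHAPE_CATEGORIES,
    mean = colMeans(shares),
    sd = if (nrow(shares) > 1L) apply(shares, 2, sd) else NA_real_,
    n = nrow(shares), row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(shares = shares, summary = summ, treatment = table$treatment),
            class = "shape_shares")
}

#' @export
print.shape_shares <- function(x, ...) {
  cat(sprintf("Shape shares '%s' (%% of population):\n", x$treatment))
  s <- x$summary
  s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Compare shape-category shares against a control population
#'
#' Per category, replicate shares of treated and control populations are
#' compared two-sidedly with the Dunnett machinery (a pooled t-test for the
#' single-treatment case). Shares are arcsine-square-root transformed before
#' testing to stabilise the variance of proportions
#' (`transform = "none"` switches this off). Rare categories — share below
#' 2% in both groups — are still tested but marked `rare`, and the print
#' method collapses them into an "other" row.
#'
#' @param treated,control [morphology_table] objects with at least 2 (by
#'   design 3 or more) replicates each.
#' @param alpha Significance level (default 0.01, the convention for
#'   morphology flags).
#' @param transform `"asinsqrt"` (default) or `"none"`.
#' @return Object of class `shape_comparison`: per-category table with mean
#'   shares, difference, adjusted p-value, `significant`, flag, and `rare`
#'   marker.
#' @export
compare_shapes <- function(treated, control, alpha = 0.01,
                           transform = c("asinsqrt", "none")) {
  stopifnot(inherits(treated, "morphology_table"),
            inherits(control, "morphology_table"))
  transform <- match.arg(transform)
  if (nrow(treated$counts) < 2L || nrow(control$counts) < 2L)
    stop_memfluor("at least 2 replicates per group are required", "statistical_error")
  sh_t <- shape_shares(treated)$shares
  sh_c <- shape_shares(control)$shares
  tf <- switch(transform,
               asinsqrt = function(p) asin(sqrt(pmin(pmax(p / 100, 0), 1))),
               none = function(p) p)
  rows <- lapply(SHAPE_CATEGORIES, function(cat) {
    vt <- tf(sh_t[, cat]); vc <- tf(sh_c[, cat])
    if (sd(c(vt, vc)) == 0) {
      p <- 1  # identical constant shares: no evidence of difference
    } else {
      dt <- dunnett_many_to_one(c(vc, vt),
                                rep(c("control", "treated"),
                                    c(length(vc), length(vt))),
                                control = "control", alpha = alpha)
      p <- dt$comparisons$p_adjusted
    }
    data.frame(category = cat,
               mean_control = mean(sh_c[, cat]),
               mean_treated = mean(sh_t[, cat]),
               diff = mean(sh_t[, cat]) - mean(sh_c[, cat]),
               p_adjusted = p,
               significant = p <= alpha,
               flag = ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")),
               rare = max(mean(sh_t[, cat]), mean(sh_c[, cat])) < 2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, transform = transform,
                 treated = treated$treatment, control = control$treatment),
            class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, collapse_rare = TRUE, ...) {
  cat(sprintf("Shape comparison '%s' vs '%s' (alpha = %g, transform = %s)\n",
              x$treated, x$control, x$alpha, x$transform))
  tab <- x$table
  if (collapse_rare && any(tab$rare)) {
    rare <- tab[tab$rare, , drop = FALSE]
    main <- tab[!tab$rare, , drop = FALSE]
    other <- data.frame(category = "other",
                        mean_control = sum(rare$mean_control),
                        mean_treated = sum(rare$mean_treated),
                        diff = sum(rare$diff),
                        p_adjusted = NA_real_,
                        significant = any(rare$significant),
                        flag = if (any(rare$significant)) "(see detail)" else "",
                        rare = TRUE, stringsAsFactors = FALSE)
    tab <- rbind(main, other)
  }
  num <- c("mean_control", "mean_treated", "diff")
  tab[num] <- lapply(tab[num], round, 2)
  tab$p_adjusted <- signif(tab$p_adjusted, 3)
  print(tab[, setdiff(names(tab), "rare")], row.names = FALSE)
  invisible(x)
}
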