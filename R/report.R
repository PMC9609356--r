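#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages in dependency order — `quench`
#' (titration, Stern-Volmer, Scatchard, mechanism), `probes`
#' (anisotropy/GP dose-response with Dunnett flags), `hemolysis`
#' (fragility curves, C50, resistance classification), `morphology`
#' (shape shares and comparison) — and assembles an `analysis_report`
#' whose parameter tables mirror the conventional reporting columns
#' (K_SV, R*, K_q, K_a, R**, n) and whose significance flags carry the
#' `*`/`**` alpha convention. All randomness flows from the single
#' top-level `seed` via per-stage derived streams, so equal configurations
#' give identical report bodies.
#'
#' @param config Named list, or path to a YAML file, with optional
#'   top-level `seed` and one section per stage:
#'   * `quench`: either `input` (titration CSV) or `simulate` (arguments
#'     for [simulate_titration()]), plus optional `tau0_ns`.
#'   * `probes`: `input` (readings CSV) or `simulate`
#'     (`metric`, `A_true`/`GP_true` per treatment), plus `metric`,
#'     `control`, `alpha`.
#'   * `hemolysis`: `input` (fragility CSV) or `simulate` (named lists of
#'     [simulate_fragility()] arguments), plus `control`, `alpha`.
#'   * `morphology`: `input` (counts CSV) or `simulate` (named lists of
#'     [simulate_morphology()] arguments), plus `control`, `alpha`.
#' @return Object of class `analysis_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_memfluor(sprintf("config file not found: %s", config), "io_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0L)
    stop_memfluor("empty configuration: name at least one stage", "usage_error")
  stages <- intersect(c("quench", "probes", "hemolysis", "morphology"),
                      names(config))
  if (length(stages) == 0L)
    stop_memfluor("configuration names no known stage", "usage_error")
  seed <- config$seed
  out <- list()
  for (i in seq_along(stages)) {
    st <- stages[i]
    stage_seed <- derive_seed(seed, i)
    out[[st]] <- tryCatch(
      switch(st,
             quench = stage_quench(config[[st]], stage_seed),
             probes = stage_probes(config[[st]], stage_seed),
             hemolysis = stage_hemolysis(config[[st]], stage_seed),
             morphology = stage_morphology(config[[st]], stage_seed)),
      memfluor_error = function(e) stop(errorCondition(
        sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
        class = c(class(e)[1L], "stage_failure", "memfluor_error"))))
  }
  structure(
    list(stages = out,
         provenance = list(
           seed = if (is.null(seed)) NA else seed,
           stages_run = stages,
           config = config,
           package_version = as.character(utils::packageVersion("memfluor")))),
    class = "analysis_report"
  )
}

stage_quench <- function(cfg, seed) {
  tau0 <- if (!is.null(cfg$tau0_ns)) cfg$tau0_ns else 2.5
  series <- if (!is.null(cfg$input)) {
    read_titration_csv(cfg$input, tau0_ns = tau0)
  } else if (!is.null(cfg$simulate)) {
    do.call(simulate_titration,
            modifyList(list(tau0_ns = tau0, seed = seed), cfg$simulate))
  } else stop_memfluor("quench stage needs 'input' or 'simulate'", "usage_error")
  if (!is.null(series$spectra)) {
    window <- if (!is.null(cfg$smooth_window)) cfg$smooth_window else 5L
    series <- smooth_titration(series, window = window)
  }
  sv <- stern_volmer_fit(series)
  sc <- scatchard_fit(series)
  shift <- detect_emission_shift(series)
  list(
    parameters = data.frame(
      quencher = series$quencher,
      K_SV_per_M = sv$K_SV, R_sv = sv$R,
      K_q_per_M_s = sv$K_q, f_a = sv$f_a, mechanism = sv$mechanism,
      K_a_per_M = sc$K_a, R_scatchard = sc$R, n_sites = sc$n,
      n_points_sv = sv$n_points_used, n_points_scatchard = sc$n_points_used,
      tau0_ns = sv$tau0_ns, stringsAsFactors = FALSE),
    emission_shift = list(applicable = shift$applicable,
                          max_shift_nm = shift$max_shift_nm,
                          shifted = shift$shifted),
    units = c(K_SV_per_M = "1/M", K_q_per_M_s = "1/(M s)",
              K_a_per_M = "1/M", n_sites = "sites/molecule")
  )
}

stage_probes <- function(cfg, seed) {
  metric <- if (!is.null(cfg$metric)) cfg$metric else "anisotropy"
  control <- if (!is.null(cfg$control)) cfg$control else "control"
  alpha <- if (!is.null(cfg$alpha)) cfg$alpha else 0.05
  readings <- if (!is.null(cfg$input)) {
    read_probe_readings_csv(cfg$input)
  } else if (!is.null(cfg$simulate)) {
    simulate_probe_readings(cfg$simulate, metric, control, seed)
  } else stop_memfluor("probes stage needs 'input' or 'simulate'", "usage_error")
  tab <- build_dose_response(readings, metric = metric, control = control)
  dn <- dunnett_many_to_one(tab, alpha = alpha)
  list(summary = tab$summary, comparisons = dn$comparisons,
       alpha = alpha, metric = metric, control = control)
}

# Replicated probe readings for the simulated probes stage: one cell per
# treatment entry (name = label; value = list(A_true or GP_true,
# concentration_uM, n, noise_sd)).
simulate_probe_readings <- function(sim, metric, control, seed) {
  rows <- list()
  for (i in seq_along(sim)) {
    s <- sim[[i]]
    label <- names(sim)[i]
    n <- if (!is.null(s$n)) s$n else 3L
    noise <- if (!is.null(s$noise_sd)) s$noise_sd else 0.01
    conc <- if (!is.null(s$concentration_uM)) s$concentration_uM else 0
    cell_seed <- derive_seed(seed, i)
    if (metric == "anisotropy") {
      r <- simulate_polarized(s$A_true, G = 1, noise_sd = noise, n = n,
                              seed = cell_seed)
      rows[[i]] <- data.frame(treatment = label, concentration_uM = conc,
                              replicate = seq_len(n),
                              I_parallel = r$I_parallel,
                              I_perpendicular = r$I_perpendicular, G = r$G)
    } else {
      r <- simulate_gp(s$GP_true, noise_sd = noise, n = n, seed = cell_seed)
      rows[[i]] <- data.frame(treatment = label, concentration_uM = conc,
                              replicate = seq_len(n),
                              I_440 = r$I_440, I_490 = r$I_490)
    }
  }
  do.call(rbind, rows)
}

stage_hemolysis <- function(cfg, seed) {
  control <- if (!is.null(cfg$control)) cfg$control else "control"
  alpha <- if (!is.null(cfg$alpha)) cfg$alpha else 0.05
  curves <- if (!is.null(cfg$input)) {
    read_fragility_csv(cfg$input)
  } else if (!is.null(cfg$simulate)) {
    cs <- lapply(seq_along(cfg$simulate), function(i)
      do.call(simulate_fragility,
              modifyList(list(seed = derive_seed(seed, i),
                              treatment = names(cfg$simulate)[i]),
                         cfg$simulate[[i]])))
    names(cs) <- names(cfg$simulate)
    cs
  } else stop_memfluor("hemolysis stage needs 'input' or 'simulate'", "usage_error")
  if (!control %in% names(curves))
    stop_memfluor(sprintf("control curve '%s' not present", control),
                  "missing_control")
  treated <- setdiff(names(curves), control)
  cmp <- lapply(treated, function(tr)
    compare_resistance(curves[[tr]], curves[[control]], alpha = alpha))
  names(cmp) <- treated
  list(
    c50 = data.frame(
      treatment = names(curves),
      c50_percent_nacl = vapply(curves, function(cv)
        unname(coef(fit_c50(cv))["c50"]), numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE),
    classification = data.frame(
      treatment = treated,
      classification = vapply(cmp, function(x) x$classification, character(1L)),
      row.names = NULL, stringsAsFactors = FALSE),
    alpha = alpha, control = control)
}

stage_morphology <- function(cfg, seed) {
  control <- if (!is.null(cfg$control)) cfg$control else "control"
  alpha <- if (!is.null(cfg$alpha)) cfg$alpha else 0.01
  tables <- if (!is.null(cfg$input)) {
    read_morphology_csv(cfg$input)
  } else if (!is.null(cfg$simulate)) {
    ts <- lapply(seq_along(cfg$simulate), function(i)
      do.call(simulate_morphology,
              modifyList(list(seed = derive_seed(seed, i),
                              treatment = names(cfg$simulate)[i]),
                         cfg$simulate[[i]])))
    names(ts) <- names(cfg$simulate)
    ts
  } else stop_memfluor("morphology stage needs 'input' or 'simulate'", "usage_error")
  if (!control %in% names(tables))
    stop_memfluor(sprintf("control table '%s' not present", control),
                  "missing_control")
  treated <- setdiff(names(tables), control)
  comparisons <- lapply(treated, function(tr)
    compare_shapes(tables[[tr]], tables[[control]], alpha = alpha)$table)
  names(comparisons) <- treated
  list(shares = lapply(tables, function(tb) shape_shares(tb)$summary),
       comparisons = comparisons, alpha = alpha, control = control)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("memfluor analysis report\n")
  cat(sprintf("  stages: %s; seed: %s; version %s\n",
              paste(x$provenance$stages_run, collapse = ", "),
              x$provenance$seed, x$provenance$package_version))
  if (!is.null(x$stages$quench)) {
    cat("\n-- Quenching / binding parameters --\n")
    p <- x$stages$quench$parameters
    cat(sprintf("  %s: K_SV = %s 1/M (R = %.3f), K_q = %s 1/(M s) [%s], f_a = %.3f\n",
                p$quencher, fmt_sci(p$K_SV_per_M), p$R_sv,
                fmt_sci(p$K_q_per_M_s), p$mechanism, p$f_a))
    cat(sprintf("  Scatchard: K_a = %s 1/M (R = %.3f), n = %.3f sites\n",
                fmt_sci(p$K_a_per_M), p$R_scatchard, p$n_sites))
  }
  if (!is.null(x$stages$probes)) {
    cat(sprintf("\n-- Probe dose-response (%s, alpha = %g) --\n",
                x$stages$probes$metric, x$stages$probes$alpha))
    print(x$stages$probes$comparisons, row.names = FALSE)
  }
  if (!is.null(x$stages$hemolysis)) {
    cat(sprintf("\n-- Osmotic fragility (alpha = %g) --\n",
                x$stages$hemolysis$alpha))
    print(merge(x$stages$hemolysis$c50, x$stages$hemolysis$classification,
                all.x = TRUE), row.names = FALSE)
  }
  if (!is.null(x$stages$morphology)) {
    cat(sprintf("\n-- Morphology (alpha = %g) --\n", x$stages$morphology$alpha))
    for (tr in names(x$stages$morphology$comparisons)) {
      cat(sprintf("  %s vs %s:\n", tr, x$stages$morphology$control))
      print(x$stages$morphology$comparisons[[tr]], row.names = FALSE)
    }
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' The report body contains only plain values and data frames, so it
#' round-trips losslessly through its JSON form (see [read_report()]).
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a serialized analysis report
#' @param path JSON path written by [write_report()].
#' @return An `analysis_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_memfluor(sprintf("report file not found: %s", path), "io_error")
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "analysis_report")
}
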