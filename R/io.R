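# Plain-text (CSV) interchange for the dialects used by each stage.
# All files are UTF-8 with period decimal separators.

#' Read emission spectra from CSV
#'
#' Dialect: header `wavelength_nm,<label1>,<label2>,...` with one numeric
#' wavelength column and one intensity column per measurement.
#'
#' @param path CSV file path.
#' @param excitation_nm Excitation wavelength recorded on each spectrum.
#' @return Named list of [emission_spectrum] objects.
#' @export
read_spectra_csv <- function(path, excitation_nm = NA_real_) {
  if (!file.exists(path))
    stop_memfluor(sprintf("input file not found: %s", path), "io_error")
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1L] != "wavelength_nm" || ncol(d) < 2L)
    stop_memfluor("expected header wavelength_nm,<label1>,...", "invalid_data")
  wl <- d[[1L]]
  out <- lapply(names(d)[-1L], function(lab)
    emission_spectrum(wl, d[[lab]], excitation_nm = excitation_nm))
  names(out) <- names(d)[-1L]
  out
}

#' Write emission spectra to CSV
#'
#' @param spectra Named list of [emission_spectrum] objects on one grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  ref <- spectra[[1L]]
  d <- data.frame(wavelength_nm = ref$wavelengths)
  labs <- if (is.null(names(spectra))) paste0("s", seq_along(spectra))
          else names(spectra)
  for (i in seq_along(spectra)) d[[labs[i]]] <- spectra[[i]]$intensities
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read probe (anisotropy/GP) replicate readings from CSV
#'
#' Dialect: `treatment,concentration_uM,replicate,I_parallel,I_perpendicular,G`
#' for anisotropy or `treatment,concentration_uM,replicate,I_440,I_490` for
#' Laurdan GP.
#'
#' @param path CSV file path.
#' @return The validated data frame, ready for [build_dose_response()].
#' @export
read_probe_readings_csv <- function(path) {
  if (!file.exists(path))
    stop_memfluor(sprintf("input file not found: %s", path), "io_error")
  d <- read.csv(path)
  ok <- all(c("treatment", "concentration_uM", "replicate") %in% names(d)) &&
    (all(c("I_parallel", "I_perpendicular") %in% names(d)) ||
       all(c("I_440", "I_490") %in% names(d)))
  if (!ok)
    stop_memfluor("unrecognised probe readings dialect", "invalid_data")
  d
}

#' Read osmotic-fragility replicate data from CSV
#'
#' Dialect: `treatment,concentration_uM,nacl_percent,replicate,hemolysis_percent`.
#'
#' @param path CSV file path.
#' @return Named list of [fragility_curve] objects, one per treatment.
#' @export
read_fragility_csv <- function(path) {
  if (!file.exists(path))
    stop_memfluor(sprintf("input file not found: %s", path), "io_error")
  d <- read.csv(path)
  req <- c("treatment", "concentration_uM", "nacl_percent", "replicate",
           "hemolysis_percent")
  if (!all(req %in% names(d)))
    stop_memfluor("unrecognised fragility dialect", "invalid_data")
  lapply(split(d, d$treatment), function(dd)
    fragility_curve(dd[c("nacl_percent", "replicate", "hemolysis_percent")],
                    treatment = dd$treatment[1L],
                    concentration_uM = dd$concentration_uM[1L]))
}

#' Write a fragility curve to CSV
#' @param curve A [fragility_curve].
#' @param path Output CSV path.
#' @param append Append to an existing file (headerless)?
#' @return `path`, invisibly.
#' @export
write_fragility_csv <- function(curve, path, append = FALSE) {
  d <- curve$data
  d <- data.frame(treatment = curve$treatment,
                  concentration_uM = curve$concentration_uM,
                  d, check.names = FALSE)
  write.table(d, path, sep = ",", row.names = FALSE, col.names = !append,
              append = append, quote = FALSE)
  invisible(path)
}

#' Read erythrocyte shape counts from CSV
#'
#' Dialect: `treatment,replicate,category,count` with categories from
#' [SHAPE_CATEGORIES].
#'
#' @param path CSV file path.
#' @return Named list of [morphology_table] objects, one per treatment.
#' @export
read_morphology_csv <- function(path) {
  if (!file.exists(path))
    stop_memfluor(sprintf("input file not found: %s", path), "io_error")
  d <- read.csv(path)
  req <- c("treatment", "replicate", "category", "count")
  if (!all(req %in% names(d)))
    stop_memfluor("unrecognised morphology dialect", "invalid_data")
  lapply(split(d, d$treatment), function(dd)
    morphology_table(dd[c("replicate", "category", "count")],
                     treatment = dd$treatment[1L]))
}

#' Write a morphology table to CSV
#' @param table A [morphology_table].
#' @param path Output CSV path.
#' @param append Append to an existing file (headerless)?
#' @return `path`, invisibly.
#' @export
write_morphology_csv <- function(table, path, append = FALSE) {
  m <- table$counts
  d <- data.frame(treatment = table$treatment,
                  replicate = rep(rownames(m), times = ncol(m)),
                  category = rep(colnames(m), each = nrow(m)),
                  count = as.vector(m))
  write.table(d, path, sep = ",", row.names = FALSE, col.names = !append,
              append = append, quote = FALSE)
  invisible(path)
}

#' Read a quenching titration from CSV
#'
#' Two dialects: peak intensities (`Q_uM,intensity`) or the spectra dialect
#' of [read_spectra_csv()] with one column per titration point whose label
#' contains the quencher concentration in uM (e.g. `Q0, Q5, ..., Q50`).
#'
#' @param path CSV file path.
#' @param tau0_ns Fluorophore lifetime in ns (default 2.5).
#' @param quencher Series label.
#' @return A [titration_series].
#' @export
read_titration_csv <- function(path, tau0_ns = 2.5, quencher = "compound") {
  if (!file.exists(path))
    stop_memfluor(sprintf("input file not found: %s", path), "io_error")
  head <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (identical(head[1:2], c("Q_uM", "intensity"))) {
    d <- read.csv(path)
    return(titration_series(d$Q_uM, d$intensity, tau0_ns = tau0_ns,
                            quencher = quencher))
  }
  if (head[1L] == "wavelength_nm") {
    spectra <- read_spectra_csv(path, excitation_nm = 295)
    Q <- as.numeric(gsub("[^0-9.eE+-]", "", names(spectra)))
    if (any(is.na(Q)))
      stop_memfluor("spectrum column labels must contain Q in uM", "invalid_data")
    o <- order(Q)
    return(titration_series(Q[o], spectra = spectra[o], tau0_ns = tau0_ns,
                            quencher = quencher))
  }
  stop_memfluor("unrecognised titration dialect", "invalid_data")
}

#' Write a titration series to CSV
#'
#' Writes the spectra dialect when spectra are present (labels `Q<uM>`),
#' otherwise the `Q_uM,intensity` dialect.
#'
#' @param series A [titration_series].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  if (!is.null(series$spectra)) {
    sps <- series$spectra
    names(sps) <- paste0("Q", series$Q_uM)
    write_spectra_csv(sps, path)
  } else {
    write.csv(data.frame(Q_uM = series$Q_uM, intensity = series$intensity),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
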