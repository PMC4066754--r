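# File-format contracts and reporting. CSV dialect: comma-separated,
# UTF-8, mandatory header, units encoded in column names (time_h /
# time_min, shift_ppm, *_mM), decimal point only. Sidecar configuration
# is YAML next to the data file (<file>.yml).

.sidecar_path <- function(path) paste0(path, ".yml")

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (file.exists(sc)) yaml::read_yaml(sc) else list()
}

#' Read a kinetic time course from CSV
#'
#' Expects a `time_h` or `time_min` column (unit in the name; minutes
#' are converted to hours) and a `fraction_extended` or
#' `fraction_intact` column. Assay conditions may be supplied in a YAML
#' sidecar `<path>.yml` (keys `monomer`, `monomer_mM`, `inhibitor_mM`,
#' `helper_present`, `temperature_c`, `motif`).
#'
#' @param path CSV file path.
#' @return A [time_course].
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_h", "time_min"), names(df))
  fcol <- intersect(c("fraction_extended", "fraction_intact"), names(df))
  if (length(tcol) != 1) {
    px_input(sprintf(
      "%s: need exactly one time column named time_h or time_min (unit undeclared otherwise)",
      path))
  }
  if (length(fcol) != 1) {
    px_input(sprintf(
      "%s: need a fraction_extended or fraction_intact column", path))
  }
  tt <- df[[tcol]]
  bad <- which(diff(tt) <= 0)
  if (length(bad)) {
    px_input(sprintf("%s: time not strictly increasing at row %d",
                     path, bad[1] + 1))
  }
  cfg <- .read_sidecar(path)
  time_course(tt, df[[fcol]],
              time_unit = if (tcol == "time_min") "minutes" else "hours",
              monomer = cfg$monomer %||% "",
              monomer_mM = cfg$monomer_mM %||% NA_real_,
              inhibitor_mM = cfg$inhibitor_mM %||% 0,
              helper_present = isTRUE(cfg$helper_present),
              temperature_c = cfg$temperature_c %||% 20,
              motif = cfg$motif %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time course to CSV (hours dialect)
#'
#' @param tc a [time_course].
#' @param path output CSV path; conditions go to a YAML sidecar.
#' @param fraction_col output fraction column name.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path,
                                 fraction_col = "fraction_extended") {
  if (!inherits(tc, "time_course")) px_input("`tc` must be a time_course")
  df <- data.frame(time_h = tc$time_h, f = tc$fraction)
  names(df)[2] <- fraction_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(tc$conditions, .sidecar_path(path))
  invisible(path)
}

#' Read an NMR titration from CSV
#'
#' Expects columns `ligand_total_mM` and `shift_ppm`; host
#' concentration and metadata come from the YAML sidecar `<path>.yml`
#' (keys `host_total_mM` (required), `reporter`, `temperature_c`).
#'
#' @param path CSV file path.
#' @return A [titration_series].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_total_mM", "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    px_input(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")))
  }
  cfg <- .read_sidecar(path)
  if (is.null(cfg$host_total_mM)) {
    px_input(sprintf("%s: host_total_mM must be declared in %s",
                     path, .sidecar_path(path)))
  }
  titration_series(df$ligand_total_mM, df$shift_ppm,
                   host_mM = cfg$host_total_mM,
                   reporter = cfg$reporter %||% "",
                   temperature_c = cfg$temperature_c %||% 20)
}

#' Write a titration series to CSV with YAML sidecar
#'
#' @param series a [titration_series].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  if (!inherits(series, "titration_series")) {
    px_input("`series` must be a titration_series")
  }
  utils::write.csv(
    data.frame(ligand_total_mM = series$ligand_mM,
               shift_ppm = series$shift_ppm),
    path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(host_total_mM = series$host_mM,
                        reporter = series$reporter,
                        temperature_c = series$temperature_c),
                   .sidecar_path(path))
  invisible(path)
}

#' Serialize a fit or result object to JSON
#'
#' Writes the object's fields plus provenance (package version, write
#' time) as pretty-printed JSON.
#'
#' @param obj a fit object or plain list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  payload <- list(
    class = paste(class(obj), collapse = "/"),
    tool = "primext",
    version = as.character(utils::packageVersion("primext")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    result = unclass(obj))
  # drop embedded data objects that do not serialize usefully
  payload$result$series <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Occupancy grid over records and concentrations
#'
#' Extension-site occupancy for every uncensored binding record at each
#' concentration of a grid — the tabular form of a binding-isotherm
#' figure.
#'
#' @param records a `binding_records` data frame.
#' @param conc_mM concentration grid, mM.
#' @return Data frame with record annotations, `conc_mM` and
#'   `occupancy`; empty (with a warning) for an empty grid.
#' @export
report_occupancy_grid <- function(records, conc_mM) {
  if (length(conc_mM) == 0) {
    warning("empty concentration grid: returning empty table",
            call. = FALSE)
    return(data.frame(nucleotide = character(), motif = character(),
                      kd_mM = numeric(), conc_mM = numeric(),
                      occupancy = numeric()))
  }
  check_nonnegative(conc_mM, "conc_mM")
  rec <- records[!records$censored, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
    data.frame(nucleotide = rec$nucleotide[i], motif = rec$motif[i],
               helper_present = rec$helper_present[i],
               kd_mM = rec$kd_mM[i], conc_mM = conc_mM,
               occupancy = occupancy(rec$kd_mM[i], conc_mM))))
  rownames(out) <- NULL
  out
}

#' Per-nucleotide Kd summary across binding contexts
#'
#' One row per nucleotide x context, where context is `hairpin` (NMR),
#' `duplex` (inhibition, no helper) or `duplex+helper`; censored bounds
#' render as ">=<bound>" and never enter the accompanying
#' complementary-pairing means.
#'
#' @param records a `binding_records` data frame.
#' @param temperature_c temperature filter for the mean column
#'   (default 20).
#' @return List with `table` (per-context rows: nucleotide, context,
#'   motif, pairing, `kd_display`) and `means` (per-nucleotide mean Kd
#'   over complementary uncensored records).
#' @export
report_kd_summary <- function(records, temperature_c = 20) {
  context <- ifelse(records$method == "nmr", "hairpin",
                    ifelse(records$helper_present, "duplex+helper",
                           "duplex"))
  tab <- data.frame(
    nucleotide = records$nucleotide,
    context = context,
    motif = records$motif,
    temperature_c = records$temperature_c,
    pairing = records$pairing,
    kd_display = ifelse(records$censored,
                        paste0(">=", records$kd_mM),
                        as.character(records$kd_mM)),
    stringsAsFactors = FALSE)
  nucs <- setdiff(unique(records$nucleotide), NA)
  means <- do.call(rbind, lapply(nucs, function(nu) {
    m <- tryCatch(average_kd(records, nu, temperature_c = temperature_c),
                  primext_input_error = function(e) NA_real_)
    data.frame(nucleotide = nu, mean_kd_mM = m)
  }))
  rownames(means) <- NULL
  list(table = tab, means = means)
}
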