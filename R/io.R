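#' Read traces from a delimited text file
#'
#' The trace CSV dialect: a header row with columns `time_s`, `signal`,
#' `phase` (mandatory) and `conc_M`, `replicate_id`, `scavenger` (optional,
#' with defaults); one trace per `(phase, conc_M, replicate_id, scavenger)`
#' group. Units on disk are SI (seconds, mol/L); display-unit conversion
#' happens only in reports. Unknown columns are preserved. Rows are
#' time-sorted within each group; malformed rows (negative concentration,
#' unknown phase, duplicated time points) are rejected with diagnostics.
#'
#' @param path file path.
#' @return a validated trace tibble.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  traces <- validate_traces(tab)
  dplyr::bind_rows(split_traces(traces))
}

#' Write traces to a delimited text file
#'
#' Inverse of [read_traces()]: `read_traces(write_traces(x))` reproduces the
#' trace records.
#'
#' @param traces trace tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  traces <- validate_traces(traces)
  readr::write_csv(traces, path)
  invisible(path)
}

# Convert fitted objects to plain lists for the JSON report. Units are
# converted to the display convention of the published rate table
# (k_on in 1e6 M^-1 s^-1, k_off in 1e-5 s^-1, KD in pM).
as_report_list <- function(x, ...) UseMethod("as_report_list")

#' @export
as_report_list.default <- function(x, ...) x

#' @export
as_report_list.exp_fit <- function(x, ...) {
  list(
    type = "exp_fit", k_s1 = x$k, se_k_s1 = x$se_k, A = x$A, y0 = x$y0,
    rss = x$rss, sigma = x$sigma, n = x$n, flag = x$flag
  )
}

#' @export
as_report_list.biexp_fit <- function(x, ...) {
  list(
    type = "biexp_fit", k_fast_s1 = x$k_fast, k_slow_s1 = x$k_slow,
    se_k_fast_s1 = x$se_k_fast, se_k_slow_s1 = x$se_k_slow,
    per_trace = x$per_trace, flag = x$flag, rss = x$rss, sigma = x$sigma
  )
}

#' @export
as_report_list.kinetic_fit <- function(x, ...) {
  list(
    type = "kinetic_fit",
    k_on_1e6_M1s1 = x$k_on / 1e6, se_k_on_1e6_M1s1 = x$se_k_on / 1e6,
    k_off_1e5_s1 = x$k_off * 1e5, se_k_off_1e5_s1 = x$se_k_off * 1e5,
    kd_pM = x$kd * 1e12, se_kd_pM = x$se_kd * 1e12,
    si = list(k_on_M1s1 = x$k_on, k_off_s1 = x$k_off, kd_M = x$kd),
    amplitudes = list(
      association = x$assoc$per_trace,
      dissociation = x$dissoc$per_trace
    )
  )
}

#' @export
as_report_list.titration_fit <- function(x, ...) {
  list(
    type = "titration_fit", rt_pM = x$rt * 1e12, kd_pM = x$kd * 1e12,
    se_kd_pM = x$se_kd * 1e12,
    ci_pM = x$ci * 1e12, conf_level = x$conf_level,
    bound_only = x$bound_only, bound_pM = x$bound * 1e12,
    A = x$A, y0 = x$y0, n = x$n
  )
}

#' @export
as_report_list.stabilization_panel <- function(x, ...) {
  panel <- x$panel
  panel$class <- as.character(panel$class)
  list(
    type = "stabilization_panel", k_free_s1 = x$k_free,
    detection_limit_s1 = x$detection_limit, panel = panel
  )
}

#' @export
as_report_list.tnfkin_fit <- function(x, ...) {
  lapply(unclass(x), function(el) {
    if (inherits(el, "tnfkin_fit")) as_report_list(el) else el
  })
}

#' Write an analysis report as structured JSON
#'
#' A versioned report document: the results (fit objects are serialized with
#' SI and display units), the seed and configuration used, and md5 checksums
#' of the input files, so every report can be regenerated from the inputs it
#' names. No timestamp is written: rerunning the same analysis reproduces
#' the report byte-for-byte.
#'
#' @param results a named list of results (fit objects, tibbles, scalars).
#' @param path output path (`.json`).
#' @param seed,config optional provenance: the RNG seed and configuration
#'   the analysis used.
#' @param inputs optional character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = NULL,
                         inputs = NULL) {
  stopifnot(is.list(results))
  doc <- list(
    schema = "tnfkin-report",
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("tnfkin")),
    seed = seed,
    config = config,
    input_checksums = if (!is.null(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      NULL
    },
    results = lapply(results, as_report_list)
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a JSON report
#'
#' @param path report path written by [write_report()].
#' @return the report as a nested list; numbers round-trip bit-exactly.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "tnfkin-report")) {
    rlang::abort("not a tnfkin report file")
  }
  doc
}
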