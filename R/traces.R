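trace_phases <- c("association", "dissociation", "monomerization", "stabilization")

#' Construct a trace tibble
#'
#' The universal time-series record: one row per sampled point of a biosensor
#' trace. Several traces live in one tibble and are distinguished by the
#' grouping key `(phase, conc_M, replicate_id, scavenger)`. Time is stored
#' relative to the phase start (`t = 0` at injection or phase switch), which
#' is the origin the exponential models assume.
#'
#' @param time_s time since phase start, seconds; strictly increasing within
#'   a trace.
#' @param signal normalized signal, dimensionless.
#' @param phase one of `"association"`, `"dissociation"`, `"monomerization"`,
#'   `"stabilization"`.
#' @param conc_M analyte concentration, mol/L (0 for buffer-only).
#' @param replicate_id replicate identifier.
#' @param scavenger optional scavenger label (`NA` when not applicable).
#' @return a tibble with class `tnf_trace` prepended.
#' @export
trace_tbl <- function(time_s, signal, phase, conc_M = 0,
                      replicate_id = "r1", scavenger = NA_character_) {
  out <- tibble::tibble(
    time_s = as.double(time_s),
    signal = as.double(signal),
    phase = as.character(phase),
    conc_M = as.double(conc_M),
    replicate_id = as.character(replicate_id),
    scavenger = as.character(scavenger)
  )
  validate_traces(out)
}

trace_key_cols <- c("phase", "conc_M", "replicate_id", "scavenger")

#' Validate a trace tibble
#'
#' Checks the trace contract: required columns, valid phase labels,
#' non-negative concentrations, at least 3 points per trace, and strictly
#' increasing time within each `(phase, conc_M, replicate_id, scavenger)`
#' group.
#'
#' @param traces a data frame of trace records.
#' @param single require exactly one trace group.
#' @return the validated tibble (invisibly unchanged apart from class).
#' @export
validate_traces <- function(traces, single = FALSE) {
  req <- c("time_s", "signal", "phase")
  missing_cols <- setdiff(req, names(traces))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "trace table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  traces <- tibble::as_tibble(traces)
  if (!"conc_M" %in% names(traces)) traces$conc_M <- 0
  if (!"replicate_id" %in% names(traces)) traces$replicate_id <- "r1"
  if (!"scavenger" %in% names(traces)) traces$scavenger <- NA_character_
  traces$time_s <- as.double(traces$time_s)
  traces$signal <- as.double(traces$signal)
  traces$conc_M <- as.double(traces$conc_M)
  traces$phase <- as.character(traces$phase)
  traces$replicate_id <- as.character(traces$replicate_id)
  traces$scavenger <- as.character(traces$scavenger)
  bad_phase <- setdiff(unique(traces$phase), trace_phases)
  if (length(bad_phase) > 0) {
    rlang::abort(paste0(
      "unknown phase label(s): ", paste(bad_phase, collapse = ", "),
      "; expected one of ", paste(trace_phases, collapse = ", ")
    ))
  }
  if (any(traces$conc_M < 0)) {
    rows <- which(traces$conc_M < 0)
    rlang::abort(paste0(
      "negative conc_M at row(s): ",
      paste(utils::head(rows, 5), collapse = ", ")
    ))
  }
  grp <- split_traces(traces)
  if (single && length(grp) != 1) {
    rlang::abort(sprintf("expected a single trace, found %d groups", length(grp)))
  }
  for (g in grp) {
    if (nrow(g) < 3) rlang::abort("each trace needs at least 3 points")
    if (any(diff(g$time_s) <= 0)) {
      rlang::abort("time_s must be strictly increasing within each trace")
    }
  }
  traces
}

#' Split a trace tibble into a list of single traces
#'
#' @param traces trace tibble.
#' @return named list of single-trace tibbles, keyed by
#'   `phase/conc_M/replicate_id/scavenger`, each sorted by time.
#' @export
split_traces <- function(traces) {
  key <- interaction(
    traces$phase, format(traces$conc_M, digits = 15),
    traces$replicate_id, ifelse(is.na(traces$scavenger), "<none>", traces$scavenger),
    drop = TRUE, sep = "/"
  )
  out <- lapply(split(seq_len(nrow(traces)), key), function(i) {
    g <- traces[i, , drop = FALSE]
    g[order(g$time_s), , drop = FALSE]
  })
  out
}

#' Normalize traces
#'
#' Divides the signal of each trace by a normalizer: in `"initial_value"` mode
#' the signal at the first time point (the convention used for
#' solution-titration binding curves); in `"baseline"` mode the mean signal
#' over a pre-phase time window. The operation is idempotent: normalizing an
#' already-normalized trace leaves it unchanged.
#'
#' @param traces trace tibble (one or more traces).
#' @param mode `"initial_value"` or `"baseline"`.
#' @param baseline_window numeric length-2, the `[t_min, t_max]` window (s)
#'   whose mean signal defines the baseline normalizer. Required in
#'   `"baseline"` mode.
#' @return the trace tibble with `signal` rescaled per trace.
#' @export
normalize_trace <- function(traces, mode = c("initial_value", "baseline"),
                            baseline_window = NULL) {
  mode <- match.arg(mode)
  traces <- validate_traces(traces)
  grp <- split_traces(traces)
  out <- lapply(grp, function(g) {
    norm <- switch(mode,
      initial_value = g$signal[1],
      baseline = {
        if (is.null(baseline_window) || length(baseline_window) != 2) {
          rlang::abort("baseline mode needs `baseline_window = c(t_min, t_max)`")
        }
        sel <- g$time_s >= baseline_window[1] & g$time_s <= baseline_window[2]
        if (!any(sel)) rlang::abort("baseline_window contains no points")
        mean(g$signal[sel])
      }
    )
    if (!is.finite(norm) || abs(norm) < .Machine$double.eps * 100) {
      rlang::abort("degenerate trace: normalizer is zero")
    }
    g$signal <- g$signal / norm
    g
  })
  dplyr::bind_rows(out)
}
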