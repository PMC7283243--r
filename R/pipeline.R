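#' Monomerization workflow
#'
#' Fits each replicate monomerization trace independently, excludes failed or
#' below-detection replicates with a logged reason, and reports the mean rate
#' with its standard error of the mean. If pre/post hydrodynamic diameters
#' are supplied, the endpoints are classified against the trimer/monomer
#' anchors and a trimer-fraction trajectory `f(t) = exp(-k_mean t)` (the
#' first-order surviving-trimer fraction) is tabulated with the implied
#' diameter.
#'
#' @param traces monomerization-phase trace tibble (replicates).
#' @param dh_pre,dh_post optional measured diameters (nm) before and after
#'   buffer flow.
#' @param refs a [size_refs()].
#' @return an object of class `monomerization_result`: replicate `fits`,
#'   `summary` tibble, `k_mean`, `k_sem`, `n_used`, `excluded`, `verdict`
#'   (`"monomerization"` or `"no_monomerization"`), endpoint classification
#'   and `trajectory` tibble (when diameters are given).
#' @export
run_monomerization <- function(traces, dh_pre = NULL, dh_post = NULL,
                               refs = size_refs()) {
  reps <- fit_monomerization_replicates(traces)
  verdict <- if (reps$n_used == 0) "no_monomerization" else "monomerization"
  endpoints <- NULL
  trajectory <- NULL
  if (!is.null(dh_pre) && !is.null(dh_post)) {
    endpoints <- compare_to_reference(c(dh_pre, dh_post), refs)
    endpoints$when <- c("pre", "post")
    if (verdict == "monomerization") {
      t_max <- max(traces$time_s)
      tt <- seq(0, t_max, length.out = 201)
      frac <- exp(-reps$k_mean * tt)
      trajectory <- tibble::tibble(
        time_s = tt,
        trimer_fraction = frac,
        dh_nm = refs$dh_monomer + frac * (refs$dh_trimer - refs$dh_monomer)
      )
    }
  }
  new_tnfkin_fit(c(reps, list(
    verdict = verdict, endpoints = endpoints, trajectory = trajectory,
    refs = refs
  )), "monomerization_result")
}

#' Kinetics configuration
#'
#' @param normalize normalize traces to their initial value before fitting.
#' @param biphasic_check run decay-model selection on the dissociation traces
#'   and route to the bi-exponential global fit when the biphasic model is
#'   selected for a majority of traces.
#' @param alpha model-selection significance level.
#' @param residual_complex_frac flag a dissociation trace as retaining
#'   residual complex when its fitted offset exceeds this fraction of the
#'   starting level (amplitude + offset).
#' @return a `kinetics_config` list.
#' @export
kinetics_config <- function(normalize = FALSE, biphasic_check = TRUE,
                            alpha = 0.05, residual_complex_frac = 0.1) {
  structure(
    list(
      normalize = normalize, biphasic_check = biphasic_check,
      alpha = alpha, residual_complex_frac = residual_complex_frac
    ),
    class = "kinetics_config"
  )
}

#' Full kinetic analysis of an association/dissociation series
#'
#' The standard two-step global analysis: the shared dissociation rate is
#' determined first from the dissociation curves, then fixed while the shared
#' association rate is fitted to the concentration series, and the results
#' are assembled into a rate/affinity report (`KD = k_off/k_on`).
#'
#' An optional biphasic pre-pass runs decay-model selection per dissociation
#' trace; when a majority of traces are biphasic the dissociation is fitted
#' bi-exponentially and the slow rate — assigned to scavenger dissociation,
#' as the fast rate tracks trimer monomerization — is used as `k_off`.
#' Dissociation traces whose fitted offset shows the signal not returning to
#' baseline are flagged `residual_complex` (interlinked-complex formation).
#'
#' @param assoc_traces association-phase trace tibble (conc series).
#' @param dissoc_traces dissociation-phase trace tibble.
#' @param config a [kinetics_config()].
#' @param spec a [global_fit_spec()].
#' @return an object of class `kinetics_run`: the `kinetic_fit` report plus
#'   `route` (`"mono"` or `"biphasic"`), the model-selection results, the
#'   bi-exponential fit (biphasic route), `k_fast` when present, and
#'   `residual_complex` flags per dissociation trace.
#' @export
run_kinetics <- function(assoc_traces, dissoc_traces,
                         config = kinetics_config(),
                         spec = global_fit_spec()) {
  if (config$normalize) {
    assoc_traces <- normalize_trace(assoc_traces)
    dissoc_traces <- normalize_trace(dissoc_traces)
  }
  dissoc_traces <- validate_traces(dissoc_traces)
  selections <- NULL
  route <- "mono"
  biexp <- NULL
  if (config$biphasic_check) {
    grps <- split_traces(dissoc_traces)
    selections <- lapply(grps, function(g) {
      tryCatch(select_decay_model(g, alpha = config$alpha),
        error = function(e) NULL
      )
    })
    decisions <- vapply(selections, function(s) {
      if (is.null(s)) "mono" else s$decision
    }, character(1))
    if (mean(decisions == "bi") > 0.5) route <- "biphasic"
  }
  if (route == "biphasic") {
    biexp <- fit_biexp_global(dissoc_traces)
    k_off <- biexp$k_slow
    # wrap the slow rate in a dissoc_fit-shaped summary for the report
    grps <- split_traces(dissoc_traces)
    ind_slow <- vapply(grps, function(g) {
      f <- tryCatch(fit_biexp_global(g), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$k_slow
    }, numeric(1))
    ind_slow <- ind_slow[is.finite(ind_slow)]
    dissoc <- new_tnfkin_fit(list(
      k_off = k_off, se_k_off = biexp$se_k_slow,
      sem_k_off = if (length(ind_slow) > 1) {
        stats::sd(ind_slow) / sqrt(length(ind_slow))
      } else {
        NA_real_
      },
      per_trace = dplyr::mutate(biexp$per_trace,
        A = -.data$a_slow,
        k_off_individual = NA_real_
      ),
      rss = biexp$rss, sigma = biexp$sigma, n_traces = biexp$n_traces,
      n_points = biexp$n_points, converged = biexp$converged,
      data = dissoc_traces, fitted = biexp$fitted, spec = spec
    ), "dissoc_fit")
  } else {
    dissoc <- global_fit_dissociation(dissoc_traces, spec)
  }
  assoc <- global_fit_association(assoc_traces, dissoc$k_off, spec)
  report <- kinetics_report(assoc, dissoc)
  start_level <- abs(dissoc$per_trace$A) + dissoc$per_trace$y0
  residual_complex <- dissoc$per_trace$y0 >
    config$residual_complex_frac * pmax(start_level, .Machine$double.eps)
  flags <- dplyr::mutate(
    dissoc$per_trace[, c("replicate_id", "conc_M")],
    residual_complex = residual_complex
  )
  new_tnfkin_fit(list(
    report = report, route = route, selections = selections,
    biexp = biexp, k_fast = if (!is.null(biexp)) biexp$k_fast else NA_real_,
    residual_complex = flags, config = config
  ), "kinetics_run")
}

#' Titration workflow over several receptor concentrations
#'
#' Runs [fit_titration()] once per receptor concentration and collects the
#' per-condition dissociation constants or upper bounds. The 1:1 isotherm is
#' an approximation for multivalent binders (it underestimates the steepness
#' of the dose response when higher-order complexes form), so the summary
#' carries that caveat.
#'
#' @param tables a single tibble with an `rt_M` column, or a list of tibbles
#'   (one per receptor concentration).
#' @param rt receptor concentrations, mol/L; required when `tables` is a
#'   list without `rt_M` columns.
#' @param ... passed to [fit_titration()] (`nboot`, `conf_level`, `seed`).
#' @return an object of class `titration_scan`: `fits` (list of
#'   `titration_fit`), `summary` tibble with `rt_M`, `kd_M`, CI, `bound_only`
#'   and `bound_M`, and `caveat`.
#' @export
run_titration <- function(tables, rt = NULL, ...) {
  if (is.data.frame(tables)) {
    if (nrow(tables) == 0) rlang::abort("empty titration table")
    if (!"rt_M" %in% names(tables)) {
      if (is.null(rt)) rlang::abort("supply `rt` or an rt_M column")
      tables$rt_M <- rt
    }
    tables <- split(tables, tables$rt_M)
  }
  if (length(tables) == 0) rlang::abort("empty titration table")
  fits <- lapply(tables, function(tab) {
    fit_titration(tab, rt = tab$rt_M[1], ...)
  })
  summary <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      rt_M = f$rt, kd_M = f$kd, kd_lo_M = f$ci[1], kd_hi_M = f$ci[2],
      bound_only = f$bound_only, bound_M = f$bound, n_points = f$n
    )
  }))
  new_tnfkin_fit(list(
    fits = fits, summary = summary,
    caveat = paste(
      "1:1 isotherm approximation: multivalent receptor/ligand pairs form",
      "higher-order complexes that steepen the true dose response."
    )
  ), "titration_scan")
}

panel_class_levels <- c("full_suppression", "strong", "moderate", "weak")

#' Trimer-stabilization panel analysis
#'
#' For each scavenger, averages the replicate stabilization traces
#' point-wise, fits the monomerization rate of the scavenger-bound trimer,
#' and compares it with the free-trimer rate `k_free`. Per-replicate fits are
#' retained for the SEM. Classification:
#' \describe{
#'   \item{full_suppression}{no detectable decay amplitude (the fit's
#'     below-detection criterion) or `k_mono` below `detection_limit` —
#'     suppression is an amplitude statement, not a zero-rate estimate;}
#'   \item{strong}{`k_mono <= 3 * detection_limit`;}
#'   \item{moderate}{`k_mono <= weak_frac * k_free`;}
#'   \item{weak}{faster than that.}
#' }
#' The suppression factor is `k_free / k_mono` (`Inf` under full
#' suppression); the buffer control's factor is 1 by construction.
#'
#' @param traces stabilization-phase trace tibble with a `scavenger` column;
#'   triplicate replicates per scavenger.
#' @param k_free free-trimer monomerization rate, s^-1. If `NULL`, a control
#'   labelled `"buffer"`, `"none"` or `"free"` must be present and its fitted
#'   rate is used; without either the suppression factors are undefined and
#'   the analysis stops.
#' @param detection_limit smallest resolvable rate, s^-1. The default 2e-5
#'   corresponds to a decay amplitude of a few times the typical residual
#'   noise over the 4200 s recording window.
#' @param weak_frac moderate/weak class boundary as a fraction of `k_free`
#'   (default 0.25).
#' @return an object of class `stabilization_panel`: `panel` tibble (one row
#'   per scavenger: `k_mono`, `se_k`, `sem_k`, `below_detection`,
#'   `suppression_factor`, `class`), ordered by `k_mono`; `k_free`,
#'   `detection_limit`, per-scavenger fits.
#' @export
run_stabilization_panel <- function(traces, k_free = NULL,
                                    detection_limit = 2e-5,
                                    weak_frac = 0.25) {
  traces <- validate_traces(traces)
  if (!all(traces$phase == "stabilization")) {
    rlang::abort("all traces must be stabilization phase")
  }
  control_labels <- c("buffer", "none", "free")
  by_scav <- split(traces, traces$scavenger)
  avg_fit <- function(tr) {
    avg <- tr |>
      dplyr::group_by(.data$time_s) |>
      dplyr::summarise(signal = mean(.data$signal), .groups = "drop")
    fit_monomerization(trace_tbl(avg$time_s, avg$signal,
      phase = "stabilization", scavenger = tr$scavenger[1]
    ))
  }
  rep_sem <- function(tr) {
    reps <- fit_monomerization_replicates(tr)
    reps$k_sem
  }
  if (is.null(k_free)) {
    ctrl <- intersect(tolower(names(by_scav)), control_labels)
    if (length(ctrl) == 0) {
      rlang::abort(paste(
        "no `k_free` supplied and no buffer/none/free control trace present:",
        "suppression factors cannot be computed"
      ))
    }
    ctrl_name <- names(by_scav)[tolower(names(by_scav)) %in% control_labels][1]
    k_free <- avg_fit(by_scav[[ctrl_name]])$k
  }
  rows <- lapply(names(by_scav), function(nm) {
    f <- avg_fit(by_scav[[nm]])
    below <- f$flag == "below_detection" || f$k < detection_limit
    k_mono <- if (below) NA_real_ else f$k
    cls <- if (below) {
      "full_suppression"
    } else if (f$k <= 3 * detection_limit) {
      "strong"
    } else if (f$k <= weak_frac * k_free) {
      "moderate"
    } else {
      "weak"
    }
    tibble::tibble(
      scavenger = nm, k_mono = k_mono, se_k = if (below) NA_real_ else f$se_k,
      sem_k = if (below) NA_real_ else rep_sem(by_scav[[nm]]),
      below_detection = below,
      suppression_factor = if (below) Inf else k_free / f$k,
      class = cls
    )
  })
  panel <- dplyr::bind_rows(rows)
  panel$class <- factor(panel$class, levels = panel_class_levels)
  panel <- panel[order(panel$class, dplyr::coalesce(panel$k_mono, 0)), ]
  fits <- lapply(by_scav, avg_fit)
  new_tnfkin_fit(list(
    panel = panel, k_free = k_free, detection_limit = detection_limit,
    weak_frac = weak_frac, fits = fits
  ), "stabilization_panel")
}
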