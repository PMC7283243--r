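#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "A", "y0"),
    estimate = c(x$k, x$A, x$y0),
    std.error = c(x$se_k, x$se_A, x$se_y0)
  )
}

#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, se_k = x$se_k, rss = x$rss, sigma = x$sigma,
    nobs = x$n, flag = x$flag, converged = x$converged
  )
}

#' @exportS3Method generics::tidy
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_fast", "k_slow"),
    estimate = c(x$k_fast, x$k_slow),
    std.error = c(x$se_k_fast, x$se_k_slow)
  )
}

#' @exportS3Method generics::glance
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(
    k_fast = x$k_fast, k_slow = x$k_slow, rate_ratio = x$k_fast / x$k_slow,
    rss = x$rss, sigma = x$sigma, nobs = x$n_points, n_traces = x$n_traces,
    flag = x$flag, converged = x$converged
  )
}

#' @exportS3Method generics::tidy
tidy.dissoc_fit <- function(x, ...) {
  dplyr::mutate(x$per_trace, k_off = x$k_off)
}

#' @exportS3Method generics::glance
glance.dissoc_fit <- function(x, ...) {
  tibble::tibble(
    k_off = x$k_off, se_k_off = x$se_k_off, sem_k_off = x$sem_k_off,
    rss = x$rss, sigma = x$sigma, n_traces = x$n_traces, nobs = x$n_points
  )
}

#' @exportS3Method generics::tidy
tidy.assoc_fit <- function(x, ...) {
  dplyr::mutate(x$per_trace, k_on = x$k_on)
}

#' @exportS3Method generics::glance
glance.assoc_fit <- function(x, ...) {
  tibble::tibble(
    k_on = x$k_on, se_k_on = x$se_k_on, k_off = x$k_off,
    rss = x$rss, sigma = x$sigma, n_traces = x$n_traces, nobs = x$n_points
  )
}

#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_on", "k_off", "kd"),
    estimate = c(x$k_on, x$k_off, x$kd),
    std.error = c(x$se_k_on, x$se_k_off, x$se_kd),
    unit = c("M^-1 s^-1", "s^-1", "M")
  )
}

#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    k_on_1e6 = x$k_on / 1e6, k_off_1e5 = x$k_off * 1e5, kd_pM = x$kd * 1e12,
    se_k_on_1e6 = x$se_k_on / 1e6, se_k_off_1e5 = x$se_k_off * 1e5,
    se_kd_pM = x$se_kd * 1e12
  )
}

#' @exportS3Method generics::tidy
tidy.titration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "A", "y0"),
    estimate = c(x$kd, x$A, x$y0),
    std.error = c(x$se_kd, NA_real_, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.titration_fit <- function(x, ...) {
  tibble::tibble(
    rt_M = x$rt, kd_M = x$kd, kd_lo_M = x$ci[1], kd_hi_M = x$ci[2],
    conf_level = x$conf_level, bound_only = x$bound_only, bound_M = x$bound,
    sigma = x$sigma, nobs = x$n
  )
}

#' @exportS3Method generics::tidy
tidy.stabilization_panel <- function(x, ...) x$panel

#' @exportS3Method generics::glance
glance.stabilization_panel <- function(x, ...) {
  tibble::tibble(
    k_free = x$k_free, detection_limit = x$detection_limit,
    n_scavengers = nrow(x$panel),
    n_full_suppression = sum(x$panel$class == "full_suppression")
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> k = %.4g s^-1 (se %.2g), A = %.3g, y0 = %.3g [%s]\n",
    x$k, x$se_k, x$A, x$y0, x$flag
  ))
  invisible(x)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> k_fast = %.4g s^-1, k_slow = %.4g s^-1 (%d traces) [%s]\n",
    x$k_fast, x$k_slow, x$n_traces, x$flag
  ))
  invisible(x)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> k_on = %.3g x 1e6 M^-1 s^-1, k_off = %.3g x 1e-5 s^-1, KD = %.3g pM\n",
    x$k_on / 1e6, x$k_off * 1e5, x$kd * 1e12
  ))
  invisible(x)
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$bound_only) {
    cat(sprintf(
      "<titration_fit> rt = %.3g pM: KD < %.3g pM (bound only)\n",
      x$rt * 1e12, x$bound * 1e12
    ))
  } else {
    cat(sprintf(
      "<titration_fit> rt = %.3g pM: KD = %.3g pM (%.0f%% CI %.3g-%.3g)\n",
      x$rt * 1e12, x$kd * 1e12, 100 * x$conf_level,
      x$ci[1] * 1e12, x$ci[2] * 1e12
    ))
  }
  invisible(x)
}

#' @export
print.stabilization_panel <- function(x, ...) {
  cat(sprintf(
    "<stabilization_panel> k_free = %.3g s^-1, detection limit %.3g s^-1\n",
    x$k_free, x$detection_limit
  ))
  print(x$panel)
  invisible(x)
}
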