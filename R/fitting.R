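# Nonlinear least-squares backbone. Rates are log-parameterized (they span
# ~1e-5..1e-1 s^-1 and must stay positive); Levenberg-Marquardt refines from
# a rate-profile initialization in which amplitude and offset are solved
# linearly on a log-spaced rate grid, so no fit depends on a lucky start.

run_nlsfit <- function(par0, resid_fn) {
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 100000)
  )
  n <- length(fit$fvec)
  p <- length(par0)
  rss <- fit$deviance
  sigma <- if (n > p) sqrt(rss / (n - p)) else NA_real_
  se <- tryCatch(
    {
      covm <- sigma^2 * chol2inv(chol(fit$hessian))
      s <- sqrt(pmax(diag(covm), 0))
      names(s) <- names(par0)
      s
    },
    error = function(e) stats::setNames(rep(NA_real_, p), names(par0))
  )
  list(
    par = fit$par, se = se, rss = rss, sigma = sigma, n = n,
    converged = fit$info %in% 1:4, info = fit$info, message = fit$message
  )
}

# Profile initialization for y = y0 - A * exp(-k t): for each k on a log grid
# the model is linear in (A, y0). Returns the grid minimum.
profile_exp_init <- function(t, y, n_grid = 50) {
  t0 <- t - t[1]
  t_range <- max(t0)
  ks <- exp(seq(log(0.02 / t_range), log(200 / t_range), length.out = n_grid))
  best <- list(rss = Inf)
  for (k in ks) {
    x <- exp(-k * t0)
    f <- stats::.lm.fit(cbind(1, x), y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) {
      best <- list(k = k, y0 = f$coefficients[1], A = -f$coefficients[2], rss = rss)
    }
  }
  best
}

# Single-trace fit of y = y0 - A exp(-k t); A free in sign (rise or decay).
fit_exp_trace <- function(t, y) {
  init <- profile_exp_init(t, y)
  t0 <- t - t[1]
  resid_fn <- function(par) {
    y - (par[["y0"]] - par[["A"]] * exp(-exp(par[["log_k"]]) * t0))
  }
  par0 <- c(log_k = log(init$k), A = init$A, y0 = init$y0)
  res <- run_nlsfit(par0, resid_fn)
  k <- exp(res$par[["log_k"]])
  list(
    k = k, A = res$par[["A"]], y0 = res$par[["y0"]],
    se_k = k * res$se[["log_k"]], se_A = res$se[["A"]], se_y0 = res$se[["y0"]],
    rss = res$rss, sigma = res$sigma, n = res$n, converged = res$converged
  )
}

new_tnfkin_fit <- function(x, class) structure(x, class = c(class, "tnfkin_fit"))

#' Fit the monomerization rate of a single trace
#'
#' Least-squares fit of the single-exponential model
#' `y(t) = y0 - A * exp(-k * t)` to a monomerization (or stabilization) phase
#' trace, with `k > 0` enforced by log-parameterization and `se_k` from the
#' parameter covariance. A trace whose decayed amplitude over the recorded
#' window is indistinguishable from the residual noise is flagged
#' `below_detection` rather than assigned a spurious rate; absence of
#' monomerization is an amplitude statement, not a zero-rate estimate.
#'
#' @param trace a single-trace tibble, phase `"monomerization"` or
#'   `"stabilization"`, with at least 5 points.
#' @param detect_alpha significance level of the decay-detection test (an
#'   F-ratio of the exponential fit against a constant-signal model). The
#'   strict default 1e-3 keeps flat traces from being assigned spurious
#'   rates; genuine decays exceed it by many orders of magnitude.
#' @return an object of class `exp_fit`: fields `k`, `A`, `y0` (s^-1 and
#'   signal units), `se_k`, `se_A`, `se_y0`, `rss`, `sigma` (residual sd),
#'   `n`, `flag` (`"ok"` or `"below_detection"`), `converged`, plus the data
#'   and fitted values for plotting.
#' @export
fit_monomerization <- function(trace, detect_alpha = 1e-3) {
  trace <- validate_traces(trace, single = TRUE)
  if (!trace$phase[1] %in% c("monomerization", "stabilization")) {
    rlang::abort("fit_monomerization expects a monomerization or stabilization phase trace")
  }
  if (nrow(trace) < 5) rlang::abort("need at least 5 points")
  f <- fit_exp_trace(trace$time_s, trace$signal)
  if (!f$converged) {
    rlang::abort(sprintf(
      "monomerization fit did not converge (rss = %g, n = %d)", f$rss, f$n
    ))
  }
  t_window <- max(trace$time_s) - min(trace$time_s)
  amp_window <- abs(f$A) * (1 - exp(-f$k * t_window))
  noise_floor <- max(2 * f$sigma, 1e-9 * max(1, abs(f$y0)), na.rm = TRUE)
  # decay detection: the exponential (3 par) must beat a constant signal
  # (1 par) decisively, otherwise the fitted rate is a noise artifact
  n <- f$n
  rss0 <- sum((trace$signal - mean(trace$signal))^2)
  f_stat <- ((rss0 - f$rss) / 2) / (f$rss / max(n - 3, 1))
  p_detect <- if (is.finite(f_stat)) {
    stats::pf(max(f_stat, 0), 2, max(n - 3, 1), lower.tail = FALSE)
  } else if (rss0 > f$rss) 0 else 1 # rss == 0: exact fit beats exact constant
  flag <- if (amp_window < noise_floor || p_detect > detect_alpha) {
    "below_detection"
  } else {
    "ok"
  }
  fitted <- mono_exp(trace$time_s - trace$time_s[1], f$k, f$A, f$y0)
  new_tnfkin_fit(
    c(f[c("k", "A", "y0", "se_k", "se_A", "se_y0", "rss", "sigma", "n", "converged")],
      list(flag = flag, data = trace, fitted = fitted)
    ),
    "exp_fit"
  )
}

#' Fit replicate monomerization traces and summarize the rate
#'
#' Fits each replicate independently and reports the mean rate with its
#' standard error of the mean (`sd / sqrt(n)`), the convention used for
#' replicate spots on one sensor channel.
#'
#' @param traces trace tibble with >= 1 replicates.
#' @return list with `fits` (named list of [fit_monomerization()] results),
#'   `summary` tibble (one row per replicate) and `k_mean`, `k_sem`,
#'   `n_used`, `excluded` (tibble of replicate/reason).
#' @export
fit_monomerization_replicates <- function(traces) {
  grps <- split_traces(validate_traces(traces))
  fits <- list()
  excluded <- tibble::tibble(replicate = character(), reason = character())
  for (nm in names(grps)) {
    f <- tryCatch(fit_monomerization(grps[[nm]]), error = function(e) e)
    if (inherits(f, "error")) {
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        replicate = nm, reason = conditionMessage(f)
      ))
    } else if (f$flag == "below_detection") {
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        replicate = nm, reason = "amplitude below detection"
      ))
    } else {
      fits[[nm]] <- f
    }
  }
  ks <- vapply(fits, function(f) f$k, numeric(1))
  summary <- tibble::tibble(
    replicate = names(fits),
    k = unname(ks),
    se_k = vapply(fits, function(f) f$se_k, numeric(1), USE.NAMES = FALSE),
    A = vapply(fits, function(f) f$A, numeric(1), USE.NAMES = FALSE),
    y0 = vapply(fits, function(f) f$y0, numeric(1), USE.NAMES = FALSE)
  )
  list(
    fits = fits, summary = summary,
    k_mean = if (length(ks) > 0) mean(ks) else NA_real_,
    k_sem = if (length(ks) > 1) stats::sd(ks) / sqrt(length(ks)) else NA_real_,
    n_used = length(ks), excluded = excluded
  )
}

#' Global-fit specification
#'
#' Controls which parameters are shared across a concentration series in the
#' global kinetic fits: rate constants are global parameters by default while
#' amplitudes and offsets are independent per curve.
#'
#' @param share_k_off,share_k_on share the rate constant across traces.
#' @param amplitudes_free,offsets_free per-trace amplitude/offset (otherwise
#'   a single shared value).
#' @return a `global_fit_spec` list.
#' @export
global_fit_spec <- function(share_k_off = TRUE, share_k_on = TRUE,
                            amplitudes_free = TRUE, offsets_free = TRUE) {
  structure(
    list(
      share_k_off = share_k_off, share_k_on = share_k_on,
      amplitudes_free = amplitudes_free, offsets_free = offsets_free
    ),
    class = "global_fit_spec"
  )
}

check_shared <- function(spec, n_traces, rate_flag) {
  if (n_traces > 1 && !spec[[rate_flag]] && !(!spec$amplitudes_free || !spec$offsets_free)) {
    rlang::abort("global fit of multiple traces requires at least one shared parameter")
  }
}

trace_meta_row <- function(g) {
  tibble::tibble(
    replicate_id = g$replicate_id[1], conc_M = g$conc_M[1],
    scavenger = g$scavenger[1]
  )
}

#' Global fit of dissociation curves with a shared rate constant
#'
#' Fits `y(t) = A_i * exp(-k_off * t) + y0_i` simultaneously to a set of
#' dissociation traces: a single `k_off` (global parameter) minimizes the
#' pooled residual sum of squares while each curve keeps its own amplitude
#' and offset. Each trace is also fitted individually; the spread of the
#' per-trace rates supplies the standard error of the mean reported in
#' [kinetics_report()].
#'
#' @param traces dissociation-phase trace tibble (one or more traces).
#' @param spec a [global_fit_spec()].
#' @return an object of class `dissoc_fit`: `k_off` (s^-1), `se_k_off`
#'   (covariance-based), `sem_k_off` (SEM over per-trace fits, `NA` for a
#'   single trace), `per_trace` tibble (amplitude, offset, individual
#'   `k_off`), `rss`, `sigma`, `n_traces`, data and fitted values.
#' @export
global_fit_dissociation <- function(traces, spec = global_fit_spec()) {
  traces <- validate_traces(traces)
  if (!all(traces$phase == "dissociation")) {
    rlang::abort("all traces must be dissociation phase")
  }
  grps <- split_traces(traces)
  n <- length(grps)
  check_shared(spec, n, "share_k_off")
  if (n == 1) {
    rlang::warn("single trace supplied: global fit degenerates to a per-trace fit")
  }
  ind <- lapply(grps, function(g) fit_exp_trace(g$time_s, g$signal))
  k0 <- exp(mean(log(pmax(vapply(ind, `[[`, numeric(1), "k"), 1e-12))))
  n_A <- if (spec$amplitudes_free) n else 1
  n_y <- if (spec$offsets_free) n else 1
  A0 <- vapply(ind, function(f) -f$A, numeric(1)) # Eq-3 amplitude sign
  y00 <- vapply(ind, `[[`, numeric(1), "y0")
  par0 <- c(
    log_k_off = log(k0),
    if (spec$amplitudes_free) A0 else mean(A0),
    if (spec$offsets_free) y00 else mean(y00)
  )
  idx_A <- 1 + seq_len(n_A)
  idx_y <- 1 + n_A + seq_len(n_y)
  resid_fn <- function(par) {
    k <- exp(par[1])
    unlist(lapply(seq_len(n), function(i) {
      A <- par[idx_A[min(i, n_A)]]
      y0 <- par[idx_y[min(i, n_y)]]
      g <- grps[[i]]
      g$signal - dissociation_signal(g$time_s - g$time_s[1], k, A, y0)
    }), use.names = FALSE)
  }
  res <- run_nlsfit(par0, resid_fn)
  if (!res$converged) rlang::abort("global dissociation fit did not converge")
  k_off <- exp(res$par[[1]])
  ks_ind <- vapply(ind, `[[`, numeric(1), "k")
  per_trace <- dplyr::bind_rows(lapply(grps, trace_meta_row))
  per_trace$A <- unname(res$par[idx_A[pmin(seq_len(n), n_A)]])
  per_trace$y0 <- unname(res$par[idx_y[pmin(seq_len(n), n_y)]])
  per_trace$k_off_individual <- unname(ks_ind)
  fitted <- purrr::map2(grps, seq_len(n), function(g, i) {
    dissociation_signal(
      g$time_s - g$time_s[1], k_off,
      per_trace$A[i], per_trace$y0[i]
    )
  })
  new_tnfkin_fit(list(
    k_off = k_off, se_k_off = k_off * res$se[[1]],
    sem_k_off = if (n > 1) stats::sd(ks_ind) / sqrt(n) else NA_real_,
    per_trace = per_trace, rss = res$rss, sigma = res$sigma,
    n_traces = n, n_points = res$n, converged = res$converged,
    data = traces, fitted = fitted, spec = spec
  ), "dissoc_fit")
}

#' Global fit of association curves with a shared on-rate
#'
#' Fits `y(t) = y0_i - A_i * exp(-(c_i * k_on + k_off) * t)` simultaneously
#' across the concentration series, with `k_on` shared (global parameter) and
#' `k_off` fixed at the value determined from the dissociation fit — the
#' two-step procedure of the standard kinetic analysis.
#'
#' @param traces association-phase trace tibble; every trace must have
#'   `conc_M > 0`.
#' @param k_off dissociation rate constant, s^-1, from
#'   [global_fit_dissociation()].
#' @param spec a [global_fit_spec()].
#' @return an object of class `assoc_fit`: `k_on` (M^-1 s^-1), `se_k_on`,
#'   `k_off` (as supplied), `per_trace` tibble with per-curve amplitude,
#'   offset, individually fitted `k_obs` and the global-model
#'   `k_obs = c * k_on + k_off`, plus fit diagnostics.
#' @export
global_fit_association <- function(traces, k_off, spec = global_fit_spec()) {
  traces <- validate_traces(traces)
  if (!all(traces$phase == "association")) {
    rlang::abort("all traces must be association phase")
  }
  if (any(traces$conc_M <= 0)) {
    rlang::abort("association traces require conc_M > 0 (zero-concentration traces carry no k_on information)")
  }
  stopifnot(k_off >= 0)
  grps <- split_traces(traces)
  n <- length(grps)
  check_shared(spec, n, "share_k_on")
  concs <- vapply(grps, function(g) g$conc_M[1], numeric(1))
  if (n > 1 && length(unique(concs)) == 1) {
    rlang::warn("all concentrations equal: k_on and k_off trade off; estimate may be unidentifiable")
  }
  ind <- lapply(grps, function(g) fit_exp_trace(g$time_s, g$signal))
  k_obs_ind <- vapply(ind, `[[`, numeric(1), "k")
  k_on0 <- stats::median((k_obs_ind - k_off) / concs)
  if (!is.finite(k_on0) || k_on0 <= 0) k_on0 <- stats::median(k_obs_ind / concs)
  n_A <- if (spec$amplitudes_free) n else 1
  n_y <- if (spec$offsets_free) n else 1
  A0 <- vapply(ind, `[[`, numeric(1), "A")
  y00 <- vapply(ind, `[[`, numeric(1), "y0")
  par0 <- c(
    log_k_on = log(k_on0),
    if (spec$amplitudes_free) A0 else mean(A0),
    if (spec$offsets_free) y00 else mean(y00)
  )
  idx_A <- 1 + seq_len(n_A)
  idx_y <- 1 + n_A + seq_len(n_y)
  resid_fn <- function(par) {
    k_on <- exp(par[1])
    unlist(lapply(seq_len(n), function(i) {
      g <- grps[[i]]
      g$signal - association_signal(
        g$time_s - g$time_s[1], g$conc_M[1], k_on, k_off,
        par[idx_A[min(i, n_A)]], par[idx_y[min(i, n_y)]]
      )
    }), use.names = FALSE)
  }
  res <- run_nlsfit(par0, resid_fn)
  if (!res$converged) rlang::abort("global association fit did not converge")
  k_on <- exp(res$par[[1]])
  per_trace <- dplyr::bind_rows(lapply(grps, trace_meta_row))
  per_trace$A <- unname(res$par[idx_A[pmin(seq_len(n), n_A)]])
  per_trace$y0 <- unname(res$par[idx_y[pmin(seq_len(n), n_y)]])
  per_trace$k_obs_individual <- unname(k_obs_ind)
  per_trace$k_obs_global <- k_obs_rate(per_trace$conc_M, k_on, k_off)
  fitted <- purrr::map2(grps, seq_len(n), function(g, i) {
    association_signal(
      g$time_s - g$time_s[1], g$conc_M[1], k_on, k_off,
      per_trace$A[i], per_trace$y0[i]
    )
  })
  new_tnfkin_fit(list(
    k_on = k_on, se_k_on = k_on * res$se[[1]], k_off = k_off,
    per_trace = per_trace, rss = res$rss, sigma = res$sigma,
    n_traces = n, n_points = res$n, converged = res$converged,
    data = traces, fitted = fitted, spec = spec
  ), "assoc_fit")
}

# Linear solve of per-trace (a_fast, a_slow, y0) given the two rates;
# used for multi-start candidate scoring and initialization.
biexp_linear_solve <- function(grps, k_fast, k_slow) {
  rss <- 0
  coefs <- matrix(0, length(grps), 3,
    dimnames = list(NULL, c("a_fast", "a_slow", "y0"))
  )
  for (i in seq_along(grps)) {
    g <- grps[[i]]
    t0 <- g$time_s - g$time_s[1]
    X <- cbind(-exp(-k_fast * t0), -exp(-k_slow * t0), 1)
    f <- stats::.lm.fit(X, g$signal)
    coefs[i, ] <- f$coefficients
    rss <- rss + sum(f$residuals^2)
  }
  list(coefs = coefs, rss = rss)
}

#' Global bi-exponential fit of dissociation traces
#'
#' Fits `y(t) = y0_i - a_fast_i * exp(-k_fast * t) - a_slow_i * exp(-k_slow * t)`
#' with both rate constants shared across traces and amplitudes/offsets free
#' per trace — the decomposition that separates trimer monomerization (fast)
#' from scavenger dissociation (slow) on partially saturated surfaces.
#' Initialization is multi-start: `k_slow` is seeded from a single-exponential
#' fit of the tail (last 25% of each trace), `k_fast` from the residual early
#' phase, alongside fixed-ratio alternatives; the candidate with the lowest
#' profiled residual sum of squares starts the full refinement, and
#' `k_fast > k_slow` is enforced by ordering after the fit.
#'
#' @param traces dissociation-phase trace tibble (>= 1 trace).
#' @return an object of class `biexp_fit`: `k_fast`, `k_slow` (s^-1) with
#'   standard errors, `per_trace` amplitudes/offsets, `flag` — `"ok"`,
#'   `"effective_mono_slow"`/`"effective_mono_fast"` when one component is
#'   unresolvable (amplitude below the noise floor, or decaying so little
#'   over the window that it trades off against the offset), with the
#'   resolvable rate in `k_effective`, or `"rates_unresolved"` when the
#'   fitted rates differ by less than 1.5-fold — and fit diagnostics.
#' @export
fit_biexp_global <- function(traces) {
  traces <- validate_traces(traces)
  if (!all(traces$phase == "dissociation")) {
    rlang::abort("all traces must be dissociation phase")
  }
  grps <- split_traces(traces)
  n <- length(grps)
  # tail fit -> slow rate seed; early residual -> fast rate seed
  k_slow0 <- exp(mean(log(vapply(grps, function(g) {
    tail_sel <- g$time_s >= stats::quantile(g$time_s, 0.75)
    f <- fit_exp_trace(g$time_s[tail_sel], g$signal[tail_sel])
    max(f$k, 1e-10)
  }, numeric(1)))))
  k_fast0 <- exp(mean(log(vapply(grps, function(g) {
    tail_sel <- g$time_s >= stats::quantile(g$time_s, 0.75)
    f_tail <- fit_exp_trace(g$time_s[tail_sel], g$signal[tail_sel])
    r <- g$signal - mono_exp(g$time_s - g$time_s[1], f_tail$k, f_tail$A, f_tail$y0)
    early <- g$time_s <= stats::quantile(g$time_s, 0.25)
    if (sum(early) < 4 || stats::sd(r[early]) == 0) {
      return(k_slow0 * 20)
    }
    f <- fit_exp_trace(g$time_s[early], r[early])
    max(f$k, k_slow0 * 2)
  }, numeric(1)))))
  candidates <- list(
    c(k_fast0, k_slow0), c(10 * k_slow0, k_slow0), c(50 * k_slow0, k_slow0),
    c(k_fast0, k_fast0 / 30)
  )
  scored <- lapply(candidates, function(kk) {
    c(list(k = kk), biexp_linear_solve(grps, kk[1], kk[2]))
  })
  best <- scored[[which.min(vapply(scored, `[[`, numeric(1), "rss"))]]
  par0 <- c(
    log_k_fast = log(best$k[1]), log_k_slow = log(best$k[2]),
    best$coefs[, "a_fast"], best$coefs[, "a_slow"], best$coefs[, "y0"]
  )
  idx_af <- 2 + seq_len(n)
  idx_as <- 2 + n + seq_len(n)
  idx_y <- 2 + 2 * n + seq_len(n)
  resid_fn <- function(par) {
    kf <- exp(par[1])
    ks <- exp(par[2])
    unlist(lapply(seq_len(n), function(i) {
      g <- grps[[i]]
      g$signal - bi_exp(
        g$time_s - g$time_s[1], kf, ks,
        par[idx_af[i]], par[idx_as[i]], par[idx_y[i]]
      )
    }), use.names = FALSE)
  }
  res <- run_nlsfit(par0, resid_fn)
  if (!res$converged) rlang::abort("bi-exponential global fit did not converge")
  k_fast <- exp(res$par[[1]])
  k_slow <- exp(res$par[[2]])
  a_fast <- res$par[idx_af]
  a_slow <- res$par[idx_as]
  se_kf <- k_fast * res$se[[1]]
  se_ks <- k_slow * res$se[[2]]
  if (k_fast < k_slow) { # enforce ordering, swapping component labels
    tmp <- k_fast; k_fast <- k_slow; k_slow <- tmp
    tmp <- se_kf; se_kf <- se_ks; se_ks <- tmp
    tmp <- a_fast; a_fast <- a_slow; a_slow <- tmp
  }
  noise_floor <- 2 * max(res$sigma, 1e-12)
  t_window <- max(vapply(grps, function(g) diff(range(g$time_s)), numeric(1)))
  flag <- "ok"
  k_effective <- NA_real_
  if (k_fast / k_slow < 1.5) {
    flag <- "rates_unresolved"
  } else if (max(abs(a_fast)) < noise_floor) {
    flag <- "effective_mono_slow"
    k_effective <- k_slow
  } else if (max(abs(a_slow)) < noise_floor || k_slow * t_window < 0.05) {
    # a component decaying < 5% over the window trades off against the
    # offset and cannot be resolved; only the fast rate is meaningful
    flag <- "effective_mono_fast"
    k_effective <- k_fast
  }
  per_trace <- dplyr::bind_rows(lapply(grps, trace_meta_row))
  per_trace$a_fast <- unname(a_fast)
  per_trace$a_slow <- unname(a_slow)
  per_trace$y0 <- unname(res$par[idx_y])
  fitted <- purrr::map2(grps, seq_len(n), function(g, i) {
    bi_exp(
      g$time_s - g$time_s[1], k_fast, k_slow,
      per_trace$a_fast[i], per_trace$a_slow[i], per_trace$y0[i]
    )
  })
  new_tnfkin_fit(list(
    k_fast = k_fast, k_slow = k_slow, se_k_fast = se_kf, se_k_slow = se_ks,
    k_effective = k_effective,
    per_trace = per_trace, flag = flag, rss = res$rss, sigma = res$sigma,
    n_traces = n, n_points = res$n, converged = res$converged,
    data = traces, fitted = fitted
  ), "biexp_fit")
}

#' Choose between mono- and bi-exponential decay models
#'
#' Fits both the single-exponential and the bi-exponential model to one trace
#' and compares them with the small-sample-corrected information criterion
#' (AICc) and an F-ratio on residual sums of squares. `"bi"` is returned only
#' when both criteria prefer the richer model at level `alpha` and the two
#' fitted rates are resolvable; when the criteria disagree the decision falls
#' back to the parsimonious `"mono"` with `ambiguous = TRUE`.
#'
#' @param trace a single-trace tibble with >= 10 points.
#' @param alpha F-test significance level (default 0.05).
#' @return an object of class `decay_model_selection`: `decision` (`"mono"`
#'   or `"bi"`), `ambiguous` flag, both fits, the AICc values, the F
#'   statistic and its p-value.
#' @export
select_decay_model <- function(trace, alpha = 0.05) {
  trace <- validate_traces(trace, single = TRUE)
  if (nrow(trace) < 10) rlang::abort("model selection needs at least 10 points")
  n <- nrow(trace)
  mono <- fit_exp_trace(trace$time_s, trace$signal)
  # a mono fit at numerical-zero residuals leaves no evidence for a second
  # component; F-ratios on rounding noise are meaningless
  if (sqrt(mono$rss / n) < 1e-7 * max(stats::sd(trace$signal), .Machine$double.eps)) {
    return(new_tnfkin_fit(list(
      decision = "mono", ambiguous = FALSE, mono_fit = mono, bi_fit = NULL,
      aicc_mono = -Inf, aicc_bi = NA_real_, f_stat = NA_real_,
      p_value = NA_real_, alpha = alpha, n = n
    ), "decay_model_selection"))
  }
  bi <- fit_biexp_global(dplyr::mutate(trace, phase = "dissociation"))
  aicc <- function(rss, p) {
    p <- p + 1 # + residual variance
    n * log(max(rss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
  }
  aicc_mono <- aicc(mono$rss, 3)
  aicc_bi <- aicc(bi$rss, 5)
  df2 <- n - 5
  f_stat <- ((mono$rss - bi$rss) / 2) / (bi$rss / df2)
  p_value <- stats::pf(max(f_stat, 0), 2, df2, lower.tail = FALSE)
  bi_usable <- bi$flag %in% c("ok")
  prefer_bi_aicc <- aicc_bi < aicc_mono
  prefer_bi_f <- is.finite(p_value) && p_value < alpha
  decision <- if (prefer_bi_aicc && prefer_bi_f && bi_usable) "bi" else "mono"
  ambiguous <- bi_usable && (prefer_bi_aicc != prefer_bi_f)
  new_tnfkin_fit(list(
    decision = decision, ambiguous = ambiguous,
    mono_fit = mono, bi_fit = bi,
    aicc_mono = aicc_mono, aicc_bi = aicc_bi,
    f_stat = f_stat, p_value = p_value, alpha = alpha, n = n
  ), "decay_model_selection")
}

#' Assemble a kinetic rate/affinity report
#'
#' Combines a global association and dissociation fit into the standard rate
#' table row: `k_on`, `k_off`, `KD = k_off / k_on`. The `k_off` uncertainty
#' is the standard error of the mean of the individually fitted per-trace
#' `k_off` values (`NA` for a single trace); the `k_on` uncertainty comes
#' from the global-fit covariance; `se_kd` is propagated to first order.
#'
#' @param assoc an `assoc_fit` from [global_fit_association()].
#' @param dissoc a `dissoc_fit` from [global_fit_dissociation()].
#' @return an object of class `kinetic_fit` with fields `k_on` (M^-1 s^-1),
#'   `k_off` (s^-1), `kd` (mol/L), their standard errors, and the per-trace
#'   amplitude/offset tables of both phases.
#' @export
kinetics_report <- function(assoc, dissoc) {
  stopifnot(inherits(assoc, "assoc_fit"), inherits(dissoc, "dissoc_fit"))
  k_on <- assoc$k_on
  k_off <- dissoc$k_off
  kd <- kd_from_rates(k_on, k_off)
  se_k_off <- dissoc$sem_k_off
  se_k_on <- assoc$se_k_on
  rel_on <- if (is.finite(se_k_on)) (se_k_on / k_on)^2 else 0
  rel_off <- if (is.finite(se_k_off) && k_off > 0) (se_k_off / k_off)^2 else 0
  se_kd <- kd * sqrt(rel_on + rel_off)
  new_tnfkin_fit(list(
    k_on = k_on, k_off = k_off, kd = kd,
    se_k_on = se_k_on, se_k_off = se_k_off, se_kd = se_kd,
    assoc = assoc, dissoc = dissoc
  ), "kinetic_fit")
}
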