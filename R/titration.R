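titration_model <- function(lt, rt, kd, A, y0) {
  y0 + A * (1 - equilibrium_bound_fraction(rt, lt, kd))
}

# Profile initialization: for each kd on a log grid the response model is
# linear in (A, y0).
profile_titration_init <- function(lt, resp, rt, n_grid = 60) {
  kds <- exp(seq(log(min(lt[lt > 0]) / 300), log(max(lt) * 30), length.out = n_grid))
  best <- list(rss = Inf)
  for (kd in kds) {
    x <- 1 - equilibrium_bound_fraction(rt, lt, kd)
    f <- stats::.lm.fit(cbind(1, x), resp)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) {
      best <- list(kd = kd, y0 = f$coefficients[1], A = f$coefficients[2], rss = rss)
    }
  }
  best
}

fit_titration_point <- function(lt, resp, rt, init = NULL) {
  if (is.null(init)) init <- profile_titration_init(lt, resp, rt)
  resid_fn <- function(par) {
    resp - titration_model(lt, rt, exp(par[["log_kd"]]), par[["A"]], par[["y0"]])
  }
  par0 <- c(log_kd = log(init$kd), A = init$A, y0 = init$y0)
  res <- run_nlsfit(par0, resid_fn)
  list(
    kd = exp(res$par[["log_kd"]]), A = res$par[["A"]], y0 = res$par[["y0"]],
    se_log_kd = res$se[["log_kd"]], rss = res$rss, sigma = res$sigma,
    n = res$n, converged = res$converged
  )
}

#' Fit a solution-equilibrium titration to the depletion-corrected isotherm
#'
#' Least-squares fit of `response(lt) = y0 + A * (1 - b(rt, lt, kd))`, where
#' `b` is the exact mass-action bound fraction
#' ([equilibrium_bound_fraction()]) — the free-receptor readout of the
#' residual-free-TNF titration assay. The receptor concentration `rt` is
#' fixed and known; `kd >= 0` is enforced by log-parameterization.
#' Confidence intervals come from a seeded residual bootstrap.
#'
#' When the assay is depletion-limited (`kd` well below `rt`, so the
#' transition midpoint `lt = kd + rt/2` is set by `rt` rather than `kd`) or
#' the transition is not bracketed by the titrant grid, the fit reports an
#' upper bound (the upper confidence limit) instead of a point estimate,
#' flagged via `bound_only`.
#'
#' @param points tibble with columns `lt_M` (titrant concentration, mol/L)
#'   and `response`; >= 6 points spanning the transition. Points are sorted
#'   by `lt_M` internally, so the fit is order-invariant.
#' @param rt total receptor concentration, mol/L (fixed).
#' @param nboot residual-bootstrap resamples (default 1000).
#' @param conf_level bootstrap confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `titration_fit`: `kd`, `A`, `y0`, `se_kd`
#'   (bootstrap sd), `ci` (log-normal bootstrap interval), `bound_only`, `bound`
#'   (upper confidence limit, mol/L), `rt`, diagnostics and the data.
#' @export
fit_titration <- function(points, rt, nboot = 1000, conf_level = 0.95,
                          seed = 1) {
  stopifnot(is.data.frame(points), rt > 0)
  if (!all(c("lt_M", "response") %in% names(points))) {
    rlang::abort("`points` needs columns lt_M and response")
  }
  if (nrow(points) == 0) rlang::abort("empty titration table")
  if (nrow(points) < 6) rlang::abort("need at least 6 titration points")
  points <- points[order(points$lt_M), , drop = FALSE]
  lt <- points$lt_M
  resp <- points$response
  fit <- fit_titration_point(lt, resp, rt)
  if (!fit$converged) rlang::abort("titration fit did not converge")
  fitted <- titration_model(lt, rt, fit$kd, fit$A, fit$y0)
  # variance-inflated residuals: raw LS residuals underestimate the noise sd
  # by sqrt((n - p)/n), which makes the bootstrap undercover at small n
  res <- (resp - fitted) * sqrt(length(resp) / max(length(resp) - 3, 1))
  boot_kd <- withr::with_seed(seed, {
    vapply(seq_len(nboot), function(b) {
      y_star <- fitted + sample(res, length(res), replace = TRUE)
      f <- tryCatch(
        fit_titration_point(lt, y_star, rt,
          init = list(kd = fit$kd, A = fit$A, y0 = fit$y0)
        ),
        error = function(e) NULL
      )
      if (is.null(f) || !f$converged) NA_real_ else f$kd
    }, numeric(1))
  })
  boot_kd <- boot_kd[is.finite(boot_kd) & boot_kd > 0]
  alpha <- 1 - conf_level
  # normal-approximation interval on log KD with the bootstrap spread:
  # better calibrated than the raw percentile interval at small n for a
  # positive scale parameter
  ci <- if (length(boot_kd) >= 10) {
    z <- stats::qnorm(1 - alpha / 2)
    sd_log <- stats::sd(log(boot_kd))
    exp(log(fit$kd) + c(-1, 1) * z * sd_log)
  } else {
    c(NA_real_, NA_real_)
  }
  lt_half <- fit$kd + rt / 2 # half-free-receptor titrant concentration
  bracketed <- lt_half >= min(lt) && lt_half <= max(lt)
  depletion_limited <- fit$kd < rt / 10
  bound_only <- depletion_limited || !bracketed
  bound <- if (bound_only) max(ci[2], fit$kd, na.rm = TRUE) else NA_real_
  new_tnfkin_fit(list(
    kd = fit$kd, A = fit$A, y0 = fit$y0,
    se_kd = if (length(boot_kd) >= 10) stats::sd(boot_kd) else NA_real_,
    ci = ci, conf_level = conf_level,
    bound_only = bound_only, bound = bound,
    depletion_limited = depletion_limited, bracketed = bracketed,
    rt = rt, rss = fit$rss, sigma = fit$sigma, n = fit$n,
    nboot_effective = length(boot_kd), converged = fit$converged,
    data = points, fitted = fitted
  ), "titration_fit")
}
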