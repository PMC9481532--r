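# Double-Gaussian(+temporal derivative) HRF fitting by direct search, and
# 10%-of-maximum onset times.

# Map unconstrained search parameters to (mu1, mu2, sigma1, sigma2):
# centers are kept inside the data window, widths in [0.5, 10] s,
# preventing degenerate fits.
.hrf_nat <- function(theta, tmin, tmax) {
  mu <- tmin + (tmax - tmin) * stats::plogis(theta[1:2])
  sg <- 0.5 + 9.5 * stats::plogis(theta[3:4])
  list(mu1 = mu[1L], mu2 = mu[2L], sigma1 = sg[1L], sigma2 = sg[2L])
}

.hrf_inv <- function(mu1, mu2, sigma1, sigma2, tmin, tmax) {
  clamp <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
  c(stats::qlogis(clamp((c(mu1, mu2) - tmin) / (tmax - tmin))),
    stats::qlogis(clamp((c(sigma1, sigma2) - 0.5) / 9.5)))
}

# Design matrix of the four basis curves for given shape parameters; the
# amplitudes (a1, a2, d1, d2) enter linearly and are profiled out by OLS.
.hrf_design <- function(nat, t) {
  g1 <- exp(-(t - nat$mu1)^2 / (2 * nat$sigma1^2))
  g2 <- exp(-(t - nat$mu2)^2 / (2 * nat$sigma2^2))
  cbind(g1 = g1, g2 = g2,
        dg1 = -(t - nat$mu1) / nat$sigma1^2 * g1,
        dg2 = -(t - nat$mu2) / nat$sigma2^2 * g2)
}

#' Fit the double-Gaussian(+derivative) response model
#'
#' Minimizes the root-mean-squared error between [hrf_curve()] and the
#' event-locked mean series by Nelder-Mead simplex over the Gaussian
#' centers and widths (amplitude and derivative coefficients solved by
#' least squares at each step), with multiple restarts from jittered
#' initializations. Widths are bounded to [0.5, 10] s and centers to the
#' data window. Deterministic for a fixed seed.
#'
#' @param values event-locked mean series.
#' @param rel_time time axis (s relative to the event), covering the
#'   response window.
#' @param restarts number of jittered restarts, default 8.
#' @param seed RNG seed.
#' @return an object of class `hrf_fit`: list with `params`
#'   ([hrf_params()]), `rmse`, `onset` (10% onset, s), `max_amplitude`,
#'   `fitted` (curve on `rel_time`), `r_squared`, `low_confidence` flag
#'   (variance explained < 0.2), `converged`.
#' @export
fit_hrf <- function(values, rel_time, restarts = 8, seed = 1) {
  stopifnot(length(values) == length(rel_time))
  tmin <- min(rel_time); tmax <- max(rel_time)
  obj <- function(theta) {
    nat <- .hrf_nat(theta, tmin, tmax)
    D <- .hrf_design(nat, rel_time)
    fit <- lm.fit(D, values)
    sqrt(mean(fit$residuals^2))
  }
  # data-driven starts: positive-peak time for mu1, minimum time for mu2
  i_max <- which.max(values); i_min <- which.min(values)
  th0 <- .hrf_inv(rel_time[i_max], rel_time[i_min], 2, 3, tmin, tmax)
  best <- NULL
  conv <- FALSE
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      th <- if (r == 1L) th0 else th0 + rnorm(4L, sd = 1)
      o <- optim(th, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-9))
      if (is.null(best) || o$value < best$value) best <- o
      if (o$convergence == 0L) conv <- TRUE
    }
  })
  nat <- .hrf_nat(best$par, tmin, tmax)
  D <- .hrf_design(nat, rel_time)
  ab <- lm.fit(D, values)$coefficients
  ab[is.na(ab)] <- 0
  params <- hrf_params(a1 = ab[["g1"]], a2 = ab[["g2"]],
                       mu1 = nat$mu1, mu2 = nat$mu2,
                       sigma1 = nat$sigma1, sigma2 = nat$sigma2,
                       d1 = ab[["dg1"]], d2 = ab[["dg2"]])
  fitted <- hrf_curve(params, rel_time)
  rmse <- sqrt(mean((values - fitted)^2))
  r2 <- if (var(values) > 0) 1 - rmse^2 / mean((values - mean(values))^2) else 0
  fit <- structure(list(params = params, rmse = rmse,
                        max_amplitude = max(fitted), fitted = fitted,
                        rel_time = rel_time, r_squared = r2,
                        low_confidence = r2 < 0.2, converged = conv),
                   class = "hrf_fit")
  fit$onset <- tryCatch(hrf_onset(fit), error = function(e) NA_real_)
  if (!conv)
    warning("no restart converged; returning best-effort parameters",
            call. = FALSE)
  fit
}

#' Onset time of a fitted response: first crossing of a fraction of maximum
#'
#' The earliest time at which the fitted model curve reaches `fraction`
#' (default 0.1) of its positive maximum. Onset is defined on the positive
#' maximum (activation), so a curve with no positive part is an error.
#'
#' @param fit an `hrf_fit`, or an [hrf_params()] object with `rel_time`
#'   supplied.
#' @param fraction fraction of the maximum, default 0.1.
#' @param rel_time time axis, only needed when `fit` is a parameter set.
#' @return onset time (s).
#' @export
hrf_onset <- function(fit, fraction = 0.1, rel_time = NULL) {
  if (inherits(fit, "hrf_fit")) {
    curve <- fit$fitted
    t <- fit$rel_time
  } else {
    if (is.null(rel_time)) stop("`rel_time` required", call. = FALSE)
    t <- rel_time
    curve <- hrf_curve(fit, t)
  }
  mx <- max(curve)
  if (mx <= 0) stop("polarity error: fitted curve has no positive maximum",
                    call. = FALSE)
  t[which(curve >= fraction * mx)[1L]]
}

#' @export
print.hrf_fit <- function(x, ...) {
  cat("<hrf_fit> rmse =", signif(x$rmse, 4),
      " onset =", signif(x$onset, 4), "s",
      " max =", signif(x$max_amplitude, 4),
      if (x$low_confidence) " [low confidence]" else "", "\n")
  invisible(x)
}
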