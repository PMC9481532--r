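# Double-Gaussian hemodynamic response model, shared by the synthetic
# generator and the HRF fitter so that parameter recovery is well-posed.

#' Construct a double-Gaussian HRF parameter set
#'
#' The response model is a linear combination of two unit-height Gaussians
#' and their temporal derivatives:
#' \deqn{f(t) = a_1 G(t; \mu_1, \sigma_1) + a_2 G(t; \mu_2, \sigma_2)
#'            + d_1 G'(t; \mu_1, \sigma_1) + d_2 G'(t; \mu_2, \sigma_2)}
#' with \eqn{G(t) = \exp(-(t-\mu)^2 / 2\sigma^2)}. The derivative terms give
#' the fit temporal flexibility; the second Gaussian typically carries an
#' undershoot (negative \code{a2}).
#'
#' @param a1,a2 Gaussian amplitudes (a.u.).
#' @param mu1,mu2 Gaussian centers (s).
#' @param sigma1,sigma2 Gaussian widths (s), strictly positive.
#' @param d1,d2 temporal-derivative coefficients (a.u. * s).
#' @return an object of class `hrf_params`.
#' @export
#' @examples
#' p <- hrf_params(a1 = 1, mu1 = 0, sigma1 = 2)
#' curve <- hrf_curve(p, seq(-10, 20, by = 0.25))
hrf_params <- function(a1 = 1, mu1 = 0, sigma1 = 2,
                       a2 = 0, mu2 = 6, sigma2 = 3,
                       d1 = 0, d2 = 0) {
  if (!is.finite(sigma1) || sigma1 <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    stop("Gaussian widths must be positive", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2,
                 sigma1 = sigma1, sigma2 = sigma2, d1 = d1, d2 = d2),
            class = "hrf_params")
}

#' Evaluate the double-Gaussian(+derivative) model on a time axis
#'
#' @param params an [hrf_params()] object (or a list with the same fields).
#' @param t numeric time axis (s).
#' @return numeric vector, the model curve at `t`.
#' @export
hrf_curve <- function(params, t) {
  p <- params
  if (p$sigma1 <= 0 || p$sigma2 <= 0)
    stop("Gaussian widths must be positive", call. = FALSE)
  g1 <- exp(-(t - p$mu1)^2 / (2 * p$sigma1^2))
  g2 <- exp(-(t - p$mu2)^2 / (2 * p$sigma2^2))
  dg1 <- -(t - p$mu1) / p$sigma1^2 * g1
  dg2 <- -(t - p$mu2) / p$sigma2^2 * g2
  p$a1 * g1 + p$a2 * g2 + p$d1 * dg1 + p$d2 * dg2
}
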