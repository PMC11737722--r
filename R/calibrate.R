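#' Calibrate the residual noise level to a target p-value
#'
#' Chooses the residual standard deviation `sigma` so that, at the true
#' threshold cell, an F statistic computed with the true coefficients
#' and the true residual variance would land exactly at the upper-tail
#' probability `target_p`.  Writing `mu` for the noise-free model means
#' over the design and `q` for the number of retained hinge columns,
#' \deqn{\sigma^2 = \frac{\sum \mu_i^2}{q\, F^*},\qquad
#'       P(F_{q,n-q} > F^*) = target_p.}
#' This fixes the signal-to-noise ratio of a simulation in terms of the
#' evidence the truth cell would carry, rather than in raw units.
#'
#' @param truth a [dose_truth()] (its `sigma` is ignored).
#' @param target_p desired upper-tail probability at the truth cell.
#' @param collinear_tol hinge collinearity cutoff, see
#'   [build_design()].
#' @return The calibrated `sigma` (same units as the response).
#' @export
calibrate_sigma <- function(truth, target_p = 1e-4,
                            collinear_tol = 0.99) {
  validate_dose_truth(truth)
  d <- build_design(truth$design, truth$theta0, truth$phi0,
                    collinear_tol)
  q <- ncol(d$X)
  if (q == 0L)
    stop("calibrate_sigma: design has no supra-threshold observations")
  n <- nrow(truth$design)
  mu <- eq1_mean(truth$design$theta, truth$design$phi,
                 truth$theta0, truth$phi0, truth$c1, truth$c2)
  if (all(mu == 0))
    stop("calibrate_sigma: truth has no effect (all means zero)")
  f_star <- stats::qf(target_p, q, n - q, lower.tail = FALSE)
  sqrt(sum(mu^2) / (q * f_star))
}
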