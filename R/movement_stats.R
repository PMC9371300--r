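# Average travelled distance per state from the fitted step-length
# coefficients.  With covariates SL and log(SL) and uniform-in-distance
# availability, the implied step-length density is proportional to
#   d^{b_logSL} * exp(b_SL * d),
# i.e. a gamma density with shape 1 + b_logSL and rate -b_SL when
# b_SL < 0 and b_logSL > -1, whose mean is (1 + b_logSL) / (-b_SL).
# Outside that region the density (truncated to (eps, max_step]) has no
# gamma form and the mean is obtained by Metropolis sampling.

#' Closed-form mean step length (gamma case)
#'
#' @param beta_sl step-length coefficient (per km), must be < 0.
#' @param beta_logsl log-step-length coefficient, must be > -1.
#' @param step_interval relocation interval in hours; the returned speed
#'   is mean step length divided by this.
#' @return list with \code{mean_step} (km per step) and \code{speed}
#'   (km/h).
#' @export
mean_step_gamma <- function(beta_sl, beta_logsl, step_interval = 1) {
  if (beta_sl >= 0 || beta_logsl <= -1)
    stop("outside the gamma-valid region (need beta_sl < 0, beta_logsl > -1); ",
         "use mean_step_metropolis()")
  m <- (1 + beta_logsl) / (-beta_sl)
  list(mean_step = m, speed = m / step_interval)
}

#' Mean step length by Metropolis sampling
#'
#' Samples the truncated density d^{b_logSL} exp(b_SL d) on
#' (\code{eps}, \code{max_step}] with a Metropolis chain alternating
#' log-scale random-walk moves with log-uniform independence jumps, and
#' averages the last \code{n_keep} of \code{n_total} draws.  The
#' hybrid kernel handles both tightly concentrated step-length
#' densities and densities that spike at the lower truncation.  A positive lower truncation
#' \code{eps} is required when \code{beta_logsl <= -1} (the density is
#' otherwise non-integrable at 0); by default \code{eps} is 0 in the
#' integrable region and 1e-3 km otherwise.
#'
#' @param beta_sl,beta_logsl coefficients as in
#'   \code{\link{mean_step_gamma}}.
#' @param max_step upper truncation in km (the sampling radius).
#' @param n_total,n_keep chain length and number of final draws kept.
#' @param eps lower truncation in km (NULL = automatic).
#' @param step_interval relocation interval in hours.
#' @param seed RNG seed.
#' @return list with \code{mean_step}, \code{speed}, \code{eps},
#'   \code{acceptance}.
#' @export
mean_step_metropolis <- function(beta_sl, beta_logsl, max_step,
                                 n_total = 20000, n_keep = 10000,
                                 eps = NULL, step_interval = 1,
                                 seed = NULL) {
  stopifnot(max_step > 0, n_keep <= n_total)
  if (is.null(eps)) eps <- if (beta_logsl > -1) 0 else 1e-3
  if (beta_logsl <= -1 && eps <= 0)
    stop("beta_logsl <= -1 makes the density non-integrable at 0; ",
         "a positive lower truncation eps is required")
  logdens <- function(d) beta_logsl * log(d) + beta_sl * d
  run_manifest("mean_step_metropolis", seed,
               list(beta_sl = beta_sl, beta_logsl = beta_logsl,
                    max_step = max_step, eps = eps))
  with_seed(seed, {
    # proposal floor: eps itself, or small enough that the excluded
    # near-zero mass is negligible for any integrable exponent
    epsq <- max(eps, 1e-7)
    lr <- log(max_step / epsq)
    d <- max(min(max_step / 2, 1), eps * 2, 1e-4)
    u_ind <- stats::runif(n_total)
    rw <- stats::rnorm(n_total, 0, 0.8)
    us <- log(stats::runif(n_total))
    draws <- numeric(n_total)
    acc <- 0L
    for (i in seq_len(n_total)) {
      if (i %% 2 == 0) {
        # independence move, q(d) proportional to 1/d on (epsq, max]:
        # Metropolis ratio f(p) p / (f(d) d)
        p <- epsq * exp(u_ind[i] * lr)
        if (p > eps &&
            us[i] < logdens(p) + log(p) - logdens(d) - log(d)) {
          d <- p; acc <- acc + 1L
        }
      } else {
        # log-scale random walk (same Jacobian-corrected ratio)
        p <- d * exp(rw[i])
        if (p > eps && p <= max_step &&
            us[i] < logdens(p) + log(p) - logdens(d) - log(d)) {
          d <- p; acc <- acc + 1L
        }
      }
      draws[i] <- d
    }
    m <- mean(draws[(n_total - n_keep + 1):n_total])
    list(mean_step = m, speed = m / step_interval, eps = eps,
         acceptance = acc / n_total)
  })
}

# deterministic quadrature of the truncated mean; used internally for
# state relabelling and as a test oracle for the Metropolis routine
mean_step_quadrature <- function(beta_sl, beta_logsl, max_step,
                                 eps = 1e-3) {
  f <- function(d) exp(beta_logsl * log(d) + beta_sl * d)
  num <- stats::integrate(function(d) d * f(d), eps, max_step,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(f, eps, max_step, rel.tol = 1e-10)$value
  num / den
}

# robust mean step length for any coefficient pair (closed form in the
# gamma-valid region, quadrature otherwise)
mean_step_length <- function(beta_sl, beta_logsl, max_step) {
  if (is.finite(beta_sl) && is.finite(beta_logsl) &&
      beta_sl < 0 && beta_logsl > -1)
    return((1 + beta_logsl) / (-beta_sl))
  tryCatch(mean_step_quadrature(beta_sl, beta_logsl, max_step),
           error = function(e) NA_real_)
}
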