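# Population-level estimates: fixed-effect inverse-variance pooling of
# the N individual coefficient vectors.  With V_all the block-diagonal
# matrix of individual variance matrices and Q the stacked-identity
# design, the pooled estimate is the weighted-least-squares solve
#   beta_Pop = (Q' V_all^-1 Q)^-1 Q' V_all^-1 beta_all,
#   V_Pop    = (Q' V_all^-1 Q)^-1,
# which reduces to beta_Pop = (sum W_n)^-1 sum W_n beta_n with
# W_n = V_n^-1.

#' Pool individual HMM-SSF fits into a population estimate
#'
#' Fits that did not converge or whose variance matrix is unusable
#' (non-finite or not positive semi-definite after a small ridge) are
#' excluded and listed.  Near-singular variance matrices get a 1e-8
#' ridge with a warning.  Fits in which a state is supported by fewer
#' than \code{min_state_frac} of the decoded steps (and at least 10)
#' are also excluded: a state an individual essentially never visited
#' has unidentified coefficients, and its inverse-variance weight is
#' meaningless.
#'
#' @param fits list of \code{hmm_ssf_fit} objects sharing K and
#'   covariate order.
#' @param min_state_frac minimum share of decoded steps per state for a
#'   fit to enter the pool (default 0.05; set 0 to disable).
#' @return an object of class \code{population_estimate}: \code{beta_pop}
#'   (p-vector, p = K q, states stacked), \code{vcov_pop} (p x p),
#'   \code{n_individuals}, \code{included_ids}, \code{excluded_ids},
#'   \code{K}, \code{covariates}.
#' @export
pool_fits <- function(fits, min_state_frac = 0.05) {
  if (!length(fits)) stop("no fits supplied")
  covn <- fits[[1]]$covariates
  K <- fits[[1]]$K
  for (f in fits)
    if (!identical(f$covariates, covn) || f$K != K)
      stop("fits have mismatched coefficient layouts")
  p <- K * length(covn)
  usable <- logical(length(fits))
  Ws <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!isTRUE(f$converged) || !isTRUE(f$vcov_ok) ||
        !all(is.finite(f$vcov))) next
    if (min_state_frac > 0 && !is.null(f$state_support) &&
        min(f$state_support) < max(10, min_state_frac *
                                     sum(f$state_support))) next
    V <- (f$vcov + t(f$vcov)) / 2
    W <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(W)) {
      W <- tryCatch(solve(V + diag(1e-8, p)), error = function(e) NULL)
      if (!is.null(W))
        warning("ridge (1e-8) applied to near-singular vcov of individual ",
                f$individual_id)
    }
    if (is.null(W) || !all(is.finite(W))) next
    usable[i] <- TRUE
    Ws[[i]] <- W
  }
  if (!any(usable)) stop("no fit with a usable variance matrix")
  Wsum <- matrix(0, p, p)
  wb <- numeric(p)
  for (i in which(usable)) {
    Wsum <- Wsum + Ws[[i]]
    wb <- wb + Ws[[i]] %*% as.vector(t(fits[[i]]$beta))
  }
  Vpop <- solve(Wsum)
  bpop <- drop(Vpop %*% wb)
  nm <- as.vector(t(outer(seq_len(K), covn,
                          function(k, v) paste0("s", k, ".", v))))
  names(bpop) <- nm
  dimnames(Vpop) <- list(nm, nm)
  structure(list(beta_pop = bpop, vcov_pop = (Vpop + t(Vpop)) / 2,
                 n_individuals = sum(usable),
                 included_ids = vapply(fits[usable],
                                       function(f) as.character(f$individual_id), ""),
                 excluded_ids = vapply(fits[!usable],
                                       function(f) as.character(f$individual_id), ""),
                 K = K, covariates = covn),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate pooled over %d individuals (%d excluded)\n",
              x$n_individuals, length(x$excluded_ids)))
  se <- sqrt(diag(x$vcov_pop))
  print(round(data.frame(estimate = x$beta_pop, se = se,
                         lower = x$beta_pop - 1.96 * se,
                         upper = x$beta_pop + 1.96 * se), 4))
  invisible(x)
}

# pooled coefficients as a K x q matrix
pop_beta_matrix <- function(pop) {
  matrix(pop$beta_pop, pop$K, length(pop$covariates), byrow = TRUE,
         dimnames = list(NULL, pop$covariates))
}
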