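# Multi-state step selection: state-specific conditional-multinomial
# emission, grouped forward likelihood, direct numerical maximum
# likelihood, and predictive/filtered state probabilities.
#
# Model: the animal is in one of K latent movement modes following a
# Markov chain with constant transition matrix Gamma.  Given mode k, the
# probability that the observed step is the one chosen among its stratum's
# J+1 candidates is a softmax of X'beta_k over candidates.  Trajectory
# segments separated by sampling gaps are treated as independent: each
# segment restarts the forward recursion at the initial distribution and
# the segment log-likelihoods add.

#' Emission probability of one candidate
#'
#' Softmax probability exp(x_j' beta) / sum_j' exp(x_j' beta) over the
#' candidates of a stratum, computed with max-subtraction.
#'
#' @param X (J+1) x q covariate matrix of one stratum (row 1 = observed).
#' @param beta_k coefficient vector of length q.
#' @param candidate_index which candidate, 0-based (0 = observed).
#' @return a probability.
#' @export
emission_prob <- function(X, beta_k, candidate_index = 0) {
  if (!all(is.finite(X))) stop("non-finite covariates")
  if (candidate_index < 0 || candidate_index > nrow(X) - 1)
    stop("candidate_index out of range")
  s <- drop(X %*% beta_k)
  s <- s - max(s)
  exp(s[candidate_index + 1]) / sum(exp(s))
}

# log emission probabilities of the OBSERVED candidate for all strata and
# states: returns n x K matrix.  design is from strata_design().
emission_logmat <- function(design, beta) {
  E <- design$X %*% t(beta)               # (n*(J+1)) x K
  n <- design$n; Jp1 <- design$Jp1; K <- nrow(beta)
  le <- matrix(0, n, K)
  for (k in seq_len(K)) {
    m <- matrix(E[, k], Jp1, n)
    mx <- col_max(m)
    lse <- mx + log(colSums(exp(m - rep(mx, each = Jp1))))
    le[, k] <- m[1, ] - lse
  }
  le
}

# multinomial-logit transform for transition matrix rows
gamma_from_eta <- function(eta, K) {
  G <- diag(K)
  idx <- 1
  for (i in seq_len(K)) {
    e <- exp(eta[idx:(idx + K - 2)])
    idx <- idx + K - 1
    denom <- 1 + sum(e)
    row <- numeric(K)
    row[-i] <- e / denom
    row[i] <- 1 / denom
    G[i, ] <- row
  }
  G
}

eta_from_gamma <- function(G) {
  K <- nrow(G)
  unlist(lapply(seq_len(K), function(i) log(G[i, -i] / G[i, i])))
}

#' Stationary distribution of a transition matrix
#'
#' @param G K x K stochastic matrix (rows sum to 1).
#' @return the stationary probability vector.
#' @export
stationary_dist <- function(G) {
  K <- nrow(G)
  drop(solve(t(diag(K) - G + 1), rep(1, K)))
}

#' Grouped forward log-likelihood of an HMM-SSF
#'
#' Scaled forward recursion per segment group, restarted at the initial
#' distribution (stationary by default); the total is the sum of group
#' log-likelihoods, treating groups as independent.
#'
#' @param strata covariate-filled \code{ssf_strata} (or a compiled design
#'   from the internal compiler).
#' @param beta K x q coefficient matrix.
#' @param Gamma K x K transition matrix.
#' @param delta initial state distribution: "stationary" (default),
#'   "uniform", or a numeric vector.
#' @return the log-likelihood (scalar).
#' @export
forward_loglik <- function(strata, beta, Gamma, delta = "stationary") {
  design <- if (is.list(strata) && !is.data.frame(strata)) strata
            else strata_design(strata)
  beta <- rbind(beta)
  K <- nrow(beta)
  if (K > 1) {
    if (any(Gamma <= 0) || any(abs(rowSums(Gamma) - 1) > 1e-8))
      stop("Gamma rows must sum to 1 with entries in (0,1)")
  }
  le <- emission_logmat(design, beta)
  if (K == 1) return(sum(le))
  d0 <- if (identical(delta, "stationary")) stationary_dist(Gamma)
        else if (identical(delta, "uniform")) rep(1 / K, K)
        else delta
  .forward_ll_cpp(exp(le), Gamma, d0, group_codes(design))
}

group_codes <- function(design) {
  as.integer(factor(design$group, levels = unique(design$group)))
}

# single-state conditional-multinomial fit (used for initialization and
# as the K = 1 reduction)
fit_single_ssf <- function(design, init = NULL) {
  q <- ncol(design$X)
  nll <- function(b) {
    v <- sum(log(.emission_obs_cpp(design$X, rbind(b), design$Jp1)))
    if (!is.finite(v)) 1e10 else -v
  }
  b0 <- if (is.null(init)) rep(0, q) else init
  opt <- stats::optim(b0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  H <- stats::optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA, q, q))
  list(beta = opt$par, vcov = V, loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' Fit a multi-state step selection function
#'
#' Direct numerical maximization of the grouped forward log-likelihood
#' over the state-specific selection coefficients (unconstrained) and
#' the transition matrix (multinomial-logit transform).  Initialization:
#' the coefficients of a single-state fit perturbed by N(0, 0.5^2) per
#' restart, with a diagonally dominant (0.9) starting transition matrix;
#' the best of \code{n_restarts} optima is kept.  States are then
#' relabelled so that implied mean step length increases with state
#' index (state K = "travelling").  The variance matrix is the inverse
#' of the numerical Hessian of the negative log-likelihood, reported for
#' the stacked coefficient block.
#'
#' @param strata covariate-filled \code{ssf_strata}.
#' @param K number of states (K = 1 reduces to a single-state SSF).
#' @param n_restarts number of perturbed initializations.
#' @param seed RNG seed for the restarts.
#' @param delta initial state distribution passed to
#'   \code{\link{forward_loglik}}.
#' @param sl_covariates names of the step-length and log step-length
#'   covariates used for the relabelling convention (skipped if absent).
#' @return an object of class \code{hmm_ssf_fit}: \code{beta} (K x q),
#'   \code{Gamma}, \code{vcov} (Kq x Kq, coefficient block), \code{loglik},
#'   \code{converged}, \code{vcov_ok}, \code{n_strata}, \code{covariates},
#'   \code{individual_id}, \code{delta}.
#' @export
fit_hmm_ssf <- function(strata, K = 2, n_restarts = 5, seed = NULL,
                        delta = "stationary",
                        sl_covariates = c("sl", "log_sl")) {
  design <- strata_design(strata)
  q <- ncol(design$X)
  covn <- design$covariates
  run_manifest("fit_hmm_ssf", seed, list(K = K, n_restarts = n_restarts))
  ss <- fit_single_ssf(design)
  if (K == 1) {
    fit <- list(beta = rbind(ss$beta), Gamma = matrix(1, 1, 1),
                vcov = ss$vcov, loglik = ss$loglik,
                converged = ss$converged,
                vcov_ok = all(is.finite(ss$vcov)) &&
                  all(eigen(ss$vcov, symmetric = TRUE,
                            only.values = TRUE)$values > -1e-10),
                n_strata = design$n, covariates = covn,
                individual_id = design$id[1], delta = delta, K = 1)
    colnames(fit$beta) <- covn
    class(fit) <- "hmm_ssf_fit"
    return(fit)
  }
  n_eta <- K * (K - 1)
  grp <- group_codes(design)
  uniform_delta <- identical(delta, "uniform")
  nll <- function(par) {
    beta <- matrix(par[1:(K * q)], K, q, byrow = TRUE)
    G <- gamma_from_eta(par[(K * q + 1):(K * q + n_eta)], K)
    d0 <- if (uniform_delta) rep(1 / K, K)
          else tryCatch(stationary_dist(G), error = function(e) NULL)
    if (is.null(d0) || any(!is.finite(d0))) return(1e10)
    e <- .emission_obs_cpp(design$X, beta, design$Jp1)
    v <- .forward_ll_cpp(e, G, d0, grp)
    if (!is.finite(v)) 1e10 else -v
  }
  G0 <- matrix(0.1 / (K - 1), K, K); diag(G0) <- 0.9
  eta0 <- eta_from_gamma(G0)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      beta0 <- matrix(rep(ss$beta, each = K), K, q) +
        matrix(stats::rnorm(K * q, 0, 0.5), K, q)
      par0 <- c(as.vector(t(beta0)), eta0)
      opt <- tryCatch(
        stats::optim(par0, nll, method = "BFGS",
                     control = list(maxit = 400, reltol = 1e-9)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })
  if (is.null(best)) stop("all restarts failed")
  par <- best$par
  beta <- matrix(par[1:(K * q)], K, q, byrow = TRUE)
  Gamma <- gamma_from_eta(par[(K * q + 1):(K * q + n_eta)], K)
  H <- tryCatch(stats::optimHess(par, nll), error = function(e) NULL)
  Vfull <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  vcov_ok <- !is.null(Vfull) && all(is.finite(Vfull[1:(K * q), 1:(K * q)]))
  V <- if (!is.null(Vfull)) Vfull[1:(K * q), 1:(K * q), drop = FALSE]
       else matrix(NA_real_, K * q, K * q)
  V <- (V + t(V)) / 2
  if (vcov_ok) {
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    vcov_ok <- all(ev > -1e-8 * max(abs(ev)))
  }
  # relabel states by increasing mean step length of the steps each
  # state actually claims (filtered-probability weighted empirical
  # mean); the faster state is "travelling".  The closed-form gamma
  # mean is not used here: a near-degenerate state (shape ~ 0) makes it
  # misleading while the decoded mean stays interpretable.
  perm <- seq_len(K)
  si <- if (is.null(sl_covariates)) NA_integer_
        else match(sl_covariates, covn)
  if (length(si) == 2 && !anyNA(si)) {
    pf <- .forward_probs_cpp(exp(emission_logmat(design, beta)), Gamma,
                             stationary_dist(Gamma), group_codes(design))
    w <- pf[, K + seq_len(K), drop = FALSE]    # filtered probabilities
    sl_obs <- design$X[seq(1, by = design$Jp1, length.out = design$n),
                       si[1]]
    ms <- colSums(w * sl_obs) / pmax(colSums(w), 1e-12)
    perm <- order(ms)
  }
  beta <- beta[perm, , drop = FALSE]
  Gamma <- Gamma[perm, perm, drop = FALSE]
  pidx <- as.vector(vapply(perm, function(k) (k - 1) * q + seq_len(q),
                           numeric(q)))
  V <- V[pidx, pidx, drop = FALSE]
  colnames(beta) <- covn
  # decoded (filtered argmax) step count per state: a state supported by
  # only a handful of steps has unidentified coefficients
  support <- {
    pf <- .forward_probs_cpp(exp(emission_logmat(design, beta)), Gamma,
                             stationary_dist(Gamma), group_codes(design))
    filt <- pf[, K + seq_len(K), drop = FALSE]
    tabulate(max.col(filt, ties.method = "first"), nbins = K)
  }
  fit <- list(beta = beta, Gamma = Gamma, vcov = V, loglik = -best$value,
              converged = best$convergence == 0, vcov_ok = vcov_ok,
              n_strata = design$n, state_support = support,
              covariates = covn,
              individual_id = design$id[1], delta = delta, K = K)
  class(fit) <- "hmm_ssf_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hmm_ssf_fit <- function(x, ...) {
  cat(sprintf("HMM-SSF fit: K = %d states, %d strata, logLik = %.3f%s\n",
              x$K, x$n_strata, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  cat("Selection coefficients (rows = states, state K = travelling):\n")
  print(round(x$beta, 4))
  if (x$K > 1) { cat("Transition matrix:\n"); print(round(x$Gamma, 4)) }
  invisible(x)
}

#' Predictive and filtered state probabilities
#'
#' Forward recursion per segment group (restarted at the initial
#' distribution): predictive P(S_t = k | data up to t-1) and filtered
#' P(S_t = k | data up to t).
#'
#' @param fit an \code{hmm_ssf_fit}.
#' @param strata the covariate-filled strata the fit was built on (or new
#'   data with the same covariates).
#' @return a data.frame of class \code{state_prob_series}: id, segment,
#'   stratum, time, then \code{pred_k} and \code{filt_k} columns per
#'   state.
#' @export
state_probs <- function(fit, strata) {
  design <- strata_design(strata, fit$covariates)
  K <- fit$K
  le <- emission_logmat(design, fit$beta)
  d0 <- if (identical(fit$delta, "stationary")) stationary_dist(fit$Gamma)
        else if (identical(fit$delta, "uniform")) rep(1 / K, K)
        else fit$delta
  pf <- .forward_probs_cpp(exp(le), fit$Gamma, d0, group_codes(design))
  pred <- pf[, seq_len(K), drop = FALSE]
  filt <- pf[, K + seq_len(K), drop = FALSE]
  out <- data.frame(id = design$id, segment = design$group,
                    stratum = design$stratum, time = design$time)
  for (k in seq_len(K)) out[[paste0("pred_", k)]] <- pred[, k]
  for (k in seq_len(K)) out[[paste0("filt_", k)]] <- filt[, k]
  structure(out, K = K, class = c("state_prob_series", "data.frame"))
}

#' Decode states from predictive probabilities
#'
#' For K = 2 the rule is: state 1 iff P(S_t = 1 | history) >= threshold.
#' For K > 2 the most probable state is taken (argmax).
#'
#' @param probs a \code{state_prob_series}.
#' @param threshold probability threshold in (0, 1) (K = 2 only).
#' @param which use "pred" (predictive, default) or "filt" (filtered)
#'   probabilities.
#' @return integer state sequence.
#' @export
decode <- function(probs, threshold = 0.5, which = c("pred", "filt")) {
  which <- match.arg(which)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  K <- attr(probs, "K")
  P <- as.matrix(probs[, paste0(which, "_", seq_len(K)), drop = FALSE])
  if (K == 2) return(ifelse(P[, 1] >= threshold, 1L, 2L))
  max.col(P, ties.method = "first")
}
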