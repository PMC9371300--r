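# Shared fixtures and independent oracles, built in code at test time.

# Brute-force HMM likelihood: enumerate all K^T state sequences within
# each group and sum their joint probabilities.  Independent of the
# forward implementation.
brute_force_ll <- function(e, Gamma, delta, group) {
  K <- ncol(e)
  total <- 0
  for (g in split(seq_len(nrow(e)), group)) {
    Tn <- length(g)
    seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    lik <- 0
    for (r in seq_len(nrow(seqs))) {
      s <- seqs[r, ]
      p <- delta[s[1]] * e[g[1], s[1]]
      if (Tn > 1) for (t in 2:Tn)
        p <- p * Gamma[s[t - 1], s[t]] * e[g[t], s[t]]
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# A compiled design with random covariates (no geometry), for direct
# likelihood checks.
make_toy_design <- function(n, Jp1 = 4, q = 2, n_groups = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * Jp1 * q), ncol = q)
    colnames(X) <- paste0("x", seq_len(q))
    grp <- sort(rep_len(paste0("g", seq_len(n_groups)), n))
    list(X = X, Jp1 = Jp1, n = n, covariates = colnames(X),
         group = grp, id = rep("toy", n), time = seq_len(n),
         stratum = seq_len(n))
  })
}

# Model-true generator: hidden Markov chain + conditional multinomial
# emission over J+1 candidates with iid normal covariates.  The observed
# candidate is placed at index 0, so fitting this data is a pure
# parameter-recovery problem with no misspecification.
simulate_hmm_strata <- function(T_steps, J, beta, Gamma, seed,
                                id = "sim", n_groups = 1) {
  K <- nrow(beta); q <- ncol(beta)
  withr::with_seed(seed, {
    delta <- hmmssf::stationary_dist(Gamma)
    s <- numeric(T_steps)
    s[1] <- sample(K, 1, prob = delta)
    for (t in 2:T_steps) s[t] <- sample(K, 1, prob = Gamma[s[t - 1], ])
    rows <- vector("list", T_steps)
    grp <- sort(rep_len(seq_len(n_groups), T_steps))
    for (t in seq_len(T_steps)) {
      Xc <- matrix(rnorm((J + 1) * q), J + 1, q)
      pr <- exp(Xc %*% beta[s[t], ])
      pick <- sample(J + 1, 1, prob = pr)
      Xc <- Xc[c(pick, setdiff(seq_len(J + 1), pick)), , drop = FALSE]
      df <- data.frame(id = id, segment = paste0(id, ".", grp[t]),
                       stratum = t, time = t, candidate = 0:J,
                       x_start = 0, y_start = 0, prev_heading = 0,
                       x_end = 0, y_end = 0)
      for (j in seq_len(q)) df[[paste0("x", j)]] <- Xc[, j]
      rows[[t]] <- df
    }
    out <- do.call(rbind, rows)
    attr(out, "covariates") <- paste0("x", seq_len(q))
    attr(out, "J") <- J
    class(out) <- c("ssf_strata", "data.frame")
    list(strata = out, states = s)
  })
}

# Minimal hand-built fit objects for pooling tests.
fake_fit <- function(beta, vcov, id = "a", covariates = NULL, K = NULL) {
  beta <- rbind(beta)
  if (is.null(K)) K <- nrow(beta)
  if (is.null(covariates)) covariates <- paste0("c", seq_len(ncol(beta)))
  structure(list(beta = beta, Gamma = diag(K), vcov = vcov,
                 loglik = 0, converged = TRUE, vcov_ok = TRUE,
                 n_strata = 10, covariates = covariates,
                 individual_id = id, delta = "stationary", K = K),
            class = "hmm_ssf_fit")
}

# Subset a strata table to a set of stratum ids, keeping attributes.
subset_strata <- function(strata, keep) {
  out <- strata[strata$stratum %in% keep, , drop = FALSE]
  attr(out, "covariates") <- attr(strata, "covariates")
  attr(out, "radius") <- attr(strata, "radius")
  class(out) <- class(strata)
  out
}

# One forager replicate fitted on its generative choice strata; used by
# several test files.  Cached per (landscape seed, rep seed).
.sim_cache <- new.env(parent = emptyenv())
forager_fit <- function(ls, rep_seed, id = paste0("f", rep_seed),
                        scenario = "forager") {
  key <- paste0(scenario, "_", rep_seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- simulate_ssf_agent(scenario, ls, id = id, seed = rep_seed)
  spec <- movement_spec("quality", with_target = scenario == "migrant")
  gs <- build_covariates(sim_choice_strata(sim), spec,
                         list(quality = ls$quality), target = sim$target)
  fit <- fit_hmm_ssf(gs, K = 2, seed = rep_seed + 7)
  out <- list(sim = sim, strata = gs, fit = fit)
  .sim_cache[[key]] <- out
  out
}
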