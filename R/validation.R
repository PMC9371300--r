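# State-specific k-fold cross-validation and ROC/AUC against known
# simulated states.
#
# The CV procedure: repeatedly split individuals 80/20; pool the fits of
# the training individuals; decode each test individual's states from
# its OWN fit (most-probable rule); within each decoded state, score
# every candidate of every test stratum with the pooled state
# coefficients, rank candidates within a stratum (rank J+1 = highest
# selection probability), and correlate the frequency of the observed
# step's rank against the rank index (Spearman).  Rank orientation is
# such that better-than-random prediction yields a POSITIVE correlation
# for observed steps; one randomly chosen random candidate per stratum
# gives the null reference ("random" group).

#' ROC area under the curve
#'
#' Midrank (Mann-Whitney) AUC of a score against a binary truth.
#'
#' @param truth binary vector (1 = positive class), or an integer state
#'   sequence combined with \code{state}.
#' @param probs numeric scores (e.g. predictive state probabilities), or
#'   a \code{state_prob_series} with \code{state} selecting the column.
#' @param state when \code{probs} is a \code{state_prob_series}: which
#'   state's predictive probability to score, with truth = indicator
#'   (true state == state).
#' @return the AUC (scalar).
#' @export
roc_auc <- function(truth, probs, state = NULL) {
  if (inherits(probs, "state_prob_series")) {
    stopifnot(!is.null(state))
    probs <- probs[[paste0("pred_", state)]]
    truth <- as.integer(truth == state)
  }
  stopifnot(length(truth) == length(probs))
  truth <- as.integer(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class truth")
  r <- rank(probs)  # midranks
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' State-specific k-fold cross-validation
#'
#' @param fits list of per-individual \code{hmm_ssf_fit} objects.
#' @param strata_list list of the matching covariate-filled strata.
#' @param reps number of 80/20 repetitions (default 100).
#' @param train_frac fraction of individuals in the training pool.
#' @param seed RNG seed.
#' @return a data.frame of class \code{cv_report}: one row per (state,
#'   group) with mean/min/max Spearman correlation over repetitions and
#'   the number of repetitions in which the state was scorable.
#' @export
kfold_cv <- function(fits, strata_list, reps = 100, train_frac = 0.8,
                     seed = NULL) {
  N <- length(fits)
  stopifnot(N >= 2, length(strata_list) == N,
            train_frac > 0, train_frac < 1)
  K <- fits[[1]]$K
  covn <- fits[[1]]$covariates
  run_manifest("kfold_cv", seed, list(reps = reps, train_frac = train_frac))
  # precompute per-individual designs and decoded states once
  designs <- lapply(strata_list, strata_design, covariates = covn)
  states <- lapply(seq_len(N), function(i) {
    pr <- state_probs(fits[[i]], strata_list[[i]])
    P <- as.matrix(pr[, paste0("pred_", seq_len(K)), drop = FALSE])
    max.col(P, ties.method = "first")
  })
  with_seed(seed, {
    res <- array(NA_real_, c(reps, K, 2),
                 dimnames = list(NULL, NULL, c("observed", "random")))
    for (r in seq_len(reps)) {
      n_train <- min(ceiling(train_frac * N), N - 1)
      train <- sample(N, n_train)
      pop <- tryCatch(pool_fits(fits[train]), error = function(e) NULL)
      if (is.null(pop)) next
      bmat <- pop_beta_matrix(pop)
      test <- setdiff(seq_len(N), train)
      obs_rank <- vector("list", K); rnd_rank <- vector("list", K)
      for (i in test) {
        d <- designs[[i]]
        Jp1 <- d$Jp1
        S <- d$X %*% t(bmat)            # (n*Jp1) x K scores
        for (k in seq_len(K)) {
          sel <- which(states[[i]] == k)
          if (!length(sel)) next
          sc <- matrix(S[, k], Jp1, d$n)[, sel, drop = FALSE]
          sc <- sc + matrix(stats::runif(length(sc), 0, 1e-9), nrow(sc))
          rk <- apply(sc, 2, rank)       # ascending: Jp1 = best
          obs_rank[[k]] <- c(obs_rank[[k]], rk[1, ])
          pick <- sample(2:Jp1, length(sel), replace = TRUE)
          rnd_rank[[k]] <- c(rnd_rank[[k]],
                             rk[cbind(pick, seq_along(sel))])
        }
      }
      Jp1 <- designs[[1]]$Jp1
      for (k in seq_len(K)) {
        if (length(obs_rank[[k]]) < 2) next  # state unscorable this rep
        fo <- tabulate(obs_rank[[k]], nbins = Jp1)
        fr <- tabulate(rnd_rank[[k]], nbins = Jp1)
        res[r, k, "observed"] <- suppressWarnings(
          stats::cor(seq_len(Jp1), fo, method = "spearman"))
        res[r, k, "random"] <- suppressWarnings(
          stats::cor(seq_len(Jp1), fr, method = "spearman"))
      }
    }
    out <- do.call(rbind, lapply(seq_len(K), function(k) {
      do.call(rbind, lapply(c("observed", "random"), function(g) {
        v <- res[, k, g]
        data.frame(state = k, group = g,
                   mean = mean(v, na.rm = TRUE),
                   min = suppressWarnings(min(v, na.rm = TRUE)),
                   max = suppressWarnings(max(v, na.rm = TRUE)),
                   n_repetitions = sum(!is.na(v)))
      }))
    }))
    rownames(out) <- NULL
    structure(out, class = c("cv_report", "data.frame"))
  })
}
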