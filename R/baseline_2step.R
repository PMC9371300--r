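# The comparison estimator: a 2-state hidden Markov movement model on
# step metrics alone (gamma step lengths, von Mises turning angles,
# transition probabilities logit-linear in covariates), smoothed state
# decoding, then a separate single-state SSF per decoded state with
# cluster-robust (sandwich) variances.  Decoding ignores habitat, so
# its errors propagate into the per-state selection estimates — the
# bias the joint model avoids.

#' Step metrics table
#'
#' One row per observed step: id, segment, start_time, step length
#' (km, zero lengths jittered to 1e-6 with a count attribute) and
#' turning angle (NA for the first step of each segment).
#'
#' @param traj segmented trajectory table.
#' @return data.frame of steps in segment order.
#' @export
steps_table <- function(traj) {
  out <- lapply(split_segments(traj), function(seg) {
    Fn <- nrow(seg)
    if (Fn < 2) return(NULL)
    dx <- diff(seg$x); dy <- diff(seg$y)
    sl <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    turn <- c(NA, wrap_angle(diff(ang)))
    data.frame(id = seg$id[1], segment = seg$segment[1],
               start_time = seg$time[-Fn], sl = sl, turn = turn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  n0 <- sum(out$sl == 0)
  out$sl[out$sl == 0] <- 1e-6
  attr(out, "n_zero_jittered") <- n0
  out
}

vm_logdens <- function(a, kappa) {
  kappa * cos(a) - log(2 * pi) -
    (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa)
}

crw_emission <- function(steps, mu, sd, kappa) {
  K <- length(mu)
  le <- matrix(0, nrow(steps), K)
  for (k in seq_len(K)) {
    sh <- (mu[k] / sd[k])^2
    rt <- mu[k] / sd[k]^2
    # extreme optimizer proposals can overflow shape/rate; the resulting
    # non-finite densities are caught by the likelihood guard
    le[, k] <- suppressWarnings(
      stats::dgamma(steps$sl, shape = sh, rate = rt, log = TRUE))
    ok <- !is.na(steps$turn)
    le[ok, k] <- le[ok, k] + vm_logdens(steps$turn[ok], kappa[k])
  }
  le
}

# time-varying 2-state transition matrices from logit-linear predictors
crw_gammas <- function(W, tpar, K) {
  # tpar: per row i of Gamma, an intercept + coefficients on W columns
  nc <- if (is.null(W)) 0 else ncol(W)
  n <- nrow(W %||% matrix(0, 1, 0))
  G <- array(0, c(K, K, max(n, 1)))
  idx <- 1
  for (i in seq_len(K)) {
    eta <- tpar[idx]
    if (nc > 0) eta <- eta + drop(W %*% tpar[(idx + 1):(idx + nc)])
    idx <- idx + 1 + nc
    p_off <- stats::plogis(eta)   # K = 2: probability of leaving state i
    G[i, i, ] <- 1 - p_off
    G[i, 3 - i, ] <- p_off
  }
  G
}

#' Fit a 2-state gamma/von Mises HMM (HMM-CRW)
#'
#' Forward-likelihood maximization of a 2-state correlated-random-walk
#' hidden Markov model: gamma step lengths, von Mises (mean 0) turning
#' angles, and transition probabilities logit-linear in the supplied
#' covariates (constant when none are given).  Segments are independent
#' likelihood groups, started at the uniform distribution.
#'
#' @param traj segmented trajectory table.
#' @param covariates optional numeric matrix/data.frame of transition
#'   covariates, one row per step of \code{steps_table(traj)}.
#' @param n_restarts perturbed initializations.
#' @param seed RNG seed.
#' @return list of class \code{hmm_crw_fit}: \code{mu}, \code{sd},
#'   \code{kappa} (per state, state 2 = faster), \code{tpar}
#'   (transition coefficients), \code{loglik}, \code{converged},
#'   \code{steps}, \code{covnames}.
#' @export
fit_hmm_crw <- function(traj, covariates = NULL, n_restarts = 2,
                        seed = NULL) {
  K <- 2
  steps <- steps_table(traj)
  if (nrow(steps) < 20) stop("need at least 20 steps")
  W <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(W) && nrow(W) != nrow(steps))
    stop("covariates must have one row per step")
  nc <- if (is.null(W)) 0 else ncol(W)
  seg_idx <- split(seq_len(nrow(steps)), steps$segment)
  nll <- function(th) {
    mu <- exp(th[c(1, 4)]); sd <- exp(th[c(2, 5)]); kap <- exp(th[c(3, 6)])
    tpar <- th[-(1:6)]
    le <- crw_emission(steps, mu, sd, kap)
    if (any(!is.finite(le))) return(1e10)
    e <- exp(le - apply(le, 1, max))
    lshift <- apply(le, 1, max)
    G <- crw_gammas(W, tpar, K)
    cst <- dim(G)[3] == 1
    ll <- 0
    for (g in seg_idx) {
      phi <- rep(1 / K, K)
      first <- TRUE
      for (t in g) {
        Gt <- if (first) NULL else G[, , if (cst) 1 else t - 1]
        v <- if (first) phi * e[t, ] else drop(phi %*% Gt) * e[t, ]
        first <- FALSE
        ct <- sum(v)
        if (!is.finite(ct) || ct <= 0) return(1e10)
        ll <- ll + log(ct) + lshift[t]
        phi <- v / ct
      }
    }
    -ll
  }
  med <- stats::median(steps$sl)
  lo <- steps$sl[steps$sl <= med]; hi <- steps$sl[steps$sl > med]
  th0 <- c(log(mean(lo)), log(stats::sd(lo) + 1e-6), log(1),
           log(mean(hi)), log(stats::sd(hi) + 1e-6), log(1),
           rep(c(stats::qlogis(0.1), rep(0, nc)), K))
  run_manifest("fit_hmm_crw", seed, list(n_restarts = n_restarts))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- if (r == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.3)
      opt <- tryCatch(stats::optim(init, nll, method = "BFGS",
                                   control = list(maxit = 400,
                                                  reltol = 1e-9)),
                      error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
  })
  if (is.null(best)) stop("HMM-CRW fit failed in all restarts")
  th <- best$par
  mu <- exp(th[c(1, 4)]); sd <- exp(th[c(2, 5)]); kap <- exp(th[c(3, 6)])
  tpar <- th[-(1:6)]
  # state 2 = faster
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sd <- rev(sd); kap <- rev(kap)
    tpar <- c(tpar[(nc + 2):(2 * nc + 2)], tpar[1:(nc + 1)])
  }
  structure(list(mu = mu, sd = sd, kappa = kap, tpar = tpar,
                 loglik = -best$value, converged = best$convergence == 0,
                 steps = steps,
                 covnames = if (is.null(W)) NULL else colnames(W)),
            class = "hmm_crw_fit")
}

#' Smoothed state probabilities and decoded states from an HMM-CRW
#'
#' Forward-backward (smoothed) probabilities per step, dichotomized at
#' 0.50 into states.
#'
#' @param fit an \code{hmm_crw_fit}.
#' @param covariates the transition covariates used in the fit.
#' @return data.frame: id, segment, start_time, smooth_1, smooth_2,
#'   state (1 = slow/encamped, 2 = fast/travelling).
#' @export
decode_crw <- function(fit, covariates = NULL) {
  K <- 2
  steps <- fit$steps
  W <- if (is.null(covariates)) NULL else as.matrix(covariates)
  le <- crw_emission(steps, fit$mu, fit$sd, fit$kappa)
  lshift <- apply(le, 1, max)
  e <- exp(le - lshift)
  G <- crw_gammas(W, fit$tpar, K)
  cst <- dim(G)[3] == 1
  sm <- matrix(NA_real_, nrow(steps), K)
  for (g in split(seq_len(nrow(steps)), steps$segment)) {
    Tn <- length(g)
    al <- matrix(0, Tn, K); sc <- numeric(Tn)
    phi <- rep(1 / K, K)
    for (j in seq_len(Tn)) {
      t <- g[j]
      v <- if (j == 1) phi * e[t, ]
           else drop(al[j - 1, ] %*% (if (cst) G[, , 1] else G[, , g[j] - 1])) * e[t, ]
      sc[j] <- sum(v)
      al[j, ] <- v / sc[j]
    }
    be <- matrix(0, Tn, K)
    be[Tn, ] <- 1
    if (Tn > 1) for (j in (Tn - 1):1) {
      Gt <- if (cst) G[, , 1] else G[, , g[j]]
      be[j, ] <- drop(Gt %*% (e[g[j + 1], ] * be[j + 1, ]))
      be[j, ] <- be[j, ] / sum(be[j, ])
    }
    p <- al * be
    sm[g, ] <- p / rowSums(p)
  }
  data.frame(id = steps$id, segment = steps$segment,
             start_time = steps$start_time,
             smooth_1 = sm[, 1], smooth_2 = sm[, 2],
             state = ifelse(sm[, 1] >= 0.5, 1L, 2L))
}

#' Single-state SSF with cluster-robust variance
#'
#' Conditional logistic (conditional multinomial, one chosen step per
#' stratum) fit by \code{survival::clogit}, with a sandwich variance
#' clustered on individuals.  Intended for strata restricted to one
#' decoded state, re-drawn with the state-specific sampling radius.
#'
#' @param strata covariate-filled \code{ssf_strata}.
#' @return list: \code{beta}, \code{vcov} (robust), \code{vcov_naive},
#'   \code{n_clusters}, \code{model}.
#' @importFrom survival clogit coxph strata cluster Surv
#' @export
fit_state_ssf <- function(strata) {
  covn <- attr(strata, "covariates")
  df <- as.data.frame(strata)
  df$case <- as.integer(df$candidate == 0)
  n_cl <- length(unique(df$id))
  rhs <- paste(paste(covn, collapse = " + "), "+ strata(stratum)")
  if (n_cl >= 2) rhs <- paste(rhs, "+ cluster(id)")
  f <- stats::as.formula(paste("case ~", rhs))
  m <- survival::clogit(f, data = df, method = "breslow")
  if (n_cl < 2)
    warning("single cluster: falling back to the model-based variance")
  list(beta = stats::coef(m), vcov = m$var,
       vcov_naive = m$naive.var %||% m$var,
       n_clusters = n_cl, model = m)
}

#' The full 2-step pipeline on one set of trajectories
#'
#' Fits the HMM-CRW, decodes states, re-draws random steps per decoded
#' state with the state-specific 99th-percentile radius, and fits one
#' single-state SSF per state.
#'
#' @param traj segmented trajectory table (may hold several
#'   individuals).
#' @param spec \code{covariate_spec} for the SSFs.
#' @param rasters,target passed to \code{\link{build_covariates}}.
#' @param J random steps per stratum.
#' @param covariates optional transition covariates (see
#'   \code{\link{fit_hmm_crw}}).
#' @param seed RNG seed.
#' @return list: \code{crw} (the movement-model fit), \code{decoded},
#'   and \code{ssf} (per-state \code{fit_state_ssf} results).
#' @export
two_step_pipeline <- function(traj, spec, rasters = list(), target = NULL,
                              J = 20, covariates = NULL, seed = NULL) {
  crw <- fit_hmm_crw(traj, covariates, seed = child_seed(seed, 1))
  dec <- decode_crw(crw, covariates)
  key <- paste(dec$id, dec$start_time)
  ssf <- list()
  for (k in 1:2) {
    sl_k <- crw$steps$sl[dec$state == k]
    if (length(sl_k) < 2) { ssf[[k]] <- NULL; next }
    rad <- stats::quantile(sl_k, 0.99, type = 7)
    strata <- draw_random_steps(traj, J = J, radius = rad,
                                seed = child_seed(seed, 10 + k))
    strata <- build_covariates(strata, spec, rasters, target)
    st_of <- dec$state[match(paste(strata$id, strata$time), key)]
    keep_str <- unique(strata$stratum[st_of == k])
    sub <- strata[strata$stratum %in% keep_str, , drop = FALSE]
    attr(sub, "covariates") <- attr(strata, "covariates")
    class(sub) <- class(strata)
    ssf[[k]] <- fit_state_ssf(sub)
  }
  names(ssf) <- c("encamped", "travelling")[seq_along(ssf)]
  list(crw = crw, decoded = dec, ssf = ssf)
}
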