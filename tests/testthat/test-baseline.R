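# The 2-step baseline: HMM-CRW movement model, smoothed decoding,
# per-state conditional logistic fits with cluster-robust variances.

# two-mode gamma/von Mises walker with a Markov chain on modes
sim_crw <- function(T_steps, mu = c(0.1, 1), sd = c(0.08, 0.6),
                    kappa = c(0.5, 4), G = rbind(c(0.9, 0.1),
                                                 c(0.2, 0.8)),
                    id = "c1", seed = 1) {
  withr::with_seed(seed, {
    s <- numeric(T_steps); s[1] <- 1
    for (t in 2:T_steps) s[t] <- sample(1:2, 1, prob = G[s[t - 1], ])
    sh <- (mu / sd)^2; rt <- mu / sd^2
    sl <- rgamma(T_steps, sh[s], rt[s])
    # von Mises turns via rejection-free wrapped approximation:
    # use circular-uniform mixture for small kappa; here sample by
    # inversion on a fine grid (adequate for a generator fixture)
    grid <- seq(-pi, pi, length.out = 2001)
    turn <- vapply(seq_len(T_steps), function(t) {
      w <- exp(kappa[s[t]] * cos(grid))
      sample(grid, 1, prob = w)
    }, 0)
    ang <- cumsum(c(runif(1, -pi, pi), turn[-1]))
    df <- data.frame(id = id, time = 0:T_steps,
                     x = cumsum(c(0, sl * cos(ang))),
                     y = cumsum(c(0, sl * sin(ang))),
                     segment = paste0(id, ".1"))
    list(traj = df, states = s)
  })
}

crw_fix <- sim_crw(600, seed = 41)

test_that("steps_table computes lengths and turning angles per segment", {
  df <- data.frame(id = "a", time = 0:3,
                   x = c(0, 1, 1, 1), y = c(0, 0, 1, 1),
                   segment = "a.1")
  st <- steps_table(df)
  expect_equal(st$sl, c(1, 1, 1e-6))
  expect_equal(st$turn[1:2], c(NA, pi / 2))
  expect_equal(attr(st, "n_zero_jittered"), 1)
})

test_that("the HMM-CRW separates a fast and a slow mode", {
  fit <- fit_hmm_crw(crw_fix$traj, seed = 42)
  expect_true(fit$converged)
  expect_gt(fit$mu[2], fit$mu[1])              # state 2 = faster
  expect_lt(abs(fit$mu[1] - 0.1), 0.05)
  expect_lt(abs(fit$mu[2] - 1), 0.25)
  dec <- decode_crw(fit)
  expect_equal(rowSums(as.matrix(dec[, c("smooth_1", "smooth_2")])),
               rep(1, nrow(dec)))
  auc <- roc_auc(as.integer(crw_fix$states == 2), dec$smooth_2)
  expect_gt(auc, 0.9)
})

test_that("covariate-free transitions match a constant-Gamma refit", {
  # fitting with an all-zero covariate must reproduce the covariate-free
  # likelihood (nested-model identity)
  f0 <- fit_hmm_crw(crw_fix$traj, seed = 43)
  W <- matrix(0, nrow(steps_table(crw_fix$traj)), 1,
              dimnames = list(NULL, "z"))
  f1 <- fit_hmm_crw(crw_fix$traj, covariates = W, seed = 43)
  expect_lt(abs(f0$loglik - f1$loglik), 1e-4)
})

test_that("a single-process trajectory yields a degenerate 2-state fit", {
  one <- sim_crw(300, mu = c(0.5, 0.5), sd = c(0.3, 0.3),
                 kappa = c(1, 1), seed = 44)
  fit <- fit_hmm_crw(one$traj, seed = 45)
  dec <- decode_crw(fit)
  collapse <- abs(fit$mu[1] - fit$mu[2]) < 0.15 ||
    min(table(factor(dec$state, 1:2))) < 0.05 * nrow(dec)
  expect_true(collapse)
})

test_that("cluster-robust SSF variances exceed naive ones under clustering", {
  # several individuals share cluster-level noise in a covariate effect
  withr::with_seed(46, {
    strata <- do.call(rbind, lapply(1:8, function(i) {
      b_i <- 1 + rnorm(1, 0, 0.6)       # individual-specific slope
      rows <- lapply(1:40, function(t) {
        z <- rnorm(11)
        p <- exp(b_i * z); pick <- sample(11, 1, prob = p)
        z <- z[c(pick, setdiff(1:11, pick))]
        data.frame(id = paste0("i", i), segment = paste0("i", i, ".1"),
                   stratum = (i - 1) * 40 + t, time = t, candidate = 0:10,
                   x_start = 0, y_start = 0, prev_heading = 0,
                   x_end = 0, y_end = 0, z = z)
      })
      do.call(rbind, rows)
    }))
  })
  attr(strata, "covariates") <- "z"
  class(strata) <- c("ssf_strata", "data.frame")
  fit <- fit_state_ssf(strata)
  expect_equal(fit$n_clusters, 8)
  expect_gt(sqrt(fit$vcov[1, 1]), sqrt(fit$vcov_naive[1, 1]))

  one <- subset_strata(strata, 1:40)
  expect_warning(fit_state_ssf(one), "single cluster")
})

test_that("the 2-step pipeline runs end to end on scenario data", {
  ls <- make_patch_landscape(seed = 42)
  sims <- lapply(1:2, function(r)
    simulate_ssf_agent("forager", ls, id = paste0("f", r),
                       seed = 70 + r))
  traj <- do.call(rbind, lapply(sims, function(s) {
    tr <- s$trajectory; tr$segment <- paste0(tr$id, ".1"); tr
  }))
  out <- two_step_pipeline(traj, movement_spec("quality"),
                           rasters = list(quality = ls$quality),
                           seed = 71)
  expect_true(out$crw$converged)
  expect_equal(names(out$ssf), c("encamped", "travelling"))
  for (k in 1:2) {
    expect_true(all(is.finite(out$ssf[[k]]$beta)))
    expect_equal(out$ssf[[k]]$n_clusters, 2)
  }
  # decoded speeds: travelling steps are longer on average
  st <- steps_table(traj)
  ms <- tapply(st$sl, out$decoded$state, mean)
  expect_gt(ms["2"], ms["1"])
})

test_that("true-state strata isolate decoding error from likelihood bias", {
  # single-state fits on the walker's own choice sets, restricted to
  # the TRUE travelling steps, recover the generating coefficients --
  # so the 2-step bias comes from decoding, not from the fit
  ls <- make_patch_landscape(seed = 42)
  pieces <- lapply(1:3, function(r) {
    sim <- simulate_ssf_agent("forager", ls, id = paste0("t", r),
                              seed = 80 + r)
    gs <- build_covariates(sim_choice_strata(sim),
                           movement_spec("quality"),
                           list(quality = ls$quality))
    ts <- true_states_for(sim, gs[!duplicated(gs$stratum), ])
    gs$stratum <- paste0(r, ".", gs$stratum)
    keep <- unique(gs$stratum)[ts == 2]
    subset_strata(gs, keep)
  })
  trav <- do.call(rbind, pieces)
  attr(trav, "covariates") <- attr(pieces[[1]], "covariates")
  class(trav) <- c("ssf_strata", "data.frame")
  fit <- fit_state_ssf(trav)
  truth <- c(1, -0.3, -0.05, 0)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$beta - truth) < pmax(3 * se, 0.2)))
})
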