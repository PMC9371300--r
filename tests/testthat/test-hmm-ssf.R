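# Emission probabilities, grouped forward likelihood, fitting, decoding.

test_that("emission probabilities follow the softmax and sum to one", {
  X <- matrix(0, 21, 3)
  expect_equal(emission_prob(X, rep(0, 3), 0), 1 / 21)
  expect_equal(emission_prob(X, rep(0, 3), 20), 1 / 21)

  # q = 1, J = 1, X = (1, 0), beta = ln 2 -> observed prob 2/3
  expect_equal(emission_prob(cbind(c(1, 0)), log(2), 0), 2 / 3)

  withr::with_seed(7, {
    Xr <- matrix(rnorm(21 * 4), 21, 4)
    b <- rnorm(4)
    p <- vapply(0:20, function(j) emission_prob(Xr, b, j), 0)
    expect_equal(sum(p), 1)
  })
  expect_error(emission_prob(matrix(c(1, NA), 2, 1), 1, 0), "non-finite")
  expect_error(emission_prob(X, rep(0, 3), 21), "out of range")
})

test_that("forward likelihood equals brute-force enumeration (T <= 6)", {
  for (K in 2:3) {
    for (Tn in c(2, 4, 6)) {
      d <- make_toy_design(Tn, Jp1 = 4, q = 2, seed = K * 10 + Tn)
      withr::with_seed(K + Tn, {
        beta <- matrix(rnorm(K * 2), K, 2)
        G <- matrix(runif(K * K) + 0.2, K, K)
        G <- G / rowSums(G)
      })
      delta <- stationary_dist(G)
      e <- exp(hmmssf:::emission_logmat(d, beta))
      expect_equal(forward_loglik(d, beta, G),
                   brute_force_ll(e, G, delta, d$group),
                   tolerance = 1e-10)
    }
  }
})

test_that("grouped likelihood treats segments as independent", {
  d1 <- make_toy_design(6, Jp1 = 3, q = 2, n_groups = 1, seed = 2)
  d2 <- d1; d2$group <- rep(c("a", "b"), each = 3)
  beta <- rbind(c(0.5, -1), c(-0.2, 0.8))
  G <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  # splitting equals the sum of the two groups fitted alone
  dA <- d1; dA$X <- d1$X[1:9, , drop = FALSE]; dA$n <- 3
  dA$group <- rep("a", 3); dA$id <- dA$id[1:3]; dA$time <- 1:3
  dA$stratum <- 1:3
  dB <- dA; dB$X <- d1$X[10:18, , drop = FALSE]
  expect_equal(forward_loglik(d2, beta, G),
               forward_loglik(dA, beta, G) + forward_loglik(dB, beta, G),
               tolerance = 1e-12)
  # and differs from the unsplit likelihood by the transition/stationary
  # restart factor only (both are valid likelihoods of the same data)
  expect_false(isTRUE(all.equal(forward_loglik(d1, beta, G),
                                forward_loglik(d2, beta, G))))
})

test_that("likelihood is invariant to permuting state labels", {
  d <- make_toy_design(8, Jp1 = 4, q = 2, seed = 3)
  beta <- rbind(c(1, -0.5), c(-0.3, 0.9))
  G <- rbind(c(0.85, 0.15), c(0.3, 0.7))
  expect_equal(forward_loglik(d, beta, G),
               forward_loglik(d, beta[2:1, ], G[2:1, 2:1]),
               tolerance = 1e-12)
})

test_that("identical states collapse to the single-state likelihood", {
  d <- make_toy_design(10, Jp1 = 5, q = 2, seed = 4)
  b <- c(0.7, -0.4)
  G <- matrix(0.5, 2, 2)
  expect_equal(forward_loglik(d, rbind(b, b), G),
               sum(hmmssf:::emission_logmat(d, rbind(b))),
               tolerance = 1e-10)
})

test_that("invalid transition matrices are rejected", {
  d <- make_toy_design(4, seed = 5)
  beta <- rbind(c(1, 0), c(0, 1))
  expect_error(forward_loglik(d, beta, rbind(c(0.9, 0.2), c(0.3, 0.7))),
               "sum to 1")
})

test_that("fitting recovers parameters of model-true data", {
  beta <- rbind(c(1.5, 0, -1), c(-1, 1, 0.5))
  G <- rbind(c(0.92, 0.08), c(0.15, 0.85))
  sim <- simulate_hmm_strata(600, J = 10, beta, G, seed = 21)
  fit <- fit_hmm_ssf(sim$strata, K = 2, seed = 22, sl_covariates = NULL)
  expect_true(fit$converged)
  # align states by first coefficient (no step-length relabelling here)
  perm <- if (fit$beta[1, 1] > fit$beta[2, 1]) 1:2 else 2:1
  bhat <- fit$beta[perm, ]
  se <- sqrt(diag(fit$vcov))[c(outer(1:3, (perm - 1) * 3, "+"))]
  expect_true(all(abs(bhat - beta) < 3 * matrix(se, 2, 3, byrow = TRUE)))
  expect_true(all(abs(bhat - beta) < 0.45))
  Ghat <- fit$Gamma[perm, perm]
  expect_true(all(abs(Ghat - G) < 0.1))
  # monotonicity: more restarts never lose likelihood
  fit1 <- fit_hmm_ssf(sim$strata, K = 2, n_restarts = 1, seed = 22,
                      sl_covariates = NULL)
  expect_gte(fit$loglik, fit1$loglik - 1e-6)
})

test_that("K = 1 reduces to the conditional multinomial", {
  sim <- simulate_hmm_strata(200, J = 8, rbind(c(1, -0.5, 0)),
                             matrix(1, 1, 1), seed = 31)
  fit <- fit_hmm_ssf(sim$strata, K = 1)
  cl <- suppressWarnings(fit_state_ssf(sim$strata))
  expect_equal(unname(fit$beta[1, ]), unname(cl$beta), tolerance = 1e-4)
  expect_equal(fit$K, 1)
})

test_that("state probabilities start at the stationary law and sum to 1", {
  beta <- rbind(c(2, 0), c(-2, 1))
  G <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  sim <- simulate_hmm_strata(120, J = 6, beta, G, seed = 41, n_groups = 3)
  fit <- fit_hmm_ssf(sim$strata, K = 2, seed = 42, sl_covariates = NULL)
  pr <- state_probs(fit, sim$strata)
  P <- as.matrix(pr[, c("pred_1", "pred_2")])
  Fm <- as.matrix(pr[, c("filt_1", "filt_2")])
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_equal(unname(rowSums(Fm)), rep(1, nrow(Fm)))
  first <- !duplicated(pr$segment)
  delta <- stationary_dist(fit$Gamma)
  for (i in which(first)) expect_equal(unname(P[i, ]), delta)
})

test_that("decoding uses the >= threshold rule and argmax for K > 2", {
  pr <- data.frame(id = "a", segment = "a.1", stratum = 1:3, time = 1:3,
                   pred_1 = c(0.5, 0.49, 0.9),
                   pred_2 = c(0.5, 0.51, 0.1))
  attr(pr, "K") <- 2
  class(pr) <- c("state_prob_series", "data.frame")
  expect_equal(decode(pr, 0.5), c(1L, 2L, 1L))
  expect_error(decode(pr, 1), "threshold")
  # argmax agrees with the 0.5 rule except at exact ties
  withr::with_seed(6, {
    p1 <- runif(200)
    pr2 <- data.frame(id = "a", segment = "a.1", stratum = 1:200,
                      time = 1:200, pred_1 = p1, pred_2 = 1 - p1)
    attr(pr2, "K") <- 2
    class(pr2) <- c("state_prob_series", "data.frame")
    argmax <- ifelse(p1 >= 1 - p1, 1L, 2L)
    expect_equal(decode(pr2, 0.5), argmax)
  })
  pr3 <- data.frame(id = "a", segment = "a.1", stratum = 1, time = 1,
                    pred_1 = 0.2, pred_2 = 0.5, pred_3 = 0.3)
  attr(pr3, "K") <- 3
  class(pr3) <- c("state_prob_series", "data.frame")
  expect_equal(decode(pr3), 2L)
})
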