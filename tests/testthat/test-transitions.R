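# Transition classification, truncation, day periods, GLMM contract.

mk_probs <- function(p1, segment = "a.1", id = "a") {
  pr <- data.frame(id = id, segment = segment,
                   stratum = seq_along(p1), time = seq_along(p1),
                   pred_1 = p1, pred_2 = 1 - p1)
  attr(pr, "K") <- 2
  class(pr) <- c("state_prob_series", "data.frame")
  pr
}

test_that("transition classification follows the two-sided rule", {
  # thresholds: encamped at t requires p > 0.8; transition requires
  # p_{t+1} <= 0.2; staying requires p_{t+1} > 0.8
  pr <- mk_probs(c(0.9, 0.1, 0.9, 0.85, 0.9, 0.5, 0.3))
  rec <- classify_transitions(pr, p_threshold = 0.8)
  # pairs: (1,2) transition; (3,4) stay; (4,5) stay; (5,6) discarded;
  # (2,3), (6,7) not encamped at t
  expect_equal(rec$Y[rec$time == 1], 1L)
  expect_equal(rec$Y[rec$time %in% c(3, 4)], c(0L, 0L))
  expect_false(5 %in% rec$time)
  expect_equal(attr(rec, "n_discarded"), 3)

  # default 0.5 threshold
  rec2 <- classify_transitions(mk_probs(c(0.6, 0.4, 0.6, 0.6)), 0.5)
  expect_equal(rec2$Y, c(1L, 0L))
  expect_error(classify_transitions(pr, 0.4), "p_threshold")
  # pairs never straddle segment boundaries
  pr2 <- mk_probs(c(0.9, 0.9, 0.9, 0.1), segment = rep(c("a.1", "a.2"),
                                                       each = 2))
  rec3 <- classify_transitions(pr2, 0.8)
  expect_equal(rec3$time, c(1, 3))
  expect_equal(rec3$Y, c(0L, 1L))
})

test_that("record count is non-increasing in the threshold", {
  withr::with_seed(21, {
    pr <- mk_probs(runif(500))
  })
  n <- vapply(c(0.5, 0.6, 0.7, 0.8), function(th)
    nrow(classify_transitions(pr, th)), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("distance truncation is idempotent and 1-Lipschitz", {
  expect_equal(truncate_distance(0.1, 3.6), 0.1)
  expect_equal(truncate_distance(10, 3.6), 3.6)
  d <- seq(0, 8, by = 0.25)
  t1 <- truncate_distance(d, 3.6)
  expect_equal(truncate_distance(t1, 3.6), t1)
  expect_true(all(abs(diff(t1)) <= abs(diff(d)) + 1e-15))
  expect_error(truncate_distance(-1, 3.6))
})

test_that("day periods implement the three-level clock partition", {
  h <- c(0, 3, 6.5, 7, 15.9, 16, 21.9, 22, 2.5)
  expect_equal(as.character(day_period(h)),
               c("night", "dawn_dusk", "dawn_dusk", "day", "day",
                 "dawn_dusk", "dawn_dusk", "night", "night"))
  expect_equal(levels(day_period(h)), c("day", "dawn_dusk", "night"))
  expect_equal(as.character(day_period(c(4, 17), levels4 = TRUE)),
               c("dawn", "dusk"))
})

test_that("the null transition model recovers the pooled logit rate", {
  withr::with_seed(22, {
    rec <- data.frame(id = rep(paste0("i", 1:6), each = 80),
                      Y = rbinom(480, 1, 0.2))
  })
  fit <- suppressWarnings(suppressMessages(fit_transition_model(rec, Y ~ 1)))
  p <- mean(rec$Y)
  expect_equal(fit$coefficients$estimate[1], qlogis(p), tolerance = 0.05)
  expect_lt(fit$ranef_variance, 0.1)
  expect_error(fit_transition_model(within(rec, Y <- 0L), Y ~ 1),
               "both transition")
})

test_that("planted covariate effects are recovered with the GLMM", {
  # switching more likely outside patches and near the predator
  withr::with_seed(23, {
    n <- 220
    rec <- do.call(rbind, lapply(1:6, function(i) {
      in_patch <- rbinom(n, 1, 0.5)
      d_pred <- runif(n, 0, 3)
      eta <- -1 + 2 * (1 - in_patch) + 2 * (d_pred < 0.5)
      data.frame(id = paste0("i", i), in_patch = in_patch,
                 d_pred = d_pred, Y = rbinom(n, 1, plogis(eta)))
    }))
  })
  rec$d_tilde <- truncate_distance(rec$d_pred, 0.8)
  fit <- suppressWarnings(suppressMessages(
    fit_transition_model(rec, Y ~ in_patch + d_tilde)))
  co <- fit$coefficients
  expect_lt(co$upper[co$term == "in_patch"], 0)   # patches inhibit switching
  expect_lt(co$upper[co$term == "d_tilde"], 0)    # proximity promotes it
})

test_that("the threshold profile peaks near the planted trigger", {
  withr::with_seed(24, {
    n <- 400
    rec <- do.call(rbind, lapply(1:6, function(i) {
      d_pred <- runif(n, 0, 4)
      eta <- -2 + 2.5 * (d_pred < 0.8)
      data.frame(id = paste0("i", i), d_pred = d_pred,
                 Y = rbinom(n, 1, plogis(eta)))
    }))
  })
  prof <- suppressWarnings(suppressMessages(
    profile_d_threshold(rec, grid = seq(0.2, 3, by = 0.2),
                        formula = Y ~ d_tilde)))
  expect_lt(abs(prof$d_star - 0.8), 0.45)
  # grid endpoints are evaluated exactly
  expect_equal(prof$profile$d_threshold[1], 0.2)
  expect_equal(tail(prof$profile$d_threshold, 1), 3)
  # a covariate-free response yields an essentially flat profile
  withr::with_seed(25, {
    rec0 <- data.frame(id = rep(paste0("i", 1:4), each = 150),
                       d_pred = runif(600, 0, 4),
                       Y = rbinom(600, 1, 0.25))
  })
  prof0 <- suppressWarnings(suppressMessages(
    profile_d_threshold(rec0, grid = seq(0.5, 3, by = 0.5),
                        formula = Y ~ d_tilde)))
  expect_lt(diff(range(prof0$profile$loglik, na.rm = TRUE)), 2)
})

test_that("scenario-3 simulations feed the full transition pipeline", {
  ls <- make_patch_landscape(seed = 42)
  sim <- simulate_ssf_agent("forager_with_predator", ls, seed = 31)
  gs <- build_covariates(sim_choice_strata(sim), movement_spec("quality"),
                         list(quality = ls$quality))
  fit <- fit_hmm_ssf(gs, seed = 32)
  pr <- state_probs(fit, gs)
  rec <- transition_records_sim(sim, pr, ls, p_threshold = 0.5)
  expect_true(all(c("Y", "in_patch", "quality", "d_pred") %in% names(rec)))
  expect_true(nrow(rec) > 50)
  expect_true(all(rec$Y %in% 0:1))
  # switching frequency is higher outside patches or with the predator
  # within the trigger distance than inside patches with the predator far
  risky <- rec$in_patch == 0 | rec$d_pred <= 0.5
  safe <- rec$in_patch == 1 & rec$d_pred > 1
  if (sum(risky) > 5 && sum(safe) > 5)
    expect_gte(mean(rec$Y[risky]), mean(rec$Y[safe]))
})
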