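# Patch landscapes, SSF-walker scenarios, gap injection.

ls_fix <- make_patch_landscape(seed = 77)

test_that("patch landscapes respect the stated geometry", {
  expect_equal(nrow(ls_fix$patches), 500)
  expect_true(all(ls_fix$patches$quality %in% 1:10))
  expect_equal(ls_fix$size, sqrt(700))
  # patch area fraction: 500 x 0.25 km2 over 700 km2 = 17.9%; with
  # independently placed (overlapping) patches the covered fraction is
  # 1 - exp(-0.179) = 16.4%
  frac <- mean(ls_fix$quality$values > 0)
  expect_lt(abs(frac - (1 - exp(-500 * 0.25 / 700))), 0.01)
  # empty landscape
  ls0 <- make_patch_landscape(n_patches = 0, seed = 1)
  expect_true(all(ls0$quality$values == 0))
  # infeasible packing
  expect_error(make_patch_landscape(n_patches = 10, extent_km2 = 2,
                                    patch_ha = 25), "smaller")
})

test_that("the true state rule follows patch membership", {
  sim <- simulate_ssf_agent("forager", ls_fix, n_steps = 60, seed = 3)
  tr <- sim$trajectory
  q <- extract_raster(ls_fix$quality,
                      pmin(tr$x[1:60], ls_fix$size - 1e-9),
                      pmin(tr$y[1:60], ls_fix$size - 1e-9), outside = "na")
  manual <- ifelse(!is.na(q) & q > 0, 1L, 2L)
  expect_equal(sim$states$true_state, manual)
})

test_that("the predator forces travelling within the trigger distance", {
  sim <- simulate_ssf_agent("forager_with_predator", ls_fix,
                            n_steps = 300, seed = 4)
  tr <- sim$trajectory; pd <- sim$predator
  d <- sqrt((tr$x[1:300] - pd$x[1:300])^2 + (tr$y[1:300] - pd$y[1:300])^2)
  near <- d <= 0.5
  expect_true(all(sim$states$true_state[near] == 2L))
  # recomputable state rule: outside the trigger it is patch membership
  q <- extract_raster(ls_fix$quality,
                      pmin(tr$x[1:300], ls_fix$size - 1e-9),
                      pmin(tr$y[1:300], ls_fix$size - 1e-9), outside = "na")
  manual <- ifelse(near, 2L, ifelse(!is.na(q) & q > 0, 1L, 2L))
  expect_equal(sim$states$true_state, manual)
})

test_that("equal scores make every candidate equally likely", {
  # flat landscape, zero coefficients: chosen index should be uniform
  flat <- make_patch_landscape(n_patches = 0, seed = 1)
  betas <- list(encamped = rep(0, 5), travelling = rep(0, 5))
  withr::with_seed(5, {
    picks <- integer(0)
    for (r in 1:6) {
      sim <- simulate_ssf_agent("forager", flat, n_steps = 150,
                                betas = betas, seed = 50 + r)
      picks <- c(picks, sim$choices$picked)
    }
  })
  tab <- table(factor(picks, 1:20))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("migrants start south and drift north through travelling steps", {
  sims <- lapply(1:5, function(r)
    simulate_ssf_agent("migrant", ls_fix, n_steps = 150, seed = 60 + r))
  y0 <- vapply(sims, function(s) s$trajectory$y[1], 0)
  expect_true(all(y0 <= 0.2 * ls_fix$size))
  drift <- vapply(sims, function(s) {
    tr <- s$trajectory
    dy <- diff(tr$y)[s$states$true_state == 2]
    if (length(dy)) mean(dy) else NA_real_
  }, 0)
  expect_gt(mean(drift, na.rm = TRUE), 0)
})

test_that("generative choice strata reproduce the walker's decisions", {
  sim <- simulate_ssf_agent("forager", ls_fix, n_steps = 40, seed = 6)
  gs <- sim_choice_strata(sim)
  expect_equal(length(unique(gs$stratum)), 39)  # first step excluded
  expect_equal(unique(table(gs$stratum)), 20)   # the 20 proposals
  obs <- gs[gs$candidate == 0, ]
  tr <- sim$trajectory
  expect_equal(obs$x_end, tr$x[3:41])           # chosen = next fix
  expect_equal(obs$y_end, tr$y[3:41])
  # true-state alignment by step start time
  ts <- true_states_for(sim, gs[!duplicated(gs$stratum), ])
  expect_equal(ts, sim$states$true_state[-1])
})

test_that("gap injection matches its documented patterns", {
  tr <- data.frame(id = "a", time = 0:500, x = runif(501), y = runif(501))
  expect_identical(inject_gaps(tr, "drop_frac", drop_frac = 0), tr)

  wk <- inject_gaps(tr, "weekly_mixed")
  expect_true(all((wk$time %% 168) < 120))
  seg <- segment_trajectories(wk, nominal_interval = 1)
  expect_equal(length(unique(seg$segment)), 3)   # three 5-day blocks
  expect_true(all(table(seg$segment) == 120))

  g1 <- inject_gaps(tr, "drop_frac", drop_frac = 0.3, seed = 7)
  g2 <- inject_gaps(tr, "drop_frac", drop_frac = 0.3, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 501 - round(0.3 * 499))
})

test_that("segmented gappy data refit close to the complete-data fit", {
  sim <- simulate_ssf_agent("forager", ls_fix, n_steps = 400, seed = 8)
  tr <- sim$trajectory
  gap <- inject_gaps(tr, "drop_frac", drop_frac = 0.15, seed = 9)
  seg <- segment_trajectories(gap, nominal_interval = 1)
  expect_gt(length(unique(seg$segment)), 1)
  st <- draw_random_steps(seg, J = 20, radius = 2, seed = 10)
  st <- build_covariates(st, movement_spec("quality"),
                         list(quality = ls_fix$quality))
  fit <- fit_hmm_ssf(st, K = 2, seed = 11)
  expect_true(fit$converged)
  # the encamped state still shows positive patch-quality selection
  expect_gt(fit$beta[1, "quality"], 0)
})
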