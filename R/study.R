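# Replicated simulation studies: the end-to-end pipelines that simulate
# walkers, fit one HMM-SSF per replicate, pool the fits, and score state
# recovery.  One landscape is generated per scenario and shared by all
# replicates; replicates differ in start point and RNG stream.

#' Run a replicated SSF-scenario study
#'
#' For each replicate: simulate one walker, build its generative choice
#' strata (the availability samples the walker actually chose from),
#' fit a 2-state HMM-SSF, and record filtered state probabilities and
#' true states.  Fits are pooled with the inverse-variance formula.
#' State recovery is scored on the filtered probabilities
#' P(S_t | data up to t): the one-step-ahead predictive probabilities
#' cannot anticipate a transition (the emission that reveals it is
#' excluded by construction), so they bound the ROC well below what the
#' model actually knows about the current step.
#'
#' @param scenario "forager", "migrant" or "forager_with_predator".
#' @param n_reps number of replicate individuals.
#' @param seed base seed; every landscape, walker and fit seed derives
#'   from it.
#' @param n_steps steps per walker (scenario default when NULL).
#' @param landscape optionally, a pre-built \code{patch_landscape}.
#' @return list of class \code{scenario_study}: \code{landscape},
#'   \code{sims}, \code{fits}, \code{pooled}
#'   (\code{population_estimate}), \code{auc} (pooled AUC of the
#'   filtered travelling-state probability against the true states),
#'   \code{probs}/\code{truth} (per-replicate filtered travelling
#'   probabilities and true states), \code{scenario}, \code{spec}
#'   (the covariate layout used).
#' @export
scenario_study <- function(scenario, n_reps, seed, n_steps = NULL,
                           landscape = NULL) {
  if (is.null(landscape))
    landscape <- make_patch_landscape(seed = child_seed(seed, 0))
  spec <- movement_spec("quality", with_target = scenario == "migrant")
  sims <- vector("list", n_reps)
  fits <- vector("list", n_reps)
  probs <- truth <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_ssf_agent(scenario, landscape, n_steps = n_steps,
                              id = paste0(substr(scenario, 1, 3), r),
                              seed = child_seed(seed, r))
    gs <- build_covariates(sim_choice_strata(sim), spec,
                           list(quality = landscape$quality),
                           target = sim$target)
    fit <- fit_hmm_ssf(gs, K = 2, seed = child_seed(seed, 100000 + r))
    pr <- state_probs(fit, gs)
    sims[[r]] <- sim
    fits[[r]] <- fit
    probs[[r]] <- pr$filt_2
    truth[[r]] <- true_states_for(sim, pr)
  }
  pooled <- pool_fits(fits)
  auc <- roc_auc(as.integer(unlist(truth) == 2), unlist(probs))
  structure(list(landscape = landscape, sims = sims, fits = fits,
                 pooled = pooled, auc = auc, probs = probs,
                 truth = truth, scenario = scenario, spec = spec),
            class = "scenario_study")
}

#' State-specific cross-validation of a scenario study
#'
#' Draws fresh random-step strata (J random candidates plus the observed
#' step, the field design) for every replicate and runs the 80/20
#' individual-level k-fold procedure against the study's fits.
#'
#' @param study a \code{scenario_study}.
#' @param reps CV repetitions.
#' @param seed RNG seed.
#' @param J random steps per stratum (default 20).
#' @param radius sampling radius in km (default 2, the simulation disk).
#' @return a \code{cv_report} (see \code{\link{kfold_cv}}).
#' @export
scenario_cv <- function(study, reps = 100, seed = NULL, J = 20,
                        radius = 2) {
  strata <- lapply(seq_along(study$sims), function(r) {
    tr <- study$sims[[r]]$trajectory
    tr$segment <- paste0(tr$id, ".1")
    st <- draw_random_steps(tr, J = J, radius = radius,
                            seed = child_seed(seed, 200000 + r))
    build_covariates(st, study$spec,
                     list(quality = study$landscape$quality),
                     target = study$sims[[r]]$target)
  })
  kfold_cv(study$fits, strata, reps = reps, seed = child_seed(seed, 999))
}

#' Run a replicated BCRW study
#'
#' One Gaussian-random-field landscape per patchiness scenario; each
#' replicate simulates a consumption/memory walker, re-draws random
#' steps with the replicate's 99th-percentile radius, fits a 2-state
#' HMM-SSF (turn cosine, step length, log step length, habitat quality
#' scaled x100, plus distance to the nearest resource patch for the
#' intermediate/high presets), and scores decoded states against the
#' walker's true feeding/searching modes.
#'
#' @param patchiness "low", "intermediate" or "high".
#' @param n_reps replicate count.
#' @param seed base seed.
#' @param n_steps recorded steps per walker.
#' @return list of class \code{bcrw_study}: \code{landscape},
#'   \code{fits}, \code{auc} (pooled over replicates), \code{auc_reps},
#'   \code{patchiness}.
#' @export
bcrw_study <- function(patchiness, n_reps, seed, n_steps = 500) {
  landscape <- make_grf_landscape(patchiness, seed = child_seed(seed, 0))
  q100 <- raster_grid(landscape$values * 100, landscape$origin,
                      landscape$cell_size, "quality")
  rasters <- list(quality = q100)
  defs <- list(list(name = "cos_dp", type = "cos_turn"),
               list(name = "sl", type = "step_length"),
               list(name = "log_sl", type = "log_step_length"),
               list(name = "quality", type = "raster", raster = "quality"))
  if (patchiness != "low") {
    rasters$dist_patch <- distance_to_patches_raster(landscape)
    defs <- c(defs, list(list(name = "dist_patch", type = "raster",
                              raster = "dist_patch")))
  }
  spec <- do.call(covariate_spec, defs)
  fits <- vector("list", n_reps)
  probs <- truth <- vector("list", n_reps)
  auc_reps <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_bcrw(landscape, n_steps = n_steps,
                         id = paste0("b", r), seed = child_seed(seed, r))
    tr <- sim$trajectory
    tr$segment <- paste0(tr$id, ".1")
    rad <- radius_99(tr)
    st <- draw_random_steps(tr, J = 20, radius = rad,
                            seed = child_seed(seed, 300000 + r))
    st <- build_covariates(st, spec, rasters)
    fit <- fit_hmm_ssf(st, K = 2, seed = child_seed(seed, 100000 + r))
    pr <- state_probs(fit, st)
    ts <- true_states_for(sim, pr)
    fits[[r]] <- fit
    probs[[r]] <- pr$filt_2
    truth[[r]] <- ts
    auc_reps[r] <- tryCatch(roc_auc(as.integer(ts == 2), pr$filt_2),
                            error = function(e) NA_real_)
  }
  auc <- roc_auc(as.integer(unlist(truth) == 2), unlist(probs))
  structure(list(landscape = landscape, fits = fits, auc = auc,
                 auc_reps = auc_reps, patchiness = patchiness),
            class = "bcrw_study")
}
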