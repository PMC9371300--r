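# Scenario simulator: state-specific SSF walkers on a patch landscape,
# with known true states.
#
# Scenarios: "forager" (moves among resource patches), "migrant"
# (forager additionally attracted to a distant target), and
# "forager_with_predator" (forager fleeing a single-state SSF predator
# that tracks the prey's resource).  The walker's true mode at each step
# is a deterministic function of its position (encamped inside a
# resource patch, travelling outside) and, in the predator scenario, of
# predator proximity (travelling whenever the predator is within the
# trigger distance).  Mode transitions therefore depend on covariates,
# deliberately violating the constant-transition Markov assumption of
# the fitted model.

#' Printed scenario coefficient vectors
#'
#' Selection coefficients over (cos turn, SL, log SL, quality, cos
#' target) for the encamped (state 1) and travelling (state 2) modes of
#' each scenario; the target term applies to the migrant scenario only.
#'
#' @param scenario one of "forager", "migrant", "forager_with_predator".
#' @return list with \code{encamped} and \code{travelling} 5-vectors
#'   (NA target entries where the scenario has no target).
#' @export
scenario_betas <- function(scenario = c("forager", "migrant",
                                        "forager_with_predator")) {
  scenario <- match.arg(scenario)
  enc <- c(cos_dp = 0.0, sl = -3.0, log_sl = -0.5, quality = 1.0,
           cos_target = NA)
  tra <- c(cos_dp = 1.0, sl = -0.3, log_sl = -0.05, quality = 0.0,
           cos_target = NA)
  if (scenario == "migrant") {
    enc["cos_target"] <- 0.0
    tra["cos_target"] <- 1.0
  }
  list(encamped = enc, travelling = tra)
}

#' Generate a random patch landscape
#'
#' Circular resource patches with centres uniform over a square map and
#' integer qualities drawn uniformly from 1..10; quality outside patches
#' is 0 and overlapping patches take the maximum.  The quality surface
#' is rasterized at \code{cell_size}.
#'
#' @param n_patches number of patches (default 500).
#' @param extent_km2 map area in km^2 (default 700; the map is square).
#' @param patch_ha patch area in hectares (default 25).
#' @param cell_size raster cell size in km.
#' @param seed RNG seed.
#' @return list of class \code{patch_landscape}: \code{size} (map edge,
#'   km), \code{patches} (centre coordinates, radius, quality),
#'   \code{quality} (a \code{raster_grid}).
#' @export
make_patch_landscape <- function(n_patches = 500, extent_km2 = 700,
                                 patch_ha = 25, cell_size = 0.1,
                                 seed = NULL) {
  patch_km2 <- patch_ha / 100
  if (n_patches * patch_km2 >= extent_km2)
    stop("total patch area must be smaller than the map")
  L <- sqrt(extent_km2)
  r <- sqrt(patch_km2 / pi)
  run_manifest("make_patch_landscape", seed,
               list(n_patches = n_patches, extent_km2 = extent_km2))
  with_seed(seed, {
    nc <- ceiling(L / cell_size)
    vals <- matrix(0, nc, nc)
    patches <- data.frame(x = numeric(0), y = numeric(0),
                          radius = numeric(0), quality = integer(0))
    if (n_patches > 0) {
      cx <- stats::runif(n_patches, 0, L)
      cy <- stats::runif(n_patches, 0, L)
      qual <- sample.int(10, n_patches, replace = TRUE)
      ctr <- (seq_len(nc) - 0.5) * cell_size
      for (i in seq_len(n_patches)) {
        ix <- which(abs(ctr - cx[i]) <= r)
        iy <- which(abs(ctr - cy[i]) <= r)
        if (!length(ix) || !length(iy)) next
        dd <- outer(ctr[iy] - cy[i], ctr[ix] - cx[i],
                    function(a, b) a^2 + b^2)
        hit <- dd <= r^2
        blk <- vals[iy, ix, drop = FALSE]
        blk[hit] <- pmax(blk[hit], qual[i])
        vals[iy, ix] <- blk
      }
      patches <- data.frame(x = cx, y = cy, radius = r, quality = qual)
    }
    structure(list(size = L, patches = patches,
                   quality = raster_grid(vals, origin = c(0, 0),
                                         cell_size = cell_size,
                                         name = "quality")),
              class = "patch_landscape")
  })
}

# reflect coordinates into [0, L]
reflect_into <- function(v, L) {
  v <- abs(v)
  over <- v > L
  v[over] <- 2 * L - v[over]
  pmin(pmax(v, 0), L)
}

# one SSF walker step: draw n_cand candidates uniformly over the disk
# AREA, score with beta, pick one.  Area-uniform proposals are used for
# the walker (distance-uniform proposals concentrate candidates around
# the current position, which at the scenario coefficients traps
# walkers inside single patches for entire trajectories); the fitting
# availability sample (draw_random_steps) stays uniform in distance.
ssf_choose_step <- function(x, y, heading, beta, landscape, n_cand,
                            radius, target = NULL) {
  L <- landscape$size
  d <- radius * sqrt(stats::runif(n_cand))
  a <- stats::runif(n_cand, -pi, pi)
  xe <- reflect_into(x + d * cos(a), L)
  ye <- reflect_into(y + d * sin(a), L)
  dx <- xe - x; dy <- ye - y
  sl <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  q <- extract_raster(landscape$quality, pmin(xe, L - 1e-9),
                      pmin(ye, L - 1e-9), outside = "na")
  q[is.na(q)] <- 0
  A <- beta[1] * cos(ang - heading) + beta[2] * sl +
    beta[3] * log(pmax(sl, LOG_SL_FLOOR)) + beta[4] * q
  if (!is.null(target) && !is.na(beta[5]))
    A <- A + beta[5] * cos(atan2(target[2] - y, target[1] - x) - ang)
  p <- exp(A - max(A))
  i <- sample.int(n_cand, 1, prob = p)
  list(x = xe[i], y = ye[i], heading = ang[i], sl = sl[i],
       cand_x = xe, cand_y = ye, chosen = i)
}

#' Simulate a state-specific SSF walker
#'
#' At each step the walker's true mode is set from its current position
#' (and predator distance in the predator scenario), 20 candidate steps
#' are drawn uniform-in-distance in the sampling disk, and the next
#' location is a single multinomial draw over the candidates with the
#' mode-specific softmax weights.  In the predator scenario a predator
#' walker moves each step by its own single-state rule tracking the
#' prey's resource; the prey-predator distance is evaluated at step
#' start.
#'
#' @param scenario "forager", "migrant" or "forager_with_predator".
#' @param landscape a \code{patch_landscape}.
#' @param n_steps number of steps (defaults: 300 for the migrant, 500
#'   otherwise).
#' @param n_candidates candidates per step (default 20).
#' @param radius sampling disk radius in km (default 2).
#' @param betas scenario coefficients, as \code{\link{scenario_betas}}.
#' @param predator_beta predator coefficients (cos turn, SL, log SL,
#'   quality).
#' @param predator_trigger prey-predator distance (km) below which the
#'   prey's mode is forced to travelling (default 0.5).
#' @param id individual id for the output table.
#' @param seed RNG seed.
#' @return list of class \code{ssf_simulation}: \code{trajectory} (fix
#'   table id/time/x/y), \code{states} (per step: \code{start_time} of
#'   the step's start fix and \code{true_state}, 1 = encamped,
#'   2 = travelling), \code{predator} (fix table or NULL),
#'   \code{scenario}, \code{target}.
#' @export
simulate_ssf_agent <- function(scenario = c("forager", "migrant",
                                            "forager_with_predator"),
                               landscape, n_steps = NULL,
                               n_candidates = 20, radius = 2,
                               betas = scenario_betas(scenario),
                               predator_beta = c(1, -0.3, -0.05, 0.1),
                               predator_trigger = 0.5,
                               id = "sim1", seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(n_steps)) n_steps <- if (scenario == "migrant") 300 else 500
  L <- landscape$size
  target <- if (scenario == "migrant") c(L / 2, L) else NULL
  run_manifest("simulate_ssf_agent", seed,
               list(scenario = scenario, n_steps = n_steps))
  with_seed(seed, {
    x <- stats::runif(1, 0, L)
    y <- if (scenario == "migrant") stats::runif(1, 0, 0.2 * L)
         else stats::runif(1, 0, L)
    heading <- stats::runif(1, -pi, pi)
    has_pred <- scenario == "forager_with_predator"
    if (has_pred) {
      px <- stats::runif(1, 0, L); py <- stats::runif(1, 0, L)
      ph <- stats::runif(1, -pi, pi)
      pred <- matrix(NA_real_, n_steps + 1, 2)
      pred[1, ] <- c(px, py)
    }
    xs <- ys <- numeric(n_steps + 1)
    xs[1] <- x; ys[1] <- y
    st <- integer(n_steps)
    ch_x <- ch_y <- matrix(NA_real_, n_steps, n_candidates)
    ch_pick <- integer(n_steps)
    ch_head <- numeric(n_steps)
    bmat <- rbind(betas$encamped, betas$travelling)
    for (i in seq_len(n_steps)) {
      q_here <- extract_raster(landscape$quality, pmin(x, L - 1e-9),
                               pmin(y, L - 1e-9), outside = "na")
      in_patch <- !is.na(q_here) && q_here > 0
      k <- if (in_patch) 1L else 2L
      if (has_pred && sqrt((x - px)^2 + (y - py)^2) <= predator_trigger)
        k <- 2L
      st[i] <- k
      ch_head[i] <- heading
      mv <- ssf_choose_step(x, y, heading, bmat[k, ], landscape,
                            n_candidates, radius, target)
      ch_x[i, ] <- mv$cand_x; ch_y[i, ] <- mv$cand_y
      ch_pick[i] <- mv$chosen
      x <- mv$x; y <- mv$y; heading <- mv$heading
      xs[i + 1] <- x; ys[i + 1] <- y
      if (has_pred) {
        pv <- ssf_choose_step(px, py, ph, c(predator_beta, NA), landscape,
                              n_candidates, radius)
        px <- pv$x; py <- pv$y; ph <- pv$heading
        pred[i + 1, ] <- c(px, py)
      }
    }
    traj <- data.frame(id = id, time = 0:n_steps, x = xs, y = ys,
                       stringsAsFactors = FALSE)
    out <- list(trajectory = traj,
                states = data.frame(start_time = 0:(n_steps - 1),
                                    true_state = st),
                predator = if (has_pred)
                  data.frame(id = paste0(id, ".pred"), time = 0:n_steps,
                             x = pred[, 1], y = pred[, 2]) else NULL,
                choices = list(x = ch_x, y = ch_y, picked = ch_pick,
                               heading = ch_head),
                scenario = scenario, target = target, radius = radius,
                id = id)
    class(out) <- "ssf_simulation"
    out
  })
}

#' Choice strata of a simulated walker
#'
#' Turns the simulator's recorded per-step choice sets into
#' \code{ssf_strata}: candidate 0 is the chosen (observed) step and the
#' remaining candidates are the non-chosen proposals of the same draw.
#' Using these strata makes the conditional-multinomial likelihood the
#' exact generative likelihood of the walker (the availability sample
#' the animal actually "saw"), which is what parameter-recovery
#' assessments condition on; freshly re-drawn strata
#' (\code{\link{draw_random_steps}}) are the field situation, where the
#' choice set is unknown.  The first step of the trajectory is excluded
#' (its turning angle rests on the arbitrary initial heading).
#'
#' @param sim an \code{ssf_simulation}.
#' @return an \code{ssf_strata} data.frame (J+1 = number of simulated
#'   candidates per step).
#' @export
sim_choice_strata <- function(sim) {
  ch <- sim$choices
  if (is.null(ch)) stop("simulation has no recorded choice sets")
  n_steps <- nrow(ch$x)
  n_cand <- ncol(ch$x)
  tr <- sim$trajectory
  rows <- vector("list", n_steps - 1)
  for (i in 2:n_steps) {
    ord <- c(ch$picked[i], setdiff(seq_len(n_cand), ch$picked[i]))
    rows[[i - 1]] <- data.frame(
      id = sim$id, segment = paste0(sim$id, ".1"),
      stratum = i - 1, time = tr$time[i],
      candidate = 0:(n_cand - 1),
      x_start = tr$x[i], y_start = tr$y[i],
      prev_heading = ch$heading[i],
      x_end = ch$x[i, ord], y_end = ch$y[i, ord],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, J = n_cand - 1, radius = sim$radius,
            class = c("ssf_strata", "data.frame"))
}

#' True states aligned with strata or probability series
#'
#' Matches each stratum (by its step start time) to the simulator's
#' recorded true state.
#'
#' @param sim an \code{ssf_simulation} (or any list with a
#'   \code{states} table of \code{start_time}/\code{true_state}).
#' @param obj an \code{ssf_strata} or \code{state_prob_series}; one state
#'   per stratum is returned, in stratum order.
#' @return integer vector of true states.
#' @export
true_states_for <- function(sim, obj) {
  tt <- if (inherits(obj, "state_prob_series")) obj$time
        else obj$time[!duplicated(obj$stratum)]
  sim$states$true_state[match(tt, sim$states$start_time)]
}

#' Inject sampling gaps into a regular trajectory
#'
#' Patterns: \code{"drop_frac"} removes a random fraction of the
#' interior fixes; \code{"weekly_mixed"} emulates a schedule of hourly
#' fixes five days a week and 3-hourly fixes two days a week after
#' keeping only the hourly part, i.e. it deletes the fixes of the last
#' two days of every 7-day cycle, leaving 2-day holes.
#'
#' @param traj fix table with numeric \code{time} in hours.
#' @param pattern "drop_frac" or "weekly_mixed".
#' @param drop_frac fraction of interior fixes removed (drop_frac
#'   pattern).
#' @param seed RNG seed.
#' @return the thinned fix table.
#' @export
inject_gaps <- function(traj, pattern = c("drop_frac", "weekly_mixed"),
                        drop_frac = 0.3, seed = NULL) {
  pattern <- match.arg(pattern)
  run_manifest("inject_gaps", seed,
               list(pattern = pattern, drop_frac = drop_frac))
  if (pattern == "weekly_mixed") {
    keep <- (traj$time %% 168) < 120
    return(traj[keep, , drop = FALSE])
  }
  if (drop_frac <= 0) return(traj)
  with_seed(seed, {
    n <- nrow(traj)
    interior <- 2:(n - 1)
    drop <- sample(interior, round(drop_frac * length(interior)))
    traj[-drop, , drop = FALSE]
  })
}
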