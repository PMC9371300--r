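# Consumption-regeneration-memory biased correlated random walk on a
# Gaussian-random-field landscape, discretized with explicit Euler
# substeps.  The walker feeds (slow, tortuous) until its instantaneous
# intake drops below its running mean intake, then searches (fast,
# straighter, biased toward remembered productive cells that are also
# close), and switches back when intake recovers.  All spatial units are
# grid cells; one recorded step is 1/dt Euler substeps.

#' Gaussian random field landscape
#'
#' Stationary GRF with exponential covariance (variance 1, nugget 0) and
#' mean \code{mu_q} on an \code{n x n} cell grid; negative values are
#' truncated to 0 and the field is normalized to sum to 1.  Patchiness
#' presets: low (mu = -1.5, range 2), intermediate (-0.5, 2), high
#' (1, 10).
#'
#' @param patchiness "low", "intermediate" or "high"; or NULL to use
#'   \code{mu_q}/\code{gamma_q} directly.
#' @param n grid side (default 50).
#' @param mu_q,gamma_q mean and range of the exponential covariance.
#' @param seed RNG seed.
#' @return a \code{raster_grid} (cell size 1, origin (0, 0)).
#' @export
make_grf_landscape <- function(patchiness = c("low", "intermediate", "high"),
                               n = 50, mu_q = NULL, gamma_q = NULL,
                               seed = NULL) {
  if (is.null(mu_q) || is.null(gamma_q)) {
    patchiness <- match.arg(patchiness)
    pp <- switch(patchiness,
                 low = c(-1.5, 2), intermediate = c(-0.5, 2),
                 high = c(1, 10))
    mu_q <- pp[1]; gamma_q <- pp[2]
  }
  run_manifest("make_grf_landscape", seed,
               list(n = n, mu_q = mu_q, gamma_q = gamma_q))
  R <- grf_chol(n, gamma_q)
  with_seed(seed, {
    z <- mu_q + drop(crossprod(R, stats::rnorm(n * n)))
    m <- matrix(pmax(z, 0), n, n)
    s <- sum(m)
    if (s <= 0) stop("degenerate landscape: all mass truncated to zero")
    raster_grid(m / s, origin = c(0, 0), cell_size = 1, name = "quality")
  })
}

# cache the Cholesky factor of the exponential-covariance matrix per
# (n, range); the factor is seed-independent and expensive
.grf_cache <- new.env(parent = emptyenv())
grf_chol <- function(n, gamma_q) {
  key <- paste0(n, "_", gamma_q)
  if (!is.null(.grf_cache[[key]])) return(.grf_cache[[key]])
  ctr <- expand.grid(x = seq_len(n) - 0.5, y = seq_len(n) - 0.5)
  D <- as.matrix(stats::dist(ctr))
  C <- exp(-D / gamma_q) + diag(1e-10, n * n)
  R <- chol(C)
  .grf_cache[[key]] <- R
  R
}

#' BCRW model parameters
#'
#' Defaults satisfy the model's qualitative constraints: searching is
#' faster (\code{v_search > v_feed}) and straighter
#' (\code{sd_search < sd_feed}); short-term memory learns and decays
#' faster than long-term memory so a just-visited cell is transiently
#' repulsive.
#'
#' @param beta_r regeneration rate (per time unit).
#' @param beta_c consumption rate.
#' @param gamma_c consumption kernel scale (cells).
#' @param beta_l,gamma_l,phi_l long-term memory learning rate, kernel
#'   scale and decay rate.
#' @param beta_s,gamma_s,phi_s short-term memory analogues.
#' @param psi_m weight of the short-term (repulsive) memory in
#'   M = L - psi_m * S.
#' @param gamma_z scale (cells) of the exponential distance kernel
#'   weighting the memory when choosing a search target.
#' @param sd_feed,sd_search heading noise (wrapped-normal sd per unit
#'   time) in the feeding and searching modes.
#' @param w_persist weight of the previous heading in the searching-mode
#'   circular mixture of persistence and bias.
#' @param v_feed,v_search speeds in cells per unit time.
#' @param dt Euler step as a fraction of a recorded step.
#' @return a list of class \code{bcrw_params}.
#' @export
bcrw_params <- function(beta_r = 0.05, beta_c = 1, gamma_c = 1,
                        beta_l = 0.3, gamma_l = 1, phi_l = 0.001,
                        beta_s = 0.6, gamma_s = 1, phi_s = 0.05,
                        psi_m = 2, gamma_z = 5,
                        sd_feed = 1.2, sd_search = 0.25,
                        w_persist = 0.5,
                        v_feed = 0.7, v_search = 2.8, dt = 0.1) {
  p <- as.list(environment())
  stopifnot(p$v_search > p$v_feed, p$dt > 0,
            all(unlist(p[c("beta_r", "beta_c", "beta_l", "beta_s",
                           "phi_l", "phi_s")]) >= 0))
  class(p) <- "bcrw_params"
  p
}

# initial walker state on a landscape
bcrw_init <- function(landscape, params, x = NULL, y = NULL,
                      heading = NULL) {
  n <- nrow(landscape$values)
  st <- list(
    n = n,
    x = x %||% stats::runif(1, 0, n),
    y = y %||% stats::runif(1, 0, n),
    heading = heading %||% stats::runif(1, -pi, pi),
    mode = 1L,                      # 1 feeding, 2 searching
    Q0 = landscape$values,
    inv_Q0 = ifelse(landscape$values > 0, 1 / landscape$values, 0),
    Q = landscape$values,
    L = matrix(0, n, n),
    S = matrix(0, n, n),
    M = matrix(0, n, n),
    cons_log = numeric(0),
    cxy = cbind(rep(seq_len(n) - 0.5, each = n),
                rep(seq_len(n) - 0.5, n)))   # (x, y) per cell, row-major y
  # cell centre coordinate layout matching matrix [row=y, col=x]
  st$cell_x <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  st$cell_y <- matrix(rep(seq_len(n) - 0.5, n), n, n)
  st
}

# squared distance of every cell centre from the walker
cell_dist2 <- function(state) {
  (state$cell_x - state$x)^2 + (state$cell_y - state$y)^2
}

gauss_kernel <- function(d2, scale) {
  exp(-d2 / (2 * scale^2)) / (2 * pi * scale^2)
}

# index window of cells within 5*scale of the walker (the bivariate
# normal kernels are numerically zero beyond that)
cell_window <- function(state, scale) {
  r <- ceiling(5 * scale)
  rows <- max(1, floor(state$y - r)):min(state$n, ceiling(state$y + r))
  cols <- max(1, floor(state$x - r)):min(state$n, ceiling(state$x + r))
  list(rows = rows, cols = cols)
}

#' Euler update of the resource field
#'
#' Q <- Q + dt * (R - C) * Q with regeneration
#' R = beta_r (1 - Q/Q0) and consumption C = beta_c * f_c(|z - Z|),
#' f_c an isotropic bivariate-normal kernel; Q is clamped to [0, Q0].
#'
#' @param state a BCRW walker state.
#' @param params \code{bcrw_params}.
#' @param dt Euler step.
#' @return the state with updated \code{Q} and the instantaneous intake
#'   appended to \code{cons_log}.
#' @export
step_resources <- function(state, params, dt = params$dt) {
  # regeneration acts everywhere (logistic toward Q0, stable without a
  # clamp when dt * beta_r < 1); consumption only within the local
  # kernel support around the walker, clamped below at 0
  inv0 <- state$inv_Q0 %||% ifelse(state$Q0 > 0, 1 / state$Q0, 0)
  newQ <- state$Q * (1 + dt * params$beta_r * (1 - state$Q * inv0))
  w <- cell_window(state, params$gamma_c)
  qold <- state$Q[w$rows, w$cols]
  d2 <- (state$cell_x[w$rows, w$cols] - state$x)^2 +
    (state$cell_y[w$rows, w$cols] - state$y)^2
  C <- params$beta_c * gauss_kernel(d2, params$gamma_c)
  qnew <- newQ[w$rows, w$cols] - dt * C * qold
  over <- sum(pmax(-qnew, 0))
  if (over > 0.1 * max(sum(qold), .Machine$double.eps))
    warning("Euler step overshoots the [0, Q0] clamp by > 10%; reduce dt")
  newQ[w$rows, w$cols] <- pmin(pmax(qnew, 0), state$Q0[w$rows, w$cols])
  intake <- sum(C * qold)
  state$Q <- newQ
  state$cons_log <- c(state$cons_log, intake)
  state$cons_sum <- (state$cons_sum %||% 0) + intake
  state
}

#' Euler update of the memory fields
#'
#' L and S relax toward Q0 where the walker is (bivariate-normal
#' learning kernels) and decay exponentially elsewhere;
#' M = L - psi_m * S.
#'
#' @inheritParams step_resources
#' @return the state with updated \code{L}, \code{S}, \code{M}.
#' @export
step_memory <- function(state, params, dt = params$dt) {
  # exponential decay everywhere; learning within the kernel support
  state$L <- state$L - dt * params$phi_l * state$L
  state$S <- state$S - dt * params$phi_s * state$S
  wl <- cell_window(state, max(params$gamma_l, params$gamma_s))
  d2 <- (state$cell_x[wl$rows, wl$cols] - state$x)^2 +
    (state$cell_y[wl$rows, wl$cols] - state$y)^2
  fL <- gauss_kernel(d2, params$gamma_l)
  fS <- gauss_kernel(d2, params$gamma_s)
  state$L[wl$rows, wl$cols] <- state$L[wl$rows, wl$cols] +
    dt * params$beta_l * fL * (state$Q0[wl$rows, wl$cols] -
                                 state$L[wl$rows, wl$cols])
  state$S[wl$rows, wl$cols] <- state$S[wl$rows, wl$cols] +
    dt * params$beta_s * fS * (state$Q0[wl$rows, wl$cols] -
                                 state$S[wl$rows, wl$cols])
  state$M <- state$L - params$psi_m * state$S
  state
}

#' One movement substep
#'
#' Mode switching: to searching when the latest intake is below the
#' running mean intake, back to feeding otherwise.  Feeding: correlated
#' walk (heading + wrapped-normal noise, speed v_feed).  Searching:
#' biased correlated walk whose bias points to the cell maximizing
#' M weighted by an exponential distance kernel (known productive
#' patches that are also close); the new heading mixes persistence and
#' bias.
#'
#' @inheritParams step_resources
#' @param retarget recompute the searching-mode bias target from the
#'   current memory map; when FALSE a cached bias direction is reused
#'   (the simulator re-targets once per recorded step).
#' @return the state with updated position, heading and mode.
#' @export
step_movement <- function(state, params, dt = params$dt, retarget = TRUE) {
  nlog <- length(state$cons_log)
  if (nlog >= 2) {
    cur <- state$cons_log[nlog]
    avg <- (state$cons_sum %||% sum(state$cons_log)) / nlog
    state$mode <- if (cur < avg) 2L else 1L
  }
  if (state$mode == 1L) {
    state$heading <- wrap_angle(state$heading +
                                  stats::rnorm(1, 0, params$sd_feed * sqrt(dt)))
    v <- params$v_feed
  } else {
    if (retarget || is.null(state$bias_dir)) {
      d2 <- cell_dist2(state)
      w <- state$M * exp(-sqrt(d2) / params$gamma_z)
      i <- which.max(w)
      state$bias_dir <- atan2(state$cell_y[i] - state$y,
                              state$cell_x[i] - state$x)
    }
    bias <- state$bias_dir
    wp <- params$w_persist
    mu <- atan2(wp * sin(state$heading) + (1 - wp) * sin(bias),
                wp * cos(state$heading) + (1 - wp) * cos(bias))
    state$heading <- wrap_angle(mu +
                                  stats::rnorm(1, 0, params$sd_search * sqrt(dt)))
    v <- params$v_search
  }
  state$x <- state$x + v * dt * cos(state$heading)
  state$y <- state$y + v * dt * sin(state$heading)
  # reflective boundary
  if (state$x < 0 || state$x > state$n) {
    state$x <- reflect_into(state$x, state$n)
    state$heading <- wrap_angle(pi - state$heading)
  }
  if (state$y < 0 || state$y > state$n) {
    state$y <- reflect_into(state$y, state$n)
    state$heading <- wrap_angle(-state$heading)
  }
  state
}

#' Simulate a memory-based BCRW walker
#'
#' @param landscape a GRF \code{raster_grid} from
#'   \code{\link{make_grf_landscape}}.
#' @param params \code{bcrw_params}.
#' @param n_steps recorded steps (default 500); each recorded step is
#'   \code{1/params$dt} Euler substeps.
#' @param id individual id.
#' @param seed RNG seed.
#' @return list of class \code{bcrw_simulation}: \code{trajectory} (fix
#'   table), \code{states} (per step \code{start_time} and
#'   \code{true_state}: 1 feeding/encamped, 2 searching/travelling),
#'   \code{final} (the final walker state with Q/L/S/M fields),
#'   \code{params}.
#' @export
simulate_bcrw <- function(landscape, params = bcrw_params(),
                          n_steps = 500, id = "bcrw1", seed = NULL) {
  run_manifest("simulate_bcrw", seed, list(n_steps = n_steps))
  with_seed(seed, {
    st <- bcrw_init(landscape, params)
    nsub <- round(1 / params$dt)
    xs <- ys <- numeric(n_steps + 1)
    xs[1] <- st$x; ys[1] <- st$y
    mode <- integer(n_steps)
    for (i in seq_len(n_steps)) {
      mode[i] <- st$mode
      for (s in seq_len(nsub)) {
        st <- step_resources(st, params)
        st <- step_memory(st, params)
        st <- step_movement(st, params, retarget = s == 1)
      }
      xs[i + 1] <- st$x; ys[i + 1] <- st$y
    }
    out <- list(trajectory = data.frame(id = id, time = 0:n_steps,
                                        x = xs, y = ys,
                                        stringsAsFactors = FALSE),
                states = data.frame(start_time = 0:(n_steps - 1),
                                    true_state = mode),
                final = st, params = params)
    class(out) <- "bcrw_simulation"
    out
  })
}

#' Distance-to-patch raster for a GRF landscape
#'
#' Defines "resource patches" as the cells above a quality quantile and
#' returns the Euclidean distance (cell units) from every cell centre to
#' the nearest patch cell centre.
#'
#' @param landscape a quality \code{raster_grid}.
#' @param threshold_quantile quantile of positive cell values defining a
#'   patch cell (default 0.9).
#' @return a \code{raster_grid} named "dist_patch".
#' @export
distance_to_patches_raster <- function(landscape, threshold_quantile = 0.9) {
  v <- landscape$values
  thr <- stats::quantile(v[v > 0], threshold_quantile)
  patch <- which(v >= thr, arr.ind = TRUE)
  n <- nrow(v)
  ctr <- landscape$cell_size
  py <- (patch[, 1] - 0.5) * ctr + landscape$origin[2]
  px <- (patch[, 2] - 0.5) * ctr + landscape$origin[1]
  cy <- matrix(rep((seq_len(n) - 0.5) * ctr + landscape$origin[2],
                   ncol(v)), n, ncol(v))
  cx <- matrix(rep((seq_len(ncol(v)) - 0.5) * ctr + landscape$origin[1],
                   each = n), n, ncol(v))
  dmin <- matrix(Inf, n, ncol(v))
  for (j in seq_along(px))
    dmin <- pmin(dmin, (cx - px[j])^2 + (cy - py[j])^2)
  raster_grid(sqrt(dmin), origin = landscape$origin,
              cell_size = landscape$cell_size, name = "dist_patch")
}
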