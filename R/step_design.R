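# Discrete-choice design: one stratum per observed step, holding the
# observed step plus J random alternative steps sharing the same start
# point, and the covariate matrix over all candidates.
#
# Random steps use the uniform-in-distance convention: distance drawn
# Uniform(0, radius], angle Uniform(-pi, pi].  Under this availability
# convention a fit with covariates SL and log(SL) implies a gamma
# step-length distribution with mean (1 + b_logSL) / (-b_SL), which is
# the closed form used throughout for state speeds.

LOG_SL_FLOOR <- 1e-6  # km; step lengths floored here before log()

#' 99th percentile sampling radius
#'
#' Empirical 99th percentile (type-7 linear interpolation) of all
#' observed step lengths pooled over segments; the conventional choice
#' of radius for the random-step disk.
#'
#' @param traj segmented trajectory table (see
#'   \code{\link{segment_trajectories}}).
#' @param prob quantile level (default 0.99).
#' @return radius in km.
#' @export
radius_99 <- function(traj, prob = 0.99) {
  lens <- unlist(lapply(split_segments(traj), function(seg) {
    if (nrow(seg) < 2) return(numeric(0))
    sqrt(diff(seg$x)^2 + diff(seg$y)^2)
  }))
  if (!length(lens)) stop("no observed steps")
  unname(stats::quantile(lens, prob, type = 7))
}

#' Draw random steps and build choice strata
#'
#' For every observed step except the first of each segment (whose
#' turning angle is undefined), draws \code{J} random endpoints from the
#' disk of the given radius around the step's start point
#' (uniform-in-distance, uniform angle) and stores the observed endpoint
#' as candidate 0.
#'
#' @param traj segmented trajectory table.
#' @param J number of random steps per stratum (default 20).
#' @param radius disk radius in km.
#' @param seed RNG seed.
#' @return a long data.frame of class \code{ssf_strata}: columns
#'   \code{id}, \code{segment}, \code{stratum}, \code{time},
#'   \code{candidate} (0 = observed), \code{x_start}, \code{y_start},
#'   \code{prev_heading}, \code{x_end}, \code{y_end}.
#' @export
draw_random_steps <- function(traj, J = 20, radius, seed = NULL) {
  if (J < 1) stop("J must be >= 1")
  stopifnot(radius > 0)
  run_manifest("draw_random_steps", seed, list(J = J, radius = radius))
  with_seed(seed, {
    segs <- split_segments(traj)
    out <- vector("list", length(segs))
    stratum0 <- 0L
    for (si in seq_along(segs)) {
      seg <- segs[[si]]
      Fn <- nrow(seg)
      if (Fn < 3) next
      # steps t: fix t -> fix t+1, t = 2..Fn-1 (first step dropped)
      t_idx <- 2:(Fn - 1)
      n_str <- length(t_idx)
      head_prev <- atan2(seg$y[t_idx] - seg$y[t_idx - 1],
                         seg$x[t_idx] - seg$x[t_idx - 1])
      d <- stats::runif(n_str * J, 0, radius)
      a <- stats::runif(n_str * J, -pi, pi)
      xs <- rep(seg$x[t_idx], each = J + 1)
      ys <- rep(seg$y[t_idx], each = J + 1)
      xe <- ye <- numeric(n_str * (J + 1))
      obs <- rep(c(TRUE, rep(FALSE, J)), n_str)
      xe[obs] <- seg$x[t_idx + 1]
      ye[obs] <- seg$y[t_idx + 1]
      st <- rep(seg$x[t_idx], each = J)
      xe[!obs] <- st + d * cos(a)
      ye[!obs] <- rep(seg$y[t_idx], each = J) + d * sin(a)
      out[[si]] <- data.frame(
        id = seg$id[1], segment = seg$segment[1],
        stratum = stratum0 + rep(seq_len(n_str), each = J + 1),
        time = rep(seg$time[t_idx], each = J + 1),
        candidate = rep(0:J, n_str),
        x_start = xs, y_start = ys,
        prev_heading = rep(head_prev, each = J + 1),
        x_end = xe, y_end = ye,
        stringsAsFactors = FALSE)
      stratum0 <- stratum0 + n_str
    }
    out <- do.call(rbind, out)
    if (is.null(out)) stop("no segment long enough to form strata")
    rownames(out) <- NULL
    structure(out, J = J, radius = radius, class = c("ssf_strata", "data.frame"))
  })
}

#' Define the covariate layout of a step-selection design
#'
#' Each argument is one covariate, in coefficient order.  Supported
#' types: \code{"cos_turn"} (cosine of the turning angle, directional
#' persistence), \code{"step_length"}, \code{"log_step_length"},
#' \code{"raster"} (value of a named raster at the candidate endpoint),
#' \code{"log_dist"} (log Euclidean distance from the endpoint to the
#' nearest of a set of feature points), \code{"dir_bias"} (cosine of the
#' difference between the step heading and the heading to a target).
#'
#' @param ... covariate definitions, each a list with elements
#'   \code{name}, \code{type}, and for rasters \code{raster} (raster
#'   name), for log-distances \code{points} (2-column matrix of feature
#'   coordinates).
#' @return a \code{covariate_spec} object.
#' @export
covariate_spec <- function(...) {
  defs <- list(...)
  nm <- vapply(defs, function(d) d$name, "")
  if (anyDuplicated(nm)) stop("covariate names must be unique")
  ok <- c("cos_turn", "step_length", "log_step_length", "raster",
          "log_dist", "dir_bias")
  for (d in defs) if (!d$type %in% ok) stop("unknown covariate type ", d$type)
  structure(defs, class = "covariate_spec", names = nm)
}

#' The standard movement covariate layout
#'
#' cos(turning angle), step length, log step length, then optionally a
#' habitat-quality raster and a directional-bias-to-target term — the
#' layout of the simulation scenarios.
#'
#' @param quality name of the habitat quality raster (NULL to omit).
#' @param with_target include a directional-bias covariate.
#' @return a \code{covariate_spec}.
#' @export
movement_spec <- function(quality = "quality", with_target = FALSE) {
  defs <- list(list(name = "cos_dp", type = "cos_turn"),
               list(name = "sl", type = "step_length"),
               list(name = "log_sl", type = "log_step_length"))
  if (!is.null(quality))
    defs <- c(defs, list(list(name = "quality", type = "raster",
                              raster = quality)))
  if (with_target)
    defs <- c(defs, list(list(name = "cos_target", type = "dir_bias")))
  do.call(covariate_spec, defs)
}

#' Fill covariates into choice strata
#'
#' Computes every covariate of the layout for all candidates.  Strata in
#' which any candidate endpoint falls outside a needed raster are
#' dropped (counted in attribute \code{n_dropped_strata}).
#'
#' @param strata an \code{ssf_strata} table from
#'   \code{\link{draw_random_steps}}.
#' @param spec a \code{covariate_spec}.
#' @param rasters named list of \code{raster_grid} objects.
#' @param target optional length-2 (x, y) target for \code{dir_bias}.
#' @return the strata table with one numeric column per covariate;
#'   attribute \code{covariates} holds the coefficient order.
#' @export
build_covariates <- function(strata, spec, rasters = list(), target = NULL) {
  dx <- strata$x_end - strata$x_start
  dy <- strata$y_end - strata$y_start
  sl <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  drop <- rep(FALSE, nrow(strata))
  for (d in spec) {
    v <- switch(d$type,
      cos_turn = cos(ang - strata$prev_heading),
      step_length = sl,
      log_step_length = log(pmax(sl, LOG_SL_FLOOR)),
      raster = {
        g <- rasters[[d$raster]]
        if (is.null(g)) stop("raster '", d$raster, "' not supplied")
        extract_raster(g, strata$x_end, strata$y_end, outside = "na")
      },
      log_dist = {
        pts <- d$points
        dmin <- apply(pts, 1, function(p)
          (strata$x_end - p[1])^2 + (strata$y_end - p[2])^2)
        log(pmax(sqrt(do.call(pmin, as.data.frame(dmin))), LOG_SL_FLOOR))
      },
      dir_bias = {
        if (is.null(target)) stop("dir_bias covariate needs a target")
        cos(atan2(target[2] - strata$y_start,
                  target[1] - strata$x_start) - ang)
      })
    drop <- drop | !is.finite(v) & !is.na(v)
    strata[[d$name]] <- v
  }
  miss <- rowSums(is.na(strata[, names(spec), drop = FALSE])) > 0
  bad_strata <- unique(strata$stratum[miss | drop])
  if (length(bad_strata)) {
    strata <- strata[!strata$stratum %in% bad_strata, , drop = FALSE]
    if (!nrow(strata)) stop("all strata dropped (off-raster candidates)")
  }
  attr(strata, "covariates") <- names(spec)
  attr(strata, "n_dropped_strata") <- length(bad_strata)
  class(strata) <- c("ssf_strata", "data.frame")
  strata
}

# Compile a covariate-filled strata table into the dense form the
# likelihood consumes: X is ((J+1) x n_strata) x q, candidate-major with
# the observed step first in each stratum.
strata_design <- function(strata, covariates = attr(strata, "covariates")) {
  if (is.null(covariates)) stop("strata have no covariates; run build_covariates()")
  o <- order(strata$stratum, strata$candidate)
  strata <- strata[o, , drop = FALSE]
  cnt <- table(strata$stratum)
  if (length(unique(cnt)) != 1)
    stop("unequal candidate counts across strata")
  Jp1 <- unname(cnt[1])
  first <- !duplicated(strata$stratum)
  list(X = as.matrix(strata[, covariates, drop = FALSE]),
       Jp1 = Jp1,
       n = length(cnt),
       covariates = covariates,
       group = strata$segment[first],
       id = strata$id[first],
       time = strata$time[first],
       stratum = strata$stratum[first])
}

#' Serialize strata to CSV
#'
#' Long format: stratum, candidate index, is_observed flag, endpoint and
#' covariate columns.
#'
#' @param strata covariate-filled strata.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_strata <- function(strata, path) {
  df <- as.data.frame(strata)
  df$is_observed <- as.integer(df$candidate == 0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
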