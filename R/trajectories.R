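# Trajectory I/O and gap-aware segmentation.
#
# A trajectory table has one row per GPS fix: columns id, time, x, y with
# planar projected coordinates in km.  Segmentation cuts each individual's
# fix series wherever the sampling interval deviates from the nominal one,
# yielding "segments" of regularly spaced fixes; the model later treats
# segments as independent blocks of the likelihood.

#' Read trajectories from CSV and segment them
#'
#' Reads a fix table (columns \code{id}, \code{time}, \code{x}, \code{y};
#' \code{time} either ISO-8601 timestamps or a numeric index in hours),
#' sorts fixes within individuals, and splits each individual's series
#' into segments of (approximately) regular sampling: a new segment
#' starts wherever the time gap deviates from \code{nominal_interval} by
#' more than \code{tolerance_frac * nominal_interval}.  Segments with
#' fewer than \code{min_fixes} fixes are dropped and counted.
#'
#' @param path CSV file path, or a data.frame already in fix-table form.
#' @param nominal_interval nominal sampling interval in hours.
#' @param tolerance_frac allowed proportional deviation of a gap from the
#'   nominal interval (default 0.10).
#' @param min_fixes minimum number of fixes for a segment to be kept
#'   (default 3: a turning angle needs two preceding fixes).
#' @return a data.frame with columns \code{id}, \code{time} (hours,
#'   numeric), \code{x}, \code{y}, \code{segment} (id-unique segment
#'   label) and, when timestamps were supplied, \code{clock} (POSIXct).
#'   Attributes: \code{n_dropped_segments}, \code{n_dropped_fixes},
#'   \code{nominal_interval}.
#' @export
read_trajectories <- function(path, nominal_interval = 1,
                              tolerance_frac = 0.1, min_fixes = 3) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns id, time, x, y; missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  clock <- NULL
  if (!is.numeric(df$time)) {
    clock <- as.POSIXct(df$time, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                       "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    if (anyNA(clock)) stop("unparseable timestamps in column 'time'")
    df$clock <- clock
    df$time <- as.numeric(difftime(clock, min(clock), units = "hours"))
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("non-finite coordinates")
  df <- df[order(df$id, df$time), , drop = FALSE]
  # strictly increasing times within individuals
  for (ind in unique(df$id)) {
    tt <- df$time[df$id == ind]
    if (any(diff(tt) <= 0))
      stop("non-monotone or duplicated times within individual ", ind)
  }
  segment_trajectories(df, nominal_interval, tolerance_frac, min_fixes)
}

#' Segment an already-read trajectory table
#'
#' @inheritParams read_trajectories
#' @param df fix table with columns id, time (hours), x, y.
#' @return see \code{\link{read_trajectories}}.
#' @export
segment_trajectories <- function(df, nominal_interval = 1,
                                 tolerance_frac = 0.1, min_fixes = 3) {
  tol <- tolerance_frac * nominal_interval
  pieces <- list()
  n_drop_seg <- 0L; n_drop_fix <- 0L
  for (ind in unique(df$id)) {
    sub <- df[df$id == ind, , drop = FALSE]
    gaps <- diff(sub$time)
    newseg <- c(TRUE, abs(gaps - nominal_interval) > tol + 1e-12)
    segno <- cumsum(newseg)
    for (s in unique(segno)) {
      seg <- sub[segno == s, , drop = FALSE]
      if (nrow(seg) < min_fixes) {
        n_drop_seg <- n_drop_seg + 1L
        n_drop_fix <- n_drop_fix + nrow(seg)
        next
      }
      seg$segment <- paste0(ind, ".", s)
      pieces[[length(pieces) + 1]] <- seg
    }
  }
  if (!length(pieces))
    stop("no segment with >= ", min_fixes, " fixes survives segmentation")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "n_dropped_segments") <- n_drop_seg
  attr(out, "n_dropped_fixes") <- n_drop_fix
  attr(out, "nominal_interval") <- nominal_interval
  out
}

#' Write a trajectory table to CSV
#'
#' Writes columns id, time, x, y (plus segment if present); reading the
#' file back with \code{read_trajectories} reproduces the fix table.
#'
#' @param df trajectory table.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_trajectories <- function(df, path) {
  keep <- intersect(c("id", "time", "x", "y", "segment", "true_state"),
                    names(df))
  utils::write.csv(df[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Net squared displacement
#'
#' Squared Euclidean distance of every fix from the first fix of the
#' segment, in km^2; used to delineate migration phases.
#'
#' @param segment data.frame with columns x, y (one segment, ordered).
#' @return numeric vector, first element 0.
#' @export
nsd <- function(segment) {
  if (nrow(segment) == 0) stop("empty segment")
  (segment$x - segment$x[1])^2 + (segment$y - segment$y[1])^2
}

# split a segmented trajectory table into a list of segment data.frames
split_segments <- function(df) {
  if (is.null(df$segment)) df$segment <- paste0(df$id, ".1")
  split(df, df$segment, drop = TRUE)
}
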