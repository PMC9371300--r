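# Classify encamped -> travelling transitions from decoded state
# probabilities and relate them to covariates with a binomial mixed
# model (logit link, random intercept per individual, Laplace
# approximation via lme4), including the truncated predator-distance
# index and its threshold profile.

#' Classify transitions from state probabilities
#'
#' For consecutive strata (t, t+1) within a segment, with p_t the
#' predictive probability of the encamped state: Y = 1 (transition)
#' when p_t > threshold and p_{t+1} <= 1 - threshold; Y = 0
#' (non-transition) when both exceed the threshold; pairs matching
#' neither rule are discarded (counted in attribute
#' \code{n_discarded}).
#'
#' @param probs a \code{state_prob_series} (2 states).
#' @param p_threshold probability threshold in [0.5, 1).
#' @param encamped_state index of the encamped state (default 1).
#' @return data.frame with id, segment, time (of step t), Y; attribute
#'   \code{n_discarded}.
#' @export
classify_transitions <- function(probs, p_threshold = 0.5,
                                 encamped_state = 1) {
  if (p_threshold < 0.5 || p_threshold >= 1)
    stop("p_threshold must be in [0.5, 1)")
  p <- probs[[paste0("pred_", encamped_state)]]
  out <- NULL; n_disc <- 0L
  for (g in split(seq_len(nrow(probs)), probs$segment)) {
    if (length(g) < 2) next
    t1 <- g[-length(g)]; t2 <- g[-1]
    is_enc <- p[t1] > p_threshold
    trans <- is_enc & (p[t2] <= 1 - p_threshold)
    stay <- is_enc & (p[t2] > p_threshold)
    keep <- trans | stay
    n_disc <- n_disc + sum(!keep)
    if (!any(keep)) next
    out <- rbind(out, data.frame(id = probs$id[t1][keep],
                                 segment = probs$segment[t1][keep],
                                 time = probs$time[t1][keep],
                                 Y = as.integer(trans[keep])))
  }
  if (is.null(out)) out <- data.frame(id = character(0),
                                      segment = character(0),
                                      time = numeric(0), Y = integer(0))
  attr(out, "n_discarded") <- n_disc
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Truncated distance index
#'
#' min(d, d_threshold): the predator only matters within the threshold.
#'
#' @param d distances (km, >= 0).
#' @param d_threshold truncation distance (km, > 0).
#' @return truncated distances.
#' @export
truncate_distance <- function(d, d_threshold) {
  stopifnot(d_threshold > 0, all(d >= 0, na.rm = TRUE))
  pmin(d, d_threshold)
}

#' Day period factor
#'
#' Three-level partition of the clock hour: dawn-dusk (03:00-06:59 and
#' 16:00-21:59), day (07:00-15:59), night (22:00-02:59).
#'
#' @param hour_of_day numeric hours in [0, 24).
#' @param levels4 use the 4-level variant (night/dawn/day/dusk) instead.
#' @return a factor with reference level "day".
#' @export
day_period <- function(hour_of_day, levels4 = FALSE) {
  h <- hour_of_day %% 24
  if (levels4) {
    out <- ifelse(h >= 22 | h < 3, "night",
                  ifelse(h < 7, "dawn", ifelse(h < 16, "day", "dusk")))
    return(factor(out, levels = c("day", "dawn", "dusk", "night")))
  }
  out <- ifelse((h >= 3 & h < 7) | (h >= 16 & h < 22), "dawn_dusk",
                ifelse(h >= 7 & h < 16, "day", "night"))
  factor(out, levels = c("day", "dawn_dusk", "night"))
}

#' Fit the binomial transition model
#'
#' Logit-link binomial mixed model with a scalar random intercept per
#' individual (Laplace approximation).  The default formula covers the
#' predator analysis (day period, in-patch flag, predator utilization
#' and truncated distance with interaction); any formula over the
#' supplied record columns may be given.
#'
#' @param records data.frame of transition records: Y plus covariates
#'   and an \code{id} column.
#' @param formula model formula (random intercept added automatically if
#'   absent).
#' @return list with \code{coefficients} (estimate, se, lower, upper),
#'   \code{ranef_variance}, \code{loglik} and the fitted \code{model}.
#' @export
fit_transition_model <- function(records,
                                 formula = Y ~ day_period + in_patch +
                                   ud + d_tilde + ud:d_tilde) {
  if (length(unique(records$Y)) < 2)
    stop("both transition and non-transition records are required")
  if (length(unique(records$id)) < 2)
    stop("at least 2 individuals are required for the random intercept")
  f <- stats::update(formula, . ~ . + (1 | id))
  m <- lme4::glmer(f, data = records, family = stats::binomial())
  co <- summary(m)$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    lower = co[, 1] - 1.96 * co[, 2],
                    upper = co[, 1] + 1.96 * co[, 2], row.names = NULL)
  list(coefficients = out,
       ranef_variance = unname(lme4::VarCorr(m)$id[1]),
       loglik = as.numeric(stats::logLik(m)),
       model = m)
}

#' Profile the distance-truncation threshold
#'
#' Refits the transition model over a grid of \code{d_threshold} values
#' (the raw distance column is re-truncated each time) and returns the
#' profile of the model log-likelihood with its maximizer.
#'
#' @param records transition records including a raw distance column
#'   \code{d_pred} (km).
#' @param grid threshold grid in km (default 50 values on [0.1, 5]).
#' @param formula passed to \code{\link{fit_transition_model}}; must use
#'   \code{d_tilde}.
#' @return list with \code{d_star} (argmax), \code{profile}
#'   (data.frame d_threshold, loglik).
#' @export
profile_d_threshold <- function(records,
                                grid = seq(0.1, 5, length.out = 50),
                                formula = Y ~ in_patch + d_tilde) {
  ll <- vapply(grid, function(dthr) {
    records$d_tilde <- truncate_distance(records$d_pred, dthr)
    fit <- tryCatch(fit_transition_model(records, formula),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$loglik
  }, 0)
  prof <- data.frame(d_threshold = grid, loglik = ll)
  list(d_star = grid[which.max(ll)], profile = prof)
}

#' Build transition records from a predator-scenario simulation
#'
#' Joins classified transitions with the simulation's covariates at the
#' end-of-step-t location: patch quality / in-patch flag and the
#' prey-predator distance.
#'
#' @param sim an \code{ssf_simulation} from the predator scenario.
#' @param probs the \code{state_prob_series} of the fitted HMM-SSF.
#' @param landscape the \code{patch_landscape} used in the simulation.
#' @param p_threshold classification threshold.
#' @return transition records with columns Y, in_patch, quality, d_pred.
#' @export
transition_records_sim <- function(sim, probs, landscape,
                                   p_threshold = 0.5) {
  rec <- classify_transitions(probs, p_threshold)
  if (!nrow(rec)) return(rec)
  # end of step t = fix at time t+1 (fix tables are indexed by time)
  tr <- sim$trajectory
  i_end <- match(rec$time + 1, tr$time)
  L <- landscape$size
  q <- extract_raster(landscape$quality, pmin(tr$x[i_end], L - 1e-9),
                      pmin(tr$y[i_end], L - 1e-9), outside = "na")
  rec$quality <- ifelse(is.na(q), 0, q)
  rec$in_patch <- as.integer(rec$quality > 0)
  if (!is.null(sim$predator)) {
    ip <- match(rec$time + 1, sim$predator$time)
    rec$d_pred <- sqrt((tr$x[i_end] - sim$predator$x[ip])^2 +
                         (tr$y[i_end] - sim$predator$y[ip])^2)
  }
  rec
}
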