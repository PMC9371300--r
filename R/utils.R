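# Internal helpers shared across the package.

#' Wrap angles to (-pi, pi]
#'
#' Angles are radians measured counter-clockwise from the +x axis.
#'
#' @param theta numeric vector of angles (radians).
#' @return angles wrapped to the interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- theta %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  # %% can return exactly -pi via floating error; force half-open interval
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# log(sum(exp(x))) with max subtraction
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise max of a matrix without apply() (hot path).
col_max <- function(m) {
  m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
}

# Run expr with a temporary RNG seed; NULL seed leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a reproducible child seed from a base seed, kept below 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000003 + offset) %% 2147483629
}

#' Log a run manifest
#'
#' Records the seed and a hash of the configuration used by an
#' RNG-consuming operation, so that every stochastic run can be traced.
#'
#' @param operation name of the operation.
#' @param seed the seed used (may be NULL).
#' @param config a list of parameters; hashed into the manifest.
#' @param quiet suppress the message (manifest still returned).
#' @return invisibly, a list with operation, seed, config hash and time.
#' @export
run_manifest <- function(operation, seed = NULL, config = list(), quiet = TRUE) {
  hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  man <- list(operation = operation, seed = seed, config_hash = hash,
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!quiet)
    message(sprintf("[%s] seed=%s config_hash=%d", operation,
                    ifelse(is.null(seed), "NULL", seed), hash))
  invisible(man)
}
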