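# internal helpers shared across modules

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a sub-seed for a pipeline stage from the scene seed; keeps stages
# decoupled so re-running one stage does not perturb another's draws.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + (match(stage, c(
    "trajectories", "vocalizations", "render", "noise", "profiles",
    "stats")) * 7919L) %% 1000L
}

amp_to_db <- function(a, ref = 1) 20 * log10(pmax(a, .Machine$double.xmin) / ref)
db_to_amp <- function(db) 10^(db / 20)

# truncated-normal draw used for interval distributions (ms); lower bound
# keeps intervals physical
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  i <- 0L
  while (any(bad <- x < lower) && i < 100L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    i <- i + 1L
  }
  x[x < lower] <- lower
  x
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
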