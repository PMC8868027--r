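# RNG hygiene: run expr under a local seed without disturbing the
# caller's RNG stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Log-normal jitter with a given arithmetic mean and SD; degenerate to
# the mean when sd = 0. Used for positive-valued between-cell jitter.
rlnorm_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0) return(rep(mean, n))
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Linear interpolation of the time at which y crosses `level`
# between samples i and i+1.
cross_time <- function(t, y, i, level) {
  if (y[i + 1] == y[i]) return(t[i])
  t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}
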