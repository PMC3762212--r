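# Seed scoping: run code under a given seed, restoring the caller's RNG
# state afterwards so generator calls do not perturb the session stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normal draws truncated to (lo, hi] by resampling.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lo | x > hi)
    guard <- guard + 1
  }
  if (length(bad) > 0) x[bad] <- pmin(pmax(x[bad], lo + 1e-6), hi)
  x
}
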