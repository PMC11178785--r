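#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-track stream seeds derived from one root seed by a fixed counter scheme,
# so cohorts reproduce regardless of iteration order. Kept below 2^31 - 1.
derive_seed <- function(root_seed, counter) {
  as.integer((as.double(root_seed) * 48271 + as.double(counter) * 7919 + 12345) %%
               2147483629)
}

# Truncated normal sampler on (lo, hi] by rejection; sd = 0 degenerates to the
# (clamped) mean. Assumes non-vanishing mass in the interval for the
# parameter ranges used by the presets.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) {
    return(rep(min(max(mean, lo + .Machine$double.eps), hi), n))
  }
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("truncated-normal rejection sampler failed to converge; ",
           "check that [", lo, ", ", hi, "] has mass under N(", mean, ", ", sd, ")")
    }
    draw <- stats::rnorm(max(n * 2L, 16L), mean, sd)
    out <- c(out, draw[draw > lo & draw <= hi])
  }
  out[seq_len(n)]
}

# Centered moving average with partial windows at the ends (window must be odd).
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
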