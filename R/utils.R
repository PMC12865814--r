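# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive k reproducible child seeds below 2^31 from one parent seed
child_seeds <- function(seed, k) {
  with_seed(seed, sample.int(1073741823L, k)) # < 2^30, headroom for offsets
}

# mean of a gamma(shape, scale) truncated to [lo, hi]
trunc_gamma_mean <- function(shape, scale, lo, hi) {
  num <- pgamma(hi, shape + 1, scale = scale) -
    pgamma(lo, shape + 1, scale = scale)
  den <- pgamma(hi, shape, scale = scale) - pgamma(lo, shape, scale = scale)
  shape * scale * num / den
}

# gamma draws with the *truncated* mean calibrated to `mean`; shape fixed,
# scale solved by root finding, truncation to [lo, hi] by rejection
rtrunc_gamma <- function(n, mean, lo, hi, shape = 4) {
  stopifnot(mean > lo, mean < hi)
  f <- function(sc) trunc_gamma_mean(shape, sc, lo, hi) - mean
  sc0 <- mean / shape
  sc <- uniroot(f, lower = sc0 / 10, upper = sc0 * 10, tol = 1e-10)$root
  out <- numeric(0)
  while (length(out) < n) {
    x <- rgamma(2L * (n - length(out)) + 10L, shape, scale = sc)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# normal draws truncated to [lo, hi] by rejection
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}
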