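# Internal utilities shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps every generator a pure function
# of (config, seed) without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

# Draws from N(mu, Sigma) via Cholesky; Sigma symmetrized and jittered.
rmvnorm_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  S <- (Sigma + t(Sigma)) / 2
  L <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-8, p)))
  matrix(stats::rnorm(n * p), n, p) %*% L + rep(mu, each = n)
}

# Highest posterior density interval of a draw vector: the narrowest
# interval containing `prob` of the sorted draws.
hpdi <- function(draws, prob) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# Runs of TRUE in a logical vector, as a list of index vectors.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) starts[k]:ends[k])
}

# Cheap stable hash of an R object (for config content-addressing).
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  bytes <- as.integer(bytes[-seq_len(14L)])  # drop header (R version stamp)
  h <- 0
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 512))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
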