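# Internal helpers shared across modules.

# Deterministically derive a per-stage seed from a master seed and a label.
# Polynomial string hash folded into [0, 2^31 - 2]; keeps independent stages
# on distinct, reproducible RNG streams.
stage_seed <- function(master, label) {
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Column-wise sd of a matrix with denominator n - 1, without apply overhead.
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt((colSums(X^2) - n * mu^2) / (n - 1))
}

# Polynomial rolling hash of a configuration list (over its canonical
# deparse), reported in pipeline manifests so outputs can be tied to the
# exact parameter set that produced them.  Two lanes with different odd
# multipliers give 64 hex-digit-worth of collision resistance, plenty for
# provenance bookkeeping.
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg, control = c("keepNA", "niceNames")), collapse = "")
  h1 <- 0; h2 <- 5381
  for (code in utf8ToInt(txt)) {
    h1 <- (h1 * 131 + code) %% 2147483647
    h2 <- (h2 * 33 + code) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)))
  invisible(x)
}
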