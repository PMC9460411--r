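# Internal helpers shared across the package.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is restored afterwards so seeded helpers leave no trace.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a named substream seed from a master seed; keeps results reproducible
# from the master seed alone while decoupling the random streams of the
# different generator stages. Stays within 32-bit integer range.
substream_seed <- function(master_seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master_seed) * 7919 + h * 131 + index) %% 2147483587)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Pairwise Euclidean distances between rows of a (n x d) and b (m x d).
cross_dist <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
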