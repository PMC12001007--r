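## split-chain convergence diagnostic (potential scale reduction factor):
## each chain is split in half and the usual between/within variance ratio
## is computed over the resulting 2C half-chains
.split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## deterministic sub-seed per table so each generator can be re-run
## independently of the others (master seed + fixed table offset)
.sub_seed <- function(seed, offset) (seed + offset) %% .Machine$integer.max
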