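# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable log(1 + exp(x)), elementwise.
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "boltzgen_error")))
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stopf("`%s` must be a single integer >= %d", name, min,
          class = "boltzgen_validation_error")
  }
  as.integer(x)
}

# Deterministic per-task seed derivation; stays below 2^31 - 1.
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 1009 + 7919 * as.double(offset)) %% 2147483647)
}

# All 2^n binary configurations as a (2^n x n) matrix; n <= ~20.
all_binary_configs <- function(n) {
  if (n == 0L) return(matrix(0, nrow = 1L, ncol = 0L))
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(m) <- NULL
  m
}

# Draw a binary matrix with entrywise success probabilities `p` (matrix).
draw_bernoulli <- function(p) {
  (matrix(stats::runif(length(p)), nrow = nrow(p)) < p) * 1
}
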