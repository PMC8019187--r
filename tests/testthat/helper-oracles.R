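# Brute-force oracles and fixtures. The oracles work directly from the
# parameter arrays via the energy definition, independently of the package's
# computational shortcuts (analytic hidden-sum collapse, block Gibbs, AIS).

random_rbm <- function(n_visible, n_hidden, sd = 0.5, seed = 1) {
  withr::with_seed(seed, rbm(
    matrix(rnorm(n_visible * n_hidden, sd = sd), n_visible, n_hidden),
    rnorm(n_visible, sd = sd), rnorm(n_hidden, sd = sd)))
}

random_dbm <- function(sizes, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    weights <- lapply(seq_len(length(sizes) - 1L), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sd), sizes[l], sizes[l + 1L])
    })
    biases <- lapply(sizes, function(k) rnorm(k, sd = sd))
    dbm(weights, biases)
  })
}

zero_rbm <- function(n_visible, n_hidden) {
  rbm(matrix(0, n_visible, n_hidden), numeric(n_visible), numeric(n_hidden))
}

zero_dbm <- function(sizes) {
  dbm(lapply(seq_len(length(sizes) - 1L), function(l) {
    matrix(0, sizes[l], sizes[l + 1L])
  }), lapply(sizes, numeric))
}

binary_grid <- function(n) {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(m) <- NULL
  m
}

# Full-state enumeration of the RBM joint from the raw energy formula.
oracle_rbm_joint <- function(m) {
  vs <- binary_grid(nrow(m$weights))
  hs <- binary_grid(ncol(m$weights))
  loge <- matrix(NA_real_, nrow(vs), nrow(hs))
  for (i in seq_len(nrow(vs))) {
    for (j in seq_len(nrow(hs))) {
      v <- vs[i, ]; h <- hs[j, ]
      loge[i, j] <- as.numeric(v %*% m$weights %*% h) +
        sum(m$visible_bias * v) + sum(m$hidden_bias * h)
    }
  }
  z <- sum(exp(loge))
  list(vs = vs, hs = hs, probs = exp(loge) / z, log_z = log(z))
}

# Full-state enumeration of the layered DBM joint.
oracle_dbm_joint <- function(m) {
  sizes <- vapply(m$biases, length, integer(1))
  grids <- lapply(sizes, binary_grid)
  idx <- expand.grid(lapply(grids, function(g) seq_len(nrow(g))))
  loge <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    states <- lapply(seq_along(grids), function(l) grids[[l]][idx[r, l], ])
    e <- 0
    for (l in seq_along(m$layer_weights)) {
      e <- e + as.numeric(states[[l]] %*% m$layer_weights[[l]] %*% states[[l + 1L]])
    }
    for (l in seq_along(states)) e <- e + sum(states[[l]] * m$biases[[l]])
    loge[r] <- e
  }
  z <- sum(exp(loge))
  list(idx = idx, grids = grids, probs = exp(loge) / z, log_z = log(z))
}

# Marginal p(v) of an RBM from the enumerated joint.
oracle_rbm_marginal_v <- function(m) {
  joint <- oracle_rbm_joint(m)
  rowSums(joint$probs)
}

# Marginal p(v) of a DBM from the enumerated joint.
oracle_dbm_marginal_v <- function(m) {
  joint <- oracle_dbm_joint(m)
  nv <- length(m$biases[[1L]])
  vs <- binary_grid(nv)
  p <- numeric(nrow(vs))
  for (r in seq_len(nrow(joint$idx))) {
    p[joint$idx[r, 1L]] <- p[joint$idx[r, 1L]] + joint$probs[r]
  }
  list(vs = vs, p = p)
}

# Blocked fixture an RBM can learn: two complementary half-active patterns
# plus flip noise.
blocked_data <- function(n = 120, n_variables = 8, flip = 0.05, seed = 1) {
  withr::with_seed(seed, {
    half <- n_variables %/% 2
    base <- rbind(c(rep(1, half), rep(0, n_variables - half)),
                  c(rep(0, half), rep(1, n_variables - half)))
    x <- base[sample(1:2, n, replace = TRUE), ]
    flips <- matrix(runif(length(x)) < flip, nrow(x))
    binary_dataset(abs(x - flips))
  })
}

point_mass_data <- function(n = 200, n_variables = 6) {
  binary_dataset(matrix(1, n, n_variables))
}

# Empirical distribution of rows over the 2^k state space.
empirical_state_probs <- function(values) {
  keys <- apply(values, 1L, paste, collapse = "")
  grid <- binary_grid(ncol(values))
  all_keys <- apply(grid, 1L, paste, collapse = "")
  counts <- table(factor(keys, levels = all_keys))
  as.numeric(counts) / nrow(values)
}

# Seed whose random 2-variable order is the identity (for MICE recovery).
identity_order_seed <- function(n_vars) {
  for (s in 1:50) {
    if (identical(withr::with_seed(s, sample.int(n_vars)), seq_len(n_vars))) {
      return(s)
    }
  }
  stop("no identity-order seed found in 1..50")
}
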