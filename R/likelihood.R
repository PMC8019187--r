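#' Annealed importance sampling configuration
#'
#' @param n_temperatures number of inverse temperatures on the annealing
#'   path (equally spaced in `[0, 1]`, applied to the weights), at least 2.
#' @param n_particles number of independent AIS particles.
#' @param seed integer RNG seed.
#' @return a list of class `ais_config`.
#' @export
ais_config <- function(n_temperatures = 100L, n_particles = 100L, seed = 1L) {
  structure(list(
    n_temperatures = check_count(n_temperatures, "n_temperatures", min = 2L),
    n_particles = check_count(n_particles, "n_particles"),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "ais_config")
}

likelihood_estimate <- function(value, std_error, method) {
  structure(list(value = value, std_error = std_error, method = method),
            class = "likelihood_estimate")
}

#' @export
print.likelihood_estimate <- function(x, ...) {
  cat(sprintf("<likelihood_estimate (%s): %.4f (se %.4g)>\n",
              x$method, x$value, x$std_error))
  invisible(x)
}

# log-mean-exp of particle log-weights plus a delta-method standard error
# of the log of the mean on the ratio scale.
log_mean_weights <- function(logw) {
  n <- length(logw)
  m <- max(logw)
  w <- exp(logw - m)
  est <- m + log(mean(w))
  se <- if (n > 1L) stats::sd(w) / (mean(w) * sqrt(n)) else Inf
  list(estimate = est, se = se)
}

#' Estimate a log partition function by annealed importance sampling
#'
#' Anneals from a base model with the target's biases but zero weights
#' (whose partition function is analytic) to the target along a geometric
#' path: `n_temperatures` equally spaced inverse temperatures scale the
#' weight matrices while the biases stay fixed. Particles are propagated by
#' one block-Gibbs transition per temperature; the estimate is the base
#' log partition function plus the log of the mean importance weight
#' (log-sum-exp stabilised). For DBMs the annealing state consists of the
#' even layers, with the odd layers summed out analytically.
#'
#' @param model an [rbm()] or [dbm()].
#' @param config an [ais_config()].
#' @return a `likelihood_estimate` with `method = "ais"`.
#' @export
ais_log_partition <- function(model, config = ais_config()) {
  UseMethod("ais_log_partition")
}

#' @export
ais_log_partition.rbm <- function(model, config = ais_config()) {
  stopifnot(inherits(config, "ais_config"))
  betas <- seq(0, 1, length.out = config$n_temperatures)
  a <- model$visible_bias
  b <- model$hidden_bias
  log_z0 <- sum(softplus(a)) + sum(softplus(b))
  res <- withr::with_seed(config$seed, {
    v <- draw_bernoulli(matrix(sigmoid(a), config$n_particles,
                               length(a), byrow = TRUE))
    logw <- numeric(config$n_particles)
    for (k in seq_len(length(betas) - 1L)) {
      logw <- logw + rbm_log_pstar(model, v, betas[k + 1L]) -
        rbm_log_pstar(model, v, betas[k])
      beta <- betas[k + 1L]
      h <- draw_bernoulli(sigmoid(sweep(v %*% model$weights * beta, 2L, b, `+`)))
      v <- draw_bernoulli(sigmoid(sweep(tcrossprod(h, model$weights) * beta,
                                        2L, a, `+`)))
    }
    log_mean_weights(logw)
  })
  likelihood_estimate(log_z0 + res$estimate, res$se, "ais")
}

#' @export
ais_log_partition.dbm <- function(model, config = ais_config()) {
  stopifnot(inherits(config, "ais_config"))
  betas <- seq(0, 1, length.out = config$n_temperatures)
  sizes <- dbm_layer_sizes(model)
  log_z0 <- sum(vapply(model$biases, function(b) sum(softplus(b)), numeric(1)))
  even_idx <- seq(0L, length(sizes) - 1L, by = 2L)  # 0-based layer indices
  res <- withr::with_seed(config$seed, {
    states <- lapply(seq_along(sizes), function(i) {
      p <- sigmoid(model$biases[[i]])
      draw_bernoulli(matrix(p, config$n_particles, sizes[i], byrow = TRUE))
    })
    logw <- numeric(config$n_particles)
    for (k in seq_len(length(betas) - 1L)) {
      logw <- logw + dbm_log_pstar_even(model, states, betas[k + 1L]) -
        dbm_log_pstar_even(model, states, betas[k])
      states <- dbm_gibbs_sweep(scale_dbm_weights(model, betas[k + 1L]), states)
    }
    log_mean_weights(logw)
  })
  likelihood_estimate(log_z0 + res$estimate, res$se, "ais")
}

scale_dbm_weights <- function(model, beta) {
  model$layer_weights <- lapply(model$layer_weights, function(w) w * beta)
  model
}

# Unnormalized log-probability of the even layers of a DBM with the odd
# layers summed out analytically; `states` is the full layer-state list but
# only even entries are read. Weights are scaled by `beta`, biases are not.
dbm_log_pstar_even <- function(model, states, beta = 1) {
  n_layers <- length(model$layer_weights)
  n <- nrow(states[[1L]])
  out <- numeric(n)
  for (l in seq(0L, n_layers, by = 2L)) {
    out <- out + as.numeric(states[[l + 1L]] %*% model$biases[[l + 1L]])
  }
  for (l in seq(1L, n_layers, by = 2L)) {
    input <- states[[l]] %*% model$layer_weights[[l]] * beta
    if (l < n_layers) {
      input <- input +
        tcrossprod(states[[l + 2L]], model$layer_weights[[l + 1L]]) * beta
    }
    out <- out + rowSums(softplus(sweep(input, 2L, model$biases[[l + 1L]], `+`)))
  }
  out
}

#' Estimated log-likelihood of an RBM
#'
#' Estimates the partition function with AIS and combines it with the
#' analytic per-sample free energy: the mean log-likelihood is
#' \eqn{\mathrm{mean}_v[-F(v)] - \log \hat{Z}}.
#'
#' @param rbm an [rbm()].
#' @param data a [binary_dataset()].
#' @param config an [ais_config()].
#' @return a `likelihood_estimate` (mean log-likelihood per sample, nats).
#' @export
rbm_loglikelihood <- function(rbm, data, config = ais_config()) {
  stopifnot(inherits(rbm, "rbm"), inherits(data, "binary_dataset"))
  if (n_variables(data) != nrow(rbm$weights)) {
    stopf("data has %d variables but RBM has %d visible units",
          n_variables(data), nrow(rbm$weights),
          class = "boltzgen_validation_error")
  }
  z <- ais_log_partition(rbm, config)
  likelihood_estimate(mean(rbm_log_pstar(rbm, data$values)) - z$value,
                      z$std_error, "ais")
}

#' Estimated variational lower bound of a DBM's log-likelihood
#'
#' Per sample, the bound is the mean-field expected negative energy plus
#' the entropy of the factorised mean-field distribution, minus the AIS
#' estimate of `log Z`. This is the training objective of the fine-tuning
#' stage; for a zero-weight model the bound is exact.
#'
#' @param dbm a [dbm()].
#' @param data a [binary_dataset()].
#' @param config an [ais_config()].
#' @param mf_iters,mf_tol mean-field controls.
#' @return a `likelihood_estimate` (mean bound per sample, nats).
#' @export
dbm_logproblowerbound <- function(dbm, data, config = ais_config(),
                                  mf_iters = 10L, mf_tol = 1e-6) {
  stopifnot(inherits(dbm, "dbm"), inherits(data, "binary_dataset"))
  sizes <- dbm_layer_sizes(dbm)
  if (n_variables(data) != sizes[1L]) {
    stopf("data has %d variables but DBM visible layer has %d",
          n_variables(data), sizes[1L], class = "boltzgen_validation_error")
  }
  z <- ais_log_partition(dbm, config)
  v <- data$values
  mu <- mean_field_inference(dbm, v, mf_iters, mf_tol)
  layers <- c(list(v), mu)
  bound <- numeric(nrow(v))
  for (l in seq_along(dbm$layer_weights)) {
    bound <- bound +
      rowSums((layers[[l]] %*% dbm$layer_weights[[l]]) * layers[[l + 1L]])
  }
  for (l in seq_along(layers)) {
    bound <- bound + as.numeric(layers[[l]] %*% dbm$biases[[l]])
  }
  for (l in seq_along(mu)) {
    bound <- bound + rowSums(binary_entropy(mu[[l]]))
  }
  likelihood_estimate(mean(bound) - z$value, z$std_error, "ais")
}

binary_entropy <- function(p) {
  h <- matrix(0, nrow(p), ncol(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log(p[ok]) - (1 - p[ok]) * log(1 - p[ok])
  h
}

#' Estimated log-likelihood of a DBM
#'
#' Runs a separate clamped AIS pass for every sample: the visible layer is
#' held at the sample while the even hidden layers are annealed, giving an
#' estimate of the unnormalized marginal \eqn{\log p^*(v)}; the
#' log-likelihood is \eqn{\log p^*(v) - \log \hat{Z}} with \eqn{\hat{Z}}
#' from one full AIS run, averaged over samples.
#'
#' @param dbm a [dbm()].
#' @param data a [binary_dataset()].
#' @param config an [ais_config()]; the per-sample runs reuse its sizes.
#' @return a `likelihood_estimate` (mean log-likelihood per sample, nats).
#' @export
dbm_loglikelihood <- function(dbm, data, config = ais_config()) {
  stopifnot(inherits(dbm, "dbm"), inherits(data, "binary_dataset"))
  sizes <- dbm_layer_sizes(dbm)
  if (n_variables(data) != sizes[1L]) {
    stopf("data has %d variables but DBM visible layer has %d",
          n_variables(data), sizes[1L], class = "boltzgen_validation_error")
  }
  z <- ais_log_partition(dbm, config)
  n_layers <- length(dbm$layer_weights)
  betas <- seq(0, 1, length.out = config$n_temperatures)
  # base normalizer over hidden layers with v clamped, minus the a.v term
  log_h0 <- sum(vapply(dbm$biases[-1L], function(b) sum(softplus(b)), numeric(1)))
  vals <- numeric(n_samples(data))
  ses <- numeric(n_samples(data))
  for (i in seq_len(n_samples(data))) {
    v <- data$values[i, ]
    clamp <- list(idx = seq_along(v), values = v)
    res <- withr::with_seed(derive_seed(config$seed, i), {
      states <- lapply(seq_along(sizes), function(j) {
        if (j == 1L) {
          matrix(v, config$n_particles, sizes[1L], byrow = TRUE)
        } else {
          p <- sigmoid(dbm$biases[[j]])
          draw_bernoulli(matrix(p, config$n_particles, sizes[j], byrow = TRUE))
        }
      })
      logw <- numeric(config$n_particles)
      for (k in seq_len(length(betas) - 1L)) {
        logw <- logw + dbm_log_pstar_even(dbm, states, betas[k + 1L]) -
          dbm_log_pstar_even(dbm, states, betas[k])
        states <- dbm_gibbs_sweep(scale_dbm_weights(dbm, betas[k + 1L]),
                                  states, clamp = clamp)
      }
      log_mean_weights(logw)
    })
    vals[i] <- sum(v * dbm$biases[[1L]]) + log_h0 + res$estimate - z$value
    ses[i] <- res$se
  }
  se <- sqrt(z$std_error^2 + sum(ses^2) / length(ses)^2)
  likelihood_estimate(mean(vals), se, "ais")
}

#' Exact log-likelihood by enumeration
#'
#' Computes `log Z` and the per-sample unnormalized marginals exactly by
#' summing over all configurations (hidden sums collapsed analytically).
#' Exponential complexity, so only available below the unit cap.
#'
#' @param model an [rbm()] or [dbm()].
#' @param data a [binary_dataset()].
#' @param max_units cap on the total number of units (default 24).
#' @return a `likelihood_estimate` with `method = "exact"`, `std_error = 0`.
#' @export
exact_loglikelihood <- function(model, data, max_units = 24L) {
  UseMethod("exact_loglikelihood")
}

#' @export
exact_loglikelihood.rbm <- function(model, data, max_units = 24L) {
  stopifnot(inherits(data, "binary_dataset"))
  if (n_variables(data) != nrow(model$weights)) {
    stopf("data has %d variables but RBM has %d visible units",
          n_variables(data), nrow(model$weights),
          class = "boltzgen_validation_error")
  }
  log_z <- exact_log_partition(model, max_units)
  likelihood_estimate(mean(rbm_log_pstar(model, data$values)) - log_z,
                      0, "exact")
}

#' @export
exact_loglikelihood.dbm <- function(model, data, max_units = 24L) {
  stopifnot(inherits(data, "binary_dataset"))
  sizes <- dbm_layer_sizes(model)
  if (n_variables(data) != sizes[1L]) {
    stopf("data has %d variables but DBM visible layer has %d",
          n_variables(data), sizes[1L], class = "boltzgen_validation_error")
  }
  log_z <- exact_log_partition(model, max_units)
  vals <- vapply(seq_len(n_samples(data)), function(i) {
    dbm_log_pstar_visible(model, data$values[i, ])
  }, numeric(1))
  likelihood_estimate(mean(vals) - log_z, 0, "exact")
}

#' @export
exact_log_partition.dbm <- function(model, max_units = 24L) {
  sizes <- dbm_layer_sizes(model)
  if (sum(sizes) > max_units) {
    stopf("model has %d units, exceeding the cap of %d; use ais_log_partition()",
          sum(sizes), max_units, class = "boltzgen_size_error")
  }
  even <- seq(1L, length(sizes), by = 2L)  # list positions of even layers
  configs <- all_binary_configs(sum(sizes[even]))
  states <- split_even_configs(configs, sizes, even)
  logsumexp(dbm_log_pstar_even(model, states, 1))
}

# Exact unnormalized log p*(v): enumerate even hidden layers, odd collapsed.
dbm_log_pstar_visible <- function(model, v) {
  sizes <- dbm_layer_sizes(model)
  even_hidden <- seq(3L, length(sizes), by = 2L)  # list positions 3, 5, ...
  if (length(even_hidden) == 0L) {
    states <- list(matrix(v, nrow = 1L))
    return(dbm_log_pstar_even(model, states, 1))
  }
  configs <- all_binary_configs(sum(sizes[even_hidden]))
  states <- split_even_configs(configs, sizes, even_hidden)
  states[[1L]] <- matrix(v, nrow = nrow(configs), ncol = sizes[1L], byrow = TRUE)
  logsumexp(dbm_log_pstar_even(model, states, 1))
}

# Distribute enumerated columns of `configs` into a full layer-state list at
# the given (1-based) list positions.
split_even_configs <- function(configs, sizes, positions) {
  states <- vector("list", length(sizes))
  offset <- 0L
  for (pos in positions) {
    states[[pos]] <- configs[, offset + seq_len(sizes[pos]), drop = FALSE]
    offset <- offset + sizes[pos]
  }
  for (i in seq_along(states)) {
    if (is.null(states[[i]])) {
      states[[i]] <- matrix(0, nrow(configs), sizes[i])
    }
  }
  states
}
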