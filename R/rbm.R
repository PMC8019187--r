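#' Restricted Boltzmann machine parameters
#'
#' A binary--binary RBM over `n_visible` visible and `n_hidden` hidden units
#' with the bilinear energy
#' \deqn{E(v, h) = -v^\top W h - a^\top v - b^\top h,}
#' joint distribution \eqn{p(v, h) = e^{-E(v, h)} / Z} and partition
#' function \eqn{Z = \sum_{v, h} e^{-E(v, h)}}.
#'
#' @param weights `n_visible x n_hidden` matrix `W`.
#' @param visible_bias length-`n_visible` vector `a`.
#' @param hidden_bias length-`n_hidden` vector `b`.
#' @return an object of class `rbm`.
#' @export
rbm <- function(weights, visible_bias, hidden_bias) {
  weights <- as.matrix(weights)
  visible_bias <- as.numeric(visible_bias)
  hidden_bias <- as.numeric(hidden_bias)
  if (nrow(weights) != length(visible_bias) ||
      ncol(weights) != length(hidden_bias)) {
    stopf("inconsistent RBM dimensions: W is %dx%d, |a| = %d, |b| = %d",
          nrow(weights), ncol(weights), length(visible_bias),
          length(hidden_bias), class = "boltzgen_validation_error")
  }
  if (!all(is.finite(weights)) || !all(is.finite(visible_bias)) ||
      !all(is.finite(hidden_bias))) {
    stopf("RBM parameters must be finite", class = "boltzgen_validation_error")
  }
  structure(list(weights = weights, visible_bias = visible_bias,
                 hidden_bias = hidden_bias), class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm: %d visible x %d hidden>\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Training configuration for RBMs and DBMs
#'
#' Collects the hyperparameters governing pre-training (layer-wise
#' contrastive divergence) and fine-tuning (stochastic maximisation of the
#' variational lower bound). Defaults are the settings used throughout the
#' package's simulated SNP experiments: two hidden layers of 50 and 10
#' nodes, 30 epochs of pre-training at learning rate 0.001 and 30 epochs of
#' fine-tuning at learning rate 0.1.
#'
#' @param epochs fine-tuning (or standalone RBM training) epochs.
#' @param epochspretraining pre-training epochs per layer.
#' @param learningrate fine-tuning learning rate.
#' @param learningratepretraining pre-training learning rate.
#' @param nhiddens integer vector, hidden layer sizes (one entry per layer).
#' @param batchsizepretraining minibatch size for contrastive divergence.
#' @param batchsize minibatch size for fine-tuning.
#' @param cdsteps number of Gibbs steps `k` in CD-k.
#' @param seed integer RNG seed.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, epochspretraining = 30L,
                         learningrate = 0.1, learningratepretraining = 0.001,
                         nhiddens = c(50L, 10L), batchsizepretraining = 20L,
                         batchsize = 20L, cdsteps = 1L, seed = 1L) {
  cfg <- list(
    epochs = check_count(epochs, "epochs", min = 0L),
    epochspretraining = check_count(epochspretraining, "epochspretraining", min = 0L),
    learningrate = learningrate,
    learningratepretraining = learningratepretraining,
    nhiddens = vapply(nhiddens, check_count, integer(1), name = "nhiddens"),
    batchsizepretraining = check_count(batchsizepretraining, "batchsizepretraining"),
    batchsize = check_count(batchsize, "batchsize"),
    cdsteps = check_count(cdsteps, "cdsteps"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(learningrate) || learningrate <= 0 ||
      !is.numeric(learningratepretraining) || learningratepretraining <= 0) {
    stopf("learning rates must be positive", class = "boltzgen_validation_error")
  }
  structure(cfg, class = "train_config")
}

#' RBM energy function
#'
#' @param rbm an [rbm()].
#' @param v binary visible vector.
#' @param h binary hidden vector.
#' @return \eqn{E(v,h) = -v^\top W h - a^\top v - b^\top h}.
#' @export
energy <- function(rbm, v, h) {
  stopifnot(inherits(rbm, "rbm"))
  if (length(v) != nrow(rbm$weights) || length(h) != ncol(rbm$weights)) {
    stopf("state dimensions (%d, %d) do not match RBM (%d, %d)",
          length(v), length(h), nrow(rbm$weights), ncol(rbm$weights),
          class = "boltzgen_validation_error")
  }
  -as.numeric(v %*% rbm$weights %*% h) - sum(rbm$visible_bias * v) -
    sum(rbm$hidden_bias * h)
}

#' Conditional activation probabilities of one RBM layer given the other
#'
#' The bipartite structure of the RBM graph makes the conditional
#' distribution of each layer factorise: `hidden_conditional` returns
#' \eqn{p(h_j = 1 \mid v) = \sigma(b_j + \sum_i v_i W_{ij})} and
#' `visible_conditional` the mirror image
#' \eqn{p(v_i = 1 \mid h) = \sigma(a_i + \sum_j W_{ij} h_j)}. Inputs may be
#' binary states or mean activations in `[0, 1]` (as used when stacking
#' RBMs), and may be a single vector or a matrix with one state per row.
#'
#' @param rbm an [rbm()].
#' @param v,h state vector (or matrix of states, rows = samples).
#' @return probability vector (or matrix) for the opposite layer.
#' @export
hidden_conditional <- function(rbm, v) {
  stopifnot(inherits(rbm, "rbm"))
  v <- as_state_matrix(v, nrow(rbm$weights), "v")
  p <- sigmoid(sweep(v %*% rbm$weights, 2L, rbm$hidden_bias, `+`))
  drop_state(p)
}

#' @rdname hidden_conditional
#' @export
visible_conditional <- function(rbm, h) {
  stopifnot(inherits(rbm, "rbm"))
  h <- as_state_matrix(h, ncol(rbm$weights), "h")
  p <- sigmoid(sweep(tcrossprod(h, rbm$weights), 2L, rbm$visible_bias, `+`))
  drop_state(p)
}

as_state_matrix <- function(x, d, name) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != d) {
    stopf("`%s` has %d components, expected %d", name, ncol(x), d,
          class = "boltzgen_validation_error")
  }
  attr(x, "was_vector") <- nrow(x) == 1L
  x
}

drop_state <- function(p) if (nrow(p) == 1L) as.numeric(p) else p

# Contrastive-divergence workhorse shared by fit_rbm and pretrain_stack.
# `up_factor` / `down_factor` scale the weight term of the hidden / visible
# conditionals during training (the double-counting compensation used when a
# stack is assembled into a DBM). Plain SGD; weights ~ N(0, 0.01^2), biases 0.
# `callback(epoch, rbm)` is invoked after every epoch when supplied.
cd_train <- function(x, n_hidden, epochs, learningrate, batchsize, cdsteps,
                     up_factor = 1, down_factor = 1, callback = NULL) {
  n <- nrow(x)
  n_visible <- ncol(x)
  w <- matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden)
  a <- numeric(n_visible)
  b <- numeric(n_hidden)
  up <- function(v) sigmoid(sweep(v %*% w * up_factor, 2L, b, `+`))
  down <- function(h) sigmoid(sweep(tcrossprod(h, w) * down_factor, 2L, a, `+`))
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batchsize)
    for (s in starts) {
      idx <- ord[s:min(s + batchsize - 1L, n)]
      v0 <- x[idx, , drop = FALSE]
      m <- nrow(v0)
      h0_prob <- up(v0)
      hk <- draw_bernoulli(h0_prob)
      for (step in seq_len(cdsteps)) {
        vk <- draw_bernoulli(down(hk))
        hk_prob <- up(vk)
        if (step < cdsteps) hk <- draw_bernoulli(hk_prob)
      }
      w <- w + learningrate * (crossprod(v0, h0_prob) - crossprod(vk, hk_prob)) / m
      a <- a + learningrate * (colMeans(v0) - colMeans(vk))
      b <- b + learningrate * (colMeans(h0_prob) - colMeans(hk_prob))
    }
    if (!is.null(callback)) callback(epoch, rbm(w, a, b))
  }
  rbm(w, a, b)
}

#' Fit an RBM by contrastive divergence
#'
#' Stochastic gradient ascent on the CD-k approximation of the likelihood
#' gradient: per minibatch, the data-driven statistics
#' \eqn{\langle v h^\top\rangle, \langle v\rangle, \langle h\rangle}
#' (hidden units as probabilities) minus the corresponding statistics after
#' `k` alternating Gibbs steps. Deterministic given `config$seed`.
#'
#' @param data a [binary_dataset()].
#' @param config a [train_config()]; uses `epochs`, `learningrate`,
#'   `batchsizepretraining`, `cdsteps`, `seed` and the first entry of
#'   `nhiddens` as the hidden layer size.
#' @param monitor character vector of metrics to record once per epoch,
#'   from `reconstruction_error`, `exact_loglik`, `ais_loglik`. Empty by
#'   default (no monitoring).
#' @param monitor_data named list of `binary_dataset`s (typically
#'   `list(train = ..., test = ...)`) on which the metrics are evaluated;
#'   defaults to the training data.
#' @return a list with elements `rbm` (the fitted [rbm()]) and `monitoring`
#'   (a data frame with columns `epoch`, `metric`, `value`, `partition`).
#' @export
fit_rbm <- function(data, config = train_config(), monitor = character(),
                    monitor_data = NULL) {
  stopifnot(inherits(data, "binary_dataset"), inherits(config, "train_config"))
  if (n_samples(data) == 0L) {
    stopf("cannot fit an RBM on an empty dataset",
          class = "boltzgen_validation_error")
  }
  if (is.null(monitor_data)) monitor_data <- list(train = data)
  records <- monitoring_log()
  cb <- if (length(monitor) > 0L) {
    function(epoch, model) records$add(evaluate_rbm_metrics(
      model, epoch, monitor, monitor_data))
  }
  model <- withr::with_seed(config$seed,
    cd_train(data$values, config$nhiddens[1L], config$epochs,
             config$learningrate, config$batchsizepretraining,
             config$cdsteps, callback = cb))
  list(rbm = model, monitoring = records$table())
}

# Simple accumulator for per-epoch monitoring records.
monitoring_log <- function() {
  rows <- list()
  list(
    add = function(df) rows[[length(rows) + 1L]] <<- df,
    table = function() {
      if (length(rows) == 0L) {
        data.frame(epoch = integer(), metric = character(),
                   value = numeric(), partition = character())
      } else {
        do.call(rbind, rows)
      }
    }
  )
}

evaluate_rbm_metrics <- function(model, epoch, metrics, monitor_data) {
  out <- list()
  for (part in names(monitor_data)) {
    d <- monitor_data[[part]]
    for (m in metrics) {
      value <- switch(m,
        reconstruction_error = reconstruction_error(model, d),
        exact_loglik = exact_loglikelihood(model, d)$value,
        ais_loglik = rbm_loglikelihood(model, d)$value,
        stopf("unknown RBM monitoring metric '%s'", m,
              class = "boltzgen_validation_error"))
      out[[length(out) + 1L]] <- data.frame(
        epoch = epoch, metric = m, value = value, partition = part)
    }
  }
  do.call(rbind, out)
}

#' One-step reconstruction error
#'
#' Takes each sample as the visible activation, computes the hidden
#' activation probabilities conditioned on it and from those the visible
#' probabilities again; the reconstruction error is the mean (over samples)
#' squared Euclidean distance between each sample and its reconstruction.
#' It tracks the likelihood closely and is the standard cheap monitoring
#' quantity for contrastive-divergence training.
#'
#' @param rbm an [rbm()].
#' @param data a [binary_dataset()] with matching variables.
#' @return nonnegative scalar.
#' @export
reconstruction_error <- function(rbm, data) {
  stopifnot(inherits(rbm, "rbm"), inherits(data, "binary_dataset"))
  v <- data$values
  if (ncol(v) != nrow(rbm$weights)) {
    stopf("data has %d variables but RBM has %d visible units",
          ncol(v), nrow(rbm$weights), class = "boltzgen_validation_error")
  }
  recon <- visible_conditional(rbm, hidden_conditional(rbm, v))
  if (is.null(dim(recon))) recon <- matrix(recon, nrow = 1L)
  mean(rowSums((v - recon)^2))
}

#' Gibbs sampling from an RBM
#'
#' Runs independent alternating block-Gibbs chains (`h | v` then `v | h`)
#' for `burnin` steps per sample, starting from uniform random visible
#' states. Visible variables listed in `clamped` are reset to their fixed
#' value after every visible update (and at initialisation), which yields
#' samples from the conditional distribution given those variables.
#'
#' @param rbm an [rbm()].
#' @param n_samples number of samples (= independent chains).
#' @param burnin Gibbs sweeps per chain, at least 1.
#' @param clamped optional clamping map: a numeric vector of 0/1 values
#'   whose names are visible variable indices (e.g. `c("1" = 1)`), or a
#'   full-length vector with `NA` for free variables.
#' @param seed integer RNG seed.
#' @return a [binary_dataset()] of `n_samples` binary visible states.
#' @export
gibbs_sample <- function(rbm, n_samples, burnin = 50L, clamped = NULL,
                         seed = 1L) {
  stopifnot(inherits(rbm, "rbm"))
  n_samples <- check_count(n_samples, "n_samples")
  burnin <- check_count(burnin, "burnin")
  n_visible <- nrow(rbm$weights)
  cl <- resolve_clamped(clamped, n_visible)
  withr::with_seed(seed, {
    v <- matrix(stats::rbinom(n_samples * n_visible, 1L, 0.5),
                n_samples, n_visible)
    v <- apply_clamp(v, cl)
    for (step in seq_len(burnin)) {
      h <- draw_bernoulli(hidden_conditional_mat(rbm, v))
      v <- draw_bernoulli(visible_conditional_mat(rbm, h))
      v <- apply_clamp(v, cl)
    }
    binary_dataset(v)
  })
}

hidden_conditional_mat <- function(rbm, v) {
  sigmoid(sweep(v %*% rbm$weights, 2L, rbm$hidden_bias, `+`))
}

visible_conditional_mat <- function(rbm, h) {
  sigmoid(sweep(tcrossprod(h, rbm$weights), 2L, rbm$visible_bias, `+`))
}

# Normalize a clamping specification to list(idx =, values =).
resolve_clamped <- function(clamped, n_visible) {
  if (is.null(clamped)) return(NULL)
  if (is.null(names(clamped)) && length(clamped) == n_visible) {
    idx <- which(!is.na(clamped))
    values <- clamped[idx]
  } else {
    idx <- suppressWarnings(as.integer(names(clamped)))
    if (anyNA(idx)) {
      stopf("clamped names must be variable indices",
            class = "boltzgen_validation_error")
    }
    values <- as.numeric(clamped)
  }
  if (length(idx) > 0L && (min(idx) < 1L || max(idx) > n_visible)) {
    stopf("clamped index out of range 1..%d", n_visible,
          class = "boltzgen_validation_error")
  }
  if (!all(values %in% c(0, 1))) {
    stopf("clamped values must be 0 or 1", class = "boltzgen_validation_error")
  }
  list(idx = idx, values = values)
}

apply_clamp <- function(v, cl) {
  if (is.null(cl) || length(cl$idx) == 0L) return(v)
  v[, cl$idx] <- rep(cl$values, each = nrow(v))
  v
}

#' Exact log partition function of an RBM
#'
#' Sums \eqn{e^{-E(v,h)}} over all configurations, collapsing the hidden
#' sum analytically: \eqn{\log Z = \mathrm{logsumexp}_v\,[a^\top v + \sum_j
#' \log(1 + e^{b_j + v^\top W_{\cdot j}})]}. Exponential in the number of
#' visible units, so a total-unit cap is enforced; use
#' [ais_log_partition()] beyond it.
#'
#' @param model an [rbm()] or [dbm()].
#' @param max_units cap on the total number of units (default 24).
#' @return `log Z` as a scalar.
#' @export
exact_log_partition <- function(model, max_units = 24L) {
  UseMethod("exact_log_partition")
}

#' @export
exact_log_partition.rbm <- function(model, max_units = 24L) {
  rbm <- model
  nv <- nrow(rbm$weights)
  nh <- ncol(rbm$weights)
  if (nv + nh > max_units) {
    stopf("model has %d units, exceeding the cap of %d; use ais_log_partition()",
          nv + nh, max_units, class = "boltzgen_size_error")
  }
  configs <- all_binary_configs(nv)
  logsumexp(rbm_log_pstar(rbm, configs))
}

# Unnormalized log p*(v) with the hidden layer summed out (negative free
# energy), vectorized over rows of `v`; `beta` scales the weights only.
rbm_log_pstar <- function(rbm, v, beta = 1) {
  act <- sweep(v %*% rbm$weights * beta, 2L, rbm$hidden_bias, `+`)
  as.numeric(v %*% rbm$visible_bias) + rowSums(softplus(act))
}
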