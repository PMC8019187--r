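#' Deep Boltzmann machine parameters
#'
#' A layered undirected energy model: layer 0 is the visible layer, layers
#' `1...L` are hidden. Only adjacent layers are connected, giving the energy
#' \deqn{E(s_0, \ldots, s_L) = -\sum_{l=1}^L s_{l-1}^\top W^{(l)} s_l -
#'   \sum_{l=0}^L b^{(l)\top} s_l.}
#' Unlike a deep belief network (same layout, directed sampling), a DBM
#' generates samples by Gibbs sampling through the full network.
#'
#' @param layer_weights list of matrices `W^(1)...W^(L)`; `W^(l)` connects
#'   layer `l-1` to layer `l`.
#' @param biases list of vectors `b^(0)...b^(L)` (one more entry than
#'   `layer_weights`).
#' @return an object of class `dbm`.
#' @export
dbm <- function(layer_weights, biases) {
  if (length(layer_weights) < 1L || length(biases) != length(layer_weights) + 1L) {
    stopf("a DBM needs L >= 1 weight matrices and L + 1 bias vectors",
          class = "boltzgen_validation_error")
  }
  layer_weights <- lapply(layer_weights, as.matrix)
  biases <- lapply(biases, as.numeric)
  for (l in seq_along(layer_weights)) {
    w <- layer_weights[[l]]
    if (nrow(w) != length(biases[[l]]) || ncol(w) != length(biases[[l + 1L]])) {
      stopf("layer %d weight matrix %dx%d does not chain with biases (%d, %d)",
            l, nrow(w), ncol(w), length(biases[[l]]), length(biases[[l + 1L]]),
            class = "boltzgen_validation_error")
    }
    if (!all(is.finite(w)) || !all(is.finite(biases[[l]]))) {
      stopf("DBM parameters must be finite", class = "boltzgen_validation_error")
    }
  }
  structure(list(layer_weights = layer_weights, biases = biases),
            class = "dbm")
}

#' @export
print.dbm <- function(x, ...) {
  sizes <- dbm_layer_sizes(x)
  cat(sprintf("<dbm: layers %s>\n", paste(sizes, collapse = "-")))
  invisible(x)
}

dbm_layer_sizes <- function(dbm) vapply(dbm$biases, length, integer(1))

#' Per-layer pre-training configuration
#'
#' Pre-training parameters can be controlled individually for each RBM in
#' the stack; [fit_dbm()] builds one of these per entry of
#' `config$nhiddens`.
#'
#' @param nhidden hidden layer size.
#' @param learningratepretraining learning rate of the layer's CD training.
#' @param epochspretraining epochs of the layer's CD training.
#' @param batchsizepretraining minibatch size.
#' @return a list of class `layer_config`.
#' @export
layer_config <- function(nhidden, learningratepretraining = 0.001,
                         epochspretraining = 30L,
                         batchsizepretraining = 20L) {
  structure(list(
    nhidden = check_count(nhidden, "nhidden"),
    learningratepretraining = learningratepretraining,
    epochspretraining = check_count(epochspretraining, "epochspretraining", min = 0L),
    batchsizepretraining = check_count(batchsizepretraining, "batchsizepretraining")
  ), class = "layer_config")
}

#' Greedy layer-wise pre-training of an RBM stack
#'
#' Trains the first RBM on the data and each subsequent RBM on the hidden
#' activation probabilities of the previous one. When the stack has more
#' than one layer (i.e. is destined for a DBM), the input of each RBM is
#' compensated for the double counting that occurs once the layers are
#' joined into one undirected network: the first RBM doubles its
#' visible-to-hidden input, the last doubles its hidden-to-visible input,
#' and intermediate RBMs double both (their weights are halved on assembly
#' by [stack_to_dbm()]). A single-layer stack is trained exactly like
#' [fit_rbm()].
#'
#' @param data a [binary_dataset()].
#' @param layers list of [layer_config()]s, one per hidden layer.
#' @param seed integer RNG seed.
#' @param callback optional `function(layer, epoch, rbm)` monitoring hook.
#' @return list of fitted [rbm()]s; each carries its training scaling
#'   factors as attribute `factors = c(up, down)`.
#' @export
pretrain_stack <- function(data, layers, seed = 1L, callback = NULL) {
  stopifnot(inherits(data, "binary_dataset"))
  if (length(layers) == 0L) {
    stopf("at least one layer is required", class = "boltzgen_validation_error")
  }
  layers <- lapply(layers, function(l) {
    if (inherits(l, "layer_config")) l else do.call(layer_config, l)
  })
  n_layers <- length(layers)
  x <- data$values
  stack <- vector("list", n_layers)
  withr::with_seed(seed, {
    for (l in seq_len(n_layers)) {
      cfg <- layers[[l]]
      up_factor <- if (n_layers > 1L && l < n_layers) 2 else 1
      down_factor <- if (n_layers > 1L && l > 1L) 2 else 1
      cb <- if (!is.null(callback)) {
        function(epoch, model) callback(l, epoch, model)
      }
      model <- cd_train(x, cfg$nhidden, cfg$epochspretraining,
                        cfg$learningratepretraining,
                        cfg$batchsizepretraining, cdsteps = 1L,
                        up_factor = up_factor, down_factor = down_factor,
                        callback = cb)
      attr(model, "factors") <- c(up = up_factor, down = down_factor)
      stack[[l]] <- model
      # propagate mean activations (not samples) upward, with the same
      # input scaling the RBM was trained with
      x <- sigmoid(sweep(x %*% model$weights * up_factor, 2L,
                         model$hidden_bias, `+`))
    }
  })
  stack
}

#' Assemble a pre-trained RBM stack into a DBM
#'
#' Reverses the double-counting compensation of [pretrain_stack()]:
#' intermediate RBM weights (trained with doubled input on both sides) are
#' halved; first and last layer weights are kept. Interior layer biases are
#' the mean of the two estimates available from adjacent RBMs.
#'
#' @param stack list of [rbm()]s as returned by [pretrain_stack()].
#' @return a [dbm()].
#' @export
stack_to_dbm <- function(stack) {
  n_layers <- length(stack)
  for (l in seq_len(n_layers - 1L)) {
    if (ncol(stack[[l]]$weights) != nrow(stack[[l + 1L]]$weights)) {
      stopf("stack dimensions do not chain at layer %d", l,
            class = "boltzgen_validation_error")
    }
  }
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers + 1L)
  biases[[1L]] <- stack[[1L]]$visible_bias
  for (l in seq_len(n_layers)) {
    halve <- n_layers > 1L && l > 1L && l < n_layers
    weights[[l]] <- if (halve) stack[[l]]$weights / 2 else stack[[l]]$weights
    biases[[l + 1L]] <- if (l < n_layers) {
      (stack[[l]]$hidden_bias + stack[[l + 1L]]$visible_bias) / 2
    } else {
      stack[[l]]$hidden_bias
    }
  }
  dbm(weights, biases)
}

#' Mean-field inference of the hidden layers of a DBM
#'
#' Fixed-point iteration of the fully factorised variational approximation:
#' each hidden layer's mean activation is updated from the means of its
#' adjacent layers, \eqn{\mu_l = \sigma(b^{(l)} + \mu_{l-1} W^{(l)} +
#' \mu_{l+1} W^{(l+1)\top})} (the top layer lacking the upward term), until
#' the largest change falls below `tol` or `max_iters` sweeps are reached.
#' For a one-hidden-layer model the first sweep is already exact and equals
#' [hidden_conditional()].
#'
#' @param dbm a [dbm()].
#' @param v visible state vector or matrix (rows = samples), entries in
#'   `[0, 1]`.
#' @param max_iters maximum sweeps (default 10).
#' @param tol convergence threshold on the largest mean change.
#' @return list of mean-activation matrices, one per hidden layer (rows =
#'   samples); vectors if `v` was a vector.
#' @export
mean_field_inference <- function(dbm, v, max_iters = 10L, tol = 1e-6) {
  stopifnot(inherits(dbm, "dbm"))
  sizes <- dbm_layer_sizes(dbm)
  was_vec <- is.null(dim(v))
  v <- as_state_matrix(v, sizes[1L], "v")
  n_layers <- length(dbm$layer_weights)
  mu <- vector("list", n_layers)
  # upward initialisation
  below <- v
  for (l in seq_len(n_layers)) {
    mu[[l]] <- sigmoid(sweep(below %*% dbm$layer_weights[[l]], 2L,
                             dbm$biases[[l + 1L]], `+`))
    below <- mu[[l]]
  }
  for (iter in seq_len(max_iters)) {
    delta <- 0
    for (l in seq_len(n_layers)) {
      below <- if (l == 1L) v else mu[[l - 1L]]
      input <- sweep(below %*% dbm$layer_weights[[l]], 2L,
                     dbm$biases[[l + 1L]], `+`)
      if (l < n_layers) {
        input <- input + tcrossprod(mu[[l + 1L]], dbm$layer_weights[[l + 1L]])
      }
      new <- sigmoid(input)
      delta <- max(delta, max(abs(new - mu[[l]])))
      mu[[l]] <- new
    }
    if (delta < tol) break
  }
  if (was_vec) mu <- lapply(mu, as.numeric)
  mu
}

#' Fine-tune a pre-trained stack as a DBM
#'
#' Converts the stack into DBM parameters ([stack_to_dbm()]) and runs
#' stochastic gradient ascent on the variational lower bound of the
#' likelihood: the positive phase uses mean-field inference on each
#' minibatch, the negative phase uses persistent block-Gibbs chains on the
#' full network. With `config$epochs = 0` the converted stack is returned
#' unchanged (pre-training-only model).
#'
#' @param stack list of [rbm()]s from [pretrain_stack()], or a [dbm()].
#' @param data a [binary_dataset()] matching the visible layer.
#' @param config a [train_config()]; uses `epochs`, `learningrate`,
#'   `batchsize`, `seed`.
#' @param n_chains number of persistent Gibbs chains (default 5).
#' @param gibbs_steps Gibbs sweeps per parameter update (default 5).
#' @param mf_iters,mf_tol mean-field iteration controls.
#' @param checkpoint_epochs integer vector of fine-tuning epochs after which
#'   a parameter snapshot is stored (attribute `checkpoints` of the result).
#' @return a [dbm()]; when `checkpoint_epochs` is nonempty the result has an
#'   attribute `checkpoints`, a named list of `dbm` snapshots.
#' @export
finetune_dbm <- function(stack, data, config = train_config(), n_chains = 5L,
                         gibbs_steps = 5L, mf_iters = 10L, mf_tol = 1e-6,
                         checkpoint_epochs = integer()) {
  stopifnot(inherits(data, "binary_dataset"))
  model <- if (inherits(stack, "dbm")) stack else stack_to_dbm(stack)
  sizes <- dbm_layer_sizes(model)
  if (n_variables(data) != sizes[1L]) {
    stopf("data has %d variables but DBM visible layer has %d",
          n_variables(data), sizes[1L], class = "boltzgen_validation_error")
  }
  checkpoints <- list()
  if (config$epochs == 0L) {
    if (length(checkpoint_epochs) > 0L) attr(model, "checkpoints") <- checkpoints
    return(model)
  }
  n_layers <- length(model$layer_weights)
  x <- data$values
  n <- nrow(x)
  lr <- config$learningrate
  withr::with_seed(derive_seed(config$seed, 1L), {
    chains <- lapply(sizes, function(k) {
      matrix(stats::rbinom(n_chains * k, 1L, 0.5), n_chains, k)
    })
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = config$batchsize)) {
        idx <- ord[s:min(s + config$batchsize - 1L, n)]
        v0 <- x[idx, , drop = FALSE]
        m <- nrow(v0)
        mu <- mean_field_inference(model, v0, mf_iters, mf_tol)
        pos <- c(list(v0), mu)
        for (g in seq_len(gibbs_steps)) {
          chains <- dbm_gibbs_sweep(model, chains)
        }
        for (l in seq_len(n_layers)) {
          grad_w <- crossprod(pos[[l]], pos[[l + 1L]]) / m -
            crossprod(chains[[l]], chains[[l + 1L]]) / n_chains
          model$layer_weights[[l]] <- model$layer_weights[[l]] + lr * grad_w
        }
        for (l in seq_len(n_layers + 1L)) {
          grad_b <- colMeans(pos[[l]]) - colMeans(chains[[l]])
          model$biases[[l]] <- model$biases[[l]] + lr * grad_b
        }
      }
      if (epoch %in% checkpoint_epochs) {
        checkpoints[[as.character(epoch)]] <- model
      }
    }
  })
  if (length(checkpoint_epochs) > 0L) attr(model, "checkpoints") <- checkpoints
  model
}

# One odd-then-even block-Gibbs sweep over the layer states (list of
# matrices, layer 0 first). Optionally clamps visible columns.
dbm_gibbs_sweep <- function(model, states, clamp = NULL) {
  n_layers <- length(model$layer_weights)
  layer_input <- function(l) {
    # l is 0-based layer index into states[[l + 1]]
    input <- matrix(rep(model$biases[[l + 1L]], each = nrow(states[[1L]])),
                    nrow = nrow(states[[1L]]))
    if (l >= 1L) {
      input <- input + states[[l]] %*% model$layer_weights[[l]]
    }
    if (l < n_layers) {
      input <- input + tcrossprod(states[[l + 2L]], model$layer_weights[[l + 1L]])
    }
    input
  }
  for (parity in c(1L, 0L)) {
    for (l in seq(parity, n_layers, by = 2L)) {
      states[[l + 1L]] <- draw_bernoulli(sigmoid(layer_input(l)))
      if (l == 0L) states[[1L]] <- apply_clamp(states[[1L]], clamp)
    }
  }
  states
}

#' Fit a deep Boltzmann machine
#'
#' Runs greedy layer-wise pre-training ([pretrain_stack()]) followed by
#' variational fine-tuning ([finetune_dbm()]), the full training pipeline.
#' Optional monitoring records the first layer's reconstruction error per
#' pre-training epoch and, when requested, the estimated variational lower
#' bound per fine-tuning epoch.
#'
#' @param data a [binary_dataset()].
#' @param config a [train_config()]; `nhiddens` must be nonempty.
#' @param monitor character vector among `"reconstruction_error"` (tracked
#'   during pre-training) and `"logproblowerbound"` (tracked during
#'   fine-tuning via AIS; noticeably slower). Empty = no monitoring.
#' @param monitor_data named list of datasets for evaluation (default
#'   `list(train = data)`).
#' @param monitor_ais an [ais_config()] for lower-bound monitoring.
#' @param ... passed to [finetune_dbm()] (`n_chains`, `gibbs_steps`,
#'   `checkpoint_epochs`, ...).
#' @return list with elements `dbm` and `monitoring` (data frame with
#'   columns `epoch`, `metric`, `value`, `partition`).
#' @export
fit_dbm <- function(data, config = train_config(), monitor = character(),
                    monitor_data = NULL, monitor_ais = NULL, ...) {
  stopifnot(inherits(data, "binary_dataset"), inherits(config, "train_config"))
  if (length(config$nhiddens) == 0L) {
    stopf("config$nhiddens must name at least one hidden layer",
          class = "boltzgen_validation_error")
  }
  if (is.null(monitor_data)) monitor_data <- list(train = data)
  records <- monitoring_log()
  cb <- if ("reconstruction_error" %in% monitor) {
    function(layer, epoch, model) {
      if (layer == 1L) {
        for (part in names(monitor_data)) {
          records$add(data.frame(
            epoch = epoch, metric = "reconstruction_error",
            value = reconstruction_error(model, monitor_data[[part]]),
            partition = part))
        }
      }
    }
  }
  layers <- lapply(config$nhiddens, function(k) {
    layer_config(k, config$learningratepretraining,
                 config$epochspretraining, config$batchsizepretraining)
  })
  stack <- pretrain_stack(data, layers, seed = config$seed, callback = cb)
  extra <- list(...)
  want_bound <- "logproblowerbound" %in% monitor
  if (want_bound) {
    if (is.null(monitor_ais)) monitor_ais <- ais_config(30L, 30L, seed = config$seed)
    # per-epoch snapshots so the bound can be evaluated along the way
    extra$checkpoint_epochs <- union(extra$checkpoint_epochs, seq_len(config$epochs))
  }
  model <- do.call(finetune_dbm,
                   c(list(stack = stack, data = data, config = config), extra))
  if (want_bound) {
    snaps <- attr(model, "checkpoints")
    for (ep in names(snaps)) {
      for (part in names(monitor_data)) {
        est <- dbm_logproblowerbound(snaps[[ep]], monitor_data[[part]], monitor_ais)
        records$add(data.frame(epoch = as.integer(ep),
                               metric = "logproblowerbound",
                               value = est$value, partition = part))
      }
    }
  }
  list(dbm = model, monitoring = records$table())
}

#' Gibbs sampling from a DBM
#'
#' Runs independent block-Gibbs chains over the full layered network: all
#' odd layers are updated given the even layers and vice versa (layers of
#' equal parity are conditionally independent). Clamped visible variables
#' are held at their fixed values throughout, giving conditional samples.
#'
#' @param dbm a [dbm()].
#' @param n_samples number of samples (independent chains).
#' @param burnin Gibbs sweeps per chain (default 50).
#' @param clamped clamping map as in [gibbs_sample()].
#' @param seed integer RNG seed.
#' @return a [binary_dataset()] of visible-layer samples.
#' @export
dbm_gibbs_sample <- function(dbm, n_samples, burnin = 50L, clamped = NULL,
                             seed = 1L) {
  stopifnot(inherits(dbm, "dbm"))
  n_samples <- check_count(n_samples, "n_samples")
  burnin <- check_count(burnin, "burnin")
  sizes <- dbm_layer_sizes(dbm)
  cl <- resolve_clamped(clamped, sizes[1L])
  withr::with_seed(seed, {
    states <- lapply(sizes, function(k) {
      matrix(stats::rbinom(n_samples * k, 1L, 0.5), n_samples, k)
    })
    states[[1L]] <- apply_clamp(states[[1L]], cl)
    for (step in seq_len(burnin)) {
      states <- dbm_gibbs_sweep(dbm, states, clamp = cl)
    }
    binary_dataset(states[[1L]])
  })
}

#' Two-dimensional latent representation
#'
#' Requires the top hidden layer to have exactly two nodes; returns the
#' mean-field mean activations of those two nodes for every sample, a
#' 2-D embedding of the data in the model's most abstract latent space.
#'
#' @param dbm a [dbm()] whose top layer has exactly 2 nodes.
#' @param data a [binary_dataset()].
#' @param max_iters,tol mean-field controls, see [mean_field_inference()].
#' @return `n_samples x 2` matrix with entries in `[0, 1]`.
#' @export
top2_latent_dims <- function(dbm, data, max_iters = 10L, tol = 1e-6) {
  stopifnot(inherits(dbm, "dbm"), inherits(data, "binary_dataset"))
  sizes <- dbm_layer_sizes(dbm)
  top <- sizes[length(sizes)]
  if (top != 2L) {
    stopf(paste0("top hidden layer has %d nodes; a 2-node top layer is ",
                 "required (e.g. nhiddens = c(..., 2))"), top,
          class = "boltzgen_contract_error")
  }
  mu <- mean_field_inference(dbm, data$values, max_iters, tol)
  out <- mu[[length(mu)]]
  rownames(out) <- data$sample_ids
  out
}
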