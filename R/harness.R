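#' Split data into consecutive equal site shares
#'
#' Emulates the multi-site setting: the rows are divided into `n_sites`
#' consecutive blocks of as-equal-as-possible size (any remainder is spread
#' over the leading sites), one block per virtual site.
#'
#' @param data a [binary_dataset()].
#' @param n_sites number of virtual sites, between 1 and the sample count.
#' @return an object of class `site_split` with field `shares`, a list of
#'   `binary_dataset`s that reassemble the input exactly.
#' @export
split_sites <- function(data, n_sites) {
  stopifnot(inherits(data, "binary_dataset"))
  n_sites <- check_count(n_sites, "n_sites")
  n <- n_samples(data)
  if (n_sites > n) {
    stopf("cannot split %d samples across %d sites", n, n_sites,
          class = "boltzgen_validation_error")
  }
  base <- n %/% n_sites
  sizes <- rep(base, n_sites) + c(rep(1L, n %% n_sites),
                                  rep(0L, n_sites - n %% n_sites))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  shares <- lapply(seq_len(n_sites), function(i) {
    subset_samples(data, starts[i]:ends[i])
  })
  structure(list(shares = shares), class = "site_split")
}

#' @export
print.site_split <- function(x, ...) {
  cat(sprintf("<site_split: %d sites of sizes %s>\n", length(x$shares),
              paste(vapply(x$shares, n_samples, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Train one generator per site and pool the synthetic data
#'
#' Fits an independent generator on every site's share and lets each site
#' generate as many synthetic samples as its share holds, so that the
#' pooled synthetic dataset matches the total training size. Per-site seeds
#' are derived deterministically from `seed`.
#'
#' @param split a [split_sites()] result.
#' @param spec a [generator_spec()].
#' @param seed master integer seed.
#' @return the pooled [binary_dataset()] of synthetic samples, in site
#'   order.
#' @export
run_sites <- function(split, spec, seed = 1L) {
  stopifnot(inherits(split, "site_split"), inherits(spec, "generator_spec"))
  pieces <- lapply(seq_along(split$shares), function(i) {
    share <- split$shares[[i]]
    model <- tryCatch(
      fit_generator(spec, share, seed = derive_seed(seed, 2L * i)),
      error = function(e) stopf("site %d: %s", i, conditionMessage(e),
                                class = "boltzgen_site_error"))
    generate_samples(model, n_samples(share),
                     seed = derive_seed(seed, 2L * i + 1L))
  })
  pool_datasets(pieces)
}

pool_datasets <- function(pieces) {
  vals <- do.call(rbind, lapply(pieces, function(d) d$values))
  binary_dataset(vals, sample_ids = paste0("gen", seq_len(nrow(vals))),
                 variable_names = pieces[[1L]]$variable_names)
}

#' Hyperparameter search over initialisations and training epochs
#'
#' For each of `n_inits` random initialisations, trains one generator per
#' site, evaluates the pooled generated data along the epoch axis, and
#' selects the (initialisation, epoch) pair minimising the log-odds-ratio
#' distance `d(x_gen, x_test)` to the held-out test data. For generators
#' without an epoch axis (IM, MICE) only initialisations are searched. The
#' fine-tuning trajectory is checkpointed at `n_checkpoints` evenly spaced
#' epochs rather than literally every epoch; set `n_checkpoints` to
#' `epoch_cap` for a full-resolution search.
#'
#' @param split a [split_sites()] of the training data.
#' @param test a [binary_dataset()] used for selection.
#' @param spec a [generator_spec()].
#' @param epoch_cap largest epoch evaluated (>= 1).
#' @param n_inits number of random initialisations (>= 1).
#' @param seed master integer seed.
#' @param n_checkpoints number of epoch-axis evaluation points (default 20).
#' @return a list of class `search_result`: `generated` (pooled dataset of
#'   the minimiser), `best` (init, epoch, distance), and `grid` (a data
#'   frame of every evaluated point).
#' @export
hyperparameter_search <- function(split, test, spec, epoch_cap = 30L,
                                  n_inits = 1L, seed = 1L,
                                  n_checkpoints = 20L) {
  stopifnot(inherits(split, "site_split"), inherits(test, "binary_dataset"),
            inherits(spec, "generator_spec"))
  epoch_cap <- check_count(epoch_cap, "epoch_cap")
  n_inits <- check_count(n_inits, "n_inits")
  checkpoints <- unique(round(seq(1L, epoch_cap,
                                  length.out = min(n_checkpoints, epoch_cap))))
  best <- list(distance = Inf)
  grid <- list()
  for (init in seq_len(n_inits)) {
    site_models <- lapply(seq_along(split$shares), function(i) {
      fit_generator_checkpoints(spec, split$shares[[i]],
                                seed = derive_seed(seed, 1000L * init + 2L * i),
                                checkpoint_epochs = checkpoints)
    })
    epochs <- names(site_models[[1L]])
    for (ep in epochs) {
      pieces <- lapply(seq_along(site_models), function(i) {
        generate_samples(site_models[[i]][[ep]],
                         n_samples(split$shares[[i]]),
                         seed = derive_seed(seed, 1000L * init + 2L * i + 1L))
      })
      pooled <- pool_datasets(pieces)
      dist <- odds_ratio_distance(pooled, test)
      grid[[length(grid) + 1L]] <- data.frame(
        init = init, epoch = as.integer(ep), distance = dist)
      if (dist < best$distance) {
        best <- list(init = init, epoch = as.integer(ep), distance = dist)
        best_pooled <- pooled
      }
    }
  }
  structure(list(generated = best_pooled, best = best,
                 grid = do.call(rbind, grid)),
            class = "search_result")
}

#' Run the full distributed benchmarking experiment
#'
#' The full factorial over datasets, generator types and site counts: each
#' dataset is split into disjoint train/test/validation subsets, the
#' training part is distributed over the virtual sites, a hyperparameter
#' search selects the best (initialisation, epoch) per cell by
#' `d(x_gen, x_test)`, and the selected pooled data are scored by the
#' utility distance to validation data, the proportion of overfitting, and
#' the membership attack. Per-cell results are summarised across datasets
#' by the median and the 5% and 95% quantiles (type-7 interpolation).
#'
#' @param datasets list of [binary_dataset()]s.
#' @param specs named list of [generator_spec()]s (names label the rows).
#' @param site_counts integer vector of site counts (e.g. `c(1, 2, 5, 20)`).
#' @param sizes integer triple `(n_train, n_test, n_val)`.
#' @param epoch_cap,n_inits,n_checkpoints search controls, see
#'   [hyperparameter_search()].
#' @param thresholds Hamming-distance grid for the attack.
#' @param seed master integer seed; the whole experiment is reproducible
#'   from it.
#' @return an object of class `experiment_result`: `cells` (one row per
#'   dataset x model x site count), `summary` (median and quantiles per
#'   model x site count) and `attacks` (list of attack curves per cell).
#' @export
run_experiment <- function(datasets, specs, site_counts,
                           sizes = c(500L, 100L, 1000L), epoch_cap = 30L,
                           n_inits = 1L, n_checkpoints = 20L,
                           thresholds = 0:10, seed = 1L) {
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) s$model, character(1))
  }
  cells <- list()
  attacks <- list()
  for (di in seq_along(datasets)) {
    parts <- split_train_test_val(datasets[[di]], sizes[1L], sizes[2L],
                                  sizes[3L], seed = derive_seed(seed, di))
    for (mi in seq_along(specs)) {
      for (ns in site_counts) {
        cell_seed <- derive_seed(seed, di * 100000L + mi * 1000L + ns)
        split <- split_sites(parts$train, ns)
        search <- hyperparameter_search(split, parts$test, specs[[mi]],
                                        epoch_cap = epoch_cap,
                                        n_inits = n_inits, seed = cell_seed,
                                        n_checkpoints = n_checkpoints)
        gen <- search$generated
        util <- odds_ratio_distance(gen, parts$validation)
        overfit <- overfitting_proportion(gen, parts$train, parts$validation)
        key <- sprintf("dataset%d.%s.%dsites", di, names(specs)[mi], ns)
        attacks[[key]] <- membership_attack(parts$train, parts$test, gen,
                                            thresholds)
        cells[[length(cells) + 1L]] <- data.frame(
          dataset = di, model = names(specs)[mi], n_sites = ns,
          utility = util, overfitting = overfit,
          best_init = search$best$init, best_epoch = search$best$epoch,
          selection_distance = search$best$distance)
      }
    }
  }
  cells <- do.call(rbind, cells)
  summarise <- function(metric) {
    agg <- stats::aggregate(cells[[metric]],
                            by = list(model = cells$model,
                                      n_sites = cells$n_sites),
                            FUN = function(v) c(
                              median = stats::median(v),
                              q05 = stats::quantile(v, 0.05, names = FALSE,
                                                    type = 7),
                              q95 = stats::quantile(v, 0.95, names = FALSE,
                                                    type = 7)))
    data.frame(model = agg$model, n_sites = agg$n_sites, metric = metric,
               median = agg$x[, "median"], q05 = agg$x[, "q05"],
               q95 = agg$x[, "q95"])
  }
  summary <- rbind(summarise("utility"), summarise("overfitting"))
  structure(list(cells = cells, summary = summary, attacks = attacks,
                 quantile_type = 7L, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %d cells>\n", nrow(x$cells)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
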