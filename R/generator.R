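#' Common generator contract
#'
#' Every generator in the package -- independent marginals, MICE, RBM and
#' DBM -- is driven through the same two-step contract: [fit_generator()]
#' fits a model on a [binary_dataset()] and [generate_samples()] draws `n`
#' synthetic samples from it. The multi-site harness relies on nothing
#' beyond this contract, so further generators can be plugged in by adding
#' methods.
#'
#' @param model one of `"im"`, `"mice"`, `"rbm"`, `"dbm"`.
#' @param config a [train_config()] (used by `"rbm"`/`"dbm"`; ignored
#'   otherwise).
#' @param burnin Gibbs burn-in used when sampling Boltzmann machines.
#' @return `generator_spec`: an object of class `generator_spec`.
#' @export
generator_spec <- function(model = c("im", "mice", "rbm", "dbm"),
                           config = train_config(), burnin = 50L) {
  model <- match.arg(model)
  structure(list(model = model, config = config,
                 burnin = check_count(burnin, "burnin")),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @param spec a `generator_spec`.
#' @param data a [binary_dataset()] to fit on.
#' @param seed integer RNG seed for the fit.
#' @return `fit_generator`: an object of class `generator_model` wrapping
#'   the fitted model.
#' @export
fit_generator <- function(spec, data, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"), inherits(data, "binary_dataset"))
  cfg <- spec$config
  cfg$seed <- check_count(seed, "seed", min = 0L)
  fitted <- switch(spec$model,
    im = fit_im(data),
    mice = fit_mice(data, seed = seed),
    rbm = fit_rbm(data, cfg)$rbm,
    dbm = fit_dbm(data, cfg)$dbm)
  generator_model(spec$model, fitted, data$variable_names, spec$burnin)
}

generator_model <- function(type, fitted, variable_names, burnin) {
  structure(list(type = type, fitted = fitted,
                 variable_names = variable_names, burnin = burnin),
            class = "generator_model")
}

#' @export
print.generator_model <- function(x, ...) {
  cat(sprintf("<generator_model: %s over %d variables>\n", x$type,
              length(x$variable_names)))
  invisible(x)
}

#' @rdname generator_spec
#' @param fitted_model a `generator_model` from [fit_generator()].
#' @param n number of synthetic samples.
#' @param seed integer RNG seed for sampling.
#' @return `generate_samples`: a [binary_dataset()] of `n` samples carrying
#'   the training variable names.
#' @export
generate_samples <- function(fitted_model, n, seed = 1L) {
  stopifnot(inherits(fitted_model, "generator_model"))
  out <- switch(fitted_model$type,
    im = sample_im(fitted_model$fitted, n, seed),
    mice = sample_mice(fitted_model$fitted, n, seed),
    rbm = gibbs_sample(fitted_model$fitted, n, burnin = fitted_model$burnin,
                       seed = seed),
    dbm = dbm_gibbs_sample(fitted_model$fitted, n,
                           burnin = fitted_model$burnin, seed = seed))
  binary_dataset(out$values, sample_ids = out$sample_ids,
                 variable_names = fitted_model$variable_names)
}

# Fit a generator while snapshotting the epoch axis; returns a named list
# of generator_model objects keyed by epoch. IM and MICE have no epoch
# axis and yield a single entry. For RBM the axis is the CD epochs, for
# DBM the fine-tuning epochs (pre-training is held fixed).
fit_generator_checkpoints <- function(spec, data, seed, checkpoint_epochs) {
  cfg <- spec$config
  cfg$seed <- check_count(seed, "seed", min = 0L)
  vn <- data$variable_names
  if (spec$model %in% c("im", "mice")) {
    m <- fit_generator(spec, data, seed)
    out <- list(m)
    names(out) <- "1"
    return(out)
  }
  checkpoint_epochs <- sort(unique(as.integer(checkpoint_epochs)))
  if (spec$model == "rbm") {
    snaps <- list()
    cb <- function(epoch, model) {
      if (epoch %in% checkpoint_epochs) snaps[[as.character(epoch)]] <<- model
    }
    cfg$epochs <- max(checkpoint_epochs)
    withr::with_seed(cfg$seed,
      cd_train(data$values, cfg$nhiddens[1L], cfg$epochs, cfg$learningrate,
               cfg$batchsizepretraining, cfg$cdsteps, callback = cb))
    return(lapply(snaps, function(m) {
      generator_model("rbm", m, vn, spec$burnin)
    }))
  }
  cfg$epochs <- max(checkpoint_epochs)
  model <- fit_dbm(data, cfg, checkpoint_epochs = checkpoint_epochs)$dbm
  snaps <- attr(model, "checkpoints")
  lapply(snaps, function(m) generator_model("dbm", m, vn, spec$burnin))
}
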