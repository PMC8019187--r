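#' Configuration of the simulated SNP-set dataset
#'
#' The study-design defaults: 500 samples over 50 binary SNP variables,
#' background noise from Bernoulli(0.1), an equal case/control split, and
#' five "SNP sets" of five consecutive variables that co-occur as runs of
#' ones among the cases.
#'
#' @param n_samples number of samples (default 500).
#' @param n_variables number of SNP variables (default 50).
#' @param noise_p background Bernoulli noise probability (default 0.1).
#' @param n_sets number of SNP-set blocks (default 5).
#' @param set_size consecutive variables per block (default 5).
#' @param case_fraction fraction of case samples (default 0.5).
#' @param set_activation_p probability that a case activates each block,
#'   independently per block (default 0.5).
#' @param seed integer RNG seed.
#' @return a list of class `snp_sim_config`.
#' @export
snp_sim_config <- function(n_samples = 500L, n_variables = 50L,
                           noise_p = 0.1, n_sets = 5L, set_size = 5L,
                           case_fraction = 0.5, set_activation_p = 0.5,
                           seed = 1L) {
  cfg <- structure(list(
    n_samples = check_count(n_samples, "n_samples"),
    n_variables = check_count(n_variables, "n_variables"),
    noise_p = noise_p,
    n_sets = check_count(n_sets, "n_sets"),
    set_size = check_count(set_size, "set_size"),
    case_fraction = case_fraction,
    set_activation_p = set_activation_p,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "snp_sim_config")
  if (cfg$n_sets * cfg$set_size > cfg$n_variables) {
    stopf("%d sets of %d variables do not fit into %d variables",
          cfg$n_sets, cfg$set_size, cfg$n_variables,
          class = "boltzgen_validation_error")
  }
  for (p in c("noise_p", "case_fraction", "set_activation_p")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stopf("%s must be a probability in [0, 1]", p,
            class = "boltzgen_validation_error")
    }
  }
  cfg
}

#' Simulate SNP-set structured case/control data
#'
#' Generates binary data that are mostly zeros with iid Bernoulli
#' background noise, in which case samples additionally carry runs of five
#' (by default) consecutive ones at evenly spaced "SNP set" positions --
#' the kind of co-occurring variant block that might jointly deactivate a
#' pathway. Each case activates each block independently with
#' `set_activation_p` (activation overwrites the noise with ones);
#' controls receive background noise only. Case/control labels are
#' assigned in random row order so that any consecutive partition of the
#' samples mixes the two groups.
#'
#' @param config a [snp_sim_config()].
#' @return an object of class `labeled_dataset`: `data` (a
#'   [binary_dataset()]), `labels` (factor `case`/`control` per sample) and
#'   `set_positions` (list of column-index blocks).
#' @export
simulate_snp_sets <- function(config = snp_sim_config()) {
  stopifnot(inherits(config, "snp_sim_config"))
  n <- config$n_samples
  k <- config$n_variables
  spacing <- k %/% config$n_sets
  set_positions <- lapply(seq_len(config$n_sets) - 1L, function(s) {
    s * spacing + seq_len(config$set_size)
  })
  n_cases <- round(config$case_fraction * n)
  withr::with_seed(config$seed, {
    labels <- factor(sample(rep(c("case", "control"), c(n_cases, n - n_cases))),
                     levels = c("case", "control"))
    vals <- draw_bernoulli(matrix(config$noise_p, n, k))
    case_rows <- which(labels == "case")
    for (block in set_positions) {
      active <- case_rows[stats::runif(length(case_rows)) < config$set_activation_p]
      vals[active, block] <- 1
    }
    structure(list(
      data = binary_dataset(vals,
                            sample_ids = paste0("p", seq_len(n)),
                            variable_names = paste0("snp", seq_len(k))),
      labels = labels,
      set_positions = set_positions
    ), class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d samples (%d cases) x %d variables, %d blocks>\n",
              n_samples(x$data), sum(x$labels == "case"),
              n_variables(x$data), length(x$set_positions)))
  invisible(x)
}

#' Simulate iid Bernoulli data
#'
#' Independent draws, one success probability per variable; the null
#' fixture for independence-related properties and the membership-attack
#' baseline.
#'
#' @param n_samples number of samples.
#' @param probabilities vector of per-variable success probabilities.
#' @param seed integer RNG seed.
#' @return a [binary_dataset()].
#' @export
simulate_iid_bernoulli <- function(n_samples, probabilities, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  if (!is.numeric(probabilities) || any(probabilities < 0) ||
      any(probabilities > 1)) {
    stopf("probabilities must lie in [0, 1]", class = "boltzgen_validation_error")
  }
  vals <- withr::with_seed(seed,
    draw_bernoulli(matrix(probabilities, n_samples, length(probabilities),
                          byrow = TRUE)))
  binary_dataset(vals)
}

#' Simulate a sequential logistic (chain) process
#'
#' Ground-truth generator of the model family fitted by [fit_mice()]: the
#' i-th variable is Bernoulli with logit equal to its intercept plus a
#' linear combination of the already-drawn predecessors. Used for
#' parameter-recovery checks.
#'
#' @param n_samples number of samples.
#' @param structure list with one element per variable; element `i` is a
#'   list with `intercept` (scalar) and `coefficients` (numeric vector of
#'   length `i - 1`, weights on variables `1 ... i-1`).
#' @param seed integer RNG seed.
#' @return a [binary_dataset()].
#' @export
simulate_logistic_chain <- function(n_samples, structure, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  nv <- length(structure)
  for (i in seq_len(nv)) {
    s <- structure[[i]]
    if (is.null(s$intercept) || length(s$coefficients %||% numeric()) != i - 1L) {
      stopf("structure[[%d]] must have an intercept and %d coefficients",
            i, i - 1L, class = "boltzgen_validation_error")
    }
  }
  withr::with_seed(seed, {
    x <- matrix(0, n_samples, nv)
    for (i in seq_len(nv)) {
      eta <- structure[[i]]$intercept
      if (i > 1L) {
        eta <- eta + as.numeric(x[, seq_len(i - 1L), drop = FALSE] %*%
                                  structure[[i]]$coefficients)
      }
      x[, i] <- stats::rbinom(n_samples, 1L, sigmoid(eta))
    }
    binary_dataset(x)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
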