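#' Independent marginals (IM) baseline generator
#'
#' The simplest reference generator: each variable is modelled by its
#' empirical frequency alone, and synthetic samples are independent
#' Bernoulli draws at those frequencies. All pairwise associations are
#' discarded by construction, which makes IM the utility floor against
#' which the structured generators are compared.
#'
#' @param data a nonempty [binary_dataset()].
#' @return an object of class `im_model` with field `frequencies`.
#' @export
fit_im <- function(data) {
  stopifnot(inherits(data, "binary_dataset"))
  if (n_samples(data) == 0L) {
    stopf("cannot fit independent marginals on an empty dataset",
          class = "boltzgen_validation_error")
  }
  structure(list(frequencies = colMeans(data$values),
                 variable_names = data$variable_names),
            class = "im_model")
}

#' @rdname fit_im
#' @param model an `im_model`.
#' @param n number of samples to generate.
#' @param seed integer RNG seed.
#' @return `sample_im`: a [binary_dataset()] of `n` samples.
#' @export
sample_im <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "im_model"))
  n <- check_count(n, "n")
  p <- model$frequencies
  vals <- withr::with_seed(seed,
    draw_bernoulli(matrix(p, n, length(p), byrow = TRUE)))
  binary_dataset(vals, variable_names = model$variable_names)
}

#' MICE-style sequential logistic generator
#'
#' Factorises the joint distribution along a random variable order: the
#' first variable is modelled by its frequency, and each later variable by
#' a logistic regression on the variables before it in the order. Predictor
#' candidates are added consecutively; a candidate whose addition does not
#' increase the rank of the design matrix (tolerance `1e-8`) is considered
#' collinear and excluded from this and every later regression. A constant
#' outcome variable is recorded as a constant prediction without fitting.
#' Regressions are fitted by maximum likelihood ([stats::glm()]); when the
#' fit separates (diverging coefficients), an L2-ridge refit
#' (`lambda = 1e-4`) is used and coefficients are clipped to `|b| <= 15`.
#'
#' @param data a [binary_dataset()] with at least 2 variables.
#' @param seed integer RNG seed (determines the variable order).
#' @return an object of class `mice_model` with fields `order` (permutation
#'   of column indices), `first_prob`, `regressions` (one record per later
#'   position) and `dropped` (indices excluded as predictors).
#' @export
fit_mice <- function(data, seed = 1L) {
  stopifnot(inherits(data, "binary_dataset"))
  nv <- n_variables(data)
  if (nv < 2L) {
    stopf("MICE requires at least 2 variables, got %d", nv,
          class = "boltzgen_validation_error")
  }
  x <- data$values
  ord <- withr::with_seed(seed, sample.int(nv))
  dropped <- integer()
  regressions <- vector("list", nv)
  for (pos in 2L:nv) {
    target <- ord[pos]
    y <- x[, target]
    if (stats::var(y) == 0) {
      regressions[[pos]] <- list(target = target, type = "constant",
                                 value = y[1L])
      next
    }
    candidates <- setdiff(ord[seq_len(pos - 1L)], dropped)
    design <- matrix(1, nrow(x), 1L)  # intercept
    kept <- integer()
    for (cand in candidates) {
      trial <- cbind(design, x[, cand])
      if (qr(trial, tol = 1e-8)$rank > qr(design, tol = 1e-8)$rank) {
        design <- trial
        kept <- c(kept, cand)
      } else {
        dropped <- c(dropped, cand)
      }
    }
    fit <- fit_logistic(x[, kept, drop = FALSE], y)
    regressions[[pos]] <- list(target = target, type = "regression",
                               predictors = kept,
                               coefficients = fit$coefficients,
                               intercept = fit$intercept)
  }
  structure(list(order = ord, first_prob = mean(x[, ord[1L]]),
                 regressions = regressions, dropped = dropped,
                 variable_names = data$variable_names),
            class = "mice_model")
}

# Logistic MLE with ridge fallback on separation; predictors may be empty.
fit_logistic <- function(xmat, y, clip = 15, lambda = 1e-4) {
  if (ncol(xmat) == 0L) {
    p <- mean(y)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    return(list(coefficients = numeric(), intercept = log(p / (1 - p))))
  }
  df <- data.frame(y = y, xmat)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  beta <- stats::coef(fit)
  if (anyNA(beta) || !fit$converged || any(abs(beta) > clip)) {
    beta <- ridge_logistic(xmat, y, lambda)
    beta <- pmin(pmax(beta, -clip), clip)
  }
  list(coefficients = unname(beta[-1L]), intercept = unname(beta[1L]))
}

# Newton-IRLS logistic regression with an L2 penalty on the non-intercept
# coefficients; used only as a fallback when the unpenalized MLE diverges.
ridge_logistic <- function(xmat, y, lambda, max_iters = 100L, tol = 1e-10) {
  X <- cbind(1, xmat)
  pen <- c(0, rep(lambda, ncol(xmat)))
  beta <- numeric(ncol(X))
  for (iter in seq_len(max_iters)) {
    eta <- as.numeric(X %*% beta)
    p <- sigmoid(eta)
    w <- pmax(p * (1 - p), 1e-10)
    hess <- crossprod(X, X * w) + diag(pen, ncol(X))
    grad <- crossprod(X, y - p) - pen * beta
    step <- solve(hess, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' @rdname fit_mice
#' @param model a `mice_model`.
#' @param n number of samples to generate.
#' @return `sample_mice`: a [binary_dataset()] of `n` samples, columns in
#'   the original variable order.
#' @export
sample_mice <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "mice_model"))
  n <- check_count(n, "n")
  nv <- length(model$order)
  withr::with_seed(seed, {
    x <- matrix(0, n, nv)
    x[, model$order[1L]] <- stats::rbinom(n, 1L, model$first_prob)
    for (pos in 2L:nv) {
      rec <- model$regressions[[pos]]
      if (rec$type == "constant") {
        x[, rec$target] <- rec$value
      } else {
        eta <- rec$intercept
        if (length(rec$predictors) > 0L) {
          eta <- eta + as.numeric(
            x[, rec$predictors, drop = FALSE] %*% rec$coefficients)
        }
        x[, rec$target] <- stats::rbinom(n, 1L, sigmoid(eta))
      }
    }
    binary_dataset(x, variable_names = model$variable_names)
  })
}
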