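#' Pairwise log-odds-ratio matrix
#'
#' For every pair of variables `(i, j)` the 2x2 cross table of counts
#' `n11, n10, n01, n00` is formed; any zero cell is replaced by 0.5 (a
#' continuity correction that keeps all odds ratios finite) and the entry
#' is `log((n11 * n00) / (n10 * n01))`. The matrix is symmetric; the
#' diagonal is undefined and set to `NA`.
#'
#' @param data a [binary_dataset()] with at least 2 variables and 1 sample.
#' @return an object of class `log_or_matrix` with fields `values`
#'   (symmetric matrix) and `variable_names`.
#' @export
log_odds_ratio_matrix <- function(data) {
  stopifnot(inherits(data, "binary_dataset"))
  if (n_variables(data) < 2L || n_samples(data) < 1L) {
    stopf("log odds ratios require >= 2 variables and >= 1 sample",
          class = "boltzgen_validation_error")
  }
  x <- data$values
  n11 <- crossprod(x)
  n10 <- crossprod(x, 1 - x)
  n01 <- t(n10)
  n00 <- crossprod(1 - x)
  cc <- function(m) { m[m == 0] <- 0.5; m }
  vals <- log(cc(n11)) + log(cc(n00)) - log(cc(n10)) - log(cc(n01))
  diag(vals) <- NA_real_
  dimnames(vals) <- NULL
  structure(list(values = vals, variable_names = data$variable_names),
            class = "log_or_matrix")
}

#' Log-odds-ratio distance between two datasets
#'
#' The utility metric of the benchmark: the root mean squared error between
#' the strictly-lower-triangle entries of the two pairwise log-odds-ratio
#' matrices, written `d(x_gen, x_val)` when comparing generated and
#' validation data. Both datasets must carry the same variables in the same
#' order.
#'
#' @param gen,ref two [binary_dataset()]s over identical variables.
#' @return nonnegative scalar RMSE.
#' @export
odds_ratio_distance <- function(gen, ref) {
  stopifnot(inherits(gen, "binary_dataset"), inherits(ref, "binary_dataset"))
  if (!identical(gen$variable_names, ref$variable_names)) {
    diff <- union(setdiff(gen$variable_names, ref$variable_names),
                  setdiff(ref$variable_names, gen$variable_names))
    stopf("variable mismatch between datasets%s",
          if (length(diff)) paste0(": ", paste(diff, collapse = ", "))
          else " (same names, different order)",
          class = "boltzgen_validation_error")
  }
  a <- log_odds_ratio_matrix(gen)$values
  b <- log_odds_ratio_matrix(ref)$values
  lower <- lower.tri(a)
  sqrt(mean((a[lower] - b[lower])^2))
}

#' Proportion of overfitting
#'
#' The disclosure proxy
#' \deqn{\frac{d(x_{gen}, x_{val}) - d(x_{gen}, x_{train})}{d(x_{gen},
#' x_{val})}:} positive values mean the generated data sit closer (in
#' log-odds-ratio distance) to the training data than to held-out
#' validation data, i.e. the generator has learned specifics of the
#' training individuals; negative values mean it fit the validation data
#' better. Bounded above by 1.
#'
#' @param gen,train,val [binary_dataset()]s over identical variables.
#' @return scalar in `(-Inf, 1]`.
#' @export
overfitting_proportion <- function(gen, train, val) {
  d_val <- odds_ratio_distance(gen, val)
  d_train <- odds_ratio_distance(gen, train)
  if (d_val == 0) {
    stopf("d(gen, val) is zero; the proportion of overfitting is undefined",
          class = "boltzgen_degenerate_error")
  }
  (d_val - d_train) / d_val
}

#' Distance-based membership attack
#'
#' Simulates an attacker who, given a probe record, guesses "training
#' member" iff some generated sample lies within Hamming distance `t` of
#' it. Every training sample guessed a member is a true positive (else
#' false negative); every test sample guessed a member is a false positive
#' (else true negative). Precision and sensitivity are reported per
#' threshold; precision is `NA` (not 0) when no positive guesses were made.
#' Train and test sets should have equal sample counts -- the attack's
#' 0.5-precision baseline assumes it -- and a warning is issued otherwise.
#'
#' @param train,test,gen [binary_dataset()]s over identical variables.
#' @param thresholds integer vector of Hamming distances (default `0:10`).
#' @return a data frame of class `attack_result` with columns `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `precision`, `sensitivity`.
#' @export
membership_attack <- function(train, test, gen, thresholds = 0:10) {
  for (d in list(test, gen)) {
    if (!identical(train$variable_names, d$variable_names)) {
      stopf("membership attack requires identical variables in train, test and gen",
            class = "boltzgen_validation_error")
    }
  }
  if (n_samples(train) != n_samples(test)) {
    warning(sprintf(
      "train (%d) and test (%d) sample counts differ; precision baseline shifts",
      n_samples(train), n_samples(test)))
  }
  thresholds <- sort(unique(as.integer(thresholds)))
  if (any(thresholds < 0L)) {
    stopf("thresholds must be nonnegative", class = "boltzgen_validation_error")
  }
  d_train <- min_hamming(train$values, gen$values)
  d_test <- min_hamming(test$values, gen$values)
  out <- lapply(thresholds, function(t) {
    tp <- sum(d_train <= t)
    fn <- n_samples(train) - tp
    fp <- sum(d_test <= t)
    tn <- n_samples(test) - fp
    data.frame(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
               precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
               sensitivity = tp / (tp + fn))
  })
  structure(do.call(rbind, out), class = c("attack_result", "data.frame"))
}

# Minimum Hamming distance from each row of `x` to any row of `gen`,
# via the identity |a - b|_1 = sum(a) + sum(b) - 2 a.b for binary vectors.
min_hamming <- function(x, gen) {
  cross <- tcrossprod(x, gen)
  d <- outer(rowSums(x), rowSums(gen), `+`) - 2 * cross
  apply(d, 1L, min)
}
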