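test_that("log odds ratios apply the 0.5 continuity correction to zero cells", {
  # pairs (1,1),(1,1),(0,0),(1,0): n11=2, n10=1, n01=0 -> 0.5, n00=1
  d <- binary_dataset(rbind(c(1, 1), c(1, 1), c(0, 0), c(1, 0)))
  lor <- log_odds_ratio_matrix(d)
  expect_equal(lor$values[2, 1], log(4))
  expect_equal(lor$values[1, 2], lor$values[2, 1])
  expect_true(is.na(lor$values[1, 1]))

  indep <- binary_dataset(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(log_odds_ratio_matrix(indep)$values[2, 1], 0)

  # odds ratios depend on the cross-table proportions only (no zero cells)
  doubled <- binary_dataset(rbind(indep$values, indep$values))
  expect_equal(log_odds_ratio_matrix(doubled)$values,
               log_odds_ratio_matrix(indep)$values)

  expect_error(log_odds_ratio_matrix(binary_dataset(matrix(1, 3, 1))),
               class = "boltzgen_validation_error")
})

test_that("the log-odds distance is a lower-triangle RMSE with exact small cases", {
  d <- simulate_iid_bernoulli(30, rep(0.4, 5), seed = 1)
  expect_equal(odds_ratio_distance(d, d), 0)

  a <- binary_dataset(rbind(c(1, 1), c(1, 1), c(0, 0), c(1, 0)))  # log OR = log 4
  b <- binary_dataset(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))        # log OR = 0
  expect_equal(odds_ratio_distance(a, b), log(4))

  mismatched <- binary_dataset(d$values, variable_names = paste0("x", 1:5))
  err <- tryCatch(odds_ratio_distance(d, mismatched), error = identity)
  expect_s3_class(err, "boltzgen_validation_error")
  expect_match(conditionMessage(err), "x1")
})

test_that("the distance equals a naive all-pairs reference implementation", {
  naive_d <- function(x, y) {
    lor1 <- function(v) {
      k <- ncol(v)
      out <- matrix(0, k, k)
      for (i in 1:k) for (j in 1:k) {
        if (i == j) next
        n11 <- sum(v[, i] == 1 & v[, j] == 1)
        n10 <- sum(v[, i] == 1 & v[, j] == 0)
        n01 <- sum(v[, i] == 0 & v[, j] == 1)
        n00 <- sum(v[, i] == 0 & v[, j] == 0)
        cc <- function(n) if (n == 0) 0.5 else n
        out[i, j] <- log(cc(n11) * cc(n00) / (cc(n10) * cc(n01)))
      }
      out
    }
    a <- lor1(x); b <- lor1(y)
    sqrt(mean((a[lower.tri(a)] - b[lower.tri(b)])^2))
  }
  for (s in 1:10) {
    x <- simulate_iid_bernoulli(25, runif(6, 0.2, 0.8), seed = 2 * s)
    y <- simulate_iid_bernoulli(25, runif(6, 0.2, 0.8), seed = 2 * s + 1)
    expect_equal(odds_ratio_distance(x, y), naive_d(x$values, y$values))
  }
  # symmetry and row-order invariance
  x <- simulate_iid_bernoulli(40, rep(0.5, 4), seed = 99)
  y <- simulate_iid_bernoulli(40, rep(0.3, 4), seed = 98)
  expect_equal(odds_ratio_distance(x, y), odds_ratio_distance(y, x))
  xs <- binary_dataset(x$values[40:1, ], x$sample_ids[40:1], x$variable_names)
  expect_equal(odds_ratio_distance(xs, y), odds_ratio_distance(x, y))
})

test_that("the proportion of overfitting follows its defining ratio", {
  # craft datasets with known distances through direct substitution checks
  gen <- binary_dataset(rbind(c(1, 1), c(1, 1), c(0, 0), c(1, 0)))
  train <- gen                                   # d(gen, train) = 0
  val <- binary_dataset(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(overfitting_proportion(gen, train, val), 1)  # (d - 0) / d
  expect_equal(overfitting_proportion(gen, val, val), 0)
  # farther from training (log OR gap log 4) than validation (gap log 2)
  halfway <- binary_dataset(rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1),
                                  c(0, 0)))  # single log OR = log 2
  expect_lt(overfitting_proportion(val, gen, halfway), 0)
  expect_error(overfitting_proportion(gen, train, gen),
               class = "boltzgen_degenerate_error")
})

test_that("the overfitting proportion never exceeds one", {
  for (s in 1:5) {
    gen <- simulate_iid_bernoulli(30, runif(4, 0.2, 0.8), seed = 3 * s)
    tr <- simulate_iid_bernoulli(30, runif(4, 0.2, 0.8), seed = 3 * s + 1)
    va <- simulate_iid_bernoulli(30, runif(4, 0.2, 0.8), seed = 3 * s + 2)
    expect_lte(overfitting_proportion(gen, tr, va), 1)
  }
})

test_that("the membership attack counts the hand-enumerated toy cases", {
  train <- binary_dataset(matrix(c(0, 0, 0), 1), "t1", c("a", "b", "c"))
  test_d <- binary_dataset(matrix(c(1, 1, 1), 1), "p1", c("a", "b", "c"))
  gen <- binary_dataset(matrix(c(0, 0, 1), 1), "g1", c("a", "b", "c"))
  res <- membership_attack(train, test_d, gen, thresholds = 0:1)
  expect_equal(res$tp, c(0L, 1L))
  expect_equal(res$fn, c(1L, 0L))
  expect_equal(res$fp, c(0L, 0L))
  expect_equal(res$sensitivity, c(0, 1))
  expect_equal(res$precision, c(NA_real_, 1))
})

test_that("exact-copy and saturation attacks behave as expected", {
  train <- simulate_iid_bernoulli(50, rep(0.5, 20), seed = 20)
  test_d <- simulate_iid_bernoulli(50, rep(0.5, 20), seed = 21)
  # at 20 variables and 100 samples the two sets are almost surely disjoint;
  # verify rather than assume
  stopifnot(min(boltzgen:::min_hamming(test_d$values, train$values)) > 0)
  copy <- membership_attack(train, test_d, train, thresholds = 0L)
  expect_equal(copy$sensitivity, 1)
  expect_equal(copy$fp, 0L)
  expect_equal(copy$precision, 1)

  sat <- membership_attack(train, test_d, train, thresholds = 20L)
  expect_equal(sat$sensitivity, 1)
  expect_equal(sat$precision, 0.5)
})

test_that("attack sensitivity is monotone and confusion totals are conserved", {
  train <- simulate_iid_bernoulli(80, rep(0.3, 10), seed = 22)
  test_d <- simulate_iid_bernoulli(80, rep(0.3, 10), seed = 23)
  gen <- simulate_iid_bernoulli(80, rep(0.3, 10), seed = 24)
  res <- membership_attack(train, test_d, gen, thresholds = 0:10)
  expect_true(all(diff(res$sensitivity) >= 0))
  expect_true(all(res$tp + res$fn == 80L))
  expect_true(all(res$tn + res$fp == 80L))

  uneq <- simulate_iid_bernoulli(40, rep(0.3, 10), seed = 25)
  expect_warning(membership_attack(train, uneq, gen, 0:2), "differ")
})
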