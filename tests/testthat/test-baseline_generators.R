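test_that("independent marginals store exactly the column frequencies", {
  d <- binary_dataset(cbind(rep(1, 4), c(1, 0, 1, 0)))
  m <- fit_im(d)
  expect_equal(unname(m$frequencies), c(1, 0.5))
  shuffled <- binary_dataset(d$values[4:1, ], d$sample_ids[4:1],
                             d$variable_names)
  expect_equal(fit_im(shuffled)$frequencies, m$frequencies)
  expect_error(fit_im(binary_dataset(matrix(0, 0, 2))),
               class = "boltzgen_validation_error")
})

test_that("IM samples recover marginals and have no pairwise association", {
  m <- structure(list(frequencies = c(1, 0.3, 0.7, 0.5),
                      variable_names = paste0("v", 1:4)),
                 class = "im_model")
  s <- sample_im(m, 100000, seed = 2)
  expect_true(all(s$values[, 1] == 1))
  expect_equal(mean(s$values[, 2]), 0.3, tolerance = 0.005 / 0.3)
  lor <- log_odds_ratio_matrix(binary_dataset(s$values[, 2:4]))$values
  expect_lt(abs(median(lor[lower.tri(lor)])), 0.05)

  # 3-sigma marginal recovery for every variable
  train <- simulate_iid_bernoulli(400, c(0.1, 0.25, 0.5, 0.8), seed = 3)
  fitted <- fit_im(train)
  gen <- sample_im(fitted, 5000, seed = 4)
  f <- fitted$frequencies
  expect_true(all(abs(colMeans(gen$values) - f) <
                    3 * sqrt(f * (1 - f) / 5000) + 1e-9))
})

test_that("MICE handles constant outcomes and permanent collinearity drops", {
  withr::with_seed(10, {
    a <- rbinom(200, 1, 0.5)
    d <- binary_dataset(cbind(a = a, b = a, c = a, noise = rbinom(200, 1, 0.4),
                              const = rep(1, 200)))
  })
  # seed 5 orders the three duplicates first, then the non-constant target,
  # so both later copies are offered (and rejected) as predictors there
  m <- fit_mice(d, seed = 5)
  expect_equal(m$order, c(2L, 3L, 1L, 4L, 5L))
  const_pos <- which(m$order == 5L)
  rec <- m$regressions[[const_pos]]
  expect_equal(rec$type, "constant")
  expect_equal(rec$value, 1)
  expect_null(rec$coefficients)
  # of the three identical columns, only the first in the order serves as a
  # predictor; later copies are dropped permanently
  dup_order <- intersect(m$order, 1:3)
  expect_setequal(intersect(m$dropped, 1:3), dup_order[-1L])
  for (pos in 2:5) {
    rec <- m$regressions[[pos]]
    if (!is.null(rec) && rec$type == "regression") {
      expect_length(intersect(rec$predictors, dup_order[-1L]), 0)
      expect_length(intersect(rec$predictors, m$dropped), 0)
    }
  }
  expect_error(fit_mice(binary_dataset(matrix(0:1, 4, 1))),
               class = "boltzgen_validation_error")
})

test_that("MICE recovers the parameters of a noisy copy relationship", {
  # v2 = v1 with 5% flips: p(v2=1|v1=1) = 0.95, p(v2=1|v1=0) = 0.05
  structure_def <- list(
    list(intercept = 0, coefficients = numeric()),
    list(intercept = stats::qlogis(0.05),
         coefficients = stats::qlogis(0.95) - stats::qlogis(0.05)))
  d <- simulate_logistic_chain(50000, structure_def, seed = 5)
  m <- fit_mice(d, seed = identity_order_seed(2))
  rec <- m$regressions[[2L]]
  expect_equal(rec$predictors, 1L)
  expect_gt(rec$coefficients, 0)
  p11 <- stats::plogis(rec$intercept + rec$coefficients)
  expect_equal(p11, 0.95, tolerance = 0.03 / 0.95)
  # marginal symmetry keeps the intercept near logit(0.05)
  expect_equal(rec$intercept, stats::qlogis(0.05), tolerance = 0.1)
})

test_that("MICE sampling respects constants, association sign and independence", {
  const_model <- structure(list(
    order = c(2L, 1L), first_prob = 1,
    regressions = list(NULL, list(target = 1L, type = "constant", value = 0)),
    dropped = integer(), variable_names = c("x", "y")), class = "mice_model")
  s <- sample_mice(const_model, 50, seed = 1)
  expect_equal(unname(s$values), cbind(rep(0, 50), rep(1, 50)))

  pos_model <- structure(list(
    order = 1:2, first_prob = 0.5,
    regressions = list(NULL, list(target = 2L, type = "regression",
                                  predictors = 1L, coefficients = 2,
                                  intercept = -1)),
    dropped = integer(), variable_names = c("x", "y")), class = "mice_model")
  s2 <- sample_mice(pos_model, 50000, seed = 2)
  lor <- log_odds_ratio_matrix(s2)$values
  expect_gt(lor[2, 1], 0)
  expect_equal(lor[2, 1], 2, tolerance = 0.1)

  # independent training data stays independent after fit + sample
  train <- simulate_iid_bernoulli(2000, rep(0.4, 5), seed = 6)
  gen <- sample_mice(fit_mice(train, seed = 3), 50000, seed = 4)
  lor2 <- log_odds_ratio_matrix(gen)$values
  expect_lt(max(abs(lor2[lower.tri(lor2)])), 0.1)
})

test_that("fit + sample recovers the pairwise log odds of a logistic chain", {
  structure_def <- list(
    list(intercept = 0, coefficients = numeric()),
    list(intercept = -0.5, coefficients = 1.5),
    list(intercept = -1, coefficients = c(1, 0.8)))
  train <- simulate_logistic_chain(50000, structure_def, seed = 7)
  gen <- sample_mice(fit_mice(train, seed = 8), 50000, seed = 9)
  lor_train <- log_odds_ratio_matrix(train)$values
  lor_gen <- log_odds_ratio_matrix(gen)$values
  expect_lt(max(abs(lor_train[lower.tri(lor_train)] -
                      lor_gen[lower.tri(lor_gen)])), 0.1)
})

test_that("every generator type satisfies the common fit/sample contract", {
  train <- simulate_iid_bernoulli(60, rep(0.4, 6), seed = 10)
  for (type in c("im", "mice", "rbm", "dbm")) {
    spec <- generator_spec(type, train_config(
      epochs = 2L, epochspretraining = 2L, nhiddens = c(4L, 2L), seed = 1L),
      burnin = 5L)
    model <- fit_generator(spec, train, seed = 11)
    g <- generate_samples(model, 17, seed = 12)
    expect_s3_class(g, "binary_dataset")
    expect_equal(n_samples(g), 17L)
    expect_equal(g$variable_names, train$variable_names)
    expect_equal(generate_samples(model, 17, seed = 12), g)
  }
})
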