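test_that("energy matches the bilinear form by hand evaluation", {
  m <- rbm(matrix(2), 1, -1)
  expect_equal(energy(m, 1, 1), -2)
  z <- zero_rbm(3, 2)
  expect_equal(energy(z, c(1, 0, 1), c(1, 1)), 0)
  r <- random_rbm(3, 2, seed = 11)
  expect_equal(energy(r, c(0, 0, 0), c(0, 0)), 0)
  expect_error(energy(r, c(1, 0), c(0, 0)),
               class = "boltzgen_validation_error")
})

test_that("enumerated joint probabilities normalize and match the conditionals", {
  m <- random_rbm(3, 2, sd = 0.8, seed = 2)
  joint <- oracle_rbm_joint(m)
  expect_equal(sum(joint$probs), 1, tolerance = 1e-10)

  # p(h_j = 1 | v) from the enumerated joint vs the analytic formula
  for (i in seq_len(nrow(joint$vs))) {
    v <- joint$vs[i, ]
    pv <- sum(joint$probs[i, ])
    ph_joint <- colSums(joint$probs[i, ] * joint$hs) / pv
    expect_equal(hidden_conditional(m, v), ph_joint, tolerance = 1e-10)
  }
  m2 <- random_rbm(2, 3, sd = 0.8, seed = 3)
  joint2 <- oracle_rbm_joint(m2)
  for (j in seq_len(nrow(joint2$hs))) {
    h <- joint2$hs[j, ]
    ph <- sum(joint2$probs[, j])
    pv_joint <- colSums(joint2$probs[, j] * joint2$vs) / ph
    expect_equal(visible_conditional(m2, h), pv_joint, tolerance = 1e-10)
  }
})

test_that("conditionals respect symmetry, saturation and the zero model", {
  z <- zero_rbm(4, 3)
  expect_equal(hidden_conditional(z, c(1, 0, 1, 0)), rep(0.5, 3))
  expect_equal(visible_conditional(z, c(1, 1, 0)), rep(0.5, 4))

  sat <- rbm(matrix(0, 2, 2), c(0, 0), c(50, -50))
  expect_equal(hidden_conditional(sat, c(0, 0)), c(1, 0), tolerance = 1e-15)

  m <- random_rbm(3, 2, seed = 4)
  flipped <- rbm(t(m$weights), m$hidden_bias, m$visible_bias)
  v <- c(1, 0, 1)
  expect_equal(hidden_conditional(m, v), visible_conditional(flipped, v))
})

test_that("contrastive divergence learns a point mass and is seed-reproducible", {
  data <- point_mass_data(200, 6)
  cfg <- train_config(epochs = 20L, learningrate = 0.1, nhiddens = 4L,
                      seed = 7L)
  fit <- fit_rbm(data, cfg)
  samples <- gibbs_sample(fit$rbm, 500, burnin = 30, seed = 1)
  expect_true(all(colMeans(samples$values) > 0.9))

  fit2 <- fit_rbm(data, cfg)
  expect_identical(fit$rbm, fit2$rbm)
})

test_that("reconstruction error is monitored and decreases on learnable data", {
  data <- blocked_data(n = 120, n_variables = 8)
  cfg <- train_config(epochs = 25L, learningrate = 0.2, nhiddens = 4L,
                      seed = 3L)
  fit <- fit_rbm(data, cfg, monitor = "reconstruction_error")
  rec <- subset(fit$monitoring, metric == "reconstruction_error" &
                  partition == "train")
  expect_equal(nrow(rec), 25L)
  expect_lt(rec$value[25L], rec$value[1L])
})

test_that("reconstruction error has its closed form for the zero model", {
  z <- zero_rbm(5, 3)
  d <- simulate_iid_bernoulli(40, rep(0.3, 5), seed = 6)
  expect_equal(reconstruction_error(z, d), 5 * 0.25)
  shuffled <- binary_dataset(d$values[40:1, ], d$sample_ids[40:1],
                             d$variable_names)
  expect_equal(reconstruction_error(z, shuffled), reconstruction_error(z, d))
  expect_error(reconstruction_error(z, simulate_iid_bernoulli(5, rep(0.5, 3))),
               class = "boltzgen_validation_error")
})

test_that("CD training with different seeds reaches similar reconstruction", {
  data <- blocked_data(n = 120, n_variables = 8)
  errs <- vapply(c(3L, 23L), function(s) {
    cfg <- train_config(epochs = 30L, learningrate = 0.2, nhiddens = 4L,
                        seed = s)
    reconstruction_error(fit_rbm(data, cfg)$rbm, data)
  }, numeric(1))
  expect_lt(abs(errs[1] - errs[2]) / max(errs), 0.2)
})

test_that("Gibbs sampling has the uniform stationary law for the zero model", {
  z <- zero_rbm(3, 2)
  s <- gibbs_sample(z, 10000, burnin = 5, seed = 2)
  expect_true(all(abs(colMeans(s$values) - 0.5) < 0.02))
})

test_that("clamped Gibbs sampling fixes the clamped columns exactly", {
  m <- random_rbm(4, 3, seed = 5)
  s <- gibbs_sample(m, 200, burnin = 10, clamped = c("1" = 1, "3" = 0),
                    seed = 3)
  expect_true(all(s$values[, 1] == 1))
  expect_true(all(s$values[, 3] == 0))
  expect_error(gibbs_sample(m, 10, clamped = c("9" = 1)),
               class = "boltzgen_validation_error")
})

test_that("long Gibbs chains reproduce the enumerated marginal p(v)", {
  m <- random_rbm(2, 2, sd = 0.8, seed = 9)
  target <- oracle_rbm_marginal_v(m)
  s <- gibbs_sample(m, 50000, burnin = 30, seed = 4)
  emp <- empirical_state_probs(s$values)
  expect_lt(sum(abs(emp - target)) / 2, 0.01)  # total variation
})

test_that("the analytic hidden-sum collapse equals full-state enumeration", {
  m <- random_rbm(3, 2, sd = 0.9, seed = 12)
  expect_equal(exact_log_partition(m), oracle_rbm_joint(m)$log_z,
               tolerance = 1e-10)
  z <- zero_rbm(4, 3)
  expect_equal(exact_log_partition(z), 7 * log(2))
  # shifting all visible biases by c moves log Z by the closed-form amount
  cshift <- 0.7
  shifted <- rbm(z$weights, rep(cshift, 4), z$hidden_bias)
  expect_equal(exact_log_partition(shifted) - exact_log_partition(z),
               4 * log((1 + exp(cshift)) / 2), tolerance = 1e-10)
  expect_equal(exact_log_partition(shifted), oracle_rbm_joint(shifted)$log_z,
               tolerance = 1e-10)
  big <- zero_rbm(20, 10)
  expect_error(exact_log_partition(big), class = "boltzgen_size_error")
})
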