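test_that("a single-layer stack is trained exactly like fit_rbm", {
  data <- blocked_data(n = 60, n_variables = 6)
  cfg <- train_config(epochs = 5L, epochspretraining = 5L,
                      learningrate = 0.05, learningratepretraining = 0.05,
                      nhiddens = 3L, seed = 21L)
  stack <- pretrain_stack(data, list(layer_config(
    3L, learningratepretraining = 0.05, epochspretraining = 5L)), seed = 21L)
  direct <- fit_rbm(data, train_config(epochs = 5L, learningrate = 0.05,
                                       nhiddens = 3L, seed = 21L))$rbm
  expect_equal(stack[[1L]]$weights, direct$weights)
  expect_equal(stack[[1L]]$visible_bias, direct$visible_bias)

  # and converting it loses nothing
  model <- stack_to_dbm(stack)
  expect_equal(model$layer_weights[[1L]], direct$weights)
  expect_equal(model$biases[[1L]], direct$visible_bias)
  expect_equal(model$biases[[2L]], direct$hidden_bias)
  expect_error(pretrain_stack(data, list()),
               class = "boltzgen_validation_error")
})

test_that("a two-layer stack has chained dimensions and is seed-reproducible", {
  sim <- simulate_snp_sets(snp_sim_config(n_samples = 100L, seed = 5L))
  layers <- list(layer_config(50L, epochspretraining = 2L),
                 layer_config(10L, epochspretraining = 2L))
  stack <- pretrain_stack(sim$data, layers, seed = 8L)
  expect_equal(dim(stack[[1L]]$weights), c(50L, 50L))
  expect_equal(dim(stack[[2L]]$weights), c(50L, 10L))
  model <- stack_to_dbm(stack)
  expect_equal(unname(vapply(model$biases, length, integer(1))),
               c(50L, 50L, 10L))
  stack2 <- pretrain_stack(sim$data, layers, seed = 8L)
  expect_identical(stack, stack2)
})

test_that("fine-tuning with zero epochs returns the converted stack unchanged", {
  data <- blocked_data(n = 60, n_variables = 6)
  stack <- pretrain_stack(data, list(layer_config(4L, epochspretraining = 3L),
                                     layer_config(2L, epochspretraining = 3L)),
                          seed = 2L)
  cfg <- train_config(epochs = 0L, nhiddens = c(4L, 2L), seed = 2L)
  expect_equal(finetune_dbm(stack, data, cfg), stack_to_dbm(stack))
})

test_that("fine-tuning does not degrade the variational bound on a point mass", {
  data <- point_mass_data(100, 5)
  cfg0 <- train_config(epochs = 0L, epochspretraining = 15L,
                       learningratepretraining = 0.05,
                       nhiddens = c(4L, 3L), seed = 4L)
  cfg <- train_config(epochs = 15L, epochspretraining = 15L,
                      learningrate = 0.05, learningratepretraining = 0.05,
                      nhiddens = c(4L, 3L), seed = 4L)
  pre <- fit_dbm(data, cfg0)$dbm
  post <- fit_dbm(data, cfg)$dbm
  ac <- ais_config(60L, 60L, seed = 10L)
  b_pre <- dbm_logproblowerbound(pre, data, ac)
  b_post <- dbm_logproblowerbound(post, data, ac)
  mc_error <- 3 * (b_pre$std_error + b_post$std_error) + 0.05
  expect_gt(b_post$value, b_pre$value - mc_error)

  # determinism of the full pipeline
  post2 <- fit_dbm(data, cfg)$dbm
  expect_identical(post, post2)
})

test_that("fit_dbm validates its architecture and monitoring contract", {
  data <- blocked_data(n = 40, n_variables = 6)
  expect_error(fit_dbm(data, train_config(nhiddens = integer())),
               class = "boltzgen_validation_error")
  fit <- fit_dbm(data, train_config(epochs = 2L, epochspretraining = 2L,
                                    nhiddens = c(3L, 2L), seed = 1L))
  expect_equal(nrow(fit$monitoring), 0L)
  fit2 <- fit_dbm(data, train_config(epochs = 2L, epochspretraining = 3L,
                                     nhiddens = c(3L, 2L), seed = 1L),
                  monitor = "reconstruction_error")
  rec <- subset(fit2$monitoring, metric == "reconstruction_error")
  expect_equal(rec$epoch, 1:3)
})

test_that("mean-field inference reduces to the RBM conditional and to 0.5", {
  z <- zero_dbm(c(3, 2, 2))
  mu <- mean_field_inference(z, c(1, 0, 1))
  expect_equal(mu, list(c(0.5, 0.5), c(0.5, 0.5)))

  one <- random_dbm(c(4, 3), sd = 0.6, seed = 6)
  as_rbm <- rbm(one$layer_weights[[1L]], one$biases[[1L]], one$biases[[2L]])
  v <- c(1, 0, 1, 1)
  expect_equal(mean_field_inference(one, v)[[1L]],
               hidden_conditional(as_rbm, v))
})

test_that("mean-field means approximate exact posterior marginals when coupling is weak", {
  m <- random_dbm(c(3, 2, 2), sd = 0.25, seed = 7)
  joint <- oracle_dbm_joint(m)
  v <- c(1, 0, 1)
  keep <- apply(joint$grids[[1L]][joint$idx[, 1L], , drop = FALSE], 1L,
                function(r) all(r == v))
  w <- joint$probs[keep] / sum(joint$probs[keep])
  post1 <- colSums(joint$grids[[2L]][joint$idx[keep, 2L], , drop = FALSE] * w)
  post2 <- colSums(joint$grids[[3L]][joint$idx[keep, 3L], , drop = FALSE] * w)
  mu <- mean_field_inference(m, v, max_iters = 100L)
  expect_true(all(abs(mu[[1L]] - post1) < 0.05))
  expect_true(all(abs(mu[[2L]] - post2) < 0.05))
})

test_that("DBM Gibbs sampling matches the enumerated visible marginal", {
  z <- zero_dbm(c(3, 2, 2))
  s <- dbm_gibbs_sample(z, 10000, burnin = 5, seed = 3)
  expect_true(all(abs(colMeans(s$values) - 0.5) < 0.02))

  m <- random_dbm(c(2, 2, 2), sd = 0.7, seed = 8)
  target <- oracle_dbm_marginal_v(m)
  s2 <- dbm_gibbs_sample(m, 40000, burnin = 40, seed = 5)
  emp <- empirical_state_probs(s2$values)
  expect_lt(sum(abs(emp - target$p)) / 2, 0.02)

  clamped <- dbm_gibbs_sample(m, 300, burnin = 10, clamped = c("2" = 1),
                              seed = 6)
  expect_true(all(clamped$values[, 2] == 1))
  expect_error(dbm_gibbs_sample(m, 10, clamped = c("5" = 1)),
               class = "boltzgen_validation_error")
})

test_that("the layered joint normalizes under the collapsed enumeration", {
  m <- random_dbm(c(2, 2, 2), sd = 0.6, seed = 9)
  joint <- oracle_dbm_joint(m)
  expect_equal(sum(joint$probs), 1, tolerance = 1e-10)
  expect_equal(exact_log_partition(m), joint$log_z, tolerance = 1e-10)
})

test_that("the 2-D latent representation separates cases from controls", {
  z <- zero_dbm(c(4, 3, 2))
  d <- simulate_iid_bernoulli(5, rep(0.5, 4), seed = 1)
  top <- top2_latent_dims(z, d)
  expect_equal(unname(top), matrix(0.5, 5, 2))
  expect_true(all(top >= 0 & top <= 1))

  wrong <- zero_dbm(c(4, 3))
  expect_error(top2_latent_dims(wrong, d), class = "boltzgen_contract_error")

  sim <- simulate_snp_sets(snp_sim_config(seed = 13L))
  cfg <- train_config(nhiddens = c(20L, 2L), seed = 2L)
  model <- fit_dbm(sim$data, cfg)$dbm
  emb <- top2_latent_dims(model, sim$data)
  case_mean <- colMeans(emb[sim$labels == "case", ])
  control_mean <- colMeans(emb[sim$labels == "control", ])
  expect_gt(max(abs(case_mean - control_mean)), 0.05)
})
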