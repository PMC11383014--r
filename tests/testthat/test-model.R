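test_that("initialization has the documented shapes and is seed-deterministic", {
  cfg <- model_config(n_protein_factors = 8, n_sample_factors = 6,
                      n_hidden_layers = 2, n_nodes_per_layer = 16, seed = 1)
  m <- init_model(cfg, n_proteins = 40, n_samples = 25)
  expect_equal(dim(m$W), c(40L, 8L))
  expect_equal(dim(m$H), c(6L, 25L))
  expect_equal(dim(m$layers[[1]]$W), c(14L, 16L))
  expect_equal(dim(m$layers[[2]]$W), c(16L, 16L))
  expect_equal(dim(m$layers[[3]]$W), c(16L, 1L))
  expect_true(all(is.finite(c(m$W, m$H,
                              unlist(lapply(m$layers, function(l) c(l$W, l$b)))))))
  m2 <- init_model(cfg, 40, 25)
  expect_identical(m, m2)
})

test_that("zeroed perceptron predicts zero everywhere", {
  cfg <- model_config(n_protein_factors = 4, n_sample_factors = 4,
                      n_hidden_layers = 1, n_nodes_per_layer = 8, seed = 2)
  m <- init_model(cfg, 10, 10)
  m$layers <- lapply(m$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(predict_matrix(m), matrix(0, 10, 10))
})

test_that("a hand-set linear model matches pencil-and-paper arithmetic", {
  W <- matrix(c(1, 2,
                3, 4), 2, 2, byrow = TRUE)
  H <- matrix(c(0.5, -1,
                2.0, 0), 2, 2, byrow = TRUE)
  w <- c(1, -1, 2, 0.5)
  m <- linear_model(W, H, w, b = 0.25)
  # entry (1, 2): concat(W[1,], H[,2]) = (1, 2, -1, 0)
  expect_equal(predict_entry(m, 1, 2), 1 * 1 + 2 * -1 + -1 * 2 + 0 * 0.5 + 0.25)
  # entry (2, 1): concat(W[2,], H[,1]) = (3, 4, 0.5, 2)
  expect_equal(predict_entry(m, 2, 1), 3 * 1 + 4 * -1 + 0.5 * 2 + 2 * 0.5 + 0.25)
  expect_error(predict_entry(m, 3, 1), "out of range")
})

test_that("batched prediction agrees with per-entry calls", {
  cfg <- model_config(n_protein_factors = 5, n_sample_factors = 3,
                      n_hidden_layers = 2, n_nodes_per_layer = 7, seed = 3)
  m <- init_model(cfg, 12, 9)
  full <- predict_matrix(m)
  for (k in 1:10) {
    i <- ((k * 5) %% 12) + 1L
    j <- ((k * 3) %% 9) + 1L
    expect_equal(full[i, j], predict_entry(m, i, j))
  }
})

test_that("tolerance criterion fires at exactly the 10th qualifying epoch", {
  cfg <- model_config()
  h <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5, rep(0.5, 10))
  # 9 qualifying epochs: not yet
  expect_false(check_convergence(h[1:15], cfg)$stop)
  res <- check_convergence(h[1:16], cfg)
  expect_true(res$stop)
  expect_equal(res$reason, "tolerance")
})

test_that("rank-sum criterion fires on a rising history with the exact", {
  cfg <- model_config()
  h <- c(0.300, 0.295, 0.292, 0.291, 0.290,
         0.288, 0.400, 0.410, 0.420, 0.430,
         0.440, 0.450, 0.460, 0.470, 0.480)
  for (k in 2:14) expect_false(check_convergence(h[1:k], cfg)$stop)
  res <- check_convergence(h, cfg)
  expect_true(res$stop)
  expect_equal(res$reason, "wilcoxon")
  # complete separation of the two 5-epoch windows: p = 1 / choose(10, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))
})

test_that("a strictly improving history never stops", {
  cfg <- model_config()
  h <- 1 * 0.9^(0:30)   # 10% relative improvement per epoch
  for (k in 2:31) expect_false(check_convergence(h[1:k], cfg)$stop)
})

test_that("a monotone-increasing history of length >= 15 always stops", {
  cfg <- model_config()
  h <- seq(1, 2, length.out = 20)
  stopped <- FALSE
  for (k in 2:20) {
    if (check_convergence(h[1:k], cfg)$stop) { stopped <- TRUE; break }
  }
  expect_true(stopped)
  expect_lte(k, 15)
})

test_that("training drives a noiseless rank-1 matrix to near-zero MSE", {
  qm <- rank1_qm(30, 20)
  masks <- mnar_partition(qm, partition_params(bernoulli_p = 0.2, seed = 4))
  masks <- mcar_validation_split(masks, 0.1, seed = 5)
  cfg <- model_config(n_protein_factors = 8, n_sample_factors = 8,
                      n_hidden_layers = 1, n_nodes_per_layer = 32,
                      learning_rate = 0.01, batch_size = 32,
                      max_epochs = 200, seed = 6)
  fit <- train_model(NULL, qm, masks, config = cfg)
  expect_lt(min(fit$log$train_mse), 1e-2)
  expect_equal(length(fit$log$train_mse), fit$log$epochs_run)
  expect_equal(length(fit$log$val_mse), fit$log$epochs_run)
  expect_true(all(is.finite(c(fit$log$train_mse, fit$log$val_mse))))
})

test_that("training is bit-reproducible given the seed", {
  qm <- rank1_qm(20, 15, seed = 8)
  masks <- mnar_partition(qm, partition_params(bernoulli_p = 0.2, seed = 9))
  masks <- mcar_validation_split(masks, 0.1, seed = 10)
  cfg <- model_config(n_protein_factors = 4, n_sample_factors = 4,
                      n_hidden_layers = 1, n_nodes_per_layer = 8,
                      max_epochs = 12, seed = 11)
  f1 <- train_model(NULL, qm, masks, config = cfg)
  f2 <- train_model(NULL, qm, masks, config = cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$W, f2$model$W)
})

test_that("one small Adam step on a fixed batch decreases the batch loss", {
  qm <- rank1_qm(15, 10, seed = 12)
  cfg <- model_config(n_protein_factors = 4, n_sample_factors = 4,
                      n_hidden_layers = 1, n_nodes_per_layer = 8,
                      learning_rate = 1e-3, seed = 13)
  model <- init_model(cfg, 15, 10)
  i <- rep(1:15, 2)
  j <- rep(1:10, 3)
  y <- qm$values[cbind(i, j)]
  g <- lupine:::mlp_gradients(model, i, j, y)
  pars <- lupine:::model_params(model)
  st <- lupine:::adam_init(pars)
  upd <- lupine:::adam_step(pars, g$grads, st, cfg$learning_rate)
  model2 <- lupine:::set_model_params(model, upd$params)
  loss2 <- mean((predict_entries(model2, i, j) - y)^2)
  expect_lt(loss2, g$loss)
})

test_that("impute_matrix completes missing entries and keeps observed ones", {
  qm <- tiny_qm(6, 5, missing = 6, seed = 14)
  pred <- matrix(99, 6, 5)
  done <- impute_matrix(qm, pred)
  expect_equal(missing_fraction(done), 0)
  obs <- !is.na(qm$values)
  expect_identical(done$values[obs], qm$values[obs])
  expect_true(all(done$values[!obs] == 99))
  # reconstruction mode replaces everything
  recon <- impute_matrix(qm, pred, keep_observed = FALSE)
  expect_true(all(recon$values == 99))
  # complete input is the identity under keep_observed
  full <- tiny_qm(4, 4, missing = 0, seed = 15)
  expect_identical(impute_matrix(full, matrix(0, 4, 4))$values, full$values)
  # non-finite predictions at missing positions are rejected
  bad <- pred
  bad[is.na(qm$values)][1] <- NaN
  expect_error(impute_matrix(qm, bad), "non-finite")
})
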