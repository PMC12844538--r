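# Splitting, metrics, training loop behavior and the tiny-overfit sanity run.

test_that("8:1:1 splits have the documented sizes", {
  sp <- split_dataset(1:1280, seed = 3)
  expect_length(sp$train_ids, 1024L)
  expect_length(sp$val_ids, 128L)
  expect_length(sp$test_ids, 128L)

  sp10 <- split_dataset(1:10, seed = 3)
  expect_identical(lengths(sp10[c("train_ids", "val_ids", "test_ids")]),
                   c(train_ids = 8L, val_ids = 1L, test_ids = 1L))

  expect_identical(split_dataset(1:50, seed = 9), split_dataset(1:50, seed = 9))
  expect_error(split_dataset(1:2, seed = 1), class = "museeg_error_too_few_ids")
})

test_that("splits partition the ids exhaustively and disjointly", {
  set.seed(808)
  for (i in 1:50) {
    n <- sample(3:300, 1)
    ids <- sample(letters, n, replace = TRUE)
    ids <- paste0(ids, seq_len(n))  # unique ids
    sp <- split_dataset(ids, seed = i)
    all_back <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_setequal(all_back, ids)
    expect_identical(length(all_back), n)
    expect_length(intersect(sp$train_ids, sp$val_ids), 0L)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_length(intersect(sp$val_ids, sp$test_ids), 0L)
  }
})

test_that("metrics reproduce hand-computed values", {
  pred <- cbind(c(3, 3), c(3, 3))
  truth <- cbind(c(2, 4), c(2, 4))
  m <- evaluate_metrics(pred, truth)
  expect_equal(m$pooled$mae, 1)
  expect_equal(m$pooled$mape, 37.5)
  expect_equal(m$pooled$r2, 0)
  expect_equal(m$valence$mae, 1)

  # perfect predictions
  y <- cbind(runif(5, 1, 9), runif(5, 1, 9))
  mp <- evaluate_metrics(y, y)
  expect_equal(mp$pooled$mae, 0)
  expect_equal(mp$pooled$mape, 0)
  expect_equal(mp$pooled$r2, 1)

  # constant prediction at the truth mean has R2 = 0 per target
  truth2 <- cbind(c(2, 4, 6), c(1, 5, 9))
  const <- cbind(rep(4, 3), rep(5, 3))
  m0 <- evaluate_metrics(const, truth2)
  expect_equal(m0$valence$r2, 0)
  expect_equal(m0$arousal$r2, 0)
})

test_that("metrics agree with independent formulas on random data", {
  set.seed(909)
  for (i in 1:500) {
    n <- sample(2:40, 1)
    truth <- matrix(runif(2 * n, 1, 9), n, 2)
    pred <- truth + matrix(rnorm(2 * n), n, 2)
    m <- evaluate_metrics(pred, truth)
    x <- as.vector(pred); y <- as.vector(truth)
    expect_equal(m$pooled$mae, sum(abs(y - x)) / (2 * n), tolerance = 1e-9)
    expect_equal(m$pooled$mape, 100 / (2 * n) * sum(abs((y - x) / y)),
                 tolerance = 1e-9)
    expect_equal(m$pooled$r2,
                 1 - sum((y - x)^2) / sum((y - mean(y))^2), tolerance = 1e-9)
  }
})

test_that("degenerate metric inputs raise structured errors", {
  expect_error(evaluate_metrics(cbind(1:3, 1:3), cbind(c(0, 1, 2), 1:3)),
               class = "museeg_error_zero_truth")
  expect_error(evaluate_metrics(cbind(1:3, 1:3), cbind(rep(2, 3), 1:3)),
               class = "museeg_error_degenerate_truth")
})

# Small real pipeline run shared by the training-behavior tests: 24 trials,
# 4 s each, no rating noise, arousal planted in Fp1/Fp2.
overfit_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_synth_config(n_subjects = 2L, n_trials = 12L, seed = 21L,
                               noise_sd = 0,
                               signal_channels = c("Fp1", "Fp2"))
      cache <<- prepare_fusion_data(generate_dataset(cfg),
                                    tiny_fusion_config())
    }
    cache
  }
})

test_that("a noise-free 16-trial set is overfit to MAE < 0.3", {
  prep <- overfit_prep()
  tensors <- museeg:::apply_scaler(prep, museeg:::fit_scaler(prep, 1:16))
  cfg <- tiny_fusion_config(dropout = 0)
  model <- build_fusion_model(cfg, ncol(tensors$features),
                              nrow(tensors$audio[[1]]),
                              nrow(tensors$psd[[1]]), seed = 31L)
  # train == val: early stopping then tracks the training loss itself
  fit <- train_fusion(model, tensors, 1:16, 1:16, max_epochs = 500L,
                      patience = 500L, seed = 32L)
  expect_lt(min(fit$history$train_loss), 0.3)
})

test_that("training is reproducible and honors the early-stopping contract", {
  prep <- overfit_prep()
  tensors <- museeg:::apply_scaler(prep, museeg:::fit_scaler(prep, 1:12))
  cfg <- tiny_fusion_config()
  run_once <- function() {
    model <- build_fusion_model(cfg, ncol(tensors$features),
                                nrow(tensors$audio[[1]]),
                                nrow(tensors$psd[[1]]), seed = 41L)
    train_fusion(model, tensors, 1:12, 13:16, max_epochs = 40L,
                 patience = 5L, seed = 42L)
  }
  fit1 <- run_once()
  fit2 <- run_once()
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$best_val, fit2$best_val)

  # returned weights are those of the best validation epoch
  expect_equal(fit1$best_val, min(fit1$history$val_loss))
  expect_equal(fit1$history$val_loss[fit1$best_epoch], fit1$best_val)
  pred <- museeg:::predict_in_chunks(fit1$model, tensors, 13:16,
                                     seq_len(ncol(tensors$features)), TRUE)
  expect_equal(mean(abs(pred - tensors$labels[13:16, ])), fit1$best_val,
               tolerance = 1e-12)

  # stopping happens within patience epochs of the best one
  expect_lte(nrow(fit1$history), fit1$best_epoch + 5L)
})

test_that("non-finite losses abort with diagnostics", {
  prep <- overfit_prep()
  tensors <- museeg:::apply_scaler(prep, museeg:::fit_scaler(prep, 1:16))
  cfg <- tiny_fusion_config(dropout = 0)
  model <- build_fusion_model(cfg, ncol(tensors$features),
                              nrow(tensors$audio[[1]]),
                              nrow(tensors$psd[[1]]), seed = 51L)
  # a divergent learning rate overflows the forward pass within a few
  # epochs; the abort is a structured museeg condition either way the
  # non-finiteness is first detected (branch output or loss)
  expect_error(
    train_fusion(model, tensors, 1:16, 1:16, lr = 1e200, max_epochs = 50L,
                 patience = 50L, seed = 52L),
    class = "museeg_error")
})

test_that("attribution rejects the EEG-less ablation model", {
  prep <- overfit_prep()
  run <- run_experiment(prep, tiny_fusion_config(), seed = 6L,
                        model = "ablation", max_epochs = 2L)
  expect_error(attribute_channels(run), class = "museeg_error_no_eeg_branch")
})

test_that("attribution scores vanish on all-zero inputs", {
  prep <- overfit_prep()
  run <- run_experiment(prep, tiny_fusion_config(), seed = 6L,
                        model = "full", max_epochs = 2L)
  zero <- run
  nt <- nrow(zero$tensors$features)
  zero$tensors$features <- zero$tensors$features * 0
  zero$tensors$audio <- lapply(zero$tensors$audio, function(m) m * 0)
  zero$tensors$psd <- lapply(zero$tensors$psd, function(m) m * 0)
  rep <- attribute_channels(zero, method = "gradient_input")
  expect_true(all(rep$channel_scores == 0))
  # occluding channels of an all-zero input changes nothing either
  rep2 <- attribute_channels(zero, method = "occlusion")
  expect_true(all(rep2$channel_scores == 0))
})
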