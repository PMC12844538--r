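# Architecture contracts of the three-branch fusion regressor.

test_that("config validation rejects malformed architectures", {
  expect_error(fusion_config(output_dim = 3L), class = "museeg_error_bad_config")
  expect_error(fusion_config(dropout = 1), class = "museeg_error_bad_config")
  expect_error(fusion_config(conv_filters = 0L),
               class = "museeg_error_bad_config")
  expect_error(fusion_config(conv_filters = 8L, dw_filters = 12L),
               class = "museeg_error_bad_config")
})

test_that("CNN branch maps a 32 x 7680 input to two outputs", {
  cfg <- fusion_config()
  br <- build_cnn_branch(cfg, in_channels = 32L, in_length = 7680L)
  params <- with_seed_test(1, museeg:::branch_init(br))
  out <- museeg:::branch_forward(br, params,
                                 list(matrix(rnorm(32 * 7680), 7680, 32)))$out
  expect_identical(dim(out), c(1L, 2L))
  expect_true(all(is.finite(out)))
})

test_that("short CNN inputs fail at build time with the minimum length", {
  cfg <- fusion_config()
  err <- expect_error(build_cnn_branch(cfg, 1L, 50L),
                      class = "museeg_error_input_too_short")
  expect_equal(err$minimum_length, cnn_min_length(cfg))
  expect_match(conditionMessage(err), as.character(cnn_min_length(cfg)))
})

test_that("zero weights reduce both branch types to their output biases", {
  cfg <- tiny_fusion_config()
  zero_params <- function(params) {
    lapply(params, function(p) {
      if (is.null(p)) return(NULL)
      lapply(p, function(a) a * 0)
    })
  }
  br <- build_cnn_branch(cfg, 1L, 64L)
  params <- zero_params(with_seed_test(1, museeg:::branch_init(br)))
  params[[length(params)]]$b <- c(3, 4)
  out <- museeg:::branch_forward(br, params, list(cbind(rnorm(64))))$out
  expect_equal(as.vector(out), c(3, 4))

  mlp <- build_mlp_branch(cfg, input_dim = 12L)
  mp <- zero_params(with_seed_test(1, museeg:::branch_init(mlp)))
  mp[[length(mp)]]$b <- c(-1, 2)
  out2 <- museeg:::branch_forward(mlp, mp, matrix(rnorm(36), 3, 12))$out
  expect_equal(out2, cbind(rep(-1, 3), rep(2, 3)))
})

test_that("parameter counts match closed-form layer arithmetic", {
  cfg <- fusion_config()
  d <- 910L; La <- 7680L; Le <- 129L
  model <- build_fusion_model(cfg, d, La, Le, seed = 3L)

  mlp_count <- (d * 1000 + 1000) + (1000 * 1000 + 1000) + (1000 * 2 + 2)
  cnn_count <- function(cin, L) {
    Lp <- L %/% 4L
    (9 * cin * 8 + 8) +          # conv, 8 filters, kernel 9
      (32 * 1 * 16 + 16) +       # depthwise to 16 channels, kernel 32
      (26 * 1 * 16 + 16) +       # depthwise, kernel 26
      (1 * 16 * 16 + 16) +       # pointwise
      (16 * Lp * 200 + 200) +    # dense to 200
      (200 * 2 + 2)              # dense to 2
  }
  expect_identical(n_params(model),
                   mlp_count + cnn_count(1L, La) + cnn_count(32L, Le))

  abl <- build_ablation_model(cfg, 590L, La, seed = 3L)
  mlp_abl <- (590 * 1000 + 1000) + (1000 * 1000 + 1000) + (1000 * 2 + 2)
  expect_identical(n_params(abl), mlp_abl + cnn_count(1L, La))

  # removing the EEG branch from the full model removes exactly its count
  full_same_mlp <- build_fusion_model(cfg, 590L, La, Le, seed = 3L)
  expect_identical(n_params(full_same_mlp) - n_params(abl), cnn_count(32L, Le))
})

test_that("fusion is elementwise addition with optional clipping", {
  expect_equal(fuse_outputs(c(1, 1), c(2, 2), c(3, 3)), c(6, 6))
  x <- c(2.5, -1)
  expect_equal(fuse_outputs(x, c(0, 0), c(0, 0)), x)
  expect_equal(fuse_outputs(c(10, 0.2), c(1, 0.2), c(1, 0.1), clip = TRUE),
               c(9, 1))
  err <- expect_error(fuse_outputs(c(1, NaN), c(0, 0), c(0, 0)),
                      class = "museeg_error_nonfinite_branch")
  expect_match(conditionMessage(err), "mlp")
  err2 <- expect_error(fuse_outputs(c(1, 1), c(0, 0), c(Inf, 0)),
                       class = "museeg_error_nonfinite_branch")
  expect_match(conditionMessage(err2), "cnn_eeg")
})

make_tiny_batch <- function(n, d, La, Le, nch, seed = 1) {
  with_seed_test(seed, list(
    features = matrix(rnorm(n * d), n, d),
    audio = lapply(seq_len(n), function(i) cbind(rnorm(La))),
    psd = lapply(seq_len(n), function(i) matrix(rnorm(Le * nch), Le, nch))))
}

test_that("the ablation model never reads EEG input", {
  cfg <- tiny_fusion_config(eeg_channels = 4L)
  abl <- build_ablation_model(cfg, 12L, 64L, seed = 5L)
  b1 <- make_tiny_batch(3, 12, 64, 20, 4, seed = 1)
  b2 <- b1
  b2$psd <- lapply(b2$psd, function(m) matrix(rnorm(length(m)), nrow(m)))
  expect_identical(predict(abl, b1), predict(abl, b2))
})

test_that("evaluation-mode forward passes are deterministic", {
  cfg <- tiny_fusion_config(eeg_channels = 4L)
  model <- build_fusion_model(cfg, 12L, 64L, 20L, seed = 6L)
  b <- make_tiny_batch(3, 12, 64, 20, 4)
  expect_identical(predict(model, b), predict(model, b))
})

test_that("a final-bias perturbation shifts the fused output by exactly delta", {
  cfg <- tiny_fusion_config(eeg_channels = 4L)
  model <- build_fusion_model(cfg, 12L, 64L, 20L, seed = 7L)
  b <- make_tiny_batch(4, 12, 64, 20, 4)
  base <- predict(model, b)
  delta <- c(0.25, -0.5)
  nl <- length(model$params$audio)
  model$params$audio[[nl]]$b <- model$params$audio[[nl]]$b + delta
  shifted <- predict(model, b)
  expect_equal(shifted - base,
               matrix(delta, 4, 2, byrow = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("every trainable tensor receives gradient from the MAE loss", {
  cfg <- tiny_fusion_config(eeg_channels = 4L)
  model <- build_fusion_model(cfg, 12L, 64L, 20L, seed = 8L)
  b <- make_tiny_batch(4, 12, 64, 20, 4, seed = 9)
  y <- matrix(rnorm(8, 5), 4, 2)
  grads <- with_seed_test(10, {
    fw <- museeg:::model_forward(model, b, training = TRUE)
    dout <- sign(fw$pred - y) / length(y)
    museeg:::model_backward(model, fw, dout)$grads
  })
  for (nm in names(model$branches)) {
    for (i in seq_along(grads[[nm]])) {
      if (is.null(grads[[nm]][[i]])) next
      for (g in grads[[nm]][[i]]) {
        expect_gt(sum(abs(g)), 0)
      }
    }
  }
})

test_that("branch gradients match finite differences", {
  set.seed(11)
  cfg <- tiny_fusion_config(dropout = 0)
  br <- build_cnn_branch(cfg, 2L, 16L)
  params <- museeg:::branch_init(br)
  x <- list(matrix(rnorm(32), 16, 2), matrix(rnorm(32), 16, 2))
  y <- matrix(rnorm(4), 2, 2)
  lossfn <- function(p) {
    mean(abs(museeg:::branch_forward(br, p, x)$out - y))
  }
  fw <- museeg:::branch_forward(br, params, x)
  bk <- museeg:::branch_backward(br, params, fw,
                                 sign(fw$out - y) / length(y),
                                 input_grad = TRUE)
  eps <- 1e-6
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      arr <- params[[i]][[nm]]
      for (j in sample(length(arr), min(6L, length(arr)))) {
        p2 <- params; p2[[i]][[nm]][j] <- p2[[i]][[nm]][j] + eps
        p3 <- params; p3[[i]][[nm]][j] <- p3[[i]][[nm]][j] - eps
        fd <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
        expect_equal(bk$grads[[i]][[nm]][j], fd, tolerance = 1e-5)
      }
    }
  }
  # input gradients, used by channel attribution
  g_in <- bk$dx_inputs[[1]]
  for (j in sample(32L, 6L)) {
    x2 <- x; x2[[1]][j] <- x2[[1]][j] + eps
    x3 <- x; x3[[1]][j] <- x3[[1]][j] - eps
    fd <- (mean(abs(museeg:::branch_forward(br, params, x2)$out - y)) -
             mean(abs(museeg:::branch_forward(br, params, x3)$out - y))) /
      (2 * eps)
    expect_equal(g_in[j], fd, tolerance = 1e-5)
  }
})
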