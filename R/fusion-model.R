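# Three-branch fusion regressor: an MLP on tabular features plus two compact
# 1-D CNN branches (raw audio waveform; per-channel EEG PSD treated as
# 32-channel sequences over frequency). The three length-2 branch outputs are
# summed into the (valence, arousal) prediction.

#' Architectural configuration of the fusion model
#'
#' Collects every architectural hyperparameter in one validated record.
#' The CNN branch is three blocks: (1) 1-D convolution with `conv_filters`
#' filters of size `conv_kernel`, depthwise convolution widening to
#' `dw_filters` channels with kernel `dw_kernel`, ELU, average pooling by
#' `pool_factor`, dropout; (2) depthwise convolution with kernel
#' `dw2_kernel` followed by a pointwise (kernel-1) convolution and ELU;
#' (3) flatten and two dense layers (`fc_intermediate` then `output_dim`).
#' The depthwise "16 filters" after an 8-channel layer is realized as depth
#' multiplier 2.
#'
#' @param mlp_input_dim MLP input width; `NULL` (default) means "computed
#'   from the composed feature vector" at build time. The width can be
#'   overridden explicitly (e.g. to 1278) for feature compositions other
#'   than the package default of 590 timbre + 320 band-peak = 910.
#' @param mlp_hidden sizes of the two hidden MLP layers.
#' @param conv_filters,conv_kernel first ordinary convolution.
#' @param dw_filters,dw_kernel first depthwise convolution (depth
#'   multiplier `dw_filters / conv_filters`).
#' @param pool_factor average-pooling factor.
#' @param dropout dropout rate in `[0, 1)` after the first block.
#' @param dw2_kernel second-block depthwise kernel size.
#' @param pointwise_filters channels out of the pointwise convolution.
#' @param fc_intermediate width of the intermediate dense layer.
#' @param output_dim number of regression targets (valence, arousal).
#' @param audio_branch_rate sample rate (Hz) the waveform branch input is
#'   resampled to. The branch models envelope-scale temporal structure; the
#'   64 Hz default keeps the flattened layer (and the training cost of its
#'   dense head) desk-scale.
#' @param eeg_channels number of EEG channels expected by the PSD branch.
#' @param use_eeg_features_in_mlp feed band-peak EEG features to the MLP
#'   alongside the timbre features (default `TRUE`).
#' @param clip_outputs clip fused predictions to the `[1, 9]` rating scale
#'   (off by default: metrics are computed on raw sums).
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(mlp_input_dim = NULL,
                          mlp_hidden = c(1000L, 1000L),
                          conv_filters = 8L, conv_kernel = 9L,
                          dw_filters = 16L, dw_kernel = 32L,
                          pool_factor = 4L, dropout = 0.5,
                          dw2_kernel = 26L, pointwise_filters = 16L,
                          fc_intermediate = 200L, output_dim = 2L,
                          audio_branch_rate = 64,
                          eeg_channels = 32L,
                          use_eeg_features_in_mlp = TRUE,
                          clip_outputs = FALSE) {
  cfg <- list(mlp_input_dim = mlp_input_dim, mlp_hidden = as.integer(mlp_hidden),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              dw_filters = as.integer(dw_filters),
              dw_kernel = as.integer(dw_kernel),
              pool_factor = as.integer(pool_factor), dropout = dropout,
              dw2_kernel = as.integer(dw2_kernel),
              pointwise_filters = as.integer(pointwise_filters),
              fc_intermediate = as.integer(fc_intermediate),
              output_dim = as.integer(output_dim),
              audio_branch_rate = audio_branch_rate,
              eeg_channels = as.integer(eeg_channels),
              use_eeg_features_in_mlp = isTRUE(use_eeg_features_in_mlp),
              clip_outputs = isTRUE(clip_outputs))
  counts <- cfg[c("conv_filters", "conv_kernel", "dw_filters", "dw_kernel",
                  "pool_factor", "dw2_kernel", "pointwise_filters",
                  "fc_intermediate", "output_dim", "eeg_channels")]
  if (!all(vapply(counts, function(v) is_count(v), logical(1)))) {
    abort_museeg("all filter/kernel/width settings must be positive integers",
                 "museeg_error_bad_config")
  }
  if (cfg$output_dim != 2L) {
    abort_museeg("output_dim must be 2 (valence, arousal)",
                 "museeg_error_bad_config")
  }
  if (!is_scalar_number(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1) {
    abort_museeg("dropout must lie in [0, 1)", "museeg_error_bad_config")
  }
  if (cfg$dw_filters %% cfg$conv_filters != 0L) {
    abort_museeg("dw_filters must be a multiple of conv_filters (depth multiplier)",
                 "museeg_error_bad_config")
  }
  structure(cfg, class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  cat(sprintf("  MLP: d -> %s -> %d\n",
              paste(x$mlp_hidden, collapse = " -> "), x$output_dim))
  cat(sprintf("  CNN: conv(%d,k%d) dw(%d,k%d) elu pool(%d) drop(%.2f) dw(k%d) pw(%d) elu fc(%d) fc(%d)\n",
              x$conv_filters, x$conv_kernel, x$dw_filters, x$dw_kernel,
              x$pool_factor, x$dropout, x$dw2_kernel, x$pointwise_filters,
              x$fc_intermediate, x$output_dim))
  invisible(x)
}

#' Minimum input length of the CNN branch
#'
#' The sequence must survive the first-block kernels and leave at least one
#' second-block receptive field after pooling.
#'
#' @param config a [fusion_config()].
#' @return minimum number of input samples.
#' @export
cnn_min_length <- function(config) {
  max(config$dw_kernel, config$pool_factor * config$dw2_kernel)
}

#' Build one CNN branch
#'
#' Composition: conv(`conv_filters`, `conv_kernel`) -> depthwise conv(to
#' `dw_filters` channels, `dw_kernel`) -> ELU -> average pool
#' (`pool_factor`) -> dropout -> depthwise conv(`dw2_kernel`) -> pointwise
#' conv -> ELU -> flatten -> dense(`fc_intermediate`) -> dense(2). All
#' convolutions use "same" padding so short inputs survive the large
#' kernels.
#'
#' @param config a [fusion_config()].
#' @param in_channels input channels (1 for audio, 32 for EEG PSD).
#' @param in_length input sequence length.
#' @param name branch label used in diagnostics.
#' @return a branch object; weights are created when the branch is
#'   assembled into a model by [build_fusion_model()].
#' @export
build_cnn_branch <- function(config, in_channels, in_length,
                             name = "cnn") {
  stopifnot(inherits(config, "fusion_config"))
  min_len <- cnn_min_length(config)
  if (in_length < min_len) {
    abort_museeg(
      sprintf("CNN branch input length %d too short: minimum is %d samples",
              in_length, min_len),
      "museeg_error_input_too_short", minimum_length = min_len)
  }
  mult <- config$dw_filters %/% config$conv_filters
  Lp <- in_length %/% config$pool_factor
  layers <- list(
    nn_conv(in_channels, config$conv_filters, config$conv_kernel, groups = 1L),
    nn_conv(config$conv_filters, config$conv_filters * mult, config$dw_kernel,
            groups = config$conv_filters),
    nn_elu(),
    nn_pool(config$pool_factor),
    nn_dropout(config$dropout),
    nn_conv(config$dw_filters, config$dw_filters, config$dw2_kernel,
            groups = config$dw_filters),
    nn_conv(config$dw_filters, config$pointwise_filters, 1L, groups = 1L),
    nn_elu(),
    nn_flatten(),
    nn_dense(config$pointwise_filters * Lp, config$fc_intermediate),
    nn_dense(config$fc_intermediate, config$output_dim)
  )
  br <- new_branch(layers, name)
  br$in_channels <- in_channels
  br$in_length <- in_length
  br
}

#' Build the MLP branch
#'
#' dense(`input_dim` -> hidden1) -> ELU -> dense(hidden1 -> hidden2) -> ELU
#' -> dense(hidden2 -> 2).
#'
#' @param config a [fusion_config()].
#' @param input_dim feature-vector width; defaults to
#'   `config$mlp_input_dim`.
#' @return a branch object.
#' @export
build_mlp_branch <- function(config, input_dim = config$mlp_input_dim) {
  stopifnot(inherits(config, "fusion_config"))
  if (!is_count(input_dim)) {
    abort_museeg("mlp input_dim must be a positive integer",
                 "museeg_error_bad_config")
  }
  h <- config$mlp_hidden
  layers <- list(
    nn_dense(as.integer(input_dim), h[1L]), nn_elu(),
    nn_dense(h[1L], h[2L]), nn_elu(),
    nn_dense(h[2L], config$output_dim)
  )
  br <- new_branch(layers, "mlp")
  br$in_dim <- as.integer(input_dim)
  br
}

#' Build the full three-branch fusion model
#'
#' @param config a [fusion_config()].
#' @param mlp_input_dim width of the tabular feature vector.
#' @param audio_length samples in the waveform branch input.
#' @param eeg_length frequency bins in the PSD branch input.
#' @param seed optional seed for weight initialization (restores the
#'   caller's RNG state afterwards).
#' @return object of class `fusion_model` with branches `mlp`, `audio`,
#'   `eeg` and their parameters.
#' @export
build_fusion_model <- function(config, mlp_input_dim, audio_length,
                               eeg_length, seed = NULL) {
  branches <- list(
    mlp = build_mlp_branch(config, mlp_input_dim),
    audio = build_cnn_branch(config, 1L, as.integer(audio_length), "audio"),
    eeg = build_cnn_branch(config, config$eeg_channels,
                           as.integer(eeg_length), "eeg")
  )
  init <- function() lapply(branches, branch_init)
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(list(config = config, branches = branches, params = params),
            class = "fusion_model")
}

#' Build the EEG-off ablation model
#'
#' Audio-only control: the MLP consumes the timbre features and the CNN the
#' audio waveform; no parameter in the model touches any EEG input, so its
#' forward pass is bit-identical whatever EEG data accompany the batch.
#'
#' @inheritParams build_fusion_model
#' @return object of class `c("ablation_model", "fusion_model")` with
#'   branches `mlp` and `audio` only.
#' @export
build_ablation_model <- function(config, mlp_input_dim, audio_length,
                                 seed = NULL) {
  branches <- list(
    mlp = build_mlp_branch(config, mlp_input_dim),
    audio = build_cnn_branch(config, 1L, as.integer(audio_length), "audio")
  )
  init <- function() lapply(branches, branch_init)
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(list(config = config, branches = branches, params = params),
            class = c("ablation_model", "fusion_model"))
}

#' Total trainable parameter count
#'
#' @param model a [build_fusion_model()] or [build_ablation_model()] result.
#' @return number of scalar weights and biases.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  sum(vapply(model$params, branch_n_params, numeric(1)))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<%s: branches [%s], %s parameters>\n",
              class(x)[1L], paste(names(x$branches), collapse = ", "),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Fuse branch outputs by elementwise addition
#'
#' @param mlp_out,cnn_audio_out,cnn_eeg_out length-2 numeric vectors (one
#'   prediction) or B x 2 matrices; `cnn_eeg_out` may be `NULL` for the
#'   ablation model.
#' @param clip clip the sum to the `[1, 9]` rating scale.
#' @return the elementwise sum, same shape as the inputs.
#' @export
fuse_outputs <- function(mlp_out, cnn_audio_out, cnn_eeg_out = NULL,
                         clip = FALSE) {
  parts <- list(mlp = mlp_out, cnn_audio = cnn_audio_out,
                cnn_eeg = cnn_eeg_out)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    if (is.null(p)) next
    if (!all(is.finite(p))) {
      abort_museeg(sprintf("non-finite output from branch '%s'", nm),
                   "museeg_error_nonfinite_branch", branch = nm)
    }
  }
  out <- mlp_out + cnn_audio_out
  if (!is.null(cnn_eeg_out)) out <- out + cnn_eeg_out
  if (clip) out <- pmin(pmax(out, 1), 9)
  out
}

# Forward pass over a prepared batch. `batch` is a list with `features`
# (B x d matrix), `audio` (list of L x 1 matrices) and, for the full model,
# `psd` (list of n_freqs x n_channels matrices).
model_forward <- function(model, batch, training = FALSE) {
  fws <- list()
  outs <- list()
  for (nm in names(model$branches)) {
    x <- switch(nm, mlp = batch$features, audio = batch$audio,
                eeg = batch$psd)
    fw <- branch_forward(model$branches[[nm]], model$params[[nm]], x,
                         training)
    fws[[nm]] <- fw
    outs[[nm]] <- fw$out
  }
  pred <- fuse_outputs(outs$mlp, outs$audio, outs$eeg,
                       clip = FALSE)
  list(pred = pred, fws = fws)
}

# Backward pass; dout is B x 2 on the fused output (shared by all branches
# since fusion is additive). Returns per-branch gradients and, optionally,
# gradients w.r.t. the branch inputs.
model_backward <- function(model, fw, dout, input_grad = FALSE) {
  grads <- list()
  dx <- list()
  for (nm in names(model$branches)) {
    bk <- branch_backward(model$branches[[nm]], model$params[[nm]],
                          fw$fws[[nm]], dout, input_grad = input_grad)
    grads[[nm]] <- bk$grads
    if (input_grad) dx[[nm]] <- bk$dx_inputs
  }
  list(grads = grads, dx = dx)
}

#' Predict valence and arousal for a prepared batch
#'
#' @param object a `fusion_model`.
#' @param batch prepared inputs as produced by [prepare_fusion_data()]
#'   slicing (`features`, `audio`, and `psd` for the full model).
#' @param ... unused.
#' @return B x 2 matrix with columns `valence`, `arousal`; clipped to
#'   `[1, 9]` when the config enables `clip_outputs`.
#' @export
predict.fusion_model <- function(object, batch, ...) {
  out <- model_forward(object, batch, training = FALSE)$pred
  if (object$config$clip_outputs) out <- pmin(pmax(out, 1), 9)
  colnames(out) <- c("valence", "arousal")
  out
}
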