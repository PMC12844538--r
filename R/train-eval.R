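# Dataset splitting, feature preparation, training with early stopping,
# regression metrics, the EEG-off ablation and per-channel attribution.

#' Random 8:1:1 train/validation/test split
#'
#' Permutes the ids under the seed and partitions them by the given ratios.
#' Validation and test sizes are `floor(n * r / sum(ratios))` (at least 1
#' each); the remainder goes to the training set.
#'
#' @param ids vector of trial identifiers (or indices).
#' @param ratios length-3 numeric ratios (train, validation, test).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return object of class `dataset_split` with fields `train_ids`,
#'   `val_ids`, `test_ids` and `seed`.
#' @examples
#' sp <- split_dataset(1:1280, seed = 7)
#' lengths(sp[c("train_ids", "val_ids", "test_ids")])  # 1024, 128, 128
#' @export
split_dataset <- function(ids, ratios = c(8, 1, 1), seed = 1L) {
  if (length(ids) < length(ratios)) {
    abort_museeg(
      sprintf("need at least %d ids to form %d partitions, got %d",
              length(ratios), length(ratios), length(ids)),
      "museeg_error_too_few_ids")
  }
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  n <- length(ids)
  perm <- with_seed(seed, sample(ids))
  n_val <- max(1L, floor(n * ratios[2L] / sum(ratios)))
  n_test <- max(1L, floor(n * ratios[3L] / sum(ratios)))
  n_train <- n - n_val - n_test
  structure(
    list(train_ids = perm[seq_len(n_train)],
         val_ids = perm[n_train + seq_len(n_val)],
         test_ids = perm[n_train + n_val + seq_len(n_test)],
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train / %d val / %d test (seed %d)>\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              x$seed))
  invisible(x)
}

#' Extract model inputs for every trial of a dataset
#'
#' Runs the full feature pipeline per trial: timbre features from 1 s / 50%
#' windows (MLP input), the waveform resampled to the branch rate (audio CNN
#' input), and band-limited Welch PSD with band-peak features (EEG CNN and
#' MLP inputs). PSD magnitudes enter the CNN on a log10 scale.
#'
#' @param examples a `trial_dataset` (or any list of `trial_example`s).
#' @param config a [fusion_config()].
#' @param verbose print progress every 20 trials.
#' @return object of class `fusion_data`: feature matrix, waveform matrix,
#'   PSD array, label matrix and a column-layout record.
#' @export
prepare_fusion_data <- function(examples, config = fusion_config(),
                                verbose = FALSE) {
  n <- length(examples)
  stopifnot(n >= 1L)
  bands <- eeg_bands()
  feats <- NULL; audio <- NULL; psd_arr <- NULL
  labels <- matrix(NA_real_, n, 2L,
                   dimnames = list(NULL, c("valence", "arousal")))
  channel_names <- NULL
  for (i in seq_len(n)) {
    ex <- examples[[i]]
    tr <- trial_audio(ex)
    tf <- track_features(tr)
    fa <- feature_vector(tf)
    wav <- resample_track(tr, config$audio_branch_rate)$samples
    eeg <- bandpass_filter(trial_eeg(ex))
    psd <- compute_psd(eeg)
    fe <- feature_vector(band_peak_features(psd, bands))
    lp <- t(log10(psd$power + 1e-12))  # n_freqs x n_channels
    if (is.null(feats)) {
      channel_names <- psd$channel_names
      feats <- matrix(NA_real_, n, length(fa) + length(fe))
      audio <- matrix(NA_real_, n, length(wav))
      psd_arr <- array(NA_real_, c(n, nrow(lp), ncol(lp)))
      layout <- list(
        n_audio_feat = length(fa), n_eeg_feat = length(fe),
        audio_cols = seq_along(fa),
        eeg_cols = length(fa) + seq_along(fe),
        eeg_channel_cols = stats::setNames(lapply(seq_along(channel_names),
          function(c) length(fa) + (c - 1L) * 2L * nrow(bands) +
            seq_len(2L * nrow(bands))), channel_names),
        channel_names = channel_names, bands = bands)
    }
    feats[i, ] <- c(fa, fe)
    audio[i, ] <- wav
    psd_arr[i, , ] <- lp
    labels[i, ] <- c(ex$valence, ex$arousal)
    if (verbose && i %% 20L == 0L) {
      message(sprintf("prepared %d/%d trials", i, n))
    }
  }
  structure(
    list(features = feats, audio = audio, psd = psd_arr, labels = labels,
         layout = layout, config = config),
    class = "fusion_data"
  )
}

# ---- standardization --------------------------------------------------------

fit_scaler <- function(data, idx) {
  safe_sd <- function(s) ifelse(is.finite(s) & s > 0, s, 1)
  pm <- apply(data$psd[idx, , , drop = FALSE], c(2L, 3L), mean)
  ps <- safe_sd(apply(data$psd[idx, , , drop = FALSE], c(2L, 3L), sd))
  list(feat_mean = colMeans(data$features[idx, , drop = FALSE]),
       feat_sd = safe_sd(apply(data$features[idx, , drop = FALSE], 2L, sd)),
       audio_mean = mean(data$audio[idx, ]),
       audio_sd = safe_sd(sd(as.vector(data$audio[idx, ]))),
       psd_mean = pm, psd_sd = ps)
}

# Standardize and convert to per-example tensors ready for the model.
apply_scaler <- function(data, scaler) {
  n <- nrow(data$features)
  feats <- sweep(sweep(data$features, 2L, scaler$feat_mean), 2L,
                 scaler$feat_sd, "/")
  audio_std <- (data$audio - scaler$audio_mean) / scaler$audio_sd
  audio_list <- lapply(seq_len(n), function(i) cbind(audio_std[i, ]))
  psd_list <- lapply(seq_len(n), function(i) {
    (data$psd[i, , ] - scaler$psd_mean) / scaler$psd_sd
  })
  list(features = feats, audio = audio_list, psd = psd_list,
       labels = data$labels, layout = data$layout)
}

# Assemble the model inputs for a set of row indices.
slice_batch <- function(tensors, idx, mlp_cols, include_eeg) {
  list(features = tensors$features[idx, mlp_cols, drop = FALSE],
       audio = tensors$audio[idx],
       psd = if (include_eeg) tensors$psd[idx] else NULL)
}

# ---- training ---------------------------------------------------------------

#' Train a fusion model with early stopping
#'
#' Adam on the mean-absolute-error loss. After every epoch the validation
#' MAE is computed in evaluation mode; the weights of the best validation
#' epoch are kept, and training stops once `patience` epochs pass without
#' improvement. All randomness (batch order, dropout) flows from `seed`.
#'
#' @param model a [build_fusion_model()] or [build_ablation_model()] result.
#' @param tensors standardized tensors from [apply_scaler()] (created for
#'   you by [run_experiment()]).
#' @param train_idx,val_idx row indices of the training and validation sets.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed for shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return object of class `fusion_fit`: the model with best-epoch weights,
#'   a per-epoch `history` data.frame and the best epoch index.
#' @export
train_fusion <- function(model, tensors, train_idx, val_idx,
                         lr = 2e-3, batch_size = 16L, max_epochs = 250L,
                         patience = 20L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"),
            length(train_idx) >= 1L, length(val_idx) >= 1L)
  include_eeg <- "eeg" %in% names(model$branches)
  mlp_cols <- model$mlp_cols %||% seq_len(model$branches$mlp$in_dim)
  y <- tensors$labels
  states <- lapply(model$params, adam_init)
  t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- model$params
  best_epoch <- 0L
  val_loss_of <- function() {
    pred <- predict_in_chunks(model, tensors, val_idx, mlp_cols, include_eeg)
    mean(abs(pred - y[val_idx, , drop = FALSE]))
  }
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(train_idx)
      n_batches <- ceiling(length(perm) / batch_size)
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * batch_size + 1L):
                      min(bi * batch_size, length(perm))]
        batch <- slice_batch(tensors, idx, mlp_cols, include_eeg)
        fw <- model_forward(model, batch, training = TRUE)
        err <- fw$pred - y[idx, , drop = FALSE]
        loss <- mean(abs(err))
        if (!is.finite(loss)) {
          abort_museeg(
            sprintf("non-finite training loss at epoch %d batch %d", epoch, bi),
            "museeg_error_nonfinite_loss", epoch = epoch, batch = bi)
        }
        epoch_loss <- epoch_loss + loss * length(idx)
        dout <- sign(err) / length(err)
        grads <- model_backward(model, fw, dout)$grads
        t_step <- t_step + 1L
        for (nm in names(model$branches)) {
          upd <- adam_step(model$params[[nm]], grads[[nm]], states[[nm]],
                           lr, t_step)
          model$params[[nm]] <- upd$params
          states[[nm]] <- upd$state
        }
      }
      train_loss <- epoch_loss / length(perm)
      val_loss <- val_loss_of()
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        train_loss, val_loss))
      }
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- model$params
        best_epoch <- epoch
      } else if (epoch - best_epoch >= patience) {
        break
      }
    }
  })
  model$params <- best_params
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 best_val = best_val, seed = as.integer(seed)),
            class = "fusion_fit")
}

predict_in_chunks <- function(model, tensors, idx, mlp_cols, include_eeg,
                              chunk = 64L) {
  out <- matrix(NA_real_, length(idx), model$config$output_dim)
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    batch <- slice_batch(tensors, idx[s:e], mlp_cols, include_eeg)
    out[s:e, ] <- model_forward(model, batch, training = FALSE)$pred
  }
  out
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("<fusion_fit: best epoch %d of %d, val MAE %.4f>\n",
              x$best_epoch, nrow(x$history), x$best_val))
  invisible(x)
}

# ---- metrics ----------------------------------------------------------------

metric_triple <- function(pred, truth) {
  if (any(truth == 0)) {
    abort_museeg("MAPE undefined: truth contains zeros (ratings live in [1, 9])",
                 "museeg_error_zero_truth")
  }
  err <- pred - truth
  sstot <- sum((truth - mean(truth))^2)
  if (sstot == 0) {
    abort_museeg("R-squared undefined: all truth values identical",
                 "museeg_error_degenerate_truth")
  }
  list(mae = mean(abs(err)),
       mape = 100 * mean(abs(err / truth)),
       r2 = 1 - sum(err^2) / sstot,
       n = length(truth))
}

#' Regression metrics for paired (valence, arousal) predictions
#'
#' MAE `= (1/n) sum |y - x|`, MAPE `= (100/n) sum |(y - x)/y|` and
#' `R^2 = 1 - sum (y - x)^2 / sum (y - ybar)^2`, computed pooled over the
#' concatenation of both targets and per target separately.
#'
#' @param predictions n x 2 matrix (valence, arousal).
#' @param truths n x 2 matrix of ground-truth ratings.
#' @return object of class `metrics_report` with elements `pooled`,
#'   `valence`, `arousal`, each a list `(mae, mape, r2, n)`.
#' @examples
#' m <- evaluate_metrics(cbind(c(3, 3), c(3, 3)), cbind(c(2, 4), c(2, 4)))
#' m$pooled$mae   # 1
#' m$pooled$mape  # 37.5
#' m$pooled$r2    # 0
#' @export
evaluate_metrics <- function(predictions, truths) {
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  stopifnot(ncol(predictions) == 2L, all(dim(predictions) == dim(truths)),
            nrow(truths) >= 2L)
  structure(
    list(pooled = metric_triple(as.vector(predictions), as.vector(truths)),
         valence = metric_triple(predictions[, 1L], truths[, 1L]),
         arousal = metric_triple(predictions[, 2L], truths[, 2L])),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  row <- function(nm, m) {
    cat(sprintf("  %-8s MAE %.3f  MAPE %6.2f%%  R2 %.3f  (n=%d)\n",
                nm, m$mae, m$mape, m$r2, m$n))
  }
  cat("<metrics_report>\n")
  row("pooled", x$pooled); row("valence", x$valence); row("arousal", x$arousal)
  invisible(x)
}

# ---- experiments ------------------------------------------------------------

fit_and_eval <- function(tensors, config, split, seed, model_type,
                         lr, batch_size, max_epochs, patience, verbose) {
  layout <- tensors$layout
  mlp_cols <- if (model_type == "full" && config$use_eeg_features_in_mlp) {
    seq_len(ncol(tensors$features))
  } else {
    layout$audio_cols
  }
  audio_len <- nrow(tensors$audio[[1L]])
  model <- if (model_type == "full") {
    build_fusion_model(config, length(mlp_cols), audio_len,
                       nrow(tensors$psd[[1L]]), seed = derive_seed(seed, 1L))
  } else {
    build_ablation_model(config, length(mlp_cols), audio_len,
                         seed = derive_seed(seed, 1L))
  }
  model$mlp_cols <- mlp_cols
  fit <- train_fusion(model, tensors, split$train_ids, split$val_ids,
                      lr = lr, batch_size = batch_size,
                      max_epochs = max_epochs, patience = patience,
                      seed = derive_seed(seed, 2L), verbose = verbose)
  include_eeg <- "eeg" %in% names(fit$model$branches)
  pred <- predict_in_chunks(fit$model, tensors, split$test_ids, mlp_cols,
                            include_eeg)
  metrics <- evaluate_metrics(pred, tensors$labels[split$test_ids, ,
                                                   drop = FALSE])
  list(fit = fit, metrics = metrics, predictions = pred)
}

#' Run one training experiment end to end
#'
#' Prepares features (unless given a ready `fusion_data`), splits 8:1:1,
#' standardizes on the training set, builds and trains the model, and
#' evaluates on the held-out test split.
#'
#' @param data a `trial_dataset` or a prepared `fusion_data`.
#' @param config a [fusion_config()].
#' @param seed master seed for split, initialization and training.
#' @param model `"full"` (three branches) or `"ablation"` (audio only).
#' @param lr,batch_size,max_epochs,patience training controls
#'   (see [train_fusion()]).
#' @param verbose print progress.
#' @return object of class `museeg_run`: `fit`, test `metrics`,
#'   `predictions`, `split`, `scaler`, standardized `tensors` and the
#'   configs used.
#' @export
run_experiment <- function(data, config = fusion_config(), seed = 1L,
                           model = c("full", "ablation"),
                           lr = 2e-3, batch_size = 16L, max_epochs = 250L,
                           patience = 20L, verbose = FALSE) {
  model <- match.arg(model)
  if (!inherits(data, "fusion_data")) {
    data <- prepare_fusion_data(data, config, verbose = verbose)
  }
  split <- split_dataset(seq_len(nrow(data$features)), seed = seed)
  scaler <- fit_scaler(data, split$train_ids)
  tensors <- apply_scaler(data, scaler)
  res <- fit_and_eval(tensors, config, split, seed, model,
                      lr, batch_size, max_epochs, patience, verbose)
  structure(
    list(fit = res$fit, metrics = res$metrics, predictions = res$predictions,
         split = split, scaler = scaler, tensors = tensors,
         config = config, model_type = model, seed = as.integer(seed)),
    class = "museeg_run"
  )
}

#' @export
print.museeg_run <- function(x, ...) {
  cat(sprintf("<museeg_run (%s model, seed %d)>\n", x$model_type, x$seed))
  print(x$metrics)
  invisible(x)
}

#' EEG-off ablation experiment
#'
#' Trains the full multimodal model and the audio-only control on identical
#' splits and seeds, and reports both test metric sets plus their
#' differences (full minus ablation).
#'
#' @inheritParams run_experiment
#' @return object of class `ablation_result`: `full` and `ablation`
#'   (`museeg_run`s) and `delta` with pooled `r2`, `mae` and `mape`
#'   differences.
#' @export
run_ablation <- function(data, config = fusion_config(), seed = 1L,
                         lr = 2e-3, batch_size = 16L, max_epochs = 250L,
                         patience = 20L, verbose = FALSE) {
  if (!inherits(data, "fusion_data")) {
    data <- prepare_fusion_data(data, config, verbose = verbose)
  }
  split <- split_dataset(seq_len(nrow(data$features)), seed = seed)
  scaler <- fit_scaler(data, split$train_ids)
  tensors <- apply_scaler(data, scaler)
  runs <- lapply(c(full = "full", ablation = "ablation"), function(mt) {
    res <- fit_and_eval(tensors, config, split, seed, mt,
                        lr, batch_size, max_epochs, patience, verbose)
    structure(
      list(fit = res$fit, metrics = res$metrics,
           predictions = res$predictions, split = split, scaler = scaler,
           tensors = tensors, config = config, model_type = mt,
           seed = as.integer(seed)),
      class = "museeg_run")
  })
  delta <- list(
    r2 = runs$full$metrics$pooled$r2 - runs$ablation$metrics$pooled$r2,
    mae = runs$full$metrics$pooled$mae - runs$ablation$metrics$pooled$mae,
    mape = runs$full$metrics$pooled$mape - runs$ablation$metrics$pooled$mape)
  structure(list(full = runs$full, ablation = runs$ablation, delta = delta),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\nfull model:\n")
  print(x$full$metrics)
  cat("audio-only ablation:\n")
  print(x$ablation$metrics)
  cat(sprintf("delta (full - ablation): R2 %+.3f, MAE %+.3f, MAPE %+.2f%%\n",
              x$delta$r2, x$delta$mae, x$delta$mape))
  invisible(x)
}

# ---- channel attribution ----------------------------------------------------

#' Per-channel attribution of a trained multimodal model
#'
#' Scores the importance of each EEG electrode for the trained model over an
#' evaluation set. `"gradient_input"` (default) averages `|gradient x input|`
#' over all EEG-derived inputs of a channel — its PSD column in the CNN
#' branch and its band-peak features in the MLP — over examples and both
#' output targets. `"occlusion"` replaces one channel's inputs with the
#' training mean (zero in standardized space) and scores the resulting
#' increase in test MAE (floored at 0).
#'
#' @param run a `museeg_run` for the full model (the EEG-less ablation model
#'   has no channel to attribute and raises a structured error).
#' @param method `"gradient_input"` or `"occlusion"`.
#' @param idx row indices to evaluate over; defaults to the test split.
#' @return object of class `attribution_report`: named `channel_scores`,
#'   `ranking` (channel names by descending score) and `method`.
#' @export
attribute_channels <- function(run, method = c("gradient_input", "occlusion"),
                               idx = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(run, "museeg_run"))
  model <- run$fit$model
  if (!("eeg" %in% names(model$branches))) {
    abort_museeg("cannot attribute EEG channels of an EEG-less ablation model",
                 "museeg_error_no_eeg_branch")
  }
  tensors <- run$tensors
  layout <- tensors$layout
  idx <- idx %||% run$split$test_ids
  mlp_cols <- model$mlp_cols %||% seq_len(ncol(tensors$features))
  channels <- layout$channel_names
  eeg_in_mlp <- all(unlist(layout$eeg_channel_cols) %in% mlp_cols)
  scores <- stats::setNames(numeric(length(channels)), channels)
  if (method == "gradient_input") {
    batch <- slice_batch(tensors, idx, mlp_cols, include_eeg = TRUE)
    fw <- model_forward(model, batch, training = FALSE)
    B <- length(idx)
    for (o in seq_len(model$config$output_dim)) {
      dout <- matrix(0, B, model$config$output_dim)
      dout[, o] <- 1
      dx <- model_backward(model, fw, dout, input_grad = TRUE)$dx
      for (b in seq_len(B)) {
        gi_psd <- abs(dx$eeg[[b]] * batch$psd[[b]])
        scores <- scores + colSums(gi_psd) / (B * 2)
      }
      if (eeg_in_mlp) {
        gi_feat <- abs(dx$mlp * batch$features)
        for (c in seq_along(channels)) {
          cols <- match(layout$eeg_channel_cols[[c]], mlp_cols)
          scores[c] <- scores[c] + sum(gi_feat[, cols]) / (B * 2)
        }
      }
    }
  } else {
    truth <- tensors$labels[idx, , drop = FALSE]
    base_batch <- slice_batch(tensors, idx, mlp_cols, include_eeg = TRUE)
    base <- mean(abs(model_forward(model, base_batch)$pred - truth))
    for (c in seq_along(channels)) {
      occ <- base_batch
      occ$psd <- lapply(occ$psd, function(m) { m[, c] <- 0; m })
      if (eeg_in_mlp) {
        cols <- match(layout$eeg_channel_cols[[c]], mlp_cols)
        occ$features[, cols] <- 0
      }
      loss <- mean(abs(model_forward(model, occ)$pred - truth))
      scores[c] <- max(0, loss - base)
    }
  }
  structure(
    list(channel_scores = scores,
         ranking = names(sort(scores, decreasing = TRUE)),
         method = method),
    class = "attribution_report"
  )
}

#' @export
print.attribution_report <- function(x, ...) {
  top <- utils::head(x$ranking, 8L)
  cat(sprintf("<attribution_report (%s)>\n  top channels: %s\n", x$method,
              paste(top, collapse = ", ")))
  invisible(x)
}
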