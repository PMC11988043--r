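## Training and evaluation pipeline.

#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param lr AdamW learning rate (constant; no schedule).
#' @param weight_decay decoupled weight decay.
#' @param seed master seed; fans out to data order, augmentation and model
#'   initialization through fixed sub-streams.
#' @param augment logical: apply online augmentation to training batches?
#' @param augment_cfg an [augment_config()] (its `out_size` is overridden by
#'   the model's `input_size`).
#' @param gaussian_sigma preprocessing smoothing sd in pixels (0 disables).
#' @param val_every compute test-split metrics every this many epochs
#'   (0 disables per-epoch validation).
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-3,
                         weight_decay = 0.05, seed = 1L, augment = TRUE,
                         augment_cfg = augment_config(),
                         gaussian_sigma = 1, val_every = 0L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
       augment = isTRUE(augment), augment_cfg = augment_cfg,
       gaussian_sigma = gaussian_sigma, val_every = as.integer(val_every))
}

## Load every pair referenced by the manifest rows into memory (preprocessed
## but not resized; resizing happens per-batch so augmentation can crop the
## native frame).
load_pairs <- function(manifest, dir = attr(manifest, "dir"),
                       gaussian_sigma = 1) {
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- read_pair(file.path(dir, manifest$rgb_path[i]),
                   file.path(dir, manifest$depth_path[i]),
                   weight = manifest$weight_kg[i],
                   sample_id = manifest$sample_id[i])
    if (gaussian_sigma > 0)
      p <- preprocess_pair(p, gaussian_sigma, color_norm = FALSE)
    p
  })
}

## stack pairs (resize-only) into rgb (S,S,3,N) and depth (S,S,1,N) arrays
stack_pairs <- function(pairs, size) {
  n <- length(pairs)
  rgb <- array(0, c(size, size, 3L, n))
  dep <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    p <- pairs[[i]]
    for (ch in 1:3) rgb[, , ch, i] <- resize_mat(p$rgb[, , ch], size, size)
    dep[, , 1L, i] <- resize_mat(p$depth * 1.0, size, size)
  }
  list(rgb = rgb, depth = dep,
       weight = vapply(pairs, function(p) p$weight, numeric(1)))
}

## per-channel normalization statistics from training arrays
norm_stats <- function(rgb, depth) {
  rs <- lapply(1:3, function(ch) {
    v <- rgb[, , ch, ]
    c(mean(v), max(stats::sd(v), 1e-6))
  })
  dv <- depth[depth > 0]
  if (!length(dv)) dv <- as.vector(depth)
  list(rgb_mean = vapply(rs, `[`, numeric(1), 1),
       rgb_sd = vapply(rs, `[`, numeric(1), 2),
       depth_mean = mean(dv), depth_sd = max(stats::sd(dv), 1e-6))
}

apply_norm <- function(rgb, depth, st) {
  for (ch in 1:3) rgb[, , ch, ] <- (rgb[, , ch, ] - st$rgb_mean[ch]) / st$rgb_sd[ch]
  depth[, , 1L, ] <- (depth[, , 1L, ] - st$depth_mean) / st$depth_sd
  list(rgb = rgb, depth = depth)
}

#' Train a weight-estimation model
#'
#' AdamW on the manifest's train split; fixed seeds make the loss trajectory
#' reproducible on a given machine. Aborts on non-finite loss.
#'
#' @param manifest manifest data.frame (see [read_manifest()]) with a
#'   non-empty train split.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param out_dir if non-NULL, the checkpoint (`checkpoint.rds`) and training
#'   log (`train_log.csv`) are written here.
#' @param pairs optional pre-loaded pair list (as from `load_pairs`) to skip
#'   disk I/O; must match the manifest rows.
#' @return list with `checkpoint` (model state + configs + normalization
#'   statistics + seed) and `log` (per-epoch data.frame).
#' @export
train <- function(manifest, mconfig, tconfig, out_dir = NULL, pairs = NULL) {
  tr_idx <- which(manifest$split == "train")
  if (!length(tr_idx)) stop("train: manifest has no train split")
  if (is.null(pairs))
    pairs <- load_pairs(manifest, gaussian_sigma = tconfig$gaussian_sigma)
  size <- mconfig$input_size
  tr_pairs <- pairs[tr_idx]
  base <- stack_pairs(tr_pairs, size)
  st <- norm_stats(base$rgb, base$depth)
  tnorm <- if (mconfig$target_norm)
    list(mean = mean(base$weight), sd = max(stats::sd(base$weight), 1e-6))
  else list(mean = 0, sd = 1)

  model <- build_model(mconfig, init_seed = sub_seed(tconfig$seed, "init"))
  params <- nn_params(model)
  opt <- adamw(params, lr = tconfig$lr, weight_decay = tconfig$weight_decay)

  n <- length(tr_pairs)
  bs <- min(tconfig$batch_size, n)
  log_rows <- vector("list", tconfig$epochs)
  aug_cfg <- tconfig$augment_cfg
  aug_cfg$out_size <- size

  for (ep in seq_len(tconfig$epochs)) {
    ord <- local_seed(sub_seed(tconfig$seed, "batch") + ep, sample.int(n))
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1L, n)]
      if (tconfig$augment) {
        aseed <- sub_seed(tconfig$seed, "augment") + ep * 100003L
        bp <- lapply(seq_along(idx), function(k) {
          augment_pair(tr_pairs[[idx[k]]], aug_cfg,
                       seed = (aseed + idx[k]) %% 2147483629)
        })
        batch <- stack_pairs(bp, size)
      } else {
        batch <- list(rgb = base$rgb[, , , idx, drop = FALSE],
                      depth = base$depth[, , , idx, drop = FALSE],
                      weight = base$weight[idx])
      }
      nb_in <- apply_norm(batch$rgb, batch$depth, st)
      target <- (batch$weight - tnorm$mean) / tnorm$sd
      ag_tape_begin()
      pred <- model_forward(model, nb_in$rgb, nb_in$depth)
      loss <- ag_loss(pred, target, mconfig$loss)
      lval <- loss$v
      if (!is.finite(lval)) {
        ag_tape_end()
        stop("train: non-finite loss at epoch ", ep)
      }
      ag_backward(loss)
      adamw_step(opt)
      ag_zero_grad(params)
      ep_loss <- ep_loss + lval
      nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / nb)
    if (tconfig$val_every > 0 && ep %% tconfig$val_every == 0L &&
        any(manifest$split == "test")) {
      ck_tmp <- list(state = nn_state(model), model_config = mconfig,
                     train_config = tconfig, norm = st, target_norm = tnorm,
                     seed = tconfig$seed, version = pkg_version())
      rep <- evaluate(ck_tmp, manifest, "test", pairs = pairs)$report
      row$val_mae <- rep$mae
      row$val_r2 <- rep$r2
    }
    log_rows[[ep]] <- row
  }
  log <- do.call(rbind, lapply(log_rows, function(r) {
    ## pad columns so epochs without validation bind cleanly
    if (is.null(r$val_mae)) { r$val_mae <- NA_real_; r$val_r2 <- NA_real_ }
    r
  }))
  checkpoint <- list(state = nn_state(model), model_config = mconfig,
                     train_config = tconfig, norm = st, target_norm = tnorm,
                     seed = tconfig$seed, version = pkg_version())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(checkpoint, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
  }
  list(checkpoint = checkpoint, log = log, model = model)
}

pkg_version <- function() {
  as.character(utils::packageVersion("rgbdweight"))
}

## rebuild a model from a checkpoint
checkpoint_model <- function(checkpoint) {
  model <- build_model(checkpoint$model_config, init_seed = 1L)
  nn_load_state(model, checkpoint$state)
  model
}

#' Predict weights for a set of pairs with a trained checkpoint
#' @param checkpoint as produced by [train()].
#' @param pairs list of `rgbd_pair` (already preprocessed as at training).
#' @param batch_size forward batch size.
#' @return numeric vector of predicted weights in kg.
#' @export
predict_pairs <- function(checkpoint, pairs, batch_size = 32L) {
  model <- checkpoint_model(checkpoint)
  size <- checkpoint$model_config$input_size
  stacked <- stack_pairs(pairs, size)
  nb <- apply_norm(stacked$rgb, stacked$depth, checkpoint$norm)
  n <- length(pairs)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    pred <- model_forward(model,
                          nb$rgb[, , , idx, drop = FALSE],
                          nb$depth[, , , idx, drop = FALSE])
    out[idx] <- as.numeric(pred$v)
  }
  out * checkpoint$target_norm$sd + checkpoint$target_norm$mean
}

#' Evaluate a checkpoint on a manifest split
#'
#' Deterministic: resize-only inputs, no augmentation; metrics are computed
#' in kg on de-normalized predictions.
#' @param checkpoint as produced by [train()].
#' @param manifest manifest data.frame.
#' @param split_tag `"train"` or `"test"`.
#' @param pairs optional pre-loaded pair list matching the manifest rows.
#' @return list with `report` (a [metrics_report()]) and `predictions`
#'   (data.frame `sample_id, weight_kg_true, weight_kg_pred`).
#' @export
evaluate <- function(checkpoint, manifest, split_tag = "test", pairs = NULL) {
  idx <- which(manifest$split == split_tag)
  if (!length(idx)) stop("evaluate: split '", split_tag, "' is empty")
  if (is.null(pairs))
    pairs <- load_pairs(manifest,
                        gaussian_sigma = checkpoint$train_config$gaussian_sigma)
  y_hat <- predict_pairs(checkpoint, pairs[idx])
  y <- manifest$weight_kg[idx]
  list(report = metrics_report(y, y_hat),
       predictions = data.frame(sample_id = manifest$sample_id[idx],
                                weight_kg_true = y, weight_kg_pred = y_hat,
                                stringsAsFactors = FALSE))
}
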