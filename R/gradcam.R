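## Gradient-weighted activation mapping for the regression output.

#' Compute a gradient-weighted activation map for one sample
#'
#' Runs a forward pass collecting named activations, backpropagates the
#' scalar weight prediction, weights each channel of the target layer by the
#' spatial mean of its gradient, rectifies the weighted sum and normalizes to
#' `[0, 1]`, upsampled to the input size.
#'
#' @param checkpoint a trained checkpoint from [train()].
#' @param pair an `rgbd_pair` (preprocessed as at training time).
#' @param target_layer activation name, e.g. `"decoder.low"`,
#'   `"encoder.R.stage3"`; see the names returned in `attr(, "layers")` on
#'   error.
#' @return list with `heatmap` (input_size x input_size matrix in `[0, 1]`)
#'   and `prediction` (kg).
#' @export
gradcam <- function(checkpoint, pair, target_layer = "decoder.low") {
  model <- checkpoint_model(checkpoint)
  size <- checkpoint$model_config$input_size
  stacked <- stack_pairs(list(pair), size)
  nb <- apply_norm(stacked$rgb, stacked$depth, checkpoint$norm)
  acts <- new.env(parent = emptyenv())
  ag_tape_begin()
  pred <- model_forward(model, nb$rgb, nb$depth, acts = acts)
  nms <- ls(acts)
  if (!target_layer %in% nms) {
    ag_tape_end()
    err <- paste0("gradcam: unknown layer '", target_layer, "'; available: ",
                  paste(nms, collapse = ", "))
    stop(err)
  }
  a <- acts[[target_layer]]
  a$needs <- TRUE  # retain gradient at the activation even for frozen inputs
  ag_backward(pred)
  act <- a$v[, , , 1, drop = FALSE]
  grd <- a$g
  if (is.null(grd)) grd <- array(0, dim(a$v))
  grd <- grd[, , , 1, drop = FALSE]
  d <- dim(act)
  wts <- colMeans(matrix(grd, d[1] * d[2], d[3]))          # GAP of gradients
  cam <- matrix(0, d[1], d[2])
  for (ci in seq_len(d[3])) cam <- cam + wts[ci] * act[, , ci, 1]
  cam <- pmax(cam, 0)
  cam <- resize_mat(cam, size, size)
  rng <- range(cam)
  heat <- if (diff(rng) > 1e-12) (cam - rng[1]) / diff(rng)
          else matrix(0, size, size)
  pred_kg <- as.numeric(pred$v) * checkpoint$target_norm$sd +
    checkpoint$target_norm$mean
  list(heatmap = heat, prediction = pred_kg)
}
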