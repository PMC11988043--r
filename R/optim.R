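## AdamW with decoupled weight decay (decay applied only to tensors flagged
## `decay`, i.e. convolution/linear weights, never biases).

#' Create an AdamW optimizer over a parameter list
#' @param params list of `ag_tensor` parameters.
#' @param lr learning rate.
#' @param weight_decay decoupled decay coefficient.
#' @param betas,eps Adam moment coefficients and stabilizer.
#' @export
adamw <- function(params, lr = 1e-3, weight_decay = 0.05,
                  betas = c(0.9, 0.999), eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$wd <- weight_decay
  opt$b1 <- betas[1]
  opt$b2 <- betas[2]
  opt$eps <- eps
  opt$t <- 0L
  opt$dims <- lapply(params, function(p) dim(p$v))
  opt$m <- lapply(params, function(p) numeric(length(p$v)))
  opt$v <- lapply(params, function(p) numeric(length(p$v)))
  class(opt) <- "adamw"
  opt
}

#' Apply one optimizer step using the accumulated gradients
#' @param opt an [adamw()] optimizer.
#' @export
adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$g
    if (is.null(g)) next
    g <- as.numeric(g)
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    step <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    if (p$decay && opt$wd > 0) step <- step + opt$wd * as.numeric(p$v)
    v <- as.numeric(p$v) - opt$lr * step
    dim(v) <- opt$dims[[i]]
    p$v <- v
  }
  invisible(opt)
}
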