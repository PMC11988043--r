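# Independent brute-force oracles, intentionally written with plain loops and
# no shared code with the package internals they check.

# direct (triple-loop) 2-D cross-correlation with zero padding
conv_naive <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1, groups = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  Cog <- Cout %/% groups
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% Cog
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- if (is.null(b)) 0 else b[co]
      for (ci in 1:Cg) for (i in 1:kh) for (j in 1:kw) {
        ih <- (ho - 1) * stride - pad + (i - 1) * dil + 1
        iw <- (wo - 1) * stride - pad + (j - 1) * dil + 1
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          s <- s + x[ih, iw, g * Cg + ci, n] * w[i, j, ci, co]
      }
      y[ho, wo, co, n] <- s
    }
  }
  y
}

# leaky rectifier as used by the network layers
lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

# internal namespace access for white-box tests of un-exported layers
ns <- asNamespace("rgbdweight")

# set every trainable parameter of a module tree to zero
zero_params <- function(module) {
  for (p in nn_params(module)) p$v[] <- 0
  invisible(module)
}

# random feature-map tensor helper
rand_feat <- function(H, W, C, N = 1, sd = 1) {
  array(rnorm(H * W * C * N, 0, sd), c(H, W, C, N))
}

# small shared model configuration used across structural tests
tiny_mconfig <- function(...) {
  model_config(input_size = 32L, widths = c(8L, 12L, 16L, 16L, 24L, 32L),
               bam_reduction = 4L, bam_dilation = 2L, decoder_width = 16L,
               head_hidden = 32L, target_norm = TRUE, ...)
}

# silhouette mask from a color image: body pixels are saturated, the gray
# background is not
rgb_silhouette <- function(rgb, thr = 0.12) {
  apply(rgb, c(1, 2), max) - apply(rgb, c(1, 2), min) > thr
}

iou <- function(a, b) sum(a & b) / max(1L, sum(a | b))
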