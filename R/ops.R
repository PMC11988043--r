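## Differentiable primitive operations on (H, W, C, N) activation arrays.
## Each op returns an ag_node whose backward closure accumulates into parents.

#' 2-D convolution (differentiable)
#'
#' Standard cross-correlation with zero padding, stride, dilation and groups;
#' `groups = C` gives a depthwise convolution. Forward and backward run through
#' compiled im2col/GEMM kernels.
#' @param x input tensor, dim `(H, W, C, N)`.
#' @param w weight tensor, dim `(kh, kw, C/groups, Cout)`.
#' @param b optional bias tensor of length `Cout`, or `NULL`.
#' @param stride,pad,dilation,groups integer convolution geometry.
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L, groups = 1L) {
  v <- conv2d_fwd(x$v, w$v, if (is.null(b)) NULL else b$v,
                  as.integer(stride), as.integer(pad), as.integer(dilation),
                  as.integer(groups))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(v, parents, function(g) {
    gr <- conv2d_bwd(x$v, w$v, g, as.integer(stride), as.integer(pad),
                     as.integer(dilation), as.integer(groups),
                     need_gx = x$needs, has_bias = !is.null(b))
    if (x$needs) ag_acc(x, gr$gx)
    ag_acc(w, gr$gw)
    if (!is.null(b)) ag_acc(b, gr$gb)
  })
}

#' @keywords internal
ag_add <- function(a, b) {
  ag_node(a$v + b$v, list(a, b), function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

#' @keywords internal
ag_mul <- function(a, b) {
  ag_node(a$v * b$v, list(a, b), function(g) {
    ag_acc(a, g * b$v)
    ag_acc(b, g * a$v)
  })
}

#' Elementwise maximum; ties route the gradient to the first argument.
#' @keywords internal
ag_pmax2 <- function(a, b) {
  m <- a$v >= b$v
  ag_node(pmax(a$v, b$v), list(a, b), function(g) {
    ag_acc(a, g * m)
    ag_acc(b, g * !m)
  })
}

#' Leaky rectifier (slope for negative inputs keeps every unit trainable).
#' @keywords internal
ag_relu <- function(x, slope = 0.01) {
  fac <- slope + (1 - slope) * (x$v > 0)
  ag_node(x$v * fac, list(x), function(g) ag_acc(x, g * fac))
}

#' @keywords internal
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_node(s, list(x), function(g) ag_acc(x, g * s * (1 - s)))
}

#' Concatenate along the channel dimension (dim 3 of H,W,C,N).
#' @param xs list of tensors sharing H, W, N.
#' @keywords internal
ag_concat_c <- function(xs) {
  vs <- lapply(xs, function(t) t$v)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (k in seq_along(vs)) {
    out[, , off + seq_len(cs[k]), ] <- vs[[k]]
    off <- off + cs[k]
  }
  ag_node(out, xs, function(g) {
    off <- 0L
    for (k in seq_along(xs)) {
      ag_acc(xs[[k]], g[, , off + seq_len(cs[k]), , drop = FALSE])
      off <- off + cs[k]
    }
  })
}

#' Select channels by index.
#' @keywords internal
ag_slice_c <- function(x, idx) {
  ag_node(x$v[, , idx, , drop = FALSE], list(x), function(g) {
    if (!x$needs) return(invisible(NULL))
    gx <- array(0, dim(x$v))
    gx[, , idx, ] <- g
    ag_acc(x, gx)
  })
}

#' Permute channels (used by the channel-shuffle step); bijective.
#' @keywords internal
ag_permute_c <- function(x, perm) {
  inv <- order(perm)
  ag_node(x$v[, , perm, , drop = FALSE], list(x), function(g) {
    ag_acc(x, g[, , inv, , drop = FALSE])
  })
}

#' Global average pooling over the spatial dimensions -> (1,1,C,N).
#' @keywords internal
ag_gap <- function(x) {
  d <- dim(x$v)
  v <- colMeans(matrix(x$v, d[1] * d[2], d[3] * d[4]))
  dim(v) <- c(1L, 1L, d[3], d[4])
  ag_node(v, list(x), function(g) {
    gx <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
    ag_acc(x, gx)
  })
}

#' Broadcast a (1,1,C,N) map over H x W.
#' @keywords internal
ag_expand_hw <- function(x, H, W) {
  d <- dim(x$v)
  v <- array(rep(x$v, each = H * W), c(H, W, d[3], d[4]))
  ag_node(v, list(x), function(g) {
    gs <- colSums(matrix(g, H * W, d[3] * d[4]))
    dim(gs) <- d
    ag_acc(x, gs)
  })
}

#' Broadcast a (H,W,1,N) map over C channels.
#' @keywords internal
ag_expand_c <- function(x, C) {
  d <- dim(x$v)
  v <- array(0, c(d[1], d[2], C, d[4]))
  for (ci in seq_len(C)) v[, , ci, ] <- x$v[, , 1L, ]
  ag_node(v, list(x), function(g) {
    gs <- array(0, d)
    gs[, , 1L, ] <- apply(g, c(1, 2, 4), sum)
    ag_acc(x, gs)
  })
}

#' @keywords internal
ag_reshape <- function(x, newdim) {
  d0 <- dim(x$v)
  v <- x$v
  dim(v) <- newdim
  ag_node(v, list(x), function(g) {
    dim(g) <- d0
    ag_acc(x, g)
  })
}

#' Affine layer on (F, N) matrices: `w %*% x + b`.
#' @keywords internal
ag_linear <- function(x, w, b = NULL) {
  v <- w$v %*% x$v
  if (!is.null(b)) v <- v + b$v
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(v, parents, function(g) {
    if (x$needs) ag_acc(x, crossprod(w$v, g))
    ag_acc(w, tcrossprod(g, x$v))
    if (!is.null(b)) ag_acc(b, rowSums(g))
  })
}

## ---- bilinear interpolation ------------------------------------------------

#' Row-interpolation matrix for bilinear resizing (half-pixel centers,
#' align_corners = FALSE convention); dense `n_out x n_in`.
#' @keywords internal
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5   # 0-based source coordinate
    src <- min(max(src, 0), n_in - 1)
    lo <- floor(src)
    fr <- src - lo
    i0 <- as.integer(lo) + 1L
    i1 <- min(i0 + 1L, n_in)
    A[o, i0] <- A[o, i0] + (1 - fr)
    A[o, i1] <- A[o, i1] + fr
  }
  A
}

## apply resize matrices to a plain (H,W,C,N) array
resize_bilinear_arr <- function(v, Ho, Wo, Ah = NULL, Aw = NULL) {
  d <- dim(v)
  if (is.null(Ah)) Ah <- bilinear_matrix(d[1], Ho)
  if (is.null(Aw)) Aw <- bilinear_matrix(d[2], Wo)
  y <- Ah %*% matrix(v, d[1], d[2] * d[3] * d[4])            # (Ho, W*C*N)
  dim(y) <- c(Ho, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Aw %*% matrix(y, d[2], Ho * d[3] * d[4])              # (Wo, Ho*C*N)
  dim(y) <- c(Wo, Ho, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

#' Differentiable bilinear resize to (Ho, Wo).
#' @keywords internal
ag_upsample <- function(x, Ho, Wo) {
  d <- dim(x$v)
  Ah <- bilinear_matrix(d[1], Ho)
  Aw <- bilinear_matrix(d[2], Wo)
  v <- resize_bilinear_arr(x$v, Ho, Wo, Ah, Aw)
  ag_node(v, list(x), function(g) {
    ag_acc(x, resize_bilinear_arr(g, d[1], d[2], t(Ah), t(Aw)))
  })
}

#' Per-sample RMS normalization over all feature dimensions
#'
#' Divides each sample's feature map by its root-mean-square activation.
#' Parameter-free scale control applied at the end of every backbone stage,
#' keeping the multiplicative fusion blocks numerically bounded.
#' @keywords internal
ag_rmsnorm <- function(x, eps = 1e-6) {
  d <- dim(x$v)
  M <- prod(d[1:3])
  xm <- matrix(x$v, M, d[4])
  s <- sqrt(colMeans(xm^2) + eps)            # one scale per sample
  v <- sweep(xm, 2, s, "/")
  dim(v) <- d
  ag_node(v, list(x), function(g) {
    gm <- matrix(g, M, d[4])
    dot <- colSums(gm * xm)
    gx <- sweep(gm, 2, s, "/") - sweep(xm, 2, dot / (M * s^3), "*")
    dim(gx) <- d
    ag_acc(x, gx)
  })
}

## ---- losses ----------------------------------------------------------------

#' Batch regression losses between predictions (vector node) and targets.
#' @param pred `ag_tensor` whose value has length n.
#' @param target numeric vector of length n.
#' @param type `"l1"`, `"l2"` or `"smooth_l1"` (Huber with delta 1).
#' @keywords internal
ag_loss <- function(pred, target, type = c("l1", "l2", "smooth_l1")) {
  type <- match.arg(type)
  d <- as.numeric(pred$v) - as.numeric(target)
  n <- length(d)
  val <- switch(type,
    l1 = mean(abs(d)),
    l2 = mean(d^2),
    smooth_l1 = mean(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)))
  grad <- switch(type,
    l1 = sign(d) / n,
    l2 = 2 * d / n,
    smooth_l1 = ifelse(abs(d) < 1, d, sign(d)) / n)
  ag_node(val, list(pred), function(g) {
    gp <- g * grad
    dim(gp) <- dim(pred$v)
    ag_acc(pred, gp)
  })
}
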