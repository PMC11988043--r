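## Cross-modality building blocks of the two-stream network.
##
## FF   : feature fusion — 1x1 smoothing of both inputs, element-wise product
##        highlighting shared content, residual concatenation, depthwise
##        separable 3x3 merge.
## BAM  : bottleneck attention — parallel channel (GAP -> bottleneck MLP) and
##        spatial (1x1 reduce -> dilated 3x3 convs -> 1x1) paths summed with
##        broadcasting; returns pre-sigmoid logits.
## CFS  : encoder-side supplementation — each branch receives the fused
##        feature gated by a sigmoid of its own BAM attention:
##        bfR = fR + sigmoid(BAM(fR)) * fF,  bfD = fD + sigmoid(BAM(fD)) * fF.
## RFB  : receptive-field refinement — channel split, residual 1x1 half plus
##        multi-dilation 3x3 half, concatenation, channel shuffle.
## CFF  : decoder-side fusion of adjacent-scale features within each modality
##        then across modalities, refined by RFB.

#' Feature fusion (FF) block constructor
#'
#' @param ca,cb input channel counts of the two feature maps.
#' @param cmid width of the 1x1 smoothing convolutions.
#' @param cout output channels of the depthwise-separable merge.
#' @keywords internal
nn_ff <- function(ca, cb, cmid, cout, name = "ff") {
  list(kind = "ff",
       sa = nn_conv(ca, cmid, k = 1L, name = paste0(name, ".sa")),
       sb = nn_conv(cb, cmid, k = 1L, name = paste0(name, ".sb")),
       merge = nn_dsconv(2L * cmid, cout, name = paste0(name, ".merge")))
}

#' Apply a feature fusion block
#'
#' Computes the smoothed features, their element-wise product, and the
#' depthwise-separable merge of the two product-residual sums. Purely linear
#' apart from the product; no activation, so the block's arithmetic can be
#' verified against pencil-and-paper evaluation.
#' @param m block from [nn_ff()].
#' @param fa,fb `ag_tensor` feature maps with identical spatial size.
#' @keywords internal
ff_apply <- function(m, fa, fb) {
  if (!all(dim(fa$v)[c(1, 2, 4)] == dim(fb$v)[c(1, 2, 4)]))
    stop("ff: spatial/batch sizes of the two inputs differ")
  fa_s <- conv_apply(m$sa, fa)
  fb_s <- conv_apply(m$sb, fb)
  fF <- ag_mul(fa_s, fb_s)
  dsconv_apply(m$merge, ag_concat_c(list(ag_add(fF, fa_s), ag_add(fF, fb_s))))
}

#' Bottleneck attention module (BAM) constructor
#'
#' @param c channel count of the attended feature map; must be at least
#'   `reduction`.
#' @param reduction bottleneck reduction ratio of both paths.
#' @param dilation dilation of the two 3x3 spatial-path convolutions.
#' @keywords internal
nn_bam <- function(c, reduction = 16L, dilation = 4L, name = "bam") {
  if (c < reduction)
    stop("bam: channel count (", c, ") is smaller than the reduction ratio (",
         reduction, ")")
  cr <- max(1L, c %/% reduction)
  list(kind = "bam", c = c,
       fc1 = nn_linear(c, cr, name = paste0(name, ".fc1")),
       fc2 = nn_linear(cr, c, name = paste0(name, ".fc2")),
       sp1 = nn_conv(c, cr, k = 1L, name = paste0(name, ".sp1")),
       sp2 = nn_conv(cr, cr, k = 3L, dilation = dilation,
                     name = paste0(name, ".sp2")),
       sp3 = nn_conv(cr, cr, k = 3L, dilation = dilation,
                     name = paste0(name, ".sp3")),
       sp4 = nn_conv(cr, 1L, k = 1L, name = paste0(name, ".sp4")))
}

#' Apply a BAM block; returns pre-sigmoid attention logits, same shape as input.
#' @keywords internal
bam_apply <- function(m, x) {
  d <- dim(x$v)
  ch <- ag_reshape(ag_gap(x), c(m$c, d[4]))
  ch <- linear_apply(m$fc2, ag_relu(linear_apply(m$fc1, ch)))
  ch <- ag_expand_hw(ag_reshape(ch, c(1L, 1L, m$c, d[4])), d[1], d[2])
  sp <- ag_relu(conv_apply(m$sp1, x))
  sp <- ag_relu(conv_apply(m$sp2, sp))
  sp <- ag_relu(conv_apply(m$sp3, sp))
  sp <- conv_apply(m$sp4, sp)
  ag_add(ch, ag_expand_c(sp, m$c))
}

#' Cross-modality feature supplementation (CFS) constructor
#' @param c stage channel count (both branches).
#' @keywords internal
nn_cfs <- function(c, bam_reduction = 16L, bam_dilation = 4L, name = "cfs") {
  ff <- nn_ff(c, c, c, c, name = paste0(name, ".ff"))
  ## residual-style small init: the supplementation path starts near the
  ## identity (small fused feature) and opens up as training proceeds,
  ## instead of injecting large random fused features into both branches
  ff$merge$pw$w$v <- ff$merge$pw$w$v * 0.1
  list(kind = "cfs", ff = ff,
       bamR = nn_bam(c, bam_reduction, bam_dilation, name = paste0(name, ".bamR")),
       bamD = nn_bam(c, bam_reduction, bam_dilation, name = paste0(name, ".bamD")))
}

#' Apply CFS: gated supplementation of each branch with the fused feature
#'
#' Shape-preserving: both outputs have exactly the shapes of their inputs.
#' With a zero fused feature the block is the identity on both branches.
#' @return list with elements `bfR` and `bfD`.
#' @keywords internal
cfs_apply <- function(m, fR, fD) {
  if (!identical(dim(fR$v), dim(fD$v)))
    stop("cfs: branch feature shapes differ")
  fF <- ff_apply(m$ff, fR, fD)
  bfR <- ag_add(fR, ag_mul(ag_sigmoid(bam_apply(m$bamR, fR)), fF))
  bfD <- ag_add(fD, ag_mul(ag_sigmoid(bam_apply(m$bamD, fD)), fF))
  list(bfR = bfR, bfD = bfD)
}

#' Interleaving channel-shuffle permutation for a split into `g` groups
#' @keywords internal
shuffle_perm <- function(c, g = 2L) {
  as.vector(matrix(seq_len(c), nrow = g, byrow = TRUE))
}

#' Receptive field block (RFB) constructor
#' @param c channel count (must be even: the block splits channels in half).
#' @param dilations dilation rates of the multi-branch half.
#' @keywords internal
nn_rfb <- function(c, dilations = c(1L, 3L, 5L), name = "rfb") {
  if (c %% 2L != 0L) stop("rfb: channel count must be even, got ", c)
  half <- c %/% 2L
  branches <- lapply(seq_along(dilations), function(k) {
    nn_conv(half, half, k = 3L, dilation = dilations[k],
            name = paste0(name, ".br", k))
  })
  list(kind = "rfb", c = c, half = half,
       res = nn_conv(half, half, k = 1L, name = paste0(name, ".res")),
       branches = branches, perm = shuffle_perm(c, 2L))
}

#' Apply RFB: split, residual 1x1 + summed dilated branches, concat, shuffle.
#' @keywords internal
rfb_apply <- function(m, x) {
  a <- ag_slice_c(x, seq_len(m$half))
  b <- ag_slice_c(x, m$half + seq_len(m$half))
  ra <- conv_apply(m$res, a)
  rb <- conv_apply(m$branches[[1]], b)
  for (k in seq_along(m$branches)[-1])
    rb <- ag_add(rb, conv_apply(m$branches[[k]], b))
  ag_permute_c(ag_concat_c(list(ra, rb)), m$perm)
}

#' Cross-modality feature fusion (CFF) module constructor
#'
#' Fuses adjacent-scale features within each branch, then across branches
#' (per `fusion_scheme`), optionally concatenates the coarser decoder output,
#' and refines with RFB.
#' @param c_lo,c_hi encoder channel counts of the finer / coarser stage.
#' @param width decoder working width (even).
#' @param has_prev does this level receive the previous (coarser) CFF output?
#' @param c_prev channel count of that previous output.
#' @param fusion_scheme `"cff"` (FF block, the default architecture) or the
#'   ablation variants `"addition"`, `"max"`, `"concatenation"`.
#' @keywords internal
nn_cff <- function(c_lo, c_hi, width, has_prev, c_prev = width,
                   fusion_scheme = "cff",
                   rfb_dilations = c(1L, 3L, 5L), name = "cff") {
  adapters <- list(
    R_lo = nn_conv(c_lo, width, k = 1L, name = paste0(name, ".aRlo")),
    R_hi = nn_conv(c_hi, width, k = 1L, name = paste0(name, ".aRhi")),
    D_lo = nn_conv(c_lo, width, k = 1L, name = paste0(name, ".aDlo")),
    D_hi = nn_conv(c_hi, width, k = 1L, name = paste0(name, ".aDhi")))
  m <- list(kind = "cff", width = width, has_prev = has_prev,
            fusion_scheme = fusion_scheme, adapters = adapters,
            ffR = nn_ff(width, width, width, width, name = paste0(name, ".ffR")),
            ffD = nn_ff(width, width, width, width, name = paste0(name, ".ffD")))
  if (fusion_scheme == "cff") {
    m$ffX <- nn_ff(width, width, width, width, name = paste0(name, ".ffX"))
  } else if (fusion_scheme == "concatenation") {
    m$xproj <- nn_conv(2L * width, width, k = 1L, name = paste0(name, ".xproj"))
  }
  if (has_prev)
    m$prev_proj <- nn_conv(c_prev, width, k = 1L, name = paste0(name, ".prev"))
  cr <- if (has_prev) 2L * width else width
  m$rfb <- nn_rfb(cr, rfb_dilations, name = paste0(name, ".rfb"))
  m
}

#' Apply a CFF module
#' @param bfR_lo,bfR_hi,bfD_lo,bfD_hi adjacent-stage features of each branch
#'   (`hi` is the coarser stage and is upsampled to the finer size).
#' @param f_prev previous CFF output (coarser level) or `NULL`.
#' @keywords internal
cff_apply <- function(m, bfR_lo, bfR_hi, bfD_lo, bfD_hi, f_prev = NULL) {
  if (m$has_prev && is.null(f_prev))
    stop("cff: this level expects the previous CFF output")
  d <- dim(bfR_lo$v)
  up <- function(t) if (all(dim(t$v)[1:2] == d[1:2])) t else
    ag_upsample(t, d[1], d[2])
  R_lo <- conv_apply(m$adapters$R_lo, bfR_lo)
  R_hi <- conv_apply(m$adapters$R_hi, up(bfR_hi))
  D_lo <- conv_apply(m$adapters$D_lo, bfD_lo)
  D_hi <- conv_apply(m$adapters$D_hi, up(bfD_hi))
  bfRm <- ff_apply(m$ffR, R_lo, R_hi)
  bfDm <- ff_apply(m$ffD, D_lo, D_hi)
  fFm <- switch(m$fusion_scheme,
    cff = ff_apply(m$ffX, bfRm, bfDm),
    addition = ag_add(bfRm, bfDm),
    max = ag_pmax2(bfRm, bfDm),
    concatenation = conv_apply(m$xproj, ag_concat_c(list(bfRm, bfDm))),
    stop("unknown fusion scheme: ", m$fusion_scheme))
  if (m$has_prev)
    fFm <- ag_concat_c(list(fFm, conv_apply(m$prev_proj, up(f_prev))))
  rfb_apply(m$rfb, fFm)
}
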