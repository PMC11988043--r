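# Fusion blocks: each operation is checked against hand-computed arithmetic
# on tiny fixtures with pinned weights, plus its structural contracts.

test_that("feature fusion reproduces the three-step formula by hand", {
  # 1-channel 2x2 inputs, hand-set 1x1 and depthwise-separable weights
  m <- ns$nn_ff(1L, 1L, 1L, 1L)
  m$sa$w$v[] <- 2;   m$sa$b$v[] <- 0.1    # smoothed a = 2*fa + 0.1
  m$sb$w$v[] <- -1;  m$sb$b$v[] <- 0.2    # smoothed b = -fb + 0.2
  # depthwise 3x3: channel 1 passes center only, channel 2 doubles center
  m$merge$dw$w$v[] <- 0
  m$merge$dw$w$v[2, 2, 1, 1] <- 1
  m$merge$dw$w$v[2, 2, 1, 2] <- 2
  m$merge$dw$b$v[] <- c(0.3, -0.3)
  m$merge$pw$w$v[1, 1, , 1] <- c(1, 0.5)  # pointwise mix
  m$merge$pw$b$v[] <- 0.25

  fa <- array(c(1, -2, 0.5, 3), c(2, 2, 1, 1))
  fb <- array(c(0.2, 1, -1, 0.4), c(2, 2, 1, 1))
  out <- ns$ff_apply(m, ns$ag_tensor(fa), ns$ag_tensor(fb))

  sa <- 2 * fa + 0.1
  sb <- -fb + 0.2
  fF <- sa * sb
  c1 <- (fF + sa) + 0.3        # depthwise identity + bias, channel 1
  c2 <- 2 * (fF + sb) - 0.3    # depthwise doubling + bias, channel 2
  want <- 1 * c1 + 0.5 * c2 + 0.25
  expect_equal(out$v, want, tolerance = 1e-12)
})

test_that("feature fusion zero-propagates and honors the shape contract", {
  m <- ns$nn_ff(8L, 8L, 8L, 8L)
  zero_params(m)
  fa <- ns$ag_tensor(rand_feat(16, 16, 8))
  fb <- ns$ag_tensor(rand_feat(16, 16, 8))
  out <- ns$ff_apply(m, fa, fb)
  expect_equal(max(abs(out$v)), 0)
  m2 <- ns$nn_ff(8L, 8L, 4L, 6L)
  out2 <- ns$ff_apply(m2, fa, fb)
  expect_equal(dim(out2$v), c(16L, 16L, 6L, 1L))
  expect_error(ns$ff_apply(m, fa, ns$ag_tensor(rand_feat(8, 8, 8))), "spatial")
})

test_that("BAM attention matches an explicit channel+spatial recomputation", {
  set.seed(99)
  C <- 2L
  m <- ns$nn_bam(C, reduction = 2L, dilation = 1L)
  for (p in nn_params(m)) p$v[] <- rnorm(length(p$v), 0, 0.5)
  x <- rand_feat(3, 3, C, 1)
  got <- ns$bam_apply(m, ns$ag_tensor(x))

  # channel path, by hand
  gap <- apply(x[, , , 1], 3, mean)
  h1 <- lrelu(m$fc1$w$v %*% gap + m$fc1$b$v)
  chl <- m$fc2$w$v %*% h1 + m$fc2$b$v           # length C logits
  # spatial path, by hand with the loop conv oracle
  s <- lrelu(conv_naive(x, m$sp1$w$v, m$sp1$b$v, pad = 0))
  s <- lrelu(conv_naive(s, m$sp2$w$v, m$sp2$b$v, pad = 1))
  s <- lrelu(conv_naive(s, m$sp3$w$v, m$sp3$b$v, pad = 1))
  s <- conv_naive(s, m$sp4$w$v, m$sp4$b$v, pad = 0)   # (3,3,1,1)
  want <- array(0, c(3, 3, C, 1))
  for (ci in 1:C) want[, , ci, 1] <- chl[ci] + s[, , 1, 1]
  expect_equal(got$v, want, tolerance = 1e-10)
})

test_that("BAM yields half-gates on constant input with zeroed output layers", {
  m <- ns$nn_bam(16L, reduction = 4L, dilation = 2L)
  m$fc2$w$v[] <- 0; m$fc2$b$v[] <- 0
  m$sp4$w$v[] <- 0; m$sp4$b$v[] <- 0
  x <- ns$ag_tensor(array(1.5, c(8, 8, 16, 1)))
  out <- ns$bam_apply(m, x)
  expect_equal(dim(out$v), c(8L, 8L, 16L, 1L))
  expect_equal(max(abs(out$v)), 0)
  gate <- ns$ag_sigmoid(out)
  expect_equal(unique(as.numeric(gate$v)), 0.5)
  expect_error(ns$nn_bam(8L, reduction = 16L), "reduction")
})

test_that("CFS reduces to the identity when the fused feature is zero", {
  set.seed(3)
  m <- ns$nn_cfs(4L, bam_reduction = 2L, bam_dilation = 1L)
  zero_params(m$ff)   # forces fF = 0; BAM weights stay random
  for (p in nn_params(m$bamR)) p$v[] <- rnorm(length(p$v), 0, 0.3)
  for (p in nn_params(m$bamD)) p$v[] <- rnorm(length(p$v), 0, 0.3)
  fR <- rand_feat(8, 8, 4)
  fD <- rand_feat(8, 8, 4)
  out <- ns$cfs_apply(m, ns$ag_tensor(fR), ns$ag_tensor(fD))
  expect_identical(out$bfR$v, fR)   # bit-exact: fR + gate * 0
  expect_identical(out$bfD$v, fD)
})

test_that("CFS matches a step-by-step recomputation and bounds the update", {
  set.seed(17)
  m <- ns$nn_cfs(4L, bam_reduction = 2L, bam_dilation = 1L)
  for (p in nn_params(m)) p$v[] <- rnorm(length(p$v), 0, 0.4)
  fR <- rand_feat(8, 8, 4); fD <- rand_feat(8, 8, 4)
  out <- ns$cfs_apply(m, ns$ag_tensor(fR), ns$ag_tensor(fD))

  # independent recomputation with the loop conv oracle and plain array math
  sa <- conv_naive(fR, m$ff$sa$w$v, m$ff$sa$b$v)
  sb <- conv_naive(fD, m$ff$sb$w$v, m$ff$sb$b$v)
  fF <- sa * sb
  cat2 <- array(0, c(8, 8, 8, 1))
  cat2[, , 1:4, ] <- fF + sa
  cat2[, , 5:8, ] <- fF + sb
  fFm <- conv_naive(conv_naive(cat2, m$ff$merge$dw$w$v, m$ff$merge$dw$b$v,
                               pad = 1, groups = 8),
                    m$ff$merge$pw$w$v, m$ff$merge$pw$b$v)
  bam_by_hand <- function(bm, x) {
    gap <- apply(x[, , , 1], 3, mean)
    chl <- bm$fc2$w$v %*% lrelu(bm$fc1$w$v %*% gap + bm$fc1$b$v) + bm$fc2$b$v
    s <- lrelu(conv_naive(x, bm$sp1$w$v, bm$sp1$b$v))
    s <- lrelu(conv_naive(s, bm$sp2$w$v, bm$sp2$b$v, pad = 1))
    s <- lrelu(conv_naive(s, bm$sp3$w$v, bm$sp3$b$v, pad = 1))
    s <- conv_naive(s, bm$sp4$w$v, bm$sp4$b$v)
    out <- array(0, dim(x))
    for (ci in seq_len(dim(x)[3])) out[, , ci, 1] <- chl[ci] + s[, , 1, 1]
    out
  }
  gateR <- 1 / (1 + exp(-bam_by_hand(m$bamR, fR)))
  gateD <- 1 / (1 + exp(-bam_by_hand(m$bamD, fD)))
  expect_equal(out$bfR$v, fR + gateR * fFm, tolerance = 1e-6)
  expect_equal(out$bfD$v, fD + gateD * fFm, tolerance = 1e-6)

  # gate boundedness: the supplementation never exceeds the fused feature
  expect_lte(max(abs(out$bfR$v - fR)), max(abs(fFm)))
  expect_lte(max(abs(out$bfD$v - fD)), max(abs(fFm)))
  expect_true(all(gateR > 0 & gateR < 1))
})

test_that("RFB preserves shape and shuffles channels by the closed form", {
  m <- ns$nn_rfb(32L)
  x <- ns$ag_tensor(rand_feat(14, 14, 32))
  expect_equal(dim(ns$rfb_apply(m, x)$v), dim(x$v))
  expect_error(ns$nn_rfb(7L), "even")

  # identity residual, zeroed branches: output = shuffle of [A, 0]
  m8 <- ns$nn_rfb(8L)
  zero_params(m8)
  for (ci in 1:4) m8$res$w$v[1, 1, ci, ci] <- 1
  xv <- array(0, c(2, 2, 8, 1))
  for (ci in 1:8) xv[, , ci, ] <- ci           # labelled channels
  out <- ns$rfb_apply(m8, ns$ag_tensor(xv))
  got_labels <- out$v[1, 1, , 1]
  want <- numeric(8)
  half_labels <- c(1:4, 0, 0, 0, 0)            # [A, 0] before shuffle
  perm <- as.vector(matrix(1:8, nrow = 2, byrow = TRUE))
  expect_equal(got_labels, half_labels[perm])
  expect_true(all(sort(ns$shuffle_perm(8L)) == 1:8))   # bijection
})

test_that("CFF equals the manual composition of its verified parts", {
  set.seed(23)
  m <- ns$nn_cff(6L, 8L, width = 8L, has_prev = TRUE, c_prev = 8L)
  for (p in nn_params(m)) p$v[] <- rnorm(length(p$v), 0, 0.3)
  R_lo <- ns$ag_tensor(rand_feat(8, 8, 6))
  R_hi <- ns$ag_tensor(rand_feat(4, 4, 8))
  D_lo <- ns$ag_tensor(rand_feat(8, 8, 6))
  D_hi <- ns$ag_tensor(rand_feat(4, 4, 8))
  prev <- ns$ag_tensor(rand_feat(4, 4, 8))
  got <- ns$cff_apply(m, R_lo, R_hi, D_lo, D_hi, f_prev = prev)

  # manual composition out of already-verified primitives
  aR_lo <- ns$conv_apply(m$adapters$R_lo, R_lo)
  aR_hi <- ns$conv_apply(m$adapters$R_hi, ns$ag_upsample(R_hi, 8, 8))
  aD_lo <- ns$conv_apply(m$adapters$D_lo, D_lo)
  aD_hi <- ns$conv_apply(m$adapters$D_hi, ns$ag_upsample(D_hi, 8, 8))
  bfRm <- ns$ff_apply(m$ffR, aR_lo, aR_hi)
  bfDm <- ns$ff_apply(m$ffD, aD_lo, aD_hi)
  fFm <- ns$ff_apply(m$ffX, bfRm, bfDm)
  up_prev <- ns$conv_apply(m$prev_proj, ns$ag_upsample(prev, 8, 8))
  want <- ns$rfb_apply(m$rfb, ns$ag_concat_c(list(fFm, up_prev)))
  expect_equal(got$v, want$v, tolerance = 1e-6)
})

test_that("CFF structure: zero propagation and the prev-link width", {
  m0 <- ns$nn_cff(4L, 6L, width = 8L, has_prev = FALSE)
  zero_params(m0)
  z <- function(H, C) ns$ag_tensor(array(0, c(H, H, C, 1)))
  out <- ns$cff_apply(m0, z(8, 4), z(4, 6), z(8, 4), z(4, 6))
  expect_equal(max(abs(out$v)), 0)
  # pre-RFB channel count differs by exactly the prev projection width
  m1 <- ns$nn_cff(4L, 6L, width = 8L, has_prev = TRUE, c_prev = 10L)
  expect_equal(m1$rfb$c - m0$rfb$c, 8L)
  expect_error(ns$cff_apply(m1, z(8, 4), z(4, 6), z(8, 4), z(4, 6)),
               "previous")
})
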