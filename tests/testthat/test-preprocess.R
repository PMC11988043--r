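# Preprocessing and paired augmentation.

make_pair <- function(res = 48, seed = 5, noise = TRUE) {
  sp <- scene_params(150, 110, 80, density = 8e-7, rng_seed = seed,
                     noise_sigma_depth = if (noise) 5 else 0,
                     noise_sigma_rgb = if (noise) 0.02 else 0)
  render_scene(sp, resolution = res)
}

test_that("small-sigma smoothing approaches the identity", {
  pair <- make_pair()
  out <- preprocess_pair(pair, gaussian_sigma = 0.05)
  expect_lt(max(abs(out$rgb - pair$rgb)), 1e-3)
  expect_lt(max(abs(out$depth - pair$depth)), 1e-2)
  expect_identical(out$weight, pair$weight)
})

test_that("color normalization yields zero-mean unit-variance channels", {
  pair <- make_pair()
  pair$rgb[] <- 0.4  # constant image: normalization must not divide by zero
  out <- preprocess_pair(pair, gaussian_sigma = 1, color_norm = TRUE)
  for (ch in 1:3) expect_equal(mean(out$rgb[, , ch]), 0, tolerance = 1e-12)

  pair2 <- make_pair()
  out2 <- preprocess_pair(pair2, gaussian_sigma = 1, color_norm = TRUE)
  for (ch in 1:3) {
    expect_equal(mean(out2$rgb[, , ch]), 0, tolerance = 1e-10)
    expect_equal(sd(out2$rgb[, , ch]), 1, tolerance = 1e-10)
  }
})

test_that("5x5 toy image matches direct convolution with the sampled kernel", {
  set.seed(8)
  img <- matrix(runif(25), 5, 5)
  k1 <- exp(-(-3:3)^2 / 2)   # sigma = 1, radius 3
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  want <- matrix(0, 5, 5)
  for (r in 1:5) for (cc in 1:5) {
    s <- 0
    for (i in -3:3) for (j in -3:3) {
      ri <- min(max(r + i, 1), 5)   # replicated edges
      cj <- min(max(cc + j, 1), 5)
      s <- s + img[ri, cj] * K[i + 4, j + 4]
    }
    want[r, cc] <- s
  }
  got <- ns$gaussian_smooth_mat(img, 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("depth smoothing ignores invalid (zero) pixels", {
  pair <- make_pair(noise = FALSE)
  pair$depth[10:12, 10:12] <- 0L
  out <- preprocess_pair(pair, gaussian_sigma = 1)
  expect_true(all(out$depth[10:12, 10:12] == 0))      # holes stay holes
  valid <- pair$depth > 0
  expect_gt(min(out$depth[valid]), 400)               # no bleed toward zero
})

test_that("non-positive sigma is rejected", {
  expect_error(preprocess_pair(make_pair(), gaussian_sigma = 0), "positive")
})

test_that("disabled augmentation is resize-only and flips are involutions", {
  pair <- make_pair(res = 64, noise = FALSE)
  off <- augment_config(hflip_prob = 0, vflip_prob = 0, rotate_deg = 0,
                        crop_prob = 0, jitter = 0, blur_prob = 0, out_size = 32)
  a <- augment_pair(pair, off, seed = 1)
  expect_equal(dim(a$rgb), c(32, 32, 3))
  expect_equal(a$rgb[, , 2], ns$resize_mat(pair$rgb[, , 2], 32, 32),
               tolerance = 1e-12)
  expect_equal(a$depth, ns$resize_mat(pair$depth * 1.0, 32, 32),
               tolerance = 1e-12)
  expect_identical(a$weight, pair$weight)

  flip <- off; flip$hflip_prob <- 1
  f1 <- augment_pair(pair, flip, seed = 2)
  # rgb and depth flipped identically: silhouettes still roughly coincide
  # (boundary ring differs through the two thresholds after interpolation)
  expect_gt(iou(rgb_silhouette(f1$rgb), f1$depth < 1180), 0.8)
  # flipping the already-flipped pair restores the resized original
  pair_flipped <- pair
  pair_flipped$rgb <- pair$rgb[, rev(seq_len(64)), , drop = FALSE]
  pair_flipped$depth <- pair$depth[, rev(seq_len(64))]
  f2 <- augment_pair(pair_flipped, flip, seed = 3)
  expect_equal(f2$rgb, a$rgb, tolerance = 1e-10)
  expect_equal(f2$depth, a$depth, tolerance = 1e-10)
})

test_that("full-turn rotation equals the resize-only output", {
  pair <- make_pair(res = 64, noise = FALSE)
  off <- augment_config(hflip_prob = 0, vflip_prob = 0, rotate_deg = 0,
                        crop_prob = 0, jitter = 0, blur_prob = 0, out_size = 32)
  base <- augment_pair(pair, off, seed = 1)
  rot <- ns$rotate_pair(list(rgb = pair$rgb, depth = pair$depth * 1.0,
                             weight = pair$weight), 2 * pi)
  rot360 <- list(rgb = rot$rgb, depth = rot$depth, weight = pair$weight)
  class(rot360) <- "rgbd_pair"
  got <- augment_pair(rot360, off, seed = 1)
  # interior agrees to interpolation accuracy; the outermost ring feels the
  # rotation's constant-fill handling
  core <- 3:30
  expect_lt(max(abs(got$rgb[core, core, ] - base$rgb[core, core, ])), 1e-6)
  expect_lt(max(abs(got$depth[core, core] - base$depth[core, core])), 1e-4)
  expect_lt(mean(abs(got$rgb - base$rgb)), 1e-3)
})

test_that("geometric transforms move both modalities' silhouettes together", {
  # sharp binary silhouette carried in BOTH modalities: if the same geometric
  # transform hits rgb and depth, the recovered masks must coincide almost
  # exactly (only identical boundary interpolation on both sides)
  sp <- scene_params(150, 110, 80, density = 8e-7, rng_seed = 5,
                     noise_sigma_depth = 0, noise_sigma_rgb = 0)
  base <- render_scene(sp, resolution = 96)
  mask <- silhouette_mask(base) * 1.0
  mp <- list(rgb = array(rep(mask, 3), c(96, 96, 3)),
             depth = mask * 1000, weight = base$weight)
  class(mp) <- "rgbd_pair"
  cfg <- augment_config(hflip_prob = 1, vflip_prob = 1, rotate_deg = 25,
                        crop_prob = 1, jitter = 0, blur_prob = 0, out_size = 64)
  for (s in 1:5) {
    a <- augment_pair(mp, cfg, seed = s)
    m_rgb <- a$rgb[, , 1] > 0.5
    m_depth <- a$depth > 500
    expect_gt(iou(m_rgb, m_depth), 0.99)
  }

  # rendered scene: the two modality-specific thresholds still agree closely
  pair <- render_scene(sp, resolution = 96)
  for (s in 1:3) {
    a <- augment_pair(pair, cfg, seed = s)
    expect_gt(iou(rgb_silhouette(a$rgb), a$depth > 0 & a$depth < 1180), 0.8)
  }
})

test_that("photometric transforms leave the depth map untouched", {
  pair <- make_pair(res = 48, noise = FALSE)
  cfg <- augment_config(hflip_prob = 0, vflip_prob = 0, rotate_deg = 0,
                        crop_prob = 0, jitter = 0.3, blur_prob = 1,
                        blur_sigma = 1.5, out_size = 48)
  a <- augment_pair(pair, cfg, seed = 4)
  expect_equal(a$depth, ns$resize_mat(pair$depth * 1.0, 48, 48),
               tolerance = 1e-12)
  expect_gt(max(abs(a$rgb - pair$rgb)), 0.005)  # rgb actually changed
})
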