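## Image preprocessing and paired augmentation.
##
## Geometric transforms (crop, flip, rotation) are applied identically to the
## color image and the depth map; photometric transforms (jitter, blur) touch
## the color image only. All interpolation is bilinear with half-pixel
## centers, matching the network-side resize.

#' Sampled, normalized 1-D Gaussian kernel
#' @param sigma standard deviation in pixels (> 0).
#' @param radius half-width; default `ceiling(3 * sigma)`.
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## separable 2-D Gaussian smoothing with edge replication
gaussian_smooth_mat <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n1 <- nrow(m); n2 <- ncol(m)
  ridx <- clamp(outer(seq_len(n1), seq(-r, r), `+`), 1L, n1)
  out <- matrix(0, n1, n2)
  for (j in seq_along(k)) out <- out + m[ridx[, j], , drop = FALSE] * k[j]
  cidx <- clamp(outer(seq_len(n2), seq(-r, r), `+`), 1L, n2)
  out2 <- matrix(0, n1, n2)
  for (j in seq_along(k)) out2 <- out2 + out[, cidx[, j], drop = FALSE] * k[j]
  out2
}

#' Preprocess an RGB-D pair
#'
#' Gaussian smoothing of both images (the depth map on valid pixels only,
#' via normalized convolution so invalid zeros never bleed into neighbours)
#' and optional per-channel color normalization to zero mean / unit variance.
#' The weight label is untouched.
#'
#' @param pair an `rgbd_pair`.
#' @param gaussian_sigma smoothing sd in pixels (> 0).
#' @param color_norm z-score each color channel?
#' @return the preprocessed pair (depth returned as numeric mm).
#' @export
preprocess_pair <- function(pair, gaussian_sigma = 1, color_norm = FALSE) {
  if (gaussian_sigma <= 0)
    stop("preprocess_pair: gaussian_sigma must be positive")
  rgb <- pair$rgb
  for (ch in 1:3)
    rgb[, , ch] <- gaussian_smooth_mat(rgb[, , ch], gaussian_sigma)
  if (color_norm) {
    for (ch in 1:3) {
      v <- rgb[, , ch]
      s <- stats::sd(v)
      rgb[, , ch] <- (v - mean(v)) / if (s > 0) s else 1
    }
  }
  d <- pair$depth * 1.0
  valid <- d > 0
  if (all(valid)) {
    d <- gaussian_smooth_mat(d, gaussian_sigma)
  } else {
    num <- gaussian_smooth_mat(d * valid, gaussian_sigma)
    den <- gaussian_smooth_mat(valid * 1.0, gaussian_sigma)
    d <- ifelse(den > 1e-9, num / den, 0)
    d[!valid] <- 0
  }
  out <- pair
  out$rgb <- rgb
  out$depth <- d
  out
}

## bilinear sample of matrix m at (rows, cols) grids (1-based, fractional)
bilinear_sample <- function(m, R, C, fill) {
  n1 <- nrow(m); n2 <- ncol(m)
  inside <- R >= 1 & R <= n1 & C >= 1 & C <= n2
  Rc <- clamp(R, 1, n1); Cc <- clamp(C, 1, n2)
  r0 <- pmin(floor(Rc), n1 - 1); c0 <- pmin(floor(Cc), n2 - 1)
  fr <- Rc - r0; fc <- Cc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  v <- (1 - fr) * (1 - fc) * m[i00] +
       fr * (1 - fc) * m[i00 + rep(c(1L, 0L), each = length(fr))] +
       (1 - fr) * fc * m[i00 + rep(c(0L, 1L), each = length(fr))] +
       fr * fc * m[i00 + rep(c(1L, 1L), each = length(fr))]
  v[!inside] <- fill
  matrix(v, nrow(R), ncol(R))
}

## resize a matrix to (Ho, Wo) with the shared bilinear convention
resize_mat <- function(m, Ho, Wo) {
  v <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  resize_bilinear_arr(v, Ho, Wo)[, , 1L, 1L]
}

apply_to_pair_channels <- function(pair, fn_rgb, fn_depth) {
  planes <- lapply(1:3, function(ch) fn_rgb(pair$rgb[, , ch]))
  rgb <- array(0, c(nrow(planes[[1]]), ncol(planes[[1]]), 3L))
  for (ch in 1:3) rgb[, , ch] <- planes[[ch]]
  out <- pair
  out$rgb <- rgb
  out$depth <- fn_depth(pair$depth * 1.0)
  out
}

#' Augmentation configuration
#'
#' Probabilities set to 1 force a transform (useful in tests); 0 disables it.
#' @param hflip_prob,vflip_prob flip probabilities.
#' @param rotate_deg maximum absolute rotation angle (degrees); 0 disables.
#' @param crop_prob probability of a random aspect-ratio crop.
#' @param crop_scale area fraction range of the crop.
#' @param crop_aspect aspect-ratio range of the crop.
#' @param jitter color jitter amplitude (multiplicative, per channel).
#' @param blur_prob,blur_sigma Gaussian blur probability and sd.
#' @param out_size final square size both images are resized to.
#' @export
augment_config <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                           rotate_deg = 15, crop_prob = 0.5,
                           crop_scale = c(0.7, 1), crop_aspect = c(3 / 4, 4 / 3),
                           jitter = 0.1, blur_prob = 0.2, blur_sigma = 1,
                           out_size = 224L) {
  list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
       rotate_deg = rotate_deg, crop_prob = crop_prob,
       crop_scale = crop_scale, crop_aspect = crop_aspect,
       jitter = jitter, blur_prob = blur_prob, blur_sigma = blur_sigma,
       out_size = as.integer(out_size))
}

#' Augment an RGB-D pair
#'
#' Applies one random geometric transform chain (crop, flips, rotation) to
#' both images identically, photometric transforms (jitter, blur) to the
#' color image only, and resizes both to `config$out_size`. The weight label
#' is unchanged.
#'
#' @param pair an `rgbd_pair`.
#' @param config an [augment_config()].
#' @param seed integer seed for the random draws.
#' @return augmented `rgbd_pair` (depth numeric).
#' @export
augment_pair <- function(pair, config = augment_config(), seed = 1L) {
  local_seed(seed, {
    p <- pair
    p$depth <- p$depth * 1.0
    n1 <- nrow(p$depth); n2 <- ncol(p$depth)

    ## random aspect-ratio crop (re-drawn until it fits; always fits since
    ## scale <= 1 and aspect close to 1, clamped to the frame)
    if (stats::runif(1) < config$crop_prob) {
      area <- stats::runif(1, config$crop_scale[1], config$crop_scale[2]) * n1 * n2
      asp <- stats::runif(1, config$crop_aspect[1], config$crop_aspect[2])
      ch <- min(n1, round(sqrt(area / asp)))
      cw <- min(n2, round(sqrt(area * asp)))
      r0 <- sample.int(n1 - ch + 1L, 1L) - 1L
      c0 <- sample.int(n2 - cw + 1L, 1L) - 1L
      p <- apply_to_pair_channels(p,
        function(m) m[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE],
        function(m) m[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE])
    }
    if (stats::runif(1) < config$hflip_prob)
      p <- apply_to_pair_channels(p, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
                                  function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
    if (stats::runif(1) < config$vflip_prob)
      p <- apply_to_pair_channels(p, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
                                  function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
    if (config$rotate_deg > 0) {
      ang <- stats::runif(1, -config$rotate_deg, config$rotate_deg) * pi / 180
      p <- rotate_pair(p, ang)
    }
    ## photometric: multiplicative channel jitter, then optional blur
    if (config$jitter > 0) {
      f <- stats::runif(3, 1 - config$jitter, 1 + config$jitter)
      for (ch in 1:3) p$rgb[, , ch] <- clamp(p$rgb[, , ch] * f[ch], 0, 1)
    }
    if (stats::runif(1) < config$blur_prob && config$blur_sigma > 0)
      for (ch in 1:3)
        p$rgb[, , ch] <- gaussian_smooth_mat(p$rgb[, , ch], config$blur_sigma)

    s <- config$out_size
    p <- apply_to_pair_channels(p, function(m) resize_mat(m, s, s),
                                function(m) resize_mat(m, s, s))
    p
  })
}

## rotate both images about the center by `ang` radians (bilinear, constant
## fill taken from the border median of each plane)
rotate_pair <- function(pair, ang) {
  n1 <- nrow(pair$depth); n2 <- ncol(pair$depth)
  cy <- (n1 + 1) / 2; cx <- (n2 + 1) / 2
  R <- matrix(rep(seq_len(n1), n2), n1, n2)
  C <- matrix(rep(seq_len(n2), each = n1), n1, n2)
  ## inverse mapping: sample source at rotation by -ang
  dy <- R - cy; dx <- C - cx
  Rs <- cy + cos(ang) * dy - sin(ang) * dx
  Cs <- cx + sin(ang) * dy + cos(ang) * dx
  border_fill <- function(m) stats::median(c(m[1, ], m[n1, ], m[, 1], m[, n2]))
  apply_to_pair_channels(pair,
    function(m) bilinear_sample(m, Rs, Cs, border_fill(m)),
    function(m) bilinear_sample(m, Rs, Cs, border_fill(m)))
}
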