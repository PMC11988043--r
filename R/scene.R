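## Synthetic top-view RGB-D scene generation.
##
## One scene is a single convex body — the upper half of an ellipsoid with
## semi-axes (a, b, c) in mm — resting on a flat ground plane, viewed by a
## fixed-height depth camera pointing straight down. The depth map is
## camera_height minus the body height field (plus sensor noise); the color
## image shows the body silhouette whose hue encodes a density class. True
## weight is closed-form: density times the half-ellipsoid volume
## V = (2/3) * pi * a * b * c, so geometry (readable from depth) and density
## (readable from color) are both needed to recover the weight.

#' Generative parameters of one synthetic scene
#'
#' Validates geometry and sensor parameters and clamps the density so the
#' derived weight lies in `weight_range` (the emulated dataset spans
#' 0.50-5.50 kg).
#'
#' @param semi_axis_x,semi_axis_y,semi_axis_z ellipsoid semi-axes in mm
#'   (x and y in the ground plane, z vertical).
#' @param center_xy length-2 body center offset from the frame center, mm.
#' @param density body density in kg/mm^3.
#' @param camera_height camera distance to the ground plane in mm; must
#'   exceed `semi_axis_z`, and the resulting depths must stay inside the
#'   sensor range 500-5000 mm.
#' @param noise_sigma_depth depth sensor noise sd, mm.
#' @param noise_sigma_rgb color pixel noise sd, on the 0-1 intensity scale.
#' @param hue_code scalar in `[0, 1]` encoding the density class in the body
#'   color; defaults to the density's position inside `density_range`.
#' @param rng_seed integer seed; fully determines the rendered scene.
#' @param weight_range attainable weight interval in kg (density is clamped
#'   into it).
#' @param density_range kg/mm^3 interval that `hue_code` linearly encodes.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(semi_axis_x, semi_axis_y, semi_axis_z,
                         center_xy = c(0, 0),
                         density = 1e-6,
                         camera_height = 1200,
                         noise_sigma_depth = 5,
                         noise_sigma_rgb = 0.02,
                         hue_code = NULL,
                         rng_seed = 1L,
                         weight_range = c(0.5, 5.5),
                         density_range = c(5e-7, 1.5e-6)) {
  if (any(c(semi_axis_x, semi_axis_y, semi_axis_z) <= 0))
    stop("scene_params: semi-axes must be positive")
  if (camera_height <= semi_axis_z)
    stop("scene_params: camera_height must exceed semi_axis_z")
  if (camera_height - semi_axis_z < 500 || camera_height > 5000)
    stop("scene_params: depths would leave the 500-5000 mm sensor range")
  vol <- half_ellipsoid_volume(semi_axis_x, semi_axis_y, semi_axis_z)
  density <- clamp(density, weight_range[1] / vol, weight_range[2] / vol)
  if (is.null(hue_code))
    hue_code <- clamp((density - density_range[1]) /
                        diff(density_range), 0, 1)
  p <- list(semi_axis_x = semi_axis_x, semi_axis_y = semi_axis_y,
            semi_axis_z = semi_axis_z, center_xy = center_xy,
            density = density, hue_code = hue_code,
            camera_height = camera_height,
            noise_sigma_depth = noise_sigma_depth,
            noise_sigma_rgb = noise_sigma_rgb,
            rng_seed = as.integer(rng_seed),
            weight_range = weight_range, density_range = density_range)
  class(p) <- "scene_params"
  p
}

#' Volume under the upper-half-ellipsoid height field
#' @param a,b,c semi-axes in mm.
#' @return volume in mm^3, `(2/3) * pi * a * b * c`.
#' @export
half_ellipsoid_volume <- function(a, b, c) (2 / 3) * pi * a * b * c

#' Render one synthetic RGB-D pair
#'
#' @param params a [scene_params()].
#' @param resolution square image size in pixels.
#' @param extent_mm ground-plane side length imaged by the frame, mm.
#' @param sample_id identifier stored in the pair.
#' @return list of class `rgbd_pair` with elements `rgb` (resolution^2 x 3
#'   array in `[0, 1]`, 8-bit quantized), `depth` (integer matrix, mm),
#'   `weight` (kg, exact closed form, pre-noise) and `sample_id`.
#' @export
render_scene <- function(params, resolution = 480L, extent_mm = 800,
                         sample_id = "scene") {
  p <- params
  half <- extent_mm / 2
  if (abs(p$center_xy[1]) + p$semi_axis_x > half ||
      abs(p$center_xy[2]) + p$semi_axis_y > half)
    stop("render_scene: body footprint exceeds the image frame")
  n <- as.integer(resolution)
  px <- extent_mm / n
  ## pixel-center coordinates, row-major image with origin top-left:
  ## rows advance +y, columns advance +x
  xs <- (seq_len(n) - 0.5) * px - half
  ys <- (seq_len(n) - 0.5) * px - half
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  r2 <- ((X - p$center_xy[1]) / p$semi_axis_x)^2 +
        ((Y - p$center_xy[2]) / p$semi_axis_y)^2
  h <- p$semi_axis_z * sqrt(pmax(1 - r2, 0))  # first arg keeps the dims
  mask <- r2 < 1

  local_seed(p$rng_seed, {
    depth <- p$camera_height - h
    if (p$noise_sigma_depth > 0)
      depth <- depth + matrix(stats::rnorm(n * n, 0, p$noise_sigma_depth), n, n)
    depth <- round(clamp(depth, 500, 5000))
    storage.mode(depth) <- "integer"

    ## background: mid gray plus low-amplitude smoothed procedural noise
    bg <- matrix(stats::rnorm(n * n, 0, 1), n, n)
    bg <- box_smooth(bg, 3L)
    bg <- 0.5 + 0.08 * bg / max(abs(bg), 1e-9)
    body_col <- grDevices::hsv(h = 0.75 * p$hue_code, s = 0.8, v = 1)
    body_rgb <- grDevices::col2rgb(body_col)[, 1] / 255
    shade <- 0.55 + 0.45 * (h / p$semi_axis_z)   # relative, leaks no scale
    rgb <- array(0, c(n, n, 3L))
    for (ch in 1:3) {
      plane <- bg
      plane[mask] <- body_rgb[ch] * shade[mask]
      if (p$noise_sigma_rgb > 0)
        plane <- plane + matrix(stats::rnorm(n * n, 0, p$noise_sigma_rgb), n, n)
      rgb[, , ch] <- plane
    }
    rgb <- round(clamp(rgb, 0, 1) * 255) / 255

    pair <- list(rgb = rgb, depth = depth,
                 weight = p$density *
                   half_ellipsoid_volume(p$semi_axis_x, p$semi_axis_y,
                                         p$semi_axis_z),
                 sample_id = sample_id)
    class(pair) <- "rgbd_pair"
    pair
  })
}

## cheap 2-D box smoothing used only for the background texture
box_smooth <- function(m, k = 3L) {
  n <- nrow(m)
  out <- m
  idx <- function(i) clamp(i, 1L, n)
  acc <- matrix(0, n, n)
  cnt <- 0L
  for (di in -(k %/% 2L):(k %/% 2L)) {
    for (dj in -(k %/% 2L):(k %/% 2L)) {
      acc <- acc + m[idx(seq_len(n) + di), idx(seq_len(n) + dj)]
      cnt <- cnt + 1L
    }
  }
  acc / cnt
}

#' Body silhouette mask of a rendered pair
#'
#' Pixels whose depth lies clearly above the ground plane. Used by the
#' geometric-consistency checks and the activation-map evaluation.
#' @param pair an `rgbd_pair`.
#' @param camera_height camera height used at render time, mm.
#' @param tol_mm minimum height above ground to count as body, mm.
#' @return logical matrix.
#' @export
silhouette_mask <- function(pair, camera_height = 1200, tol_mm = 20) {
  pair$depth > 0 & pair$depth < (camera_height - tol_mm)
}
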