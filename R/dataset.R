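## Dataset generation, file I/O and manifest handling.
##
## On disk a dataset is: 8-bit PNG color images, single-channel 16-bit TIFF
## depth maps (1 unit = 1 mm, 0 = invalid/no-return), and a CSV manifest with
## header `sample_id,rgb_path,depth_path,weight_kg,split`.

DEPTH_SCALE <- 65535  # 16-bit TIFF stores depth_mm / DEPTH_SCALE

#' Generate a synthetic weight-labelled RGB-D dataset
#'
#' Draws `n` scenes with weights uniform over `weight_range` and density
#' drawn independently of the weight, so that body volume (depth modality)
#' and density class (color modality) are both required to determine the
#' weight. Writes images and the manifest under `out_dir`.
#'
#' @param n number of pairs (>= 1).
#' @param seed integer; fully determines the dataset.
#' @param out_dir output directory (created if needed).
#' @param weight_range weight interval in kg, default 0.50-5.50.
#' @param resolution rendered square image size in pixels.
#' @param extent_mm imaged ground-plane side length, mm.
#' @param camera_height camera height, mm.
#' @param density_range density interval in kg/mm^3 encoded by the body hue.
#' @param noise_sigma_depth,noise_sigma_rgb sensor noise levels.
#' @return the manifest as a data.frame (also written to
#'   `out_dir/manifest.csv`); all rows initially carry split `"train"`.
#' @export
generate_dataset <- function(n, seed, out_dir,
                             weight_range = c(0.5, 5.5),
                             resolution = 480L,
                             extent_mm = 800,
                             camera_height = 1200,
                             density_range = c(5e-7, 1.5e-6),
                             noise_sigma_depth = 5,
                             noise_sigma_rgb = 0.02) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir)
  rows <- vector("list", n)
  s0 <- as.numeric(sub_seed(seed, "scene"))
  for (i in seq_len(n)) {
    sp <- draw_scene_params(as.integer((s0 + i) %% 2147483629), weight_range,
                            extent_mm, camera_height, density_range,
                            noise_sigma_depth, noise_sigma_rgb)
    id <- sprintf("s%05d", i)
    pair <- render_scene(sp, resolution = resolution, extent_mm = extent_mm,
                         sample_id = id)
    rgb_path <- file.path("rgb", paste0(id, ".png"))
    depth_path <- file.path("depth", paste0(id, ".tif"))
    write_pair(pair, file.path(out_dir, rgb_path), file.path(out_dir, depth_path))
    rows[[i]] <- data.frame(sample_id = id, rgb_path = rgb_path,
                            depth_path = depth_path, weight_kg = pair$weight,
                            split = "train", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

## Scene parameters for one dataset entry. Weight is drawn uniform, density
## uniform and independent; volume = weight / density is then distributed to
## the semi-axes through shape ratios, so no single modality determines the
## weight (color lacks body height; depth lacks density).
draw_scene_params <- function(seed, weight_range, extent_mm, camera_height,
                              density_range, noise_sigma_depth,
                              noise_sigma_rgb) {
  local_seed(seed, {
    w <- stats::runif(1, weight_range[1], weight_range[2])
    rho <- stats::runif(1, density_range[1], density_range[2])
    vol <- w / rho
    rx <- stats::runif(1, 1.2, 2.2)   # a / c
    ry <- stats::runif(1, 0.9, 1.5)   # b / c
    cz <- (vol / ((2 / 3) * pi * rx * ry))^(1 / 3)
    a <- rx * cz
    b <- ry * cz
    margin_x <- extent_mm / 2 - a
    margin_y <- extent_mm / 2 - b
    cx <- stats::runif(1, -0.5, 0.5) * min(margin_x, 80)
    cy <- stats::runif(1, -0.5, 0.5) * min(margin_y, 80)
    scene_params(a, b, cz, center_xy = c(cx, cy), density = rho,
                 camera_height = camera_height,
                 noise_sigma_depth = noise_sigma_depth,
                 noise_sigma_rgb = noise_sigma_rgb,
                 rng_seed = seed, weight_range = weight_range,
                 density_range = density_range)
  })
}

#' Write one RGB-D pair to disk
#' @param pair an `rgbd_pair`.
#' @param rgb_path PNG path (8-bit color).
#' @param depth_path TIFF path (16-bit single channel, 1 unit = 1 mm).
#' @export
write_pair <- function(pair, rgb_path, depth_path) {
  dir.create(dirname(rgb_path), recursive = TRUE, showWarnings = FALSE)
  dir.create(dirname(depth_path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pair$rgb, rgb_path)
  tiff::writeTIFF(pair$depth / DEPTH_SCALE, depth_path, bits.per.sample = 16L)
  invisible(NULL)
}

#' Read one RGB-D pair
#' @param rgb_path,depth_path image paths as written by [write_pair()].
#' @param weight weight label in kg.
#' @param sample_id identifier.
#' @return an `rgbd_pair` (depth as integer mm).
#' @export
read_pair <- function(rgb_path, depth_path, weight = NA_real_,
                      sample_id = basename(rgb_path)) {
  rgb <- png::readPNG(rgb_path)
  depth <- round(tiff::readTIFF(depth_path) * DEPTH_SCALE)
  storage.mode(depth) <- "integer"
  pair <- list(rgb = rgb, depth = depth, weight = weight,
               sample_id = sample_id)
  class(pair) <- "rgbd_pair"
  pair
}

#' Write a dataset manifest as CSV
#' @param manifest data.frame with columns
#'   `sample_id,rgb_path,depth_path,weight_kg,split`.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest
#' @param path CSV path; relative image paths are resolved against its
#'   directory (stored in the `dir` attribute).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rgb_path", "depth_path", "weight_kg", "split")
  if (!all(need %in% names(m)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("manifest sample_ids are not unique")
  attr(m, "dir") <- dirname(normalizePath(path))
  m
}

#' Randomly assign train/test split tags
#'
#' Random permutation under `seed`; the first `n_train` rows (in permuted
#' order) are tagged `"train"`, the remaining `n_test` rows `"test"`. Row
#' order of the returned manifest is unchanged.
#'
#' @param manifest manifest data.frame.
#' @param n_train,n_test counts; must sum to `nrow(manifest)`.
#' @param seed integer seed; the assignment is reproducible.
#' @return the manifest with an updated `split` column.
#' @export
split_manifest <- function(manifest, n_train, n_test, seed) {
  n <- nrow(manifest)
  if (n_train + n_test != n)
    stop("split_manifest: n_train + n_test (", n_train + n_test,
         ") must equal the number of rows (", n, ")")
  perm <- local_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_test > 0) split[perm[n_train + seq_len(n_test)]] <- "test"
  manifest$split <- split
  manifest
}
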