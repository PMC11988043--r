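# Synthetic scene generator: closed-form weight, determinism, file round
# trips and the train/test split protocol.

test_that("rendered weight equals the closed-form half-ellipsoid mass", {
  sp <- scene_params(100, 100, 100, density = 1e-6, rng_seed = 3)
  pair <- render_scene(sp, resolution = 64)
  expect_equal(pair$weight, 1e-6 * (2 / 3) * pi * 1e6, tolerance = 1e-9)
  expect_s3_class(pair, "rgbd_pair")
  expect_equal(dim(pair$rgb), c(64, 64, 3))
  expect_equal(dim(pair$depth), c(64, 64))
  expect_true(all(pair$depth >= 500 & pair$depth <= 5000))
})

test_that("noise-free rendering is deterministic and integrates to the weight", {
  sp <- scene_params(140, 90, 70, center_xy = c(25, -30), density = 8e-7,
                     noise_sigma_depth = 0, noise_sigma_rgb = 0, rng_seed = 9)
  p1 <- render_scene(sp, resolution = 240, extent_mm = 800)
  p2 <- render_scene(sp, resolution = 240, extent_mm = 800)
  expect_identical(p1$rgb, p2$rgb)
  expect_identical(p1$depth, p2$depth)

  # Riemann-sum oracle: volume from the rendered noise-free height field
  px <- 800 / 240
  h <- sp$camera_height - p1$depth
  vol_num <- sum(h) * px * px
  expect_equal(sp$density * vol_num, p1$weight, tolerance = 5e-3)
})

test_that("scene parameter validation enforces geometry and sensor limits", {
  expect_error(scene_params(-5, 50, 50), "positive")
  expect_error(scene_params(50, 50, 900, camera_height = 800), "camera_height")
  expect_error(render_scene(scene_params(600, 100, 80), extent_mm = 800),
               "footprint")
  # density clamped so derived weight stays within the emulated range
  sp <- scene_params(60, 60, 40, density = 1e-9)
  expect_gte(sp$density * half_ellipsoid_volume(60, 60, 40), 0.5)
  sp <- scene_params(250, 180, 150, density = 1e-4)
  expect_lte(sp$density * half_ellipsoid_volume(250, 180, 150), 5.5)
})

test_that("generate_dataset is reproducible, in range, and round-trips", {
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(10, seed = 7, out_dir = d1, resolution = 48)
  m2 <- generate_dataset(10, seed = 7, out_dir = d2, resolution = 48)
  expect_identical(m1, m2)   # paths are relative, so full manifests match
  sums1 <- tools::md5sum(file.path(d1, c(m1$rgb_path, m1$depth_path)))
  sums2 <- tools::md5sum(file.path(d2, c(m2$rgb_path, m2$depth_path)))
  expect_equal(unname(sums1), unname(sums2))

  # round trip: written files reproduce the rendered pair exactly
  back <- read_pair(file.path(d1, m1$rgb_path[1]), file.path(d1, m1$depth_path[1]),
                    weight = m1$weight_kg[1])
  expect_true(all(back$depth >= 500 & back$depth <= 5000))
  man_back <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(man_back$weight_kg, m1$weight_kg, tolerance = 1e-12)
  expect_equal(man_back$sample_id, m1$sample_id)

  # pixel-identical round trip of one explicit pair
  sp <- scene_params(120, 100, 80, density = 9e-7, rng_seed = 12)
  pair <- render_scene(sp, resolution = 64)
  fr <- tempfile(fileext = ".png"); fd <- tempfile(fileext = ".tif")
  write_pair(pair, fr, fd)
  rt <- read_pair(fr, fd, weight = pair$weight)
  expect_equal(rt$rgb, pair$rgb, tolerance = 1 / 255 / 2)
  expect_identical(rt$depth, pair$depth)
})

test_that("generated weights are approximately uniform over the stated range", {
  d <- file.path(tempdir(), "gen_u")
  unlink(d, recursive = TRUE)
  m <- generate_dataset(1000, seed = 21, out_dir = d, resolution = 24)
  expect_equal(nrow(m), 1000)
  expect_gte(min(m$weight_kg), 0.5)
  expect_lte(max(m$weight_kg), 5.5)
  # rough uniformity: quartiles near the uniform expectation
  q <- quantile(m$weight_kg, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), c(1.75, 3.0, 4.25), tolerance = 0.12)
})

test_that("split_manifest reproduces the study's 2325/540 protocol", {
  man <- data.frame(sample_id = sprintf("s%04d", 1:2865),
                    rgb_path = "r.png", depth_path = "d.tif",
                    weight_kg = runif(2865, 0.5, 5.5), split = "train")
  sp <- split_manifest(man, 2325, 540, seed = 42)
  expect_equal(sum(sp$split == "train"), 2325)
  expect_equal(sum(sp$split == "test"), 540)
  expect_setequal(unique(sp$split), c("train", "test"))

  expect_identical(split_manifest(man, 2865, 0, seed = 1)$split,
                   rep("train", 2865))
  expect_error(split_manifest(man, 2000, 100, seed = 1), "must equal")

  s1 <- split_manifest(man, 2325, 540, seed = 42)
  s2 <- split_manifest(man, 2325, 540, seed = 42)
  s3 <- split_manifest(man, 2325, 540, seed = 43)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, s3$split))
})
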