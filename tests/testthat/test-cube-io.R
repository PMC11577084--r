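make_cube <- function(nl = 6, ns = 5, nb = 7, seed = 3) {
  rotospec:::with_seed(seed, {
    spectral_cube(array(runif(nl * ns * nb), c(nl, ns, nb)),
                  seq(380, 1018, length.out = nb))
  })
}

test_that("ENVI write/read round-trips exactly in all interleaves", {
  cube <- make_cube()
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile()
    write_envi(cube, path, interleave = il)
    back <- read_envi(paste0(path, ".hdr"))
    expect_identical(back$values, cube$values)
    expect_equal(back$wavelengths, cube$wavelengths, tolerance = 1e-9)
  }
})

test_that("ENVI reader rejects a binary/header size mismatch", {
  cube <- make_cube(nb = 8)
  path <- tempfile()
  write_envi(cube, path)
  # truncate the binary by one band's worth of doubles
  sz <- file.info(path)$size
  con <- file(path, "r+b")
  truncate_to <- sz - 6 * 5 * 8
  raw <- readBin(con, "raw", truncate_to)
  close(con)
  writeBin(raw, path)
  expect_error(read_envi(paste0(path, ".hdr")), "does not match")
})

test_that("reflectance correction implements the dark/white formula", {
  d <- c(4, 4, 3)
  white <- matrix(110, 4, 4)
  dark <- matrix(10, 4, 4)
  frames <- calibration_frames(white, dark)

  origin_w <- spectral_cube(array(110, d), 1:3)
  expect_true(all(reflectance_correct(origin_w, frames)$values == 1))

  origin_d <- spectral_cube(array(10, d), 1:3)
  expect_true(all(reflectance_correct(origin_d, frames)$values == 0))

  origin <- spectral_cube(array(30, d), 1:3)
  out <- reflectance_correct(origin, frames)
  expect_equal(out$values[1, 1, 1], 0.2)   # (30 - 10) / (110 - 10)
  expect_true(out$reflectance)

  bad <- calibration_frames(matrix(10, 4, 4), matrix(10, 4, 4))
  expect_error(reflectance_correct(origin, bad), "white == dark")
})

test_that("region growing fills uniform images and respects contrast", {
  img <- matrix(1, 30, 30)
  m <- region_grow_roi(img, c(15, 15), 2.2, 50, c(100, 100))
  expect_true(sum(m$mask) > 0.9 * 900)   # target size never reached

  m2 <- region_grow_roi(img, c(15, 15), 2.2, 50, c(9, 9))
  bb <- which(m2$mask, arr.ind = TRUE)
  expect_lte(max(bb[, 1]) - min(bb[, 1]) + 1, 11)  # stops at the cap

  # two-level image: gap far exceeds multiplier * SD, growth confined
  img2 <- matrix(0, 20, 20)
  img2[, 11:20] <- 10
  m3 <- region_grow_roi(img2, c(10, 5), 2.2, 50, c(100, 100))
  expect_true(all(which(m3$mask, arr.ind = TRUE)[, 2] <= 10))
  expect_true(m3$mask[10, 5])

  expect_error(region_grow_roi(img, c(40, 2)), "outside")
})

test_that("region growing is monotone in the SD multiplier and excludes
           specular blobs", {
  spec <- rep(0.5, 6)
  cub <- generate_cube(spec, 40, 40, seed = 8, specular_blob = TRUE)
  cal <- reflectance_correct(cub$origin, cub$frames)
  band <- cal$values[, , 3]
  masks <- lapply(c(1.5, 2.2, 3.5), function(m)
    region_grow_roi(band, c(20, 20), m, 50, c(36, 36))$mask)
  expect_true(all(masks[[2]][masks[[1]]]))
  expect_true(all(masks[[3]][masks[[2]]]))
  # blob pixels are brighter than mean + 2.2 sd of the fruit region
  expect_gte(mean(!masks[[2]][cub$blob_mask]), 0.99)
})

test_that("mean ROI spectrum is the per-band mean over the mask", {
  cube <- make_cube(4, 4, 3)
  mask <- matrix(FALSE, 4, 4)
  mask[2, 3] <- TRUE
  expect_equal(mean_roi_spectrum(cube, mask), cube$values[2, 3, ])

  const <- spectral_cube(array(0.7, c(4, 4, 3)), 1:3)
  mask2 <- matrix(TRUE, 4, 4)
  expect_equal(mean_roi_spectrum(const, mask2), rep(0.7, 3))

  # hand mean over a 2x2 block
  vals <- array(0, c(4, 4, 1))
  vals[1:2, 1:2, 1] <- c(0.1, 0.2, 0.3, 0.4)
  cube3 <- spectral_cube(vals, 500)
  mask3 <- matrix(FALSE, 4, 4)
  mask3[1:2, 1:2] <- TRUE
  expect_equal(mean_roi_spectrum(cube3, mask3), 0.25)

  # bounded by per-band extremes over the mask
  ms <- mean_roi_spectrum(cube, mask2)
  for (b in 1:3) {
    expect_gte(ms[b], min(cube$values[, , b]))
    expect_lte(ms[b], max(cube$values[, , b]))
  }
  expect_error(mean_roi_spectrum(cube, matrix(FALSE, 4, 4)), "empty")
})

test_that("view aggregation averages element-wise", {
  v <- runif(10)
  expect_equal(aggregate_views(list(v, v, v, v)), v)
  expect_equal(aggregate_views(list(rep(0.2, 5), rep(0.4, 5))),
               rep(0.3, 5))
  expect_error(aggregate_views(list(1:3, 1:4)), "unequal")

  ds <- generate_dataset(spectral_model_config(seed = 1), aggregate = FALSE)
  agg <- aggregate_views(ds$spectra)
  expect_equal(nrow(agg$values), 60)
  expect_equal(agg$values["A_1" == agg$sample_id, ],
               colMeans(ds$spectra$values[ds$spectra$sample_id == "A_1", ]),
               ignore_attr = TRUE)
  prov <- agg$provenance[[length(agg$provenance)]]
  expect_equal(prov$params$n_views, 4)
})

test_that("sample spectrum extraction recovers the planted spectrum", {
  spec <- 0.2 + 0.4 * sin(seq(0, 3, length.out = 10))^2
  cub <- generate_cube(spec, 32, 32, seed = 2, specular_blob = TRUE,
                       wavelengths = seq(400, 1000, length.out = 10))
  out <- extract_sample_spectrum(cub$origin, cub$frames, c(16, 16),
                                 target_size = c(28, 28))
  expect_lt(max(abs(out$spectrum - spec)), 0.01)
})
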