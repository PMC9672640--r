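# Preprocessing: isotropic resampling, cuboid cropping, bag construction.

test_that("resample_isotropic handles identity and constant volumes", {
  v <- ct_volume(array(rnorm(6 * 6 * 6), dim = c(6, 6, 6)), spacing = 1)
  expect_identical(resample_isotropic(v, 1)$voxels, v$voxels)

  vc <- ct_volume(array(42, dim = c(9, 9, 9)), spacing = c(2, 0.7, 3))
  out <- resample_isotropic(vc, 1)
  expect_equal(dim(out$voxels), c(18, 6, 27))   # round(dim * spacing)
  expect_true(all(abs(out$voxels - 42) < 1e-12))
  expect_equal(out$spacing, c(1, 1, 1))
})

test_that("resample_isotropic matches the physical-coordinate oracle", {
  set.seed(21)
  ramp <- array(0, dim = c(10, 10, 10))
  for (i in 1:10) ramp[i, , ] <- -1000 + 150 * (i - 1)   # linear HU ramp in x
  ramp <- ramp + array(rnorm(1000, sd = 30), dim = dim(ramp))
  v <- ct_volume(ramp, spacing = 2)
  out <- resample_isotropic(v, 1)
  expect_equal(dim(out$voxels), c(20, 20, 20))
  idx <- cbind(sample(20, 100, TRUE), sample(20, 100, TRUE),
               sample(20, 100, TRUE))
  for (r in seq_len(100)) {
    point <- (idx[r, ] - 1) * 1                 # physical mm of output voxel
    expect_equal(out$voxels[idx[r, 1], idx[r, 2], idx[r, 3]],
                 oracle_trilinear(ramp, v$spacing, point), tolerance = 1e-5)
  }
})

test_that("resampling preserves extent and respects the input range", {
  set.seed(22)
  for (i in 1:5) {
    d <- sample(5:12, 3, TRUE)
    sp <- runif(3, 0.5, 4)
    v <- ct_volume(array(rnorm(prod(d), -500, 200), dim = d), spacing = sp)
    out <- resample_isotropic(v, 1)
    expect_true(all(abs(dim(out$voxels) * 1 - d * sp) <= 1 + 1e-9))
    expect_gte(min(out$voxels), min(v$voxels) - 1e-12)
    expect_lte(max(out$voxels), max(v$voxels) + 1e-12)
  }
})

test_that("resample_isotropic validates its arguments", {
  v <- ct_volume(array(0, dim = c(4, 4, 4)))
  expect_error(resample_isotropic(v, 0), "positive")
  expect_error(resample_isotropic(v, -1), "positive")
  expect_error(ct_volume(array(NA_real_, dim = c(2, 2, 2))), "finite")
  expect_error(ct_volume(array(0, dim = c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("crop_tumor_cuboid copies the centered window verbatim", {
  set.seed(23)
  v <- ct_volume(array(rnorm(128^3, -500, 100), dim = c(128, 128, 128)),
                 spacing = 1)
  center <- c(64L, 64L, 64L)
  cub <- crop_tumor_cuboid(v, center)
  expect_equal(dim(cub$voxels), c(64, 64, 32))
  # center voxel occupies cuboid index extent/2 (0-based), i.e. (33, 33, 17)
  expect_identical(cub$voxels[33, 33, 17], v$voxels[64, 64, 64])
  # full in-bounds crop reproduces source voxels bit-exactly
  expect_identical(cub$voxels,
                   v$voxels[32:95, 32:95, 48:79])
})

test_that("near-border crops pad with air and match the geometry oracle", {
  set.seed(24)
  d <- c(40L, 50L, 30L)
  v <- ct_volume(array(rnorm(prod(d), 0, 10), dim = d), spacing = 1)
  center <- c(1L, 1L, 1L)
  cub <- crop_tumor_cuboid(v, center)
  # brute-force count of in-bounds cuboid positions
  inb <- 0L
  for (x in 1:64) for (y in 1:64) for (z in 1:32) {
    src <- center + c(x - 33L, y - 33L, z - 17L)
    if (all(src >= 1L) && all(src <= d)) inb <- inb + 1L
  }
  expect_equal(sum(cub$voxels != -1000), inb)
  # spot-check: padded corner is air, center voxel copied
  expect_equal(cub$voxels[1, 1, 1], -1000)
  expect_identical(cub$voxels[33, 33, 17], v$voxels[1, 1, 1])
})

test_that("crop_tumor_cuboid enforces its preconditions", {
  v <- ct_volume(array(0, dim = c(20, 20, 20)), spacing = c(1, 1, 2))
  expect_error(crop_tumor_cuboid(v, c(10, 10, 10)), "isotropic")
  v1 <- resample_isotropic(v, 1)
  expect_error(crop_tumor_cuboid(v1, c(0, 10, 10)), "inside")
  expect_error(crop_tumor_cuboid(v1, c(10, 10, 99)), "inside")
})

test_that("build_bag windows, rescales and replicates channels", {
  # constant at the window midpoint -> every pixel 0.5 before standardization
  cub <- array(-300, dim = c(64, 64, 32))          # midpoint of [-1000, 400]
  bag <- build_bag(cub, target_size = 32, normalize = FALSE)
  expect_equal(dim(bag$instances), c(32, 32, 32, 3))
  expect_true(all(abs(bag$instances - 0.5) < 1e-12))

  # entirely below the window -> all zeros
  low <- build_bag(array(-2000, dim = c(64, 64, 32)), target_size = 16,
                   normalize = FALSE)
  expect_true(all(low$instances == 0))

  # three identical channels pre-standardization, deterministic
  set.seed(25)
  cub2 <- array(rnorm(64 * 64 * 32, -300, 300), dim = c(64, 64, 32))
  b1 <- build_bag(cub2, target_size = 24, normalize = FALSE)
  expect_identical(b1$instances[, , , 1], b1$instances[, , , 2])
  expect_identical(b1$instances[, , , 1], b1$instances[, , , 3])
  expect_true(all(b1$instances >= 0 & b1$instances <= 1))
  b2 <- build_bag(cub2, target_size = 24, normalize = FALSE)
  expect_identical(b1$instances, b2$instances)

  # standardization applies the per-channel constants
  bn <- build_bag(cub2, target_size = 24)
  for (ch in 1:3) {
    expect_equal(bn$instances[, , , ch],
                 (b1$instances[, , , ch] - imagenet_norm$mean[ch]) /
                   imagenet_norm$sd[ch])
  }
  expect_error(build_bag(cub2, window = c(400, -1000)), "lower < upper")
  expect_error(build_bag(cub2, window = c(100, 100)), "lower < upper")
})

test_that("slice resize matches the brute-force bilinear oracle", {
  checker <- outer(1:64, 1:64, function(i, j) (i + j) %% 2) * 1000 - 500
  cub <- array(0, dim = c(64, 64, 32))
  cub[, , 5] <- checker
  bag <- build_bag(cub, target_size = 224, normalize = FALSE)
  img01 <- (pmin(pmax(checker, -1000), 400) + 1000) / 1400
  set.seed(26)
  px <- cbind(sample(224, 50, TRUE), sample(224, 50, TRUE))
  for (r in seq_len(50)) {
    expect_equal(bag$instances[5, px[r, 1], px[r, 2], 1],
                 oracle_bilinear_pixel(img01, px[r, 1], px[r, 2], 224, 224),
                 tolerance = 1e-5)
  }
})
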