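test_that("volumes round-trip through NIfTI and NRRD with exact labels and metadata", {
  set.seed(11)
  meta <- grid_meta(25, origin = c(-350, 10, 0.5))
  v <- intensity_volume(array(rnorm(1000), c(10, 10, 10)), meta)
  l <- labeled_volume(array(sample(0:5, 1000, TRUE), c(10, 10, 10)), meta)
  for (ext in c(".nrrd", ".nii.gz")) {
    fv <- tempfile(fileext = ext)
    write_volume(v, fv)
    v2 <- read_volume(fv)
    expect_s3_class(v2, "intensity_volume")
    expect_equal(v2$data, v$data, tolerance = 1e-12)
    expect_equal(v2$meta$origin, meta$origin, tolerance = 1e-6)
    expect_equal(v2$meta$voxel_size, meta$voxel_size, tolerance = 1e-6)
    fl <- tempfile(fileext = ext)
    write_volume(l, fl)
    l2 <- read_volume(fl)
    expect_s3_class(l2, "labeled_volume")
    expect_identical(l2$data, l$data)
  }
  # NRRD spacing is honored
  r <- atlasforge:::read_nrrd(local({ f <- tempfile(fileext = ".nrrd"); write_volume(v, f); f }))
  expect_equal(r$meta$voxel_size, c(25, 25, 25))
  # contract violations
  expect_error(grid_meta(-25), "positive")
  bad <- v; class(bad) <- c("labeled_volume", "af_volume")
  expect_error(write_volume(bad, tempfile(fileext = ".nrrd")), "non-integer")
})

test_that("label downsampling is block majority with smallest-id tie break", {
  # constant volume stays constant at any factor
  cst <- tiny_ann(array(7L, c(6, 6, 6)))
  expect_true(all(downsample_labels(cst, 3)$data == 7L))
  # forced majority: block of {7 x4, 3 x2, 0 x2} -> 7
  blk <- tiny_ann(array(c(7L, 7L, 7L, 7L, 3L, 3L, 0L, 0L), c(2, 2, 2)))
  expect_equal(as.vector(downsample_labels(blk, 2)$data), 7L)
  # tie in a block breaks toward the smaller label
  tie <- tiny_ann(array(c(5L, 5L, 2L, 2L, 5L, 5L, 2L, 2L), c(2, 2, 2)))
  expect_equal(as.vector(downsample_labels(tie, 2)$data), 2L)
  # brute-force oracle on a random volume
  set.seed(21)
  arr <- array(sample(0:4, 8 * 6 * 4, TRUE), c(8, 6, 4))
  got <- downsample_labels(tiny_ann(arr), 2)$data
  oracle <- array(0L, c(4, 3, 2))
  for (i in 1:4) for (j in 1:3) for (k in 1:2) {
    b <- arr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    tab <- table(b)
    best <- as.integer(names(tab)[tab == max(tab)])
    oracle[i, j, k] <- min(best)
  }
  expect_identical(got, oracle)
  # never invents a label
  expect_true(all(got %in% arr))
})

test_that("intensity downsampling equals the block mean", {
  cst <- intensity_volume(array(3.5, c(4, 4, 4)), grid_meta())
  expect_true(all(downsample_intensity(cst, 2)$data == 3.5))
  blk <- intensity_volume(array(c(rep(0, 7), 8), c(2, 2, 2)), grid_meta())
  expect_equal(as.vector(downsample_intensity(blk, 2)$data), 1)
  set.seed(5)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  got <- downsample_intensity(intensity_volume(arr, grid_meta()), 2)$data
  oracle <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    oracle[i, j, k] <- mean(arr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                                (2 * k - 1):(2 * k)])
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("border cleanup removes exactly the injected stray voxels", {
  ph <- small_phantom()
  k <- 7L
  inj <- inject_stray_voxels(ph$annV3, k, label = 3001L, seed = 4)
  before <- sum(inj$volume$data != 0L)
  cleaned <- clean_border_voxels(inj$volume, min_component = 5L)
  expect_equal(attr(cleaned, "removed"), k)
  expect_equal(sum(cleaned$data != 0L), before - k)
  # the main body is untouched
  expect_identical(cleaned$data, ph$annV3$data)
  # single stray voxel far from the body
  a <- array(0L, c(12, 12, 12)); a[2:6, 2:6, 2:6] <- 9L; a[11, 11, 11] <- 9L
  cl <- clean_border_voxels(tiny_ann(a), min_component = 5L)
  expect_equal(attr(cl, "removed"), 1L)
  expect_equal(sum(cl$data == 9L), 125L)
})

test_that("symmetrization makes volumes exactly mirror-symmetric", {
  ph <- small_phantom()
  base <- symmetrize(ph$annV3, "right")
  expect_identical(base$data, mirror(base)$data)          # defining property
  expect_identical(symmetrize(base, "right")$data, base$data)  # idempotent
  n_asym <- 433L
  inj <- inject_asymmetric_voxels(base, n_asym, side = "left", seed = 2)
  xor_before <- sum(inj$volume$data != mirror(inj$volume)$data)
  expect_equal(xor_before, 2L * n_asym)  # each injected voxel breaks both sides of the mirror pair
  sym <- symmetrize(inj$volume, "right")
  expect_equal(sum(sym$data != mirror(sym)$data), 0L)
  expect_error(symmetrize(ph$annV3, "right", axis = role_axis(ph$annV3$meta, "rc")),
               "left-right")
})

test_that("padding grows the grid and preserves world coordinates", {
  ph <- small_phantom()
  v <- ph$nissl
  rc <- role_axis(v$meta, "rc")
  lo <- c(0, 0, 0); lo[rc] <- 14
  p <- pad_volume(v, lo = lo)
  expect_equal(p$meta$origin[rc], v$meta$origin[rc] - 350)  # 14 x 25 um rostral shift
  expect_identical(pad_volume(v)$data, v$data)              # pad 0 = identity
  # original voxel content sits at unchanged world coordinates
  probe_idx <- c(5, 6, 7)
  w <- v$meta$origin + (probe_idx - 1) * v$meta$voxel_size
  val_before <- atlasforge:::sample_array(v$data, v$meta, matrix(w, 1), "nearest")
  val_after <- atlasforge:::sample_array(p$data, p$meta, matrix(w, 1), "nearest")
  expect_equal(val_before, val_after)
  expect_error(pad_volume(v, lo = c(-1, 0, 0)), "non-negative")
})

test_that("field upsampling preserves physical displacements", {
  meta <- grid_meta(25)
  d <- c(8, 8, 8)
  zero <- deformation_field(array(0, c(d, 3)), meta)
  up <- upsample_field(zero, 2.5)
  expect_equal(dim(up$disp)[1:3], c(20L, 20L, 20L))
  expect_true(all(up$disp == 0))
  expect_equal(up$meta$voxel_size, c(10, 10, 10))
  # uniform 50 um translation survives any factor unchanged
  uni <- deformation_field(array(rep(c(50, 0, 0), each = prod(d)), c(d, 3)), meta)
  up2 <- upsample_field(uni, 2.5)
  expect_equal(range(up2$disp[, , , 1]), c(50, 50))
  expect_true(all(up2$disp[, , , 2:3] == 0))
})

test_that("applying a coarse field and its upsampled version agree on a smooth phantom", {
  ph <- small_phantom()
  meta <- ph$template$meta
  d <- vol_dim(ph$template)
  fld <- sinusoidal_field(meta, d, amplitude_vox = 2, wavelength_vox = 24,
                          phases = c(0.3, 1.7, 2.9))
  coarse <- apply_transform(ph$template, fld, "linear", meta, d)
  up <- upsample_field(fld, 2)
  fine_meta <- up$meta
  fine_in <- apply_transform(ph$template, NULL, "linear", fine_meta, dim(up$disp)[1:3])
  fine_out <- apply_transform(ph$template, up, "linear", fine_meta, dim(up$disp)[1:3])
  # compare the fine-grid warp against the coarse warp sampled on the fine grid
  coarse_on_fine <- apply_transform(coarse, NULL, "linear", fine_meta, dim(up$disp)[1:3])
  fg <- coarse_on_fine$data != 0 & fine_out$data != 0
  rng <- diff(range(ph$template$data))
  expect_lt(mean(abs(fine_out$data[fg] - coarse_on_fine$data[fg])) / rng, 0.02)
})
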