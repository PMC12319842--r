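# Registration engine tests. The expensive recoveries run on the reduced
# phantom; the full-amplitude known-warp recovery on the standard phantom is
# exercised by the acceptance suite.

test_that("transforms compose, invert and apply consistently", {
  A <- affine_transform(diag(c(1.1, 0.9, 1)), c(10, -5, 2))
  B <- affine_transform(atlasforge:::rot_mat(c(0.1, 0, 0)), c(-3, 4, 0))
  pts <- matrix(rnorm(30, sd = 100), 10)
  expect_equal(transform_points(compose(A, B), pts),
               transform_points(A, transform_points(B, pts)), tolerance = 1e-12)
  # compose(identity, T) = T; two translations add
  I <- affine_transform()
  expect_equal(transform_points(compose(I, A), pts), transform_points(A, pts))
  T1 <- affine_transform(translation = c(5, 0, 0))
  T2 <- affine_transform(translation = c(0, 7, 0))
  expect_equal(compose(T1, T2)$translation, c(5, 7, 0))
  # affine inversion is exact
  expect_equal(transform_points(invert_affine(A), transform_points(A, pts)),
               pts, tolerance = 1e-9)
  expect_error(affine_transform(matrix(0, 3, 3)), "invertible")
})

test_that("apply_transform honors interpolation contracts", {
  ph <- small_phantom()
  v <- ph$nissl
  d <- vol_dim(v)
  expect_identical(apply_transform(ph$annV3, NULL, "nearest")$data, ph$annV3$data)
  expect_error(apply_transform(ph$annV3, NULL, "linear"), "nearest")
  # integer-voxel translation with nearest is an exact shifted copy
  tr <- affine_transform(translation = c(2, 0, 0) * 25)
  shifted <- apply_transform(ph$annV3, tr, "nearest", v$meta, d)
  expect_identical(shifted$data[1:(d[1] - 2), , ], ph$annV3$data[3:d[1], , ])
})

test_that("field inversion is consistent on smooth fields", {
  ph <- small_phantom()
  meta <- ph$template$meta
  d <- vol_dim(ph$template)
  fld <- sinusoidal_field(meta, d, amplitude_vox = 2, wavelength_vox = 24,
                          phases = c(1, 2, 3))
  warped <- apply_transform(ph$template, fld, "linear", meta, d)
  back <- apply_transform(warped, invert_field(fld), "linear", meta, d)
  fg <- ph$template$data > 1 & back$data > 1
  rng <- diff(range(ph$template$data))
  expect_lt(mean(abs(back$data[fg] - ph$template$data[fg])) / rng, 0.02)
})

test_that("affine registration recovers synthetic rigid and similarity motions", {
  ph <- small_phantom()
  fixed <- ph$nissl_v3
  meta <- fixed$meta
  d <- vol_dim(fixed)
  params <- registration_params(levels = c(4, 2, 1), iterations = c(60, 40, 20))
  # identical volumes: within 0.1 voxel of identity
  tr0 <- register_affine(fixed, fixed, params, dof = "rigid")
  expect_lt(max(abs(tr0$translation)) / 25, 0.1)
  expect_lt(max(abs(tr0$matrix - diag(3))), 0.01)
  # known translation (5, -3, 2) voxels recovered within 0.5 voxel per axis
  tt <- affine_transform(translation = c(5, -3, 2) * 25)
  mov <- apply_transform(fixed, tt, "linear", meta, d)
  est <- register_affine(mov, fixed, params, dof = "rigid")
  expect_true(all(abs(est$translation / 25 + c(5, -3, 2)) < 0.5))
  # known isotropic 1.1x scale: the recovered fixed-to-moving transform
  # carries the inverse scale 1/1.1, required accurate to 2%
  ctr <- meta$origin + (d - 1) / 2 * meta$voxel_size
  S <- diag(3) * 1.1
  ts <- affine_transform(S, ctr - as.numeric(S %*% ctr))
  movs <- apply_transform(fixed, ts, "linear", meta, d)
  ests <- register_affine(movs, fixed, params, dof = "similarity")
  expect_lt(abs(det(ests$matrix)^(1 / 3) * 1.1 - 1), 0.02)
  # degenerate input is refused
  flat <- intensity_volume(array(1, d), meta)
  expect_error(register_affine(flat, fixed, params), "degenerate")
})

test_that("nonlinear registration is monotone, near-identity on identical inputs, and deterministic", {
  ph <- small_phantom()
  fixed <- ph$nissl_v3
  meta <- fixed$meta
  d <- vol_dim(fixed)
  params <- registration_params(levels = c(2, 1), iterations = c(30, 15))
  fld0 <- register_nonlinear(fixed, fixed, params)
  expect_lt(max(abs(fld0$disp)) / 25, 0.25)
  # warp recovery at reduced amplitude: mean endpoint error < 1 voxel
  fld_true <- sinusoidal_field(meta, d, amplitude_vox = 2, wavelength_vox = 24,
                               phases = c(0.5, 1.5, 2.5))
  mov <- apply_transform(fixed, fld_true, "linear", meta, d)
  est <- register_nonlinear(mov, fixed, registration_params(levels = c(4, 2, 1),
                                                            iterations = c(80, 40, 20)))
  fg <- which(ph$annV3$data != 0)
  pts <- grid_points(meta, d)[fg, ]
  err <- sqrt(rowSums((transform_points(est, pts) -
                       transform_points(invert_field(fld_true), pts))^2)) / 25
  expect_lt(mean(err), 1)
  # the accepted-step contract: NMI does not decrease
  expect_gte(nmi(apply_transform(mov, est, "linear", meta, d), fixed),
             nmi(mov, fixed))
  # determinism: identical final score across repeated runs
  est2 <- register_nonlinear(mov, fixed, registration_params(levels = c(4, 2, 1),
                                                             iterations = c(80, 40, 20)))
  expect_lt(abs(attr(est, "score") - attr(est2, "score")), 1e-9)
  expect_equal(est$disp, est2$disp, tolerance = 1e-12)
})

test_that("label-driven registration aligns annotations", {
  ph <- small_phantom()
  params <- registration_params(levels = c(4, 2), iterations = c(50, 25))
  # identical annotations: mean Dice over shared labels stays >= 0.99
  rl0 <- register_labels(ph$annV3, ph$annV3, params)
  w0 <- apply_transform(ph$annV3, rl0$total, "nearest", ph$annV3$meta, vol_dim(ph$annV3))
  labs <- setdiff(unique(as.vector(ph$annV3$data)), 0L)
  d0 <- mean(vapply(labs, function(l) dice(w0$data == l, ph$annV3$data == l), 1))
  expect_gte(d0, 0.99)
  # the phantom pair improves by at least 0.05 mean Dice over shared leaves
  shared <- comparable_leaves(ph$graph, ph$annV2, ph$annV3)
  pre <- mean(vapply(shared, function(l) dice(ph$annV2$data == l, ph$annV3$data == l), 1))
  rl <- register_labels(ph$annV2, ph$annV3, params)
  w <- apply_transform(ph$annV2, rl$total, "nearest", ph$annV3$meta, vol_dim(ph$annV3))
  post <- mean(vapply(shared, function(l) dice(w$data == l, ph$annV3$data == l), 1))
  expect_gte(post, pre + 0.05)
  # two single-label spheres offset by 4 voxels: centroids land within 1 voxel
  d <- c(32, 32, 32)
  mk_sphere <- function(cx) {
    i <- arrayInd(seq_len(prod(d)), d)
    tiny_ann(array(as.integer(rowSums(sweep(i, 2, cx)^2) <= 64), d))
  }
  A <- mk_sphere(c(14, 16, 16))
  B <- mk_sphere(c(18, 16, 16))
  rl2 <- register_labels(A, B, registration_params(levels = c(2, 1), iterations = c(40, 20)))
  wA <- apply_transform(A, rl2$total, "nearest", B$meta, d)
  cen <- function(m) colMeans(arrayInd(which(m$data == 1L), d))
  expect_lt(sqrt(sum((cen(wA) - cen(B))^2)), 1)
  expect_error(register_labels(tiny_ann(array(1L, c(4, 4, 4))),
                               tiny_ann(array(2L, c(4, 4, 4)))), "shared")
})
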