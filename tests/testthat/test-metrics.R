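test_that("joint histograms conserve marginals and expose dependence structure", {
  set.seed(3)
  a <- array(runif(4096), c(16, 16, 16)) + 0.01
  jh_self <- joint_histogram(a, a, bins = 16)
  expect_equal(sum(jh_self$counts), jh_self$total)
  # identical images: all mass on the diagonal
  expect_equal(sum(diag(jh_self$counts)), jh_self$total)
  # marginals equal per-image histograms
  b <- array(runif(4096), c(16, 16, 16)) + 0.01
  jh <- joint_histogram(a, b, bins = 16)
  ha <- tabulate(pmin(pmax(findInterval(as.vector(a), jh$edges_a,
                                        rightmost.closed = TRUE), 1L), 16L), 16L)
  expect_equal(rowSums(jh$counts), as.numeric(ha))
  # independent uniforms: no cell wildly off its expectation
  expected <- jh$total / 256
  chi2 <- sum((jh$counts - expected)^2 / expected)
  expect_lt(chi2, 2 * 255)  # generous chi-square sanity bound
  expect_error(joint_histogram(a, b, mask = array(FALSE, dim(a))), "empty")
})

test_that("NMI matches its closed forms and invariances", {
  set.seed(4)
  a <- array(runif(1000), c(10, 10, 10)) + 0.01
  expect_equal(nmi(a, a, bins = 32), 1, tolerance = 1e-12)
  # independence: A=[0,0,1,1], B=[0,1,0,1] with 2 bins scores 0
  A <- array(c(0, 0, 1, 1) + 1, c(4, 1, 1))  # +1 keeps voxels in the foreground
  B <- array(c(0, 1, 0, 1) + 1, c(4, 1, 1))
  expect_equal(nmi(A, B, bins = 2, mask = "all"), 0, tolerance = 1e-12)
  # hand-computed joint histogram (bits): 2 x 0.3113 / (1 + 0.8113)
  B2 <- array(c(0, 0, 0, 1) + 1, c(4, 1, 1))
  expect_equal(nmi(A, B2, bins = 2, mask = "all"), 0.3437, tolerance = 1e-3)
  # symmetry and monotone-rebinning invariance
  b <- array(runif(1000), c(10, 10, 10)) + 0.01
  expect_equal(nmi(a, b, bins = 16), nmi(b, a, bins = 16), tolerance = 1e-12)
  # a bin-assignment-preserving (linear) intensity map leaves NMI unchanged
  expect_equal(nmi(a, b, bins = 16), nmi(a * 5 + 2, b, bins = 16), tolerance = 1e-12)
  expect_error(nmi(array(1, c(4, 4, 4)), a[1:4, 1:4, 1:4], bins = 8, mask = "all"),
               "constant")
  expect_true(nmi(a, b, bins = 16) >= 0 && nmi(a, b, bins = 16) <= 1)
})

test_that("TRE is the Euclidean fiducial distance with group summaries", {
  df <- data.frame(name = c("p1", "p2"), operator = "op1",
                   group = c("g1", "g1"),
                   x_ref = c(0, 10), y_ref = c(0, 10), z_ref = c(0, 10),
                   x_reg = c(3, 10), y_reg = c(4, 10), z_reg = c(12, 10))
  r <- tre(df)
  expect_equal(r$points$tre_um, c(13, 0))
  expect_equal(r$mean, 6.5)
  expect_equal(r$by_group$mean_um, 6.5)
  expect_error(tre(df[, -4]), "missing columns")
})

test_that("Dice uses exact voxel counts", {
  m <- array(FALSE, c(4, 4, 4))
  A <- m; A[1:4, 1, 1] <- TRUE
  B <- m; B[3:4, 1, 1] <- TRUE; B[1:4, 2, 1] <- TRUE
  expect_equal(dice(A, A), 1)
  D <- m; D[1, 4, 4] <- TRUE
  expect_equal(dice(A, D), 0)
  expect_equal(dice(A, B), 2 * 2 / (4 + 6))
  expect_error(dice(m, m), "empty")
  # removing intersection voxels never increases Dice
  B2 <- B; B2[3, 1, 1] <- FALSE
  expect_lte(dice(A, B2), dice(A, B))
})

test_that("per-region and per-slice NMI are masked NMI series", {
  ph <- small_phantom()
  leaves <- sort(intersect(graph_leaves(ph$graph), unique(as.vector(ph$annV3$data))))
  tab <- per_region_nmi(ph$nissl_v3, ph$nissl_v3, ph$annV3, ph$graph, leaves)
  expect_true(all(tab$nmi[!tab$flagged] == 1))
  # single-region call equals masked nmi
  m <- region_mask(ph$annV3, ph$graph, leaves[1], TRUE)
  one <- per_region_nmi(ph$nissl_v3, ph$template, ph$annV3, ph$graph, leaves[1])
  expect_equal(one$nmi, nmi(ph$nissl_v3, ph$template, mask = m))
  sl <- per_slice_nmi(ph$nissl_v3, ph$nissl_v3, "coronal")
  expect_equal(nrow(sl), vol_dim(ph$nissl_v3)[role_axis(ph$nissl_v3$meta, "rc")])
  expect_true(all(sl$nmi[!sl$flagged] == 1))
  expect_true(any(sl$flagged))  # empty rostral/caudal planes are flagged, not scored
})

test_that("volume accounting is exact integer/voxel-size arithmetic", {
  # conversion at 25 um isotropic
  expect_equal(voxels_to_mm3(1, 25), 1.5625e-5)
  rep_ <- region_volume_report(added = c(R1 = 100L, R2 = 50L),
                               modified = c(R1 = 20L, R2 = 0L), voxel_um = 25)
  expect_equal(rep_$total_voxels, c(120, 50, 170))
  expect_equal(rep_$added_mm3 + rep_$modified_mm3, rep_$total_mm3, tolerance = 1e-15)
  # from volumes: identical annotations give all zeros
  ph <- small_phantom()
  vr0 <- volume_report(ph$annV3, ph$annV3, ph$graph, c(1001L, 1002L))
  expect_true(all(vr0$added_voxels == 0) && all(vr0$modified_voxels == 0))
  # brute-force comparison on a modified copy
  after <- ph$annV3$data
  w_bg <- which(after == 0L)[1:40]     # add 40 voxels to region 3003
  after[w_bg] <- 3003L
  w_mod <- which(ph$annV3$data == 3001L)[1:25]
  after[w_mod] <- 3002L                # modify 25 voxels within parent 2001
  vr <- volume_report(ph$annV3, labeled_volume(after, ph$annV3$meta),
                      ph$graph, c(2001L, 2002L))
  expect_equal(vr$added_voxels[vr$region == "MID"], 40)
  expect_equal(vr$modified_voxels[vr$region == "ROS"], 25)
  expect_equal(vr$total_voxels[vr$region == "TOTAL"], 65)
  expect_equal(vr$total_mm3[vr$region == "TOTAL"], 65 * 1.5625e-5)
})
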