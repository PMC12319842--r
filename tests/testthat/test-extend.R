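test_that("histogram matching equates distributions monotonically", {
  ph <- small_phantom()
  v <- ph$nissl_v3
  # src == ref: essentially the identity mapping
  same <- histogram_match(v, v)
  binw <- diff(range(v$data[v$data != 0])) / 256
  fg <- v$data != 0
  expect_lt(mean(abs(same$data[fg] - v$data[fg])), binw)
  # pure offset is undone to within a bin
  off <- intensity_volume(v$data + (v$data != 0) * 50, v$meta)
  matched <- histogram_match(off, v)
  expect_lt(mean(abs(matched$data[fg] - v$data[fg])), binw)
  # arbitrary monotone distortion recovered: KS distance < 0.02
  dist <- intensity_volume((v$data / 10)^1.7 + (v$data != 0) * 20, v$meta)
  rec <- histogram_match(dist, v)
  ks <- suppressWarnings(stats::ks.test(rec$data[fg], v$data[fg]))
  expect_lt(unname(ks$statistic), 0.02)
  # monotonicity: ordering of source intensities is preserved
  o_src <- order(dist$data[fg])
  expect_true(!is.unsorted(rec$data[fg][o_src]))
  expect_error(histogram_match(intensity_volume(array(1, c(4, 4, 4)) *
                                                  array(1, c(4, 4, 4)), v$meta), v),
               "constant")
})

test_that("junction blending averages exactly a three-plane slab", {
  meta <- grid_meta(25)
  base <- intensity_volume(array(100, c(6, 10, 6)), meta)
  addn <- intensity_volume(array(50, c(6, 10, 6)), meta)
  out <- blend_junction(base, addn, plane_index = 5)
  expect_true(all(out$data[, 4:6, ] == 75))
  expect_true(all(out$data[, c(1:3, 7:10), ] == 100))
  expect_equal(sum(out$data != base$data), 3 * 6 * 6)
  # base == addition: unchanged
  expect_identical(blend_junction(base, base, plane_index = 5)$data, base$data)
  expect_error(blend_junction(base, addn, plane_index = 1), "bounds")
})

test_that("extend_region is the identity when nothing is missing", {
  ph <- small_phantom()
  gt <- ph$extend$target_complete
  res <- extend_region(gt, gt, ph$extend$full_mask, ph$extend$full_mask)
  expect_lt(max(abs(res$extended$data - gt$data)), 1e-9)
  expect_error(extend_region(gt, gt, ph$extend$full_mask,
                             ph$extend$full_mask & FALSE), "overlap")
})

test_that("extend_region fills truncated tissue from the donor (reduced phantom)", {
  ph <- small_phantom()
  ex <- ph$extend
  res <- extend_region(ex$target, ex$donor, ex$full_mask, ex$truncated_mask)
  gt <- ex$target_complete
  filled <- ex$full_mask & !ex$truncated_mask
  rng <- diff(range(gt$data))
  # the reduced phantom's rostral cap is small and surface-dominated, so the
  # bound is looser than on the standard phantom (where the acceptance suite
  # requires < 10% of the dynamic range)
  expect_lt(mean(abs(res$extended$data[filled] - gt$data[filled])) / rng, 0.15)
  # target voxels outside the full mask and the junction slab are untouched
  ax <- ex$axis
  d <- vol_dim(gt)
  bb <- res$report$bbox
  jp <- res$report$junction_plane_crop + bb[ax, 1] - 1
  idx <- lapply(d, seq_len); idx[[ax]] <- pmax(pmin((jp - 1):(jp + 1), d[ax]), 1)
  slab <- array(FALSE, d); slab[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  untouched <- !ex$full_mask & !slab
  expect_equal(res$extended$data[untouched], ex$target$data[untouched])
})

test_that("annotation merging conserves labels and resolves overlaps by precedence", {
  ph <- small_phantom()
  base <- ph$annV3
  d <- vol_dim(base)
  # empty addon leaves the base untouched
  empty <- labeled_volume(array(0L, d), base$meta)
  out0 <- merge_annotations(base, empty)
  expect_identical(out0$data, base$data)
  expect_equal(attr(out0, "overlap"), 0L)
  # caudal concatenation of a labeled cylinder conserves totals
  dc <- d; dc[role_axis(base$meta, "rc")] <- 8L
  cyl <- array(0L, dc)
  ctr <- (d[c(1, 3)] + 1) / 2
  for (s in 1:8) {
    sl <- matrix(0L, d[1], d[3])
    ix <- arrayInd(seq_len(prod(dim(sl))), dim(sl))
    sl[rowSums(sweep(ix, 2, ctr)^2) <= 25] <- 9001L
    cyl[, s, ] <- sl
  }
  addon <- labeled_volume(cyl, base$meta)
  cc <- merge_annotations(base, addon, placement = "concat")
  expect_equal(sum(cc$data != 0L), sum(base$data != 0L) + sum(addon$data != 0L))
  rc <- role_axis(base$meta, "rc")
  expect_equal(dim(cc$data)[rc], d[rc] + 8L)
  # overlapping overlay honors precedence; overlap count matches brute force
  shifted <- array(0L, d)
  shifted[, 3:d[2], ] <- base$data[, 1:(d[2] - 2), ]
  shifted[shifted != 0L] <- 9001L
  addon2 <- labeled_volume(shifted, base$meta)
  brute_overlap <- sum(base$data != 0L & shifted != 0L)
  out_a <- merge_annotations(base, addon2, precedence = "addon")
  expect_equal(attr(out_a, "overlap"), brute_overlap)
  expect_true(all(out_a$data[base$data != 0L & shifted != 0L] == 9001L))
  out_b <- merge_annotations(base, addon2, precedence = "base")
  expect_identical(out_b$data[base$data != 0L], base$data[base$data != 0L])
  # id collisions are refused without a remap
  expect_error(merge_annotations(base, base), "collision")
  rem <- merge_annotations(base, addon2, precedence = "base",
                           remap = c(`9001` = 8001L))
  expect_true(8001L %in% rem$data)
})
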