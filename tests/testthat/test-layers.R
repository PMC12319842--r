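test_that("Otsu threshold maximizes between-class variance", {
  # two-valued sample: threshold strictly between, classes exactly recovered
  v <- c(rep(10, 100), rep(200, 100))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_equal(sum(v > thr), 100)
  expect_error(otsu_threshold(rep(5, 10)), "constant")
  # exhaustive oracle: naive scan over all bin boundaries, recomputing the
  # class statistics directly from the sample
  otsu_oracle <- function(values, bins = 256L) {
    r <- range(values)
    edges <- seq(r[1], r[2], length.out = bins + 1L)
    best <- -Inf; best_thr <- NA
    for (k in seq_len(bins - 1L)) {
      t <- edges[k + 1L]
      lo <- values[values <= t]; hi <- values[values > t]
      if (!length(lo) || !length(hi)) next
      w0 <- length(lo) / length(values)
      bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
      if (bcv > best + 1e-12) { best <- bcv; best_thr <- t }
    }
    best_thr
  }
  set.seed(9)
  for (i in 1:5) {
    x <- c(rnorm(300, 40, 6), rnorm(200, 150, 12))
    got <- otsu_threshold(x)
    ora <- otsu_oracle(x)
    binw <- diff(range(x)) / 256
    expect_lt(abs(got - ora), binw + 1e-9)
  }
  # shift invariance within one bin
  x <- c(rnorm(200, 30, 4), rnorm(200, 90, 5))
  expect_lt(abs(otsu_threshold(x + 17) - (otsu_threshold(x) + 17)),
            diff(range(x)) / 256 + 1e-9)
  # note: the implementation uses cumulative-moment recursion, the oracle
  # recomputes means per split, so agreement is a genuine cross-check
})

test_that("lobule layer segmentation recovers the concentric ground truth", {
  ph <- small_phantom()
  lay <- segment_cerebellum_layers(ph$nissl_v3, ph$annV3, ph$graph, ph$lobule_ids)
  for (k in names(lay$lobules)) {
    e <- lay$lobules[[k]]
    m <- region_mask(ph$annV3, ph$graph, as.integer(k), TRUE)
    # partition contract
    expect_equal(sum(e$granular & e$molecular), 0L)
    expect_equal(sum(e$granular | e$molecular), sum(m))
    expect_false(e$flagged)
    # inner high-intensity layer within 2% voxel-count error of ground truth
    gt <- ph$granular[[k]]
    expect_lt(abs(sum(e$granular) - sum(gt)) / sum(gt), 0.02)
    expect_gt(dice(e$granular, gt), 0.98)
  }
  # per-lobule independence: processing order cannot matter
  lay_rev <- segment_cerebellum_layers(ph$nissl_v3, ph$annV3, ph$graph,
                                       rev(ph$lobule_ids))
  for (k in names(lay$lobules))
    expect_identical(lay$lobules[[k]]$granular, lay_rev$lobules[[k]]$granular)
})

test_that("annotation upsampling replicates labels and modal smoothing stays local", {
  cst <- tiny_ann(array(7L, c(4, 4, 4)))
  up <- upsample_annotation(cst, 2)
  expect_true(all(up$data == 7L))
  expect_equal(up$meta$voxel_size, c(12.5, 12.5, 12.5))
  ph <- small_phantom()
  sub <- tiny_ann(ph$annV3$data[10:25, 10:25, 10:25])
  up2 <- upsample_annotation(sub, 2, smooth = TRUE)
  # no new labels; per-label counts within 5% of 8x the coarse counts
  expect_true(all(unique(as.vector(up2$data)) %in% unique(as.vector(sub$data))))
  for (l in setdiff(unique(as.vector(sub$data)), 0L)) {
    n_coarse <- sum(sub$data == l) * 8
    n_fine <- sum(up2$data == l)
    expect_lt(abs(n_fine - n_coarse) / n_coarse, 0.05)
  }
})

test_that("the synthesized Purkinje layer is the two-sided 6-adjacency interface", {
  # flat interface: exactly 2 planes of voxels
  d <- c(8, 10, 6)
  gran <- array(FALSE, d); gran[, 1:5, ] <- TRUE
  mol <- array(FALSE, d); mol[, 6:10, ] <- TRUE
  pk <- insert_purkinje(gran, mol)
  expect_equal(sum(pk$purkinje), 2 * d[1] * d[3])
  expect_true(all(which(apply(pk$purkinje, 2, any)) == c(5, 6)))
  # partition: relabeled voxels leave the source classes
  expect_equal(sum(pk$granular & pk$purkinje), 0L)
  expect_equal(sum(pk$molecular & pk$purkinje), 0L)
  expect_equal(sum(pk$granular | pk$molecular | pk$purkinje), sum(gran | mol))
  # spherical shell: matches a brute-force per-voxel adjacency scan
  ds <- c(20, 20, 20)
  idx <- arrayInd(seq_len(prod(ds)), ds)
  r2 <- rowSums(sweep(idx, 2, c(10.5, 10.5, 10.5))^2)
  gran_s <- array(r2 <= 36, ds)
  mol_s <- array(r2 > 36 & r2 <= 81, ds)
  pk_s <- insert_purkinje(gran_s, mol_s)
  brute <- array(FALSE, ds)
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  for (v in which(gran_s | mol_s)) {
    p <- idx[v, ]
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (any(q < 1) || any(q > ds)) next
      if (gran_s[v] && mol_s[q[1], q[2], q[3]]) brute[v] <- TRUE
      if (mol_s[v] && gran_s[q[1], q[2], q[3]]) brute[v] <- TRUE
    }
  }
  expect_identical(pk_s$purkinje, brute)
  # every Purkinje voxel has a 6-neighbor in the opposite source class
  expect_error(insert_purkinje(gran_s, array(FALSE, ds)), "empty")
})

test_that("layer labelings upsample to fine resolution and accept Purkinje synthesis", {
  ph <- small_phantom()
  lay <- segment_cerebellum_layers(ph$nissl_v3, ph$annV3, ph$graph, ph$lobule_ids)
  fine <- upsample_layer_labeling(lay, ph$annV3, factor = 2)
  k <- names(fine$lobules)[1]
  e <- fine$lobules[[k]]
  pk <- insert_purkinje(e$granular, e$molecular)
  expect_gt(sum(pk$purkinje), 0)
  expect_equal(sum(pk$granular & pk$molecular), 0L)
  ids <- data.frame(lobule = as.integer(names(fine$lobules)),
                    granular_id = 1:4 * 10L + 1L,
                    molecular_id = 1:4 * 10L + 2L)
  ann <- layer_annotation(fine, ph$annV3$meta, ids)
  expect_s3_class(ann, "labeled_volume")
  expect_true(all(ann$data %in% c(0L, ids$granular_id, ids$molecular_id)))
})
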