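# Cerebellar sublayer segmentation: per-lobule Otsu split of the
# Nissl-stained intensity into granular (high) and molecular (low) layers,
# annotation upsampling with modal smoothing, and synthesis of the two-voxel
# Purkinje layer at fine resolution.

#' Otsu threshold of an intensity sample
#'
#' Exhaustive scan over the boundaries of a fixed histogram maximizing the
#' between-class variance; deterministic (the lowest maximizing boundary is
#' returned).
#'
#' @param values numeric sample with at least 2 distinct values.
#' @param bins histogram resolution.
#' @return the threshold intensity; values strictly above it form the
#'   high-intensity class.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (r[2] <= r[1]) af_stop("Otsu threshold undefined for a constant sample")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
                     bins), nbins = bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  # between-class variance at each candidate boundary k (classes 1..k vs rest)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, bins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Segment one lobule into granular and molecular layers
#'
#' Otsu-thresholds the Nissl intensities inside the lobule mask: voxels above
#' the threshold become the granular layer (high cell density), the rest the
#' molecular layer. Small isolated islands of either class are reassigned to
#' the surrounding class. A lobule whose split leaves under 1% of voxels in
#' one class is flagged (likely unimodal).
#'
#' @param nissl [intensity_volume()].
#' @param lobule_mask logical array on the same grid.
#' @param min_island components smaller than this (26-connectivity) are
#'   reassigned.
#' @return list `granular`, `molecular` (logical arrays), `threshold`,
#'   `flagged`.
#' @export
segment_lobule_layers <- function(nissl, lobule_mask, min_island = 10L) {
  if (!any(lobule_mask)) af_stop("empty lobule mask")
  v <- nissl$data[lobule_mask]
  thr <- otsu_threshold(v)
  gran <- lobule_mask & nissl$data > thr
  mol <- lobule_mask & !gran
  # island cleanup: flip small connected islands into the surrounding class
  for (pass in 1:2) {
    for (cls in c("g", "m")) {
      m <- if (cls == "g") gran else mol
      if (!any(m)) next
      comp <- label_components(array(as.integer(m), dim(m)), 26L)
      ids <- comp[comp != 0L]
      if (length(ids) == 0L) next
      tab <- table(ids)
      small <- as.integer(names(tab)[tab < min_island])
      if (!length(small)) next
      flip <- array(comp %in% small, dim(comp))
      if (cls == "g") { gran <- gran & !flip; mol <- mol | flip }
      else { mol <- mol & !flip; gran <- gran | flip }
    }
  }
  n <- sum(lobule_mask)
  flagged <- sum(gran) < 0.01 * n || sum(mol) < 0.01 * n
  if (flagged)
    af_warn("lobule split is degenerate (%.2f%% / %.2f%%); likely unimodal",
            100 * sum(gran) / n, 100 * sum(mol) / n)
  list(granular = gran, molecular = mol, threshold = thr, flagged = flagged)
}

#' Per-lobule layer segmentation of the cerebellum
#'
#' Applies [segment_lobule_layers()] independently to each lobule.
#'
#' @param nissl [intensity_volume()] aligned to the annotation.
#' @param ann [labeled_volume()] carrying the lobule labels.
#' @param graph the `structure_graph`.
#' @param lobule_ids lobule region ids.
#' @return object of class `layer_labeling`: per-lobule entries plus a
#'   `resolution_um` tag and a QC data.frame (`qc`).
#' @export
segment_cerebellum_layers <- function(nissl, ann, graph, lobule_ids) {
  entries <- list()
  qc <- list()
  for (id in sort(as.integer(lobule_ids))) {
    m <- region_mask(ann, graph, id, include_descendants = TRUE)
    e <- segment_lobule_layers(nissl, m)
    entries[[as.character(id)]] <- e
    qc[[length(qc) + 1L]] <- data.frame(
      lobule = id, voxels = sum(m), threshold = e$threshold,
      granular_fraction = sum(e$granular) / sum(m),
      molecular_fraction = sum(e$molecular) / sum(m),
      flagged = e$flagged)
  }
  structure(list(lobules = entries, resolution_um = nissl$meta$voxel_size[1],
                 qc = do.call(rbind, qc)),
            class = "layer_labeling")
}

#' @export
print.layer_labeling <- function(x, ...) {
  cat(sprintf("layer_labeling: %d lobules at %g um\n",
              length(x$lobules), x$resolution_um))
  print(x$qc, row.names = FALSE)
  invisible(x)
}

#' Upsample an annotation by block replication with optional modal smoothing
#'
#' Nearest-neighbor replication by an integer factor, then (optionally) one
#' pass of 3x3x3 majority filtering to smooth jagged label interfaces; the
#' filter can move an interface by at most one fine voxel and never invents
#' a label.
#'
#' @param ann a [labeled_volume()].
#' @param factor integer upsampling factor (e.g. 25 um -> 10 um uses block
#'   factors approximating the ratio; the grid metadata tracks the exact
#'   voxel size).
#' @param smooth apply the modal filter.
#' @return upsampled [labeled_volume()].
#' @export
upsample_annotation <- function(ann, factor, smooth = TRUE) {
  factor <- as.integer(rep_len(factor, 3))
  if (any(factor < 1L)) af_stop("factor must be >= 1")
  arr <- ann$data
  d <- dim(arr)
  arr <- arr[rep(seq_len(d[1]), each = factor[1]),
             rep(seq_len(d[2]), each = factor[2]),
             rep(seq_len(d[3]), each = factor[3]), drop = FALSE]
  if (smooth) arr <- modal_filter3(arr)
  meta <- ann$meta
  meta$voxel_size <- meta$voxel_size / factor
  meta$origin <- meta$origin - (factor - 1) / (2 * factor) * ann$meta$voxel_size
  labeled_volume(arr, meta)
}

#' One pass of 3x3x3 majority filtering on an integer label array
#' @noRd
modal_filter3 <- function(arr) {
  labs <- sort(unique(as.vector(arr)))
  if (length(labs) <= 1L) return(arr)
  offs <- rbind(c(0, 0, 0), neighbor_offsets(26L))
  best_count <- array(0L, dim(arr))
  best_lab <- array(labs[1], dim(arr))
  for (l in labs) {
    cnt <- array(0L, dim(arr))
    is_l <- arr == l
    for (r in seq_len(nrow(offs)))
      cnt <- cnt + shift_arr(is_l, offs[r, ], FALSE)
    # ties keep the smaller label (labs ascend; strict improvement required)
    upd <- cnt > best_count
    best_count[upd] <- cnt[upd]
    best_lab[upd] <- l
  }
  storage.mode(best_lab) <- "integer"
  best_lab
}

#' Upsample a layer labeling and synthesize the Purkinje layer
#'
#' The granular and molecular masks of each lobule are upsampled to the fine
#' resolution; [insert_purkinje()] then relabels the two-voxel interface.
#'
#' @param labeling a `layer_labeling` at coarse resolution.
#' @param ann the annotation the labeling was computed on.
#' @param factor integer block-replication factor; the exact fine voxel
#'   size is tracked in the result's `resolution_um` tag.
#' @return a `layer_labeling` at fine resolution ready for
#'   [insert_purkinje()].
#' @export
upsample_layer_labeling <- function(labeling, ann, factor = 2L) {
  fine <- list()
  for (k in names(labeling$lobules)) {
    e <- labeling$lobules[[k]]
    g <- upsample_annotation(labeled_volume(array(as.integer(e$granular),
                                                  dim(e$granular)), ann$meta),
                             factor, smooth = TRUE)
    m <- upsample_annotation(labeled_volume(array(as.integer(e$molecular),
                                                  dim(e$molecular)), ann$meta),
                             factor, smooth = TRUE)
    gm <- g$data == 1L & m$data == 1L  # modal smoothing can make them touch
    fine[[k]] <- list(granular = g$data == 1L & !gm,
                      molecular = m$data == 1L,
                      threshold = e$threshold, flagged = e$flagged)
  }
  structure(list(lobules = fine,
                 resolution_um = ann$meta$voxel_size[1] / factor,
                 qc = labeling$qc),
            class = "layer_labeling")
}

#' Synthesize the two-voxel Purkinje layer at the granular/molecular
#' interface
#'
#' The Purkinje layer is the union of granular voxels 6-adjacent to the
#' molecular layer and molecular voxels 6-adjacent to the granular layer:
#' exactly one voxel from each side of the interface, hence two voxels thick
#' across any locally planar interface.
#'
#' @param granular,molecular logical arrays at fine (10 um) resolution.
#' @return list `granular`, `molecular`, `purkinje`: pairwise disjoint masks
#'   whose union is the input union.
#' @export
insert_purkinje <- function(granular, molecular) {
  if (!identical(dim(granular), dim(molecular)))
    af_stop("mask grids differ")
  offs <- neighbor_offsets(6L)
  near_m <- array(FALSE, dim(granular))
  near_g <- array(FALSE, dim(granular))
  for (r in seq_len(nrow(offs))) {
    near_m <- near_m | shift_arr(molecular, offs[r, ], FALSE)
    near_g <- near_g | shift_arr(granular, offs[r, ], FALSE)
  }
  pk <- (granular & near_m) | (molecular & near_g)
  if (!any(pk)) af_stop("empty granular/molecular interface")
  list(granular = granular & !pk, molecular = molecular & !pk, purkinje = pk)
}

#' Flatten a layer labeling into an annotation volume
#'
#' @param labeling a `layer_labeling` (optionally with `purkinje` masks).
#' @param meta grid metadata for the output volume.
#' @param ids data.frame with columns `lobule`, `granular_id`,
#'   `molecular_id`, and optionally `purkinje_id`.
#' @return a [labeled_volume()].
#' @export
layer_annotation <- function(labeling, meta, ids) {
  d <- dim(labeling$lobules[[1]]$granular)
  out <- array(0L, d)
  for (i in seq_len(nrow(ids))) {
    e <- labeling$lobules[[as.character(ids$lobule[i])]]
    if (is.null(e)) next
    out[e$granular] <- as.integer(ids$granular_id[i])
    out[e$molecular] <- as.integer(ids$molecular_id[i])
    if (!is.null(e$purkinje) && "purkinje_id" %in% names(ids))
      out[e$purkinje] <- as.integer(ids$purkinje_id[i])
  }
  vs <- labeling$resolution_um
  m <- meta
  m$voxel_size <- rep(vs, 3)
  labeled_volume(out, m)
}
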