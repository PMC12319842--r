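# Grid-level preprocessing operators: resolution changes, border-voxel
# cleanup, hemisphere symmetrization, zero-padding and deformation-field
# upsampling.

#' Downsample an annotation volume by majority vote
#'
#' Each output voxel takes the majority label of its block; ties break toward
#' the smallest label id. Blocks are padded with background when the factor
#' does not divide the extent.
#'
#' @param ann a [labeled_volume()].
#' @param factor integer downsampling factor, scalar or per axis.
#' @return a [labeled_volume()] with voxel size scaled by `factor`.
#' @export
downsample_labels <- function(ann, factor) {
  stopifnot(is_labeled(ann))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (any(factor < 1)) af_stop("factor must be >= 1")
  factor <- pmin(as.integer(factor), vol_dim(ann))
  out <- block_reduce(ann$data, factor, "majority", fill = 0L)
  meta <- ann$meta
  meta$voxel_size <- meta$voxel_size * factor
  meta$origin <- meta$origin + (factor - 1) / 2 * ann$meta$voxel_size
  labeled_volume(out, meta)
}

#' Downsample an intensity volume by block averaging
#'
#' @param vol an [intensity_volume()].
#' @param factor integer factor, scalar or per axis.
#' @return an [intensity_volume()].
#' @export
downsample_intensity <- function(vol, factor) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (any(factor < 1)) af_stop("factor must be >= 1")
  factor <- pmin(as.integer(factor), vol_dim(vol))
  out <- block_reduce(vol$data, factor, "mean", fill = 0)
  meta <- vol$meta
  meta$voxel_size <- meta$voxel_size * factor
  meta$origin <- meta$origin + (factor - 1) / 2 * vol$meta$voxel_size
  intensity_volume(out, meta)
}

neighbor_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  nz <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6" = offs[nz == 1, , drop = FALSE],
         "18" = offs[nz <= 2, , drop = FALSE],
         "26" = offs,
         af_stop("connectivity must be 6, 18 or 26"))
}

shift_arr <- function(arr, off, fill) {
  d <- dim(arr)
  out <- array(fill, d)
  s <- lapply(1:3, function(a) seq(max(1L, 1L - off[a]), min(d[a], d[a] - off[a])))
  if (any(vapply(s, length, 1L) == 0L)) return(out)
  dst <- lapply(1:3, function(a) s[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[s[[1]], s[[2]], s[[3]]]
  out
}

#' Connected components of same-label voxels
#'
#' @param lab 3D integer array (0 = background).
#' @param connectivity 6, 18 or 26.
#' @return integer array of component ids (0 at background); ids are
#'   arbitrary but stable (the smallest linear index in the component).
#' @export
label_components <- function(lab, connectivity = 26L) {
  d <- dim(lab)
  nz <- lab != 0L
  big <- .Machine$integer.max
  comp <- array(big, d)
  comp[nz] <- which(nz)
  offs <- neighbor_offsets(connectivity)
  lab_pad <- lab
  repeat {
    old <- comp
    for (r in seq_len(nrow(offs))) {
      off <- offs[r, ]
      sc <- shift_arr(comp, off, big)
      sl <- shift_arr(lab_pad, off, -1L)
      ok <- nz & (sl == lab_pad)
      comp[ok] <- pmin(comp[ok], sc[ok])
    }
    # pointer jumping: comp values are linear indices, follow them a few hops
    for (t in 1:4) comp[nz] <- comp[comp[nz]]
    if (identical(comp, old)) break
  }
  comp[!nz] <- 0L
  comp
}

#' Remove small isolated components at annotation borders
#'
#' Connected components of non-background labels smaller than `min_component`
#' voxels, and not face-adjacent to a larger component of the same label, are
#' reset to background. The number of removed voxels is attached as attribute
#' `removed`.
#'
#' @param ann a [labeled_volume()].
#' @param min_component minimum voxel count for a component to survive.
#' @param connectivity component connectivity (6, 18 or 26).
#' @return cleaned [labeled_volume()] with attribute `removed`.
#' @export
clean_border_voxels <- function(ann, min_component = 5L, connectivity = 26L) {
  stopifnot(is_labeled(ann))
  if (min_component < 1L) af_stop("min_component must be >= 1")
  comp <- label_components(ann$data, connectivity)
  ids <- comp[comp != 0L]
  if (length(ids) == 0L) {
    out <- ann
    attr(out, "removed") <- 0L
    return(out)
  }
  uids <- sort(unique(ids))
  sizes <- stats::setNames(tabulate(match(ids, uids)), uids)
  small <- uids[sizes[as.character(uids)] < min_component]
  if (length(small) == 0L) {
    attr(ann, "removed") <- 0L
    return(ann)
  }
  # face adjacency to a strictly larger same-label component rescues a
  # small component
  rescued <- logical(length(small))
  names(rescued) <- small
  offs6 <- neighbor_offsets(6L)
  for (r in seq_len(nrow(offs6))) {
    off <- offs6[r, ]
    sc <- shift_arr(comp, off, 0L)
    sl <- shift_arr(ann$data, off, -1L)
    touch <- comp != 0L & sc != 0L & sc != comp & sl == ann$data
    if (!any(touch)) next
    pairs <- unique(cbind(comp[touch], sc[touch]))
    for (p in seq_len(nrow(pairs))) {
      a <- as.character(pairs[p, 1]); b <- as.character(pairs[p, 2])
      if (a %in% names(rescued) && sizes[b] > sizes[a]) rescued[a] <- TRUE
    }
  }
  drop_ids <- as.integer(names(rescued)[!rescued])
  kill <- array(comp %in% drop_ids, dim(comp))
  data <- ann$data
  data[kill] <- 0L
  out <- labeled_volume(data, ann$meta)
  attr(out, "removed") <- sum(kill)
  out
}

#' Mirror one hemisphere onto the other
#'
#' The chosen source hemisphere (lower-index half of the left-right axis for
#' `"left"`, upper half for `"right"`) is reflected about the mid-plane so
#' that the output is exactly mirror-symmetric. With an odd extent the
#' central plane is left untouched.
#'
#' @param vol a volume object.
#' @param source_hemisphere `"left"` or `"right"`.
#' @param axis array axis of the left-right direction; defaults to the axis
#'   whose role is `"lr"` in the volume metadata.
#' @return volume of the same class.
#' @export
symmetrize <- function(vol, source_hemisphere = c("right", "left"), axis = NULL) {
  source_hemisphere <- match.arg(source_hemisphere)
  ax <- axis %||% role_axis(vol$meta, "lr")
  if (vol$meta$axis_roles[ax] != "lr")
    af_stop("axis %d is not the left-right axis", ax)
  d <- vol_dim(vol)
  n <- d[ax]
  n2 <- n %/% 2L
  if (n2 == 0L) return(vol)
  arr <- vol$data
  idx <- lapply(d, seq_len)
  if (source_hemisphere == "left") {
    src <- idx; src[[ax]] <- n2:1
    dst <- idx; dst[[ax]] <- (n - n2 + 1L):n
  } else {
    src <- idx; src[[ax]] <- n:(n - n2 + 1L)
    dst <- idx; dst[[ax]] <- 1:n2
  }
  arr[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  vol_like(vol, arr)
}

#' Mirror image of a volume about the mid-plane of an axis
#' @param vol a volume object.
#' @param axis axis index; defaults to the left-right axis.
#' @export
mirror <- function(vol, axis = NULL) {
  ax <- axis %||% role_axis(vol$meta, "lr")
  d <- vol_dim(vol)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  vol_like(vol, vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}

#' Pad a volume with constant slabs
#'
#' Padding `lo` slabs at the low-index end of an axis shifts the origin by
#' `-lo * voxel_size` on that axis, so the world coordinates of all original
#' voxels are preserved. Index 0 of the rostro-caudal axis is the rostral end,
#' so rostral padding produces the expected negative rostral origin shift.
#'
#' @param vol a volume object.
#' @param lo,hi integer vectors (length 3) of slab counts per axis.
#' @param fill fill value (0 for background).
#' @return padded volume.
#' @export
pad_volume <- function(vol, lo = c(0, 0, 0), hi = c(0, 0, 0), fill = 0) {
  lo <- as.integer(rep_len(lo, 3)); hi <- as.integer(rep_len(hi, 3))
  if (any(lo < 0) || any(hi < 0)) af_stop("slab counts must be non-negative")
  d <- vol_dim(vol)
  nd <- d + lo + hi
  arr <- array(if (is_labeled(vol)) as.integer(fill) else fill, nd)
  arr[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- vol$data
  meta <- vol$meta
  meta$origin <- meta$origin - lo * meta$voxel_size
  vol_like(vol, arr, meta)
}

#' Upsample a deformation field to a finer grid
#'
#' Displacement components (micrometres) are linearly interpolated onto the
#' finer grid; physical displacement magnitudes are preserved. Edge values are
#' clamped (no zeroing at the boundary).
#'
#' @param field a `deformation_field`.
#' @param factor integer refinement factor (e.g. 2.5 for 25 um -> 10 um).
#' @return a `deformation_field` on the finer grid.
#' @export
upsample_field <- function(field, factor) {
  if (any(factor < 1)) af_stop("factor must be >= 1")
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  d <- dim(field$disp)[1:3]
  meta <- field$meta
  fine <- meta
  fine$voxel_size <- meta$voxel_size / factor
  nd <- as.integer(round(d * factor))
  pts <- grid_points(fine, nd)
  disp <- array(0, c(nd, 3L))
  for (c3 in 1:3) {
    v <- sample_array(field_comp(field, c3), meta, pts,
                      interpolation = "linear", clamp = TRUE)
    disp[, , , c3] <- array(v, nd)
  }
  deformation_field(disp, fine)
}
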