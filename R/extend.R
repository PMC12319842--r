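# Rostral/caudal tissue extension: registering a complete donor volume onto a
# truncated target, intensity-normalizing it, copying the missing tissue and
# blending the junction; plus annotation-volume merging (concatenation or
# overlay).

#' Monotone histogram matching
#'
#' Maps `src` intensities through the monotone quantile mapping that equates
#' the cumulative distribution of `src` over `mask_src` with that of `ref`
#' over `mask_ref` (256-bin resolution). The mapping is *fitted* on the
#' masks but *applied* to every non-background voxel of `src`, so tissue
#' outside the fit region (e.g. an extension) is normalized consistently.
#' Monotonicity preserves the intensity ordering of `src`.
#'
#' @param src [intensity_volume()] to remap.
#' @param ref reference [intensity_volume()].
#' @param mask_src,mask_ref logical arrays selecting the voxels whose
#'   distributions are equated (defaults: non-background).
#' @param bins quantile resolution.
#' @return remapped [intensity_volume()].
#' @export
histogram_match <- function(src, ref, mask_src = NULL, mask_ref = NULL,
                            bins = 256L) {
  mask_src <- mask_src %||% (src$data != 0)
  mask_ref <- mask_ref %||% (ref$data != 0)
  if (!any(mask_src) || !any(mask_ref)) af_stop("empty histogram-match mask")
  sv <- src$data[mask_src]
  rv <- ref$data[mask_ref]
  if (max(sv) == min(sv)) af_stop("constant source in histogram_match")
  p <- seq(0, 1, length.out = bins)
  qs <- stats::quantile(sv, p, names = FALSE, type = 7)
  qr <- stats::quantile(rv, p, names = FALSE, type = 7)
  # collapse duplicated source quantiles to keep approx() strictly monotone
  keep <- !duplicated(qs)
  fg <- src$data != 0
  out <- src$data
  out[fg] <- stats::approx(qs[keep], qr[keep], xout = src$data[fg], rule = 2)$y
  intensity_volume(out, src$meta)
}

#' Average two volumes across a thin junction slab
#'
#' Within a `thickness`-plane slab centered at `plane_index` along `axis`,
#' the output is the voxel-wise mean of `base` and `addition`; all other
#' voxels keep `base`.
#'
#' @param base,addition [intensity_volume()]s on the same grid.
#' @param axis array axis of the junction (default rostro-caudal).
#' @param plane_index 1-based center plane of the slab.
#' @param thickness slab thickness in planes (odd; default 3).
#' @return blended [intensity_volume()].
#' @export
blend_junction <- function(base, addition, axis = NULL, plane_index,
                           thickness = 3L) {
  ax <- axis %||% role_axis(base$meta, "rc")
  d <- vol_dim(base)
  if (!identical(d, vol_dim(addition))) af_stop("grids differ in blend_junction")
  half <- (thickness - 1L) %/% 2L
  planes <- (plane_index - half):(plane_index + thickness - 1L - half)
  if (min(planes) < 1L || max(planes) > d[ax])
    af_stop("junction slab exceeds the volume bounds")
  idx <- lapply(d, seq_len)
  idx[[ax]] <- planes
  out <- base$data
  out[idx[[1]], idx[[2]], idx[[3]]] <-
    (base$data[idx[[1]], idx[[2]], idx[[3]]] +
     addition$data[idx[[1]], idx[[2]], idx[[3]]]) / 2
  intensity_volume(out, base$meta)
}

#' Extend truncated tissue from a complete donor volume
#'
#' Reconstructs the missing part of a truncated region by aligning a
#' complete donor volume of the same modality: (1) global linear (rigid +
#' scaling) registration of the donor to the target; (2) crop to the full
#' region bounding box; (3) mask the donor by the truncated annotation so
#' only shared tissue drives (4) a nonlinear (no linear stage) registration
#' to the target; (5) the field is applied to the unmasked donor so the
#' extension tissue follows continuously; (6) histogram matching onto the
#' target over the shared tissue; (7) donor voxels are copied where the full
#' mask extends beyond the truncated mask (never overwriting target tissue);
#' (8) a three-voxel junction slab is averaged along the rostro-caudal axis.
#'
#' @param target truncated [intensity_volume()] (tissue only inside
#'   `truncated_mask`).
#' @param donor complete [intensity_volume()] of the same modality.
#' @param full_mask logical array: the complete region extent.
#' @param truncated_mask logical array: the populated part (subset of
#'   `full_mask`).
#' @param params a [registration_params()] for the nonlinear stage. The
#'   default uses the local-correlation metric: donor and target come from
#'   different specimens/stains whose intensity scales differ, and an SSD
#'   objective would absorb the gain mismatch into spurious deformation.
#' @param affine_params parameters for the global linear stage.
#' @param margin crop margin (voxels).
#' @param blend_thickness junction slab thickness.
#' @return list with `extended` ([intensity_volume()]), `affine`, `field`,
#'   and a `report` (step log, junction plane, voxel counts).
#' @export
extend_region <- function(target, donor, full_mask, truncated_mask,
                          params = registration_params(levels = c(4, 2, 1),
                                                       iterations = c(80, 40, 25),
                                                       metric = "lcc",
                                                       sigma_field_um = 50,
                                                       sigma_fluid_um = 25),
                          affine_params = registration_params(levels = c(4, 2),
                                                              iterations = c(60, 30),
                                                              metric = "lcc"),
                          margin = 5L, blend_thickness = 3L) {
  if (any(truncated_mask & !full_mask))
    af_stop("truncated_mask must be a subset of full_mask")
  if (!any(truncated_mask & donor$data != 0))
    af_stop("no overlap between the truncated mask and donor tissue")
  steps <- character(0)
  log_step <- function(msg) steps <<- c(steps, msg)
  # metric mask: the shared tissue minus a band next to the cut. Both
  # volumes carry an identical artificial edge where the truncated mask
  # cuts them; left in the metric it anchors every registration to zero
  # displacement at the cut, so the band is excluded from similarity
  # evaluation and demons forces.
  ax <- role_axis(target$meta, "rc")
  d <- vol_dim(target)
  occ_tr <- apply(truncated_mask, ax, any)
  occ_miss <- apply(full_mask & !truncated_mask, ax, any)
  band <- rep(FALSE, d[ax])
  for (pl in which(occ_tr)) {
    if (any(occ_miss[max(1, pl - 3):min(d[ax], pl + 3)])) band[pl] <- TRUE
  }
  metric_mask <- truncated_mask
  if (any(band)) {
    idxb <- lapply(d, seq_len)
    idxb[[ax]] <- which(band)
    metric_mask[idxb[[1]], idxb[[2]], idxb[[3]]] <- FALSE
  }
  # (1) global linear donor -> target (rigid and scaling). The donor is
  # masked by the truncated annotation here too: tissue over the missing
  # part would otherwise bias the fit toward the populated side.
  donor_hidden <- intensity_volume(donor$data * truncated_mask, donor$meta)
  aff <- register_affine(donor_hidden, target, affine_params, dof = "similarity",
                         fixed_mask = metric_mask)
  donor_lin <- apply_transform(donor, aff, "linear", target$meta, vol_dim(target))
  log_step(sprintf("global similarity registration (score %.4f)", attr(aff, "score")))
  # (2) crop to the full-region bounding box
  bbox <- mask_bbox(full_mask, margin)
  cmeta <- target$meta
  cmeta$origin <- cmeta$origin + (bbox[, 1] - 1) * target$meta$voxel_size
  tgt_c <- intensity_volume(crop_array(target$data, bbox), cmeta)
  don_c <- intensity_volume(crop_array(donor_lin$data, bbox), cmeta)
  trunc_c <- crop_array(truncated_mask, bbox)
  full_c <- crop_array(full_mask, bbox)
  log_step(sprintf("cropped to full-mask bounding box %s",
                   paste(bbox[, 2] - bbox[, 1] + 1, collapse = "x")))
  # (3) hide the part missing from the target
  don_masked <- intensity_volume(don_c$data * trunc_c, cmeta)
  # (4) nonlinear registration, masked donor (moving) -> target (fixed),
  # with the cut-adjacent band excluded from the metric
  metric_c <- crop_array(metric_mask, bbox)
  fld <- register_nonlinear(don_masked, tgt_c, params, fixed_mask = metric_c)
  log_step(sprintf("nonlinear registration of masked donor (score %.4f)",
                   attr(fld, "score")))
  # (5) apply the field to the unmasked donor crop
  don_warp <- apply_transform(don_c, fld, "linear", cmeta, vol_dim(don_c))
  # (6) histogram matching over the shared (truncated) tissue
  don_match <- histogram_match(don_warp, tgt_c,
                               mask_src = trunc_c & don_warp$data != 0,
                               mask_ref = trunc_c & tgt_c$data != 0)
  log_step("histogram matching over the shared tissue")
  # (7) copy the missing voxels (full mask minus truncated mask), never
  # overwriting populated target tissue
  fill_mask <- full_c & !trunc_c & tgt_c$data == 0
  ext <- tgt_c$data
  ext[fill_mask] <- don_match$data[fill_mask]
  ext_c <- intensity_volume(ext, cmeta)
  log_step(sprintf("copied %d extension voxels", sum(fill_mask)))
  # (8) junction blending: slab centered on the last originally-populated
  # plane of the target along the rostro-caudal axis
  ax <- role_axis(target$meta, "rc")
  occ <- apply(trunc_c, ax, any)
  occ_ext <- apply(full_c & !trunc_c, ax, any)
  junction <- if (any(occ_ext) && min(which(occ_ext)) < min(which(occ)))
    min(which(occ)) else max(which(occ))  # rostral vs caudal extension
  blended <- blend_junction(ext_c, don_match, ax, junction, blend_thickness)
  log_step(sprintf("averaged %d-voxel junction slab at plane %d",
                   blend_thickness, junction))
  out <- target$data
  out[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2], bbox[3, 1]:bbox[3, 2]] <-
    blended$data
  list(extended = intensity_volume(out, target$meta),
       affine = aff, field = fld,
       report = list(steps = steps, junction_plane_crop = junction,
                     bbox = bbox, filled_voxels = sum(fill_mask)))
}

#' Merge an annotation add-on into a base annotation volume
#'
#' Supports slab concatenation along an axis (spinal-cord style: the grid
#' grows) and in-place overlay through an optional affine placement. Label id
#' spaces must be disjoint unless an explicit `remap` is given; voxel
#' overlaps are resolved by `precedence` and counted.
#'
#' @param base,addon [labeled_volume()]s.
#' @param placement `"overlay"` (same grid, optional `affine`), or
#'   `"concat"` (append along `axis` at the `end`).
#' @param precedence `"base"` or `"addon"` for overlapping voxels.
#' @param affine optional [affine_transform()] mapping base-grid points into
#'   addon space for overlay placement.
#' @param axis,end concatenation parameters (default: caudal end of the
#'   rostro-caudal axis).
#' @param remap named integer vector renaming addon labels (old -> new) when
#'   id spaces collide.
#' @return merged [labeled_volume()] with attribute `overlap` (voxel count).
#' @export
merge_annotations <- function(base, addon, placement = c("overlay", "concat"),
                              precedence = c("base", "addon"),
                              affine = NULL, axis = NULL,
                              end = c("caudal", "rostral"), remap = NULL) {
  placement <- match.arg(placement)
  precedence <- match.arg(precedence)
  end <- match.arg(end)
  addon_data <- addon$data
  if (!is.null(remap)) {
    for (old in names(remap)) addon_data[addon_data == as.integer(old)] <- remap[[old]]
    addon <- labeled_volume(addon_data, addon$meta)
  }
  shared <- intersect(setdiff(unique(as.vector(base$data)), 0L),
                      setdiff(unique(as.vector(addon$data)), 0L))
  if (length(shared))
    af_stop("label id collision (%s); supply a remap",
            paste(utils::head(shared, 5), collapse = ", "))
  if (placement == "concat") {
    ax <- axis %||% role_axis(base$meta, "rc")
    d <- vol_dim(base)
    da <- vol_dim(addon)
    if (!all(da[-ax] == d[-ax]))
      af_stop("in-plane dimensions must match for concatenation")
    nd <- d
    nd[ax] <- d[ax] + da[ax]
    out <- array(0L, nd)
    idx_base <- lapply(nd, seq_len)
    idx_addon <- lapply(nd, seq_len)
    if (end == "caudal") {
      idx_base[[ax]] <- seq_len(d[ax])
      idx_addon[[ax]] <- d[ax] + seq_len(da[ax])
      meta <- base$meta
    } else {
      idx_addon[[ax]] <- seq_len(da[ax])
      idx_base[[ax]] <- da[ax] + seq_len(d[ax])
      meta <- base$meta
      meta$origin[ax] <- meta$origin[ax] - da[ax] * meta$voxel_size[ax]
    }
    out[idx_base[[1]], idx_base[[2]], idx_base[[3]]] <- base$data
    out[idx_addon[[1]], idx_addon[[2]], idx_addon[[3]]] <- addon$data
    res <- labeled_volume(out, meta)
    attr(res, "overlap") <- 0L
    return(res)
  }
  placed <- if (is.null(affine)) {
    if (!identical(vol_dim(addon), vol_dim(base))) af_stop("grids differ for overlay")
    addon
  } else apply_transform(addon, affine, "nearest", base$meta, vol_dim(base))
  overlap <- base$data != 0L & placed$data != 0L
  out <- base$data
  if (precedence == "addon") {
    put <- placed$data != 0L
  } else {
    put <- placed$data != 0L & base$data == 0L
  }
  out[put] <- placed$data[put]
  res <- labeled_volume(out, base$meta)
  attr(res, "overlap") <- sum(overlap)
  res
}
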