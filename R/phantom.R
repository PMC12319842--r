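# Synthetic phantom brains with recorded ground truth.
#
# The phantom emulates the structure of the real inputs: two annotation
# versions of the same anatomy related by a known smooth deformation and with
# some leaf labels merged away in the older version; a high-contrast textured
# Nissl-like intensity volume on the older version's geometry; a smooth,
# low-contrast average-template-like volume on the newer version's geometry;
# a four-lobule "cerebellum" whose lobules carry bimodal (granular/molecular)
# intensity; plus sections, truncations and fiducials. Every random draw is
# governed by one seed and every generating transform is recorded, so tests
# can close the loop exactly.

#' Phantom generation parameters
#'
#' The defaults define the standard "mouse-64" phantom: a 64 x 80 x 56 grid
#' at 25 um, a 15-node ontology (root, 2 divisions, 4 parents, 8 leaves of
#' which 4 are cerebellar lobules), 2 leaves dropped from the older
#' annotation version, and a smooth sinusoidal inter-version warp with peak
#' displacement 3 voxels plus a small affine jitter.
#'
#' @param dim grid dimensions.
#' @param voxel_um isotropic voxel size (um).
#' @param warp_amplitude_vox peak displacement magnitude of the inter-version
#'   warp, in voxels.
#' @param warp_wavelength_vox sinusoid wavelength, in voxels.
#' @param jitter_rot_deg,jitter_scale,jitter_shift_vox affine jitter of the
#'   older version.
#' @param speckle_sd Nissl-like speckle noise standard deviation (intensity
#'   units; region means span 50-200).
#' @param template_blur_vox template-like Gaussian blur sigma (voxels).
#' @param contrast_compress template-like contrast compression factor in
#'   (0, 1]; smaller = flatter contrast.
#' @param dropped_leaves leaf ids merged into their parents in the older
#'   version (defaults: one leaf with a surviving sibling, one sole child
#'   whose parent then carries its own label).
#' @param n_fiducials number of ground-truth fiducial points.
#' @param seed integer seed fixing all randomness.
#' @export
phantom_spec <- function(dim = c(64, 80, 56), voxel_um = 25,
                         warp_amplitude_vox = 3, warp_wavelength_vox = 32,
                         jitter_rot_deg = 1, jitter_scale = 1.02,
                         jitter_shift_vox = c(0.8, -0.6, 0.5),
                         speckle_sd = 8, template_blur_vox = 1.5,
                         contrast_compress = 0.45,
                         dropped_leaves = c(3002L, 3004L),
                         n_fiducials = 8L, seed = 1L) {
  structure(list(dim = as.integer(dim), voxel_um = voxel_um,
                 warp_amplitude_vox = warp_amplitude_vox,
                 warp_wavelength_vox = warp_wavelength_vox,
                 jitter_rot_deg = jitter_rot_deg, jitter_scale = jitter_scale,
                 jitter_shift_vox = jitter_shift_vox,
                 speckle_sd = speckle_sd, template_blur_vox = template_blur_vox,
                 contrast_compress = contrast_compress,
                 dropped_leaves = as.integer(dropped_leaves),
                 n_fiducials = as.integer(n_fiducials),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @noRd
phantom_leaf_means <- function() {
  c(`3001` = 120, `3002` = 150, `3003` = 100, `3004` = 170,
    `4001` = 50, `4002` = 50, `4003` = 50, `4004` = 50)
}

#' Build the newer-version annotation geometry on the phantom grid
#' @noRd
phantom_annotation <- function(spec) {
  d <- spec$dim
  ctr <- (d + 1) / 2
  semi <- c(0.40, 0.44, 0.40) * d
  i1 <- rep.int(seq_len(d[1]), d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]), each = d[1] * d[2])
  nx <- (i1 - ctr[1]) / semi[1]
  ny <- (i2 - ctr[2]) / semi[2]
  nz <- (i3 - ctr[3]) / semi[3]
  brain <- nx^2 + ny^2 + nz^2 <= 1
  yn <- (ny + 1) / 2  # 0 rostral .. 1 caudal within the bounding ellipsoid
  lab <- integer(prod(d))
  left <- nx < 0
  down <- nz < 0
  rostral <- yn < 0.28
  mid <- yn >= 0.28 & yn < 0.52
  stem <- yn >= 0.52 & yn < 0.78
  cb <- yn >= 0.78
  lab[brain & rostral & down] <- 3001L
  lab[brain & rostral & !down] <- 3002L
  lab[brain & mid] <- 3003L
  lab[brain & stem] <- 3004L
  lab[brain & cb & left & down] <- 4001L
  lab[brain & cb & !left & down] <- 4002L
  lab[brain & cb & left & !down] <- 4003L
  lab[brain & cb & !left & !down] <- 4004L
  arr <- array(lab, d)
  meta <- grid_meta(spec$voxel_um, c(0, 0, 0), c("lr", "rc", "dv"))
  labeled_volume(arr, meta)
}

#' Granular-layer masks for the four lobules (ground truth for the layer
#' segmentation). Mirrors cerebellar cortex layering: the high-intensity
#' granular layer is the inner concentric part of each lobule, the
#' low-intensity molecular layer the outer shell, so the intensity layering
#' follows the lobule's shape.
#' @noRd
phantom_granular <- function(ann, lobule_ids, inner_fraction = 0.62) {
  d <- vol_dim(ann)
  i1 <- rep.int(seq_len(d[1]), d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]), each = d[1] * d[2])
  out <- list()
  for (id in lobule_ids) {
    m <- as.vector(ann$data == id)
    if (!any(m)) next
    cx <- c(mean(i1[m]), mean(i2[m]), mean(i3[m]))
    # normalized radial position within the lobule (per-axis scaled)
    sx <- pmax(c(stats::sd(i1[m]), stats::sd(i2[m]), stats::sd(i3[m])), 0.5)
    rho <- sqrt(((i1 - cx[1]) / sx[1])^2 + ((i2 - cx[2]) / sx[2])^2 +
                  ((i3 - cx[3]) / sx[3])^2)
    cut <- stats::quantile(rho[m], inner_fraction)
    out[[as.character(id)]] <- array(m & rho <= cut, d)
  }
  out
}

#' Analytic sinusoidal deformation realized on a grid
#'
#' Peak displacement magnitude equals `amplitude_vox` voxels (each component
#' has amplitude `amplitude_vox / sqrt(3)`).
#'
#' @param meta grid metadata.
#' @param dims grid dimensions.
#' @param amplitude_vox peak |u| in voxels.
#' @param wavelength_vox sinusoid wavelength in voxels.
#' @param phases length-3 phase offsets (radians).
#' @return a `deformation_field`.
#' @export
sinusoidal_field <- function(meta, dims, amplitude_vox = 3,
                             wavelength_vox = 32, phases = c(0, 2, 4)) {
  vs <- meta$voxel_size
  A <- amplitude_vox * vs / sqrt(3)
  lam <- wavelength_vox * vs
  pts <- grid_points(meta, dims)
  u <- cbind(
    A[1] * sin(2 * pi * pts[, 2] / lam[2] + phases[1]) *
      cos(2 * pi * pts[, 3] / lam[3] + phases[2]),
    A[2] * sin(2 * pi * pts[, 3] / lam[3] + phases[2]) *
      cos(2 * pi * pts[, 1] / lam[1] + phases[3]),
    A[3] * sin(2 * pi * pts[, 1] / lam[1] + phases[3]) *
      cos(2 * pi * pts[, 2] / lam[2] + phases[1]))
  deformation_field(array(u, c(dims, 3L)), meta)
}

#' Generate a phantom bundle
#'
#' Deterministic under `spec$seed`. Products: the structure graph; the
#' newer-version annotation `annV3`; the older-version annotation `annV2`
#' (known warp applied, dropped leaves merged into their parents; the
#' un-merged warped annotation is `annV2_full`); the Nissl-like intensity
#' volume `nissl` on the older geometry; the ground-truth aligned Nissl
#' `nissl_v3`; the smooth template-like volume `template`; the recorded
#' inter-version transform `warp` (maps older-grid points into newer space;
#' `annV2_full` re-derives from `annV3` through it voxel-exactly); lobule
#' ids and granular-core ground truth; fiducials (reference coordinates in
#' newer space, estimated coordinates in the older volume); truncated and
#' donor volumes for the tissue-extension workflow under `$extend`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_bundle`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    graph <- phantom_graph()
    annV3 <- phantom_annotation(spec)
    meta <- annV3$meta
    d <- spec$dim
    # ground-truth inter-version transform: sinusoid then affine jitter
    sfield <- sinusoidal_field(meta, d, spec$warp_amplitude_vox,
                               spec$warp_wavelength_vox,
                               phases = stats::runif(3, 0, 2 * pi))
    ctr <- meta$origin + (d - 1) / 2 * meta$voxel_size
    r <- spec$jitter_rot_deg * pi / 180
    M <- rot_mat(c(r, -r / 2, r / 3)) * spec$jitter_scale
    jitter <- affine_transform(M, ctr - as.numeric(M %*% ctr) +
                                 spec$jitter_shift_vox * meta$voxel_size)
    warp <- transform_chain(sfield, jitter)
    annV2_full <- apply_transform(annV3, warp, "nearest", meta, d)
    # merge dropped leaves into their parents in the older version
    dropped <- spec$dropped_leaves
    parents <- vapply(dropped, function(id) graph$nodes[[as.character(id)]]$parent, 1L)
    names(parents) <- as.character(dropped)
    v2 <- annV2_full$data
    for (i in seq_along(dropped)) v2[v2 == dropped[i]] <- parents[i]
    annV2 <- labeled_volume(v2, meta)
    # intensities on the newer geometry
    means <- phantom_leaf_means()
    lobules <- c(4001L, 4002L, 4003L, 4004L)
    I3_flat <- array(0, d)  # lobules uniform: the template modality has no
                            # granular/molecular contrast
    for (k in names(means)) I3_flat[annV3$data == as.integer(k)] <- means[[k]]
    I3 <- I3_flat
    granular <- phantom_granular(annV3, lobules)
    for (k in names(granular)) I3[granular[[k]]] <- 200
    nissl_v3 <- intensity_volume(
      pmax(I3 + (I3 > 0) * stats::rnorm(length(I3), 0, spec$speckle_sd), 0), meta)
    # Nissl-like volume on the older geometry: warp the clean intensity
    # model, then add speckle on the older grid
    I2vol <- apply_transform(intensity_volume(I3, meta), warp, "linear", meta, d)
    I2 <- I2vol$data
    nissl <- intensity_volume(
      pmax(I2 + (I2 > 2) * stats::rnorm(length(I2), 0, spec$speckle_sd), 0), meta)
    # template-like: contrast-compressed and blurred, no texture, and no
    # cerebellar sublayer contrast
    tmpl <- I3_flat
    fg <- I3_flat > 0
    tmpl[fg] <- 60 + spec$contrast_compress * (I3_flat[fg] - 60)
    tmpl <- smooth3d(tmpl, spec$template_blur_vox)
    template <- intensity_volume(tmpl, meta)
    # fiducials: leaf centroids in newer space; their observed position in
    # the older volume is the inverse warp image
    leaf_ids <- sort(setdiff(unique(as.vector(annV3$data)), 0L))
    cent <- t(vapply(leaf_ids, function(id) {
      w <- which(annV3$data == id)
      ix <- arrayInd(w, d)
      meta$origin + (colMeans(ix) - 1) * meta$voxel_size
    }, numeric(3)))
    take <- seq_len(min(spec$n_fiducials, nrow(cent)))
    inv_warp <- invert_transform(warp)
    reg <- transform_points(inv_warp, cent[take, , drop = FALSE])
    fiducials <- as_fiducials(data.frame(
      name = paste0("fid_", leaf_ids[take]),
      group = c("fore", "fore", "mid", "stem", "cb", "cb", "cb", "cb")[take],
      x_ref = cent[take, 1], y_ref = cent[take, 2], z_ref = cent[take, 3],
      x_reg = reg[, 1], y_reg = reg[, 2], z_reg = reg[, 3]))
    # extension phantom: complete target, rostrally truncated target, and a
    # complete donor with its own recorded warp and intensity scale
    extend <- phantom_extend_products(nissl_v3, annV3, spec)
    structure(list(spec = spec, graph = graph, annV3 = annV3,
                   annV2_full = annV2_full, annV2 = annV2,
                   nissl = nissl, nissl_v3 = nissl_v3, template = template,
                   warp = warp, dropped = parents,
                   lobule_ids = lobules, granular = granular,
                   fiducials = fiducials, extend = extend),
              class = "phantom_bundle")
  })
}

#' The phantom structure graph (15 nodes: root, 2 divisions, 4 parents,
#' 8 leaves including 4 cerebellar lobules)
#' @export
phantom_graph <- function() {
  df <- data.frame(
    id        = c(997L, 1001L, 1002L, 2001L, 2002L, 2003L, 2004L,
                  3001L, 3002L, 3003L, 3004L,
                  4001L, 4002L, 4003L, 4004L),
    parent_id = c(NA, 997L, 997L, 1001L, 1001L, 1002L, 1002L,
                  2001L, 2001L, 2002L, 2003L,
                  2004L, 2004L, 2004L, 2004L),
    acronym   = c("root", "FB", "HB", "ROS", "MID", "BS", "CBX",
                  "ROSd", "ROSv", "MIDc", "BSc",
                  "LOB1", "LOB2", "LOB3", "LOB4"),
    stringsAsFactors = FALSE)
  structure_graph(df)
}

#' @noRd
phantom_extend_products <- function(nissl_v3, annV3, spec) {
  meta <- nissl_v3$meta
  d <- vol_dim(nissl_v3)
  rc <- role_axis(meta, "rc")
  full_mask <- annV3$data != 0L
  occ <- apply(full_mask, rc, any)
  planes <- which(occ)[1:6]  # six most rostral populated planes
  idx <- lapply(d, seq_len)
  trunc_mask <- full_mask
  cut <- idx; cut[[rc]] <- planes
  trunc_mask[cut[[1]], cut[[2]], cut[[3]]] <- FALSE
  target <- nissl_v3$data
  target[cut[[1]], cut[[2]], cut[[3]]] <- 0
  # another-specimen shape difference: smooth at the scale of the whole
  # brain (one period across the volume), small amplitude
  dwarp <- sinusoidal_field(meta, d, amplitude_vox = 1.5,
                            wavelength_vox = 64, phases = c(1, 3, 5))
  donor_clean <- apply_transform(nissl_v3, dwarp, "linear", meta, d)
  dn <- donor_clean$data * 1.15 + (donor_clean$data > 0) * 12
  donor <- intensity_volume(pmax(dn + (dn > 0) * stats::rnorm(length(dn), 0, 2), 0), meta)
  list(target = intensity_volume(target, meta),
       target_complete = nissl_v3,
       donor = donor, donor_warp = dwarp,
       full_mask = full_mask, truncated_mask = trunc_mask,
       cut_planes = planes, axis = rc)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle: %dx%dx%d at %g um, seed %d\n",
              x$spec$dim[1], x$spec$dim[2], x$spec$dim[3],
              x$spec$voxel_um, x$spec$seed))
  cat(sprintf("  %d ontology nodes, dropped leaves: %s\n",
              length(x$graph$nodes), paste(names(x$dropped), collapse = ", ")))
  invisible(x)
}

#' Extract warped, noisy 2D sections from a volume
#'
#' Every `spacing`-th plane along the chosen axis is extracted, warped
#' in-plane by a recorded sinusoidal field, and corrupted with i.i.d.
#' Gaussian noise.
#'
#' @param volume an [intensity_volume()].
#' @param axis sectioning axis (default: the rostro-caudal axis).
#' @param spacing plane spacing in voxels.
#' @param warp_amplitude_px peak in-plane displacement (pixels).
#' @param noise_sd additive noise sd.
#' @param seed integer seed.
#' @param source_id specimen tag recorded in each section.
#' @return list of section records: `image` (2D matrix), `plane_axis`,
#'   `plane_index`, `source_id`, `warp` (recorded in-plane field, pixels),
#'   `pixel_um`.
#' @export
make_sections <- function(volume, axis = NULL, spacing = 8L,
                          warp_amplitude_px = 0, noise_sd = 0, seed = 1L,
                          source_id = "spec1") {
  ax <- axis %||% role_axis(volume$meta, "rc")
  d <- vol_dim(volume)
  planes <- seq(spacing, d[ax], by = spacing)
  inplane <- setdiff(1:3, ax)
  pd <- d[inplane]
  with_seed(seed, {
    lapply(seq_along(planes), function(si) {
      s <- planes[si]
      idx <- lapply(d, seq_len)
      idx[[ax]] <- s
      img <- array(volume$data[idx[[1]], idx[[2]], idx[[3]]], pd)
      warp <- NULL
      if (warp_amplitude_px > 0) {
        ph <- stats::runif(2, 0, 2 * pi)
        g1 <- matrix(rep(seq_len(pd[1]), pd[2]), pd[1])
        g2 <- matrix(rep(seq_len(pd[2]), each = pd[1]), pd[1])
        lam <- 24
        w1 <- warp_amplitude_px / sqrt(2) * sin(2 * pi * g2 / lam + ph[1])
        w2 <- warp_amplitude_px / sqrt(2) * sin(2 * pi * g1 / lam + ph[2])
        f1 <- as.vector(g1 - 1 + w1)
        f2 <- as.vector(g2 - 1 + w2)
        img <- matrix(sample_frac(array(img, c(pd, 1L)), f1, f2,
                                  rep(0, length(f1))), pd[1], pd[2])
        warp <- list(w1 = w1, w2 = w2)
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), pd[1])
      list(image = img, plane_axis = ax, plane_index = s,
           source_id = source_id, warp = warp,
           pixel_um = volume$meta$voxel_size[inplane])
    })
  })
}

#' Truncate a volume by zeroing slabs at one end of an axis
#'
#' @param volume a volume object.
#' @param axis axis index (default rostro-caudal).
#' @param fraction fraction of planes to remove (0..1).
#' @param end `"rostral"` (low index) or `"caudal"` (high index).
#' @return list with `volume` (truncated) and `record` (plane indices and the
#'   removed slab data; [restore_truncation()] undoes the cut exactly).
#' @export
truncate_volume <- function(volume, axis = NULL, fraction = 0.2,
                            end = c("rostral", "caudal")) {
  end <- match.arg(end)
  ax <- axis %||% role_axis(volume$meta, "rc")
  d <- vol_dim(volume)
  k <- floor(d[ax] * fraction)
  if (k == 0L) return(list(volume = volume, record = list(axis = ax, planes = integer(0))))
  planes <- if (end == "rostral") seq_len(k) else seq(d[ax] - k + 1L, d[ax])
  idx <- lapply(d, seq_len)
  idx[[ax]] <- planes
  slab <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  arr <- volume$data
  arr[idx[[1]], idx[[2]], idx[[3]]] <- if (is_labeled(volume)) 0L else 0
  list(volume = vol_like(volume, arr),
       record = list(axis = ax, planes = planes, slab = slab))
}

#' Undo a [truncate_volume()] cut exactly
#' @param volume truncated volume.
#' @param record the `record` element returned by [truncate_volume()].
#' @export
restore_truncation <- function(volume, record) {
  if (length(record$planes) == 0L) return(volume)
  d <- vol_dim(volume)
  idx <- lapply(d, seq_len)
  idx[[record$axis]] <- record$planes
  arr <- volume$data
  arr[idx[[1]], idx[[2]], idx[[3]]] <- record$slab
  vol_like(volume, arr)
}

#' Inject isolated stray voxels into an annotation (recorded ground truth for
#' border cleanup)
#'
#' Voxels are placed where the annotation and its 26-neighborhood (dilated
#' twice) are empty, so each injected voxel is its own connected component.
#'
#' @param ann a [labeled_volume()].
#' @param k number of voxels to inject.
#' @param label label id to use.
#' @param seed integer seed.
#' @return list `volume`, `positions` (k x 3 index matrix).
#' @export
inject_stray_voxels <- function(ann, k, label = 3001L, seed = 1L) {
  occ <- ann$data != 0L
  dil <- occ
  for (pass in 1:2) {
    offs <- neighbor_offsets(26L)
    acc <- dil
    for (r in seq_len(nrow(offs)))
      acc <- acc | shift_arr(dil, offs[r, ], FALSE)
    dil <- acc
  }
  free <- which(!dil)
  if (length(free) < k) af_stop("not enough free space for %d stray voxels", k)
  with_seed(seed, {
    pick <- sample(free, k)
    arr <- ann$data
    arr[pick] <- as.integer(label)
    list(volume = labeled_volume(arr, ann$meta),
         positions = arrayInd(pick, vol_dim(ann)))
  })
}

#' Inject hemisphere-asymmetric voxels (recorded ground truth for
#' symmetrization)
#'
#' Picks `n` empty voxels on the chosen hemisphere whose mirror voxel is also
#' empty, so the injected voxels are exactly the asymmetric set.
#'
#' @param ann a [labeled_volume()].
#' @param n number of asymmetric voxels (the real-data motivation is a small
#'   region present in one hemisphere only).
#' @param side `"left"` (low lr index) or `"right"`.
#' @param label label id.
#' @param seed integer seed.
#' @return list `volume`, `n`.
#' @export
inject_asymmetric_voxels <- function(ann, n = 433L, side = c("left", "right"),
                                     label = 3005L, seed = 1L) {
  side <- match.arg(side)
  ax <- role_axis(ann$meta, "lr")
  d <- vol_dim(ann)
  nax <- d[ax]
  idx <- arrayInd(seq_len(prod(d)), d)
  half <- if (side == "left") idx[, ax] <= nax %/% 2 else idx[, ax] > nax - nax %/% 2
  mirr <- idx
  mirr[, ax] <- nax + 1L - idx[, ax]
  lin_m <- (mirr[, 3] - 1L) * d[1] * d[2] + (mirr[, 2] - 1L) * d[1] + mirr[, 1]
  empty <- as.vector(ann$data == 0L)
  cand <- which(half & empty & empty[lin_m])
  if (length(cand) < n) af_stop("not enough empty voxels for the asymmetry")
  with_seed(seed, {
    pick <- sample(cand, n)
    arr <- ann$data
    arr[pick] <- as.integer(label)
    list(volume = labeled_volume(arr, ann$meta), n = n)
  })
}
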