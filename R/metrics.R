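# Evaluation metrics: normalized mutual information, target registration
# error, Dice overlap, multi-scale NMI reports, and per-region voxel / mm^3
# accounting. Entropies use base-2 logarithms internally (NMI is invariant to
# the base).

#' Joint intensity histogram of two images
#'
#' @param A,B [intensity_volume()]s on the same grid.
#' @param bins number of bins per image (>= 2); each image is min-max scaled
#'   over the mask.
#' @param mask logical array of voxels to include; default: voxels where
#'   either image is non-background.
#' @return object of class `joint_histogram`: `counts` (bins x bins),
#'   `edges_a`, `edges_b`, `total`.
#' @export
joint_histogram <- function(A, B, bins = 64L, mask = NULL) {
  a <- if (inherits(A, "af_volume")) A$data else A
  b <- if (inherits(B, "af_volume")) B$data else B
  if (!identical(dim(a), dim(b))) af_stop("images must share a grid")
  mask <- mask %||% (a != 0 | b != 0)
  if (!any(mask)) af_stop("empty mask in joint_histogram")
  av <- a[mask]; bv <- b[mask]
  bins <- as.integer(bins)
  if (bins < 2L) af_stop("bins must be >= 2")
  bin_of <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(list(idx = rep(1L, length(v)), edges = c(r[1], r[1])))
    e <- seq(r[1], r[2], length.out = bins + 1L)
    idx <- pmin(pmax(findInterval(v, e, rightmost.closed = TRUE), 1L), bins)
    list(idx = idx, edges = e)
  }
  ba <- bin_of(av); bb <- bin_of(bv)
  counts <- matrix(tabulate((ba$idx - 1L) * bins + bb$idx, nbins = bins * bins),
                   nrow = bins, ncol = bins)
  # counts[j, i]: row = B bin, col = A bin; transpose to A-major for clarity
  counts <- t(counts)
  structure(list(counts = counts, edges_a = ba$edges, edges_b = bb$edges,
                 total = sum(counts)),
            class = "joint_histogram")
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @noRd
nmi_arrays <- function(a, b, bins = 64L, mask = NULL) {
  jh <- joint_histogram(a, b, bins = bins, mask = mask)
  pj <- jh$counts / jh$total
  pa <- rowSums(pj); pb <- colSums(pj)
  ha <- entropy_bits(pa); hb <- entropy_bits(pb)
  if (ha == 0 || hb == 0)
    af_stop("NMI undefined for a constant image over the mask")
  hab <- entropy_bits(as.vector(pj))
  mi <- ha + hb - hab
  2 * mi / (ha + hb)
}

#' Normalized mutual information
#'
#' `NMI(A,B) = 2 I(A;B) / (H(A) + H(B))`, in `[0, 1]`: 1 for identical
#' (non-constant) images, 0 for independent ones.
#'
#' @param A,B [intensity_volume()]s (or bare arrays) on the same grid.
#' @param bins histogram bins per image.
#' @param mask one of `"either"` (default; union of non-background supports),
#'   `"both"`, `"all"`, or a logical array.
#' @return NMI score.
#' @export
nmi <- function(A, B, bins = 64L, mask = "either") {
  a <- if (inherits(A, "af_volume")) A$data else A
  b <- if (inherits(B, "af_volume")) B$data else B
  m <- if (is.character(mask)) {
    switch(mask,
           either = a != 0 | b != 0,
           both = a != 0 & b != 0,
           all = array(TRUE, dim(a)),
           af_stop("unknown mask policy '%s'", mask))
  } else mask
  nmi_arrays(a, b, bins = bins, mask = m)
}

#' Target registration error of fiducial point pairs
#'
#' Euclidean distance (um) between each reference point and its estimated
#' position, with mean/median summaries per region group and per operator.
#'
#' @param points a fiducial set (see [as_fiducials()]).
#' @return list with `points` (the table plus a `tre_um` column),
#'   `by_group`, `by_operator`, and `mean`/`median` overall.
#' @export
tre <- function(points) {
  points <- as_fiducials(as.data.frame(points))
  d <- sqrt((points$x_ref - points$x_reg)^2 +
            (points$y_ref - points$y_reg)^2 +
            (points$z_ref - points$z_reg)^2)
  points$tre_um <- d
  agg <- function(key) {
    s <- split(d, points[[key]])
    data.frame(group = names(s),
               n = vapply(s, length, 1L),
               mean_um = vapply(s, mean, 1),
               median_um = vapply(s, stats::median, 1),
               row.names = NULL)
  }
  list(points = points, by_group = agg("group"), by_operator = agg("operator"),
       mean = mean(d), median = stats::median(d))
}

#' Dice overlap between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)` with exact integer voxel counts.
#'
#' @param A,B logical arrays (or volumes whose non-background voxels define
#'   the masks).
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(A, B) {
  a <- if (inherits(A, "af_volume")) A$data != 0 else as.logical(A)
  b <- if (inherits(B, "af_volume")) B$data != 0 else as.logical(B)
  if (!identical(dim(a), dim(b))) af_stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) af_stop("Dice undefined for two empty masks")
  2 * sum(a & b) / (na + nb)
}

#' Per-region NMI table
#'
#' @param A,B [intensity_volume()]s on the same grid.
#' @param ann [labeled_volume()] defining the regions (on the same grid).
#' @param graph a `structure_graph`.
#' @param region_ids region ids to score (descendant-aggregated masks).
#' @param bins histogram bins.
#' @param min_voxels regions with fewer mask voxels are flagged, not scored.
#' @return data.frame with columns `id`, `acronym`, `voxels`, `nmi`,
#'   `flagged`.
#' @export
per_region_nmi <- function(A, B, ann, graph, region_ids, bins = 64L,
                           min_voxels = 50L) {
  rows <- lapply(region_ids, function(id) {
    m <- region_mask(ann, graph, id, include_descendants = TRUE)
    nv <- sum(m)
    val <- NA_real_
    flag <- nv < min_voxels
    if (!flag) {
      val <- tryCatch(nmi(A, B, bins = bins, mask = m), error = function(e) NA_real_)
      flag <- is.na(val)
    }
    data.frame(id = id, acronym = graph$nodes[[as.character(id)]]$acronym,
               voxels = nv, nmi = val, flagged = flag)
  })
  do.call(rbind, rows)
}

#' Per-slice NMI series along one incidence
#'
#' @param A,B [intensity_volume()]s on the same grid.
#' @param incidence `"coronal"` (slices across the rostro-caudal axis),
#'   `"sagittal"` (left-right) or `"horizontal"` (dorso-ventral).
#' @param bins histogram bins.
#' @param min_voxels near-empty planes (fewer foreground voxels) are flagged
#'   and not scored.
#' @return data.frame with `slice`, `nmi`, `flagged`.
#' @export
per_slice_nmi <- function(A, B, incidence = c("coronal", "sagittal", "horizontal"),
                          bins = 64L, min_voxels = 50L) {
  incidence <- match.arg(incidence)
  role <- switch(incidence, coronal = "rc", sagittal = "lr", horizontal = "dv")
  ax <- role_axis(A$meta, role)
  d <- vol_dim(A)
  idx <- lapply(d, seq_len)
  rows <- lapply(seq_len(d[ax]), function(s) {
    ix <- idx; ix[[ax]] <- s
    a <- A$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    b <- B$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    fg <- a != 0 | b != 0
    if (sum(fg) < min_voxels)
      return(data.frame(slice = s, nmi = NA_real_, flagged = TRUE))
    val <- tryCatch(nmi_arrays(a, b, bins = bins, mask = fg),
                    error = function(e) NA_real_)
    data.frame(slice = s, nmi = val, flagged = is.na(val))
  })
  do.call(rbind, rows)
}

#' Convert a voxel count to cubic millimetres
#'
#' @param voxels voxel count.
#' @param voxel_um isotropic voxel size in micrometres.
#' @return volume in mm^3 (`voxels * (voxel_um / 1000)^3`).
#' @export
voxels_to_mm3 <- function(voxels, voxel_um = 25) {
  voxels * (voxel_um / 1000)^3
}

#' Relative increase between two volumes, in percent
#' @param before,after volumes (any common unit).
#' @export
relative_increase_pct <- function(before, after) {
  100 * (after - before) / before
}

#' Per-region added/modified voxel accounting
#'
#' Builds the accounting table from voxel counts: `total = added + modified`
#' per region, mm^3 columns from the voxel size, plus a TOTAL row summing all
#' listed regions.
#'
#' @param added,modified named integer vectors of voxel counts (same names).
#' @param voxel_um isotropic voxel size (um).
#' @return data.frame of class `region_volume_report` with columns `region`,
#'   `added_voxels`, `modified_voxels`, `total_voxels`, `added_mm3`,
#'   `modified_mm3`, `total_mm3`.
#' @export
region_volume_report <- function(added, modified, voxel_um = 25) {
  stopifnot(length(added) == length(modified))
  regions <- names(added) %||% as.character(seq_along(added))
  added <- c(added, TOTAL = sum(added))
  modified <- c(modified, TOTAL = sum(modified))
  regions <- c(regions, "TOTAL")
  df <- data.frame(region = regions,
                   added_voxels = as.numeric(added),
                   modified_voxels = as.numeric(modified),
                   total_voxels = as.numeric(added) + as.numeric(modified),
                   row.names = NULL)
  df$added_mm3 <- voxels_to_mm3(df$added_voxels, voxel_um)
  df$modified_mm3 <- voxels_to_mm3(df$modified_voxels, voxel_um)
  df$total_mm3 <- voxels_to_mm3(df$total_voxels, voxel_um)
  attr(df, "voxel_um") <- voxel_um
  class(df) <- c("region_volume_report", "data.frame")
  df
}

#' Compare two annotation versions voxel by voxel
#'
#' An *added* voxel was background before and labeled after; a *modified*
#' voxel was labeled before but carries a different label after. Counts are
#' attributed to the listed regions by the after-label (descendant
#' aggregated).
#'
#' @param annBefore,annAfter [labeled_volume()]s on the same grid.
#' @param graph a `structure_graph`.
#' @param region_ids region ids to break out (e.g. the major divisions).
#' @return a [region_volume_report()]; the TOTAL row counts every added or
#'   modified voxel in the volume, not only those under `region_ids`.
#' @export
volume_report <- function(annBefore, annAfter, graph, region_ids) {
  if (!identical(vol_dim(annBefore), vol_dim(annAfter)))
    af_stop("annotation grids differ")
  before <- annBefore$data
  after <- annAfter$data
  added_all <- before == 0L & after != 0L
  modified_all <- before != 0L & after != 0L & before != after
  added <- integer(length(region_ids))
  modified <- integer(length(region_ids))
  nm <- character(length(region_ids))
  for (i in seq_along(region_ids)) {
    ids <- c(region_ids[i], descendants(graph, region_ids[i]))
    in_region <- array(after %in% ids, dim(after))
    added[i] <- sum(added_all & in_region)
    modified[i] <- sum(modified_all & in_region)
    nm[i] <- graph$nodes[[as.character(region_ids[i])]]$acronym
  }
  names(added) <- nm
  names(modified) <- nm
  rep_ <- region_volume_report(added, modified, annAfter$meta$voxel_size[1])
  rep_$added_voxels[rep_$region == "TOTAL"] <- sum(added_all)
  rep_$modified_voxels[rep_$region == "TOTAL"] <- sum(modified_all)
  rep_$total_voxels[rep_$region == "TOTAL"] <- sum(added_all) + sum(modified_all)
  vu <- annAfter$meta$voxel_size[1]
  tot <- rep_$region == "TOTAL"
  rep_$added_mm3[tot] <- voxels_to_mm3(rep_$added_voxels[tot], vu)
  rep_$modified_mm3[tot] <- voxels_to_mm3(rep_$modified_voxels[tot], vu)
  rep_$total_mm3[tot] <- voxels_to_mm3(rep_$total_voxels[tot], vu)
  rep_
}

#' @export
print.region_volume_report <- function(x, ...) {
  cat(sprintf("region_volume_report (voxel %g um):\n", attr(x, "voxel_um")))
  df <- as.data.frame(x)
  df$added_mm3 <- round(df$added_mm3, 4)
  df$modified_mm3 <- round(df$modified_mm3, 4)
  df$total_mm3 <- round(df$total_mm3, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
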