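# Grid metadata and the two volume classes used throughout the toolkit.
#
# Conventions: voxel indices are 0-based in all world-coordinate arithmetic;
# the world position of voxel index i is origin + i * voxel_size (voxel-center
# convention). All physical lengths are micrometres.

#' Physical grid metadata
#'
#' Describes the physical embedding of a voxel grid: voxel size in micrometres
#' per axis, the world position of voxel index 0 (`origin`, micrometres), and
#' which array axis plays which anatomical role.
#'
#' @param voxel_size numeric length 1 or 3, micrometres per voxel (> 0).
#' @param origin numeric length 3, world position (um) of voxel (0,0,0).
#' @param axis_roles character length 3, a permutation of `"lr"`
#'   (left-right), `"rc"` (rostro-caudal), `"dv"` (dorso-ventral), giving the
#'   role of each array axis.
#' @return an object of class `grid_meta`.
#' @export
grid_meta <- function(voxel_size = 25, origin = c(0, 0, 0),
                      axis_roles = c("lr", "rc", "dv")) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    af_stop("voxel_size must be positive and finite")
  if (length(origin) != 3L || any(!is.finite(origin)))
    af_stop("origin must be 3 finite numbers")
  if (!setequal(axis_roles, c("lr", "rc", "dv")) || length(axis_roles) != 3L)
    af_stop("axis_roles must be a permutation of lr, rc, dv")
  structure(list(voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 axis_roles = axis_roles),
            class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("grid_meta: voxel %s um, origin (%s) um, roles %s\n",
              paste(x$voxel_size, collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              paste(x$axis_roles, collapse = ",")))
  invisible(x)
}

#' Which array axis carries a given anatomical role
#' @param meta a [grid_meta()].
#' @param role one of `"lr"`, `"rc"`, `"dv"`.
#' @return integer axis index (1..3).
#' @export
role_axis <- function(meta, role) {
  ax <- match(role, meta$axis_roles)
  if (is.na(ax)) af_stop("unknown axis role '%s'", role)
  ax
}

#' Scalar intensity volume
#'
#' @param values 3D numeric array of finite intensities.
#' @param meta a [grid_meta()].
#' @return object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, meta = grid_meta()) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) af_stop("values must be a 3D array")
  values <- array(as.numeric(values), dim(values))
  if (any(!is.finite(values))) af_stop("intensity values must be finite")
  structure(list(data = values, meta = meta),
            class = c("intensity_volume", "af_volume"))
}

#' Integer-labeled annotation volume
#'
#' Voxel values are non-negative integer structure ids; 0 is reserved for
#' unlabeled background.
#'
#' @param labels 3D array of non-negative integers.
#' @param meta a [grid_meta()].
#' @return object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, meta = grid_meta()) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) af_stop("labels must be a 3D array")
  labels <- array(as.vector(labels), dim(labels))
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    af_stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(data = labels, meta = meta),
            class = c("labeled_volume", "af_volume"))
}

#' @export
print.af_volume <- function(x, ...) {
  kind <- if (inherits(x, "labeled_volume")) "labeled_volume" else "intensity_volume"
  d <- dim(x$data)
  cat(sprintf("%s %dx%dx%d, voxel %s um\n", kind, d[1], d[2], d[3],
              paste(x$meta$voxel_size, collapse = "x")))
  if (kind == "labeled_volume") {
    labs <- setdiff(sort(unique(as.vector(x$data))), 0L)
    cat(sprintf("  %d labels, %d labeled voxels\n",
                length(labs), sum(x$data != 0L)))
  } else {
    cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Grid dimensions of a volume
#' @param vol a volume object.
#' @export
vol_dim <- function(vol) dim(vol$data)

is_labeled <- function(vol) inherits(vol, "labeled_volume")

#' Rebuild a volume of the same class around new data
#' @noRd
vol_like <- function(vol, data, meta = vol$meta) {
  if (is_labeled(vol)) labeled_volume(data, meta) else intensity_volume(data, meta)
}

#' World coordinates (um) of every voxel of a grid
#'
#' Returns the voxel-center positions in array storage order (first axis
#' fastest), as an N x 3 matrix in micrometres.
#' @param meta a [grid_meta()].
#' @param d integer grid dimensions.
#' @export
grid_points <- function(meta, d) {
  vs <- meta$voxel_size
  o <- meta$origin
  i1 <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(o[1] + i1 * vs[1], o[2] + i2 * vs[2], o[3] + i3 * vs[3])
}

#' Sample a 3D array at world points
#'
#' @param arr 3D array.
#' @param meta grid of `arr`.
#' @param pts N x 3 matrix of world coordinates (um).
#' @param interpolation "linear" or "nearest".
#' @param background value returned outside the grid domain.
#' @param clamp if TRUE, out-of-domain points take the edge value instead of
#'   `background` (used for field resampling).
#' @return numeric vector length N.
#' @noRd
sample_array <- function(arr, meta, pts, interpolation = "linear",
                         background = 0, clamp = FALSE) {
  sample_frac(arr,
              (pts[, 1] - meta$origin[1]) / meta$voxel_size[1],
              (pts[, 2] - meta$origin[2]) / meta$voxel_size[2],
              (pts[, 3] - meta$origin[3]) / meta$voxel_size[3],
              interpolation = interpolation, background = background,
              clamp = clamp)
}

#' Sample a 3D array at fractional 0-based voxel indices
#' @noRd
sample_frac <- function(arr, f1, f2, f3, interpolation = "linear",
                        background = 0, clamp = FALSE) {
  d <- dim(arr)
  eps <- 1e-6
  inside <- if (clamp) rep(TRUE, length(f1)) else
    f1 >= -eps & f1 <= d[1] - 1 + eps &
    f2 >= -eps & f2 <= d[2] - 1 + eps &
    f3 >= -eps & f3 <= d[3] - 1 + eps
  out <- rep(background, length(f1))
  if (!any(inside)) return(out)
  f1 <- pmin(pmax(f1[inside], 0), d[1] - 1)
  f2 <- pmin(pmax(f2[inside], 0), d[2] - 1)
  f3 <- pmin(pmax(f3[inside], 0), d[3] - 1)
  if (interpolation == "nearest") {
    v <- arr[cbind(round(f1) + 1L, round(f2) + 1L, round(f3) + 1L)]
  } else {
    i1 <- if (d[1] > 1) pmin(floor(f1), d[1] - 2) else 0
    i2 <- if (d[2] > 1) pmin(floor(f2), d[2] - 2) else 0
    i3 <- if (d[3] > 1) pmin(floor(f3), d[3] - 2) else 0
    w1 <- f1 - i1; w2 <- f2 - i2; w3 <- f3 - i3
    v <- 0
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      if (d[1] == 1 && c1 == 1) next
      if (d[2] == 1 && c2 == 1) next
      if (d[3] == 1 && c3 == 1) next
      w <- (if (c1 == 1) w1 else 1 - w1) *
           (if (c2 == 1) w2 else 1 - w2) *
           (if (c3 == 1) w3 else 1 - w3)
      v <- v + w * arr[cbind(i1 + c1 + 1L, i2 + c2 + 1L, i3 + c3 + 1L)]
    }
  }
  out[inside] <- v
  out
}
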