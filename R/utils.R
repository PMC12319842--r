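# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a fixed RNG state, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

af_stop <- function(...) stop(sprintf(...), call. = FALSE)
af_warn <- function(...) warning(sprintf(...), call. = FALSE)

#' Bounding box of TRUE voxels, as a 3x2 matrix of 1-based index ranges
#' @noRd
mask_bbox <- function(mask, margin = 0L) {
  d <- dim(mask)
  w <- which(mask)
  if (length(w) == 0L) return(NULL)
  i <- arrayInd(w, d)
  lo <- pmax(apply(i, 2, min) - margin, 1L)
  hi <- pmin(apply(i, 2, max) + margin, d)
  cbind(lo, hi)
}

crop_array <- function(arr, bbox) {
  arr[bbox[1, 1]:bbox[1, 2], bbox[2, 1]:bbox[2, 2], bbox[3, 1]:bbox[3, 2], drop = FALSE]
}

#' Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
#' Edge handling replicates the border (row-normalized truncated kernel).
#' @noRd
smooth3d <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    K <- gauss_band(d[ax], sigma_vox[ax])
    if (is.null(K)) next
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(arr, perm)
    dim(x) <- c(d[ax], prod(d[-ax]))
    x <- K %*% x
    dim(x) <- d[perm]
    arr <- aperm(x, order(perm))
  }
  arr
}

gauss_band <- function(n, sigma) {
  if (n <= 1L || sigma <= 0) return(NULL)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in seq(-r, r)) {
    j <- pmin(pmax(idx + o, 1L), n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + k[o + r + 1L]
  }
  K
}

#' Central-difference gradient along one axis, in per-voxel units
#' @noRd
grad_axis <- function(arr, ax) {
  d <- dim(arr)
  n <- d[ax]
  if (n == 1L) return(array(0, d))
  perm <- c(ax, setdiff(1:3, ax))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-ax]))
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  g <- (x[ip, , drop = FALSE] - x[im, , drop = FALSE]) / (ip - im)
  dim(g) <- d[perm]
  aperm(g, order(perm))
}

#' Block-aggregate a 3D array by integer factors; fun is "mean" or "majority".
#' Pads with `fill` when the factor does not divide the extent.
#' @noRd
block_reduce <- function(arr, factor, fun = c("mean", "majority"), fill = 0) {
  fun <- match.arg(fun)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  factor <- as.integer(factor)
  if (any(factor < 1L)) af_stop("block factor must be >= 1")
  d <- dim(arr)
  factor <- pmin(factor, d)  # singleton axes are never padded away
  dpad <- as.integer(ceiling(d / factor) * factor)
  if (any(dpad != d)) {
    out <- array(fill, dpad)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- out
  }
  dn <- dpad %/% factor
  # gather the factor^3 block offsets into columns of a matrix
  nb <- prod(factor)
  m <- matrix(0, prod(dn), nb)
  col <- 1L
  for (k in seq_len(factor[3])) for (j in seq_len(factor[2])) for (i in seq_len(factor[1])) {
    sub <- arr[seq(i, dpad[1], by = factor[1]),
               seq(j, dpad[2], by = factor[2]),
               seq(k, dpad[3], by = factor[3]), drop = FALSE]
    m[, col] <- as.vector(sub)
    col <- col + 1L
  }
  if (fun == "mean") {
    v <- rowMeans(m)
  } else {
    labs <- sort(unique(as.vector(m)))
    counts <- matrix(0L, nrow(m), length(labs))
    for (li in seq_along(labs)) counts[, li] <- rowSums(m == labs[li])
    # ties break toward the smallest label id (labs sorted ascending,
    # max.col "first" picks the lowest index among ties)
    v <- labs[max.col(counts, ties.method = "first")]
  }
  array(v, dn)
}
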