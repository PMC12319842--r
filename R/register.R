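# Registration engine: world-coordinate affine transforms, dense deformation
# fields, and a multi-resolution demons-style nonlinear aligner with a
# monotone accept/reject iteration. Transforms follow the resampling
# convention: they map fixed-space points into moving-space points.

#' Affine spatial transform (world coordinates, um)
#'
#' Maps a fixed-space point p to the moving-space point `matrix %*% p +
#' translation`.
#'
#' @param matrix invertible 3x3 linear part.
#' @param translation length-3 translation (um).
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3, 3)) || abs(det(matrix)) < 1e-12)
    af_stop("affine matrix must be 3x3 and invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform (fixed -> moving, um):\n")
  print(cbind(x$matrix, t = x$translation))
  invisible(x)
}

#' Dense deformation field on a fixed grid
#'
#' `disp` holds per-voxel displacement vectors in micrometres; the transform
#' maps a fixed-space point p to p + disp(p), with disp interpolated
#' linearly (edge-clamped) between voxel centers.
#'
#' @param disp 4D array `dim x 3` of displacements (um).
#' @param meta the fixed-grid [grid_meta()].
#' @export
deformation_field <- function(disp, meta) {
  disp <- as.array(disp)
  if (length(dim(disp)) != 4L || dim(disp)[4] != 3L)
    af_stop("disp must be a dim x 3 array")
  if (any(!is.finite(disp))) af_stop("displacements must be finite")
  structure(list(disp = disp, meta = meta), class = "deformation_field")
}

# component c of a field as a 3D array (4D slicing would drop singleton axes)
field_comp <- function(field, c3) {
  d <- dim(field$disp)[1:3]
  array(field$disp[, , , c3], d)
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$disp)
  mag <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat(sprintf("deformation_field %dx%dx%d, |u| max %.2f um, mean %.2f um\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
  invisible(x)
}

#' Chain of transforms applied in list order (first element first)
#' @param ... transforms (affine, field, chain, or NULL for identity).
#' @export
transform_chain <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  flat <- list()
  for (p in parts) {
    if (inherits(p, "transform_chain")) flat <- c(flat, p$parts)
    else flat <- c(flat, list(p))
  }
  structure(list(parts = flat), class = "transform_chain")
}

#' Map fixed-space points through a transform
#'
#' @param tr an affine, deformation field, transform chain, or NULL
#'   (identity).
#' @param pts N x 3 matrix of world coordinates (um).
#' @return N x 3 matrix of moving-space coordinates.
#' @export
transform_points <- function(tr, pts) {
  if (is.null(tr)) return(pts)
  if (inherits(tr, "affine_transform")) {
    return(sweep(pts %*% t(tr$matrix), 2, tr$translation, `+`))
  }
  if (inherits(tr, "deformation_field")) {
    out <- pts
    for (c3 in 1:3)
      out[, c3] <- pts[, c3] + sample_array(field_comp(tr, c3), tr$meta, pts,
                                            interpolation = "linear", clamp = TRUE)
    return(out)
  }
  if (inherits(tr, "transform_chain")) {
    for (p in tr$parts) pts <- transform_points(p, pts)
    return(pts)
  }
  af_stop("unknown transform type")
}

#' Compose two transforms
#'
#' `transform_points(compose(outer, inner), p)` equals
#' `transform_points(outer, transform_points(inner, p))`. Two affines compose
#' exactly; any other combination yields a transform chain.
#'
#' @param outer,inner transforms.
#' @export
compose <- function(outer, inner) {
  if (is.null(inner)) return(outer)
  if (is.null(outer)) return(inner)
  if (inherits(outer, "affine_transform") && inherits(inner, "affine_transform")) {
    return(affine_transform(outer$matrix %*% inner$matrix,
                            as.numeric(outer$matrix %*% inner$translation) +
                              outer$translation))
  }
  transform_chain(inner, outer)
}

#' Invert an affine transform
#' @param tr an `affine_transform`.
#' @export
invert_affine <- function(tr) {
  Mi <- solve(tr$matrix)
  affine_transform(Mi, -as.numeric(Mi %*% tr$translation))
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration `v(p) <- -u(p + v(p))`; adequate for the smooth,
#' small-amplitude fields produced by the demons engine.
#'
#' @param field a `deformation_field`.
#' @param iterations fixed-point iterations.
#' @return a `deformation_field` approximating the inverse mapping.
#' @export
invert_field <- function(field, iterations = 25L) {
  d <- dim(field$disp)[1:3]
  pts <- grid_points(field$meta, d)
  v <- matrix(0, nrow(pts), 3)
  for (it in seq_len(iterations)) {
    q <- pts + v
    for (c3 in 1:3)
      v[, c3] <- -sample_array(field_comp(field, c3), field$meta, q,
                               interpolation = "linear", clamp = TRUE)
  }
  deformation_field(array(v, c(d, 3L)), field$meta)
}

#' Invert any transform
#' @param tr affine, field or chain.
#' @export
invert_transform <- function(tr) {
  if (is.null(tr)) return(NULL)
  if (inherits(tr, "affine_transform")) return(invert_affine(tr))
  if (inherits(tr, "deformation_field")) return(invert_field(tr))
  if (inherits(tr, "transform_chain"))
    return(do.call(transform_chain, lapply(rev(tr$parts), invert_transform)))
  af_stop("unknown transform type")
}

#' Realize any transform as a deformation field on a given grid
#' @param tr a transform.
#' @param meta target [grid_meta()].
#' @param dims target grid dimensions.
#' @export
as_deformation_field <- function(tr, meta, dims) {
  pts <- grid_points(meta, dims)
  q <- transform_points(tr, pts)
  deformation_field(array(q - pts, c(dims, 3L)), meta)
}

#' Resample a volume through a transform
#'
#' @param vol volume to resample (the moving image).
#' @param transform transform mapping output-grid points into `vol` space
#'   (NULL = identity).
#' @param interpolation `"linear"` or `"nearest"`; labeled volumes require
#'   `"nearest"`.
#' @param out_grid output [grid_meta()]; defaults to the grid of `vol`.
#' @param out_dim output dimensions; defaults to `dim(vol$data)`.
#' @return resampled volume on the output grid; out-of-domain voxels are
#'   background.
#' @export
apply_transform <- function(vol, transform = NULL,
                            interpolation = c("linear", "nearest"),
                            out_grid = NULL, out_dim = NULL) {
  interpolation <- match.arg(interpolation)
  if (is_labeled(vol) && interpolation == "linear")
    af_stop("linear interpolation on a labeled volume is refused; use nearest")
  out_grid <- out_grid %||% vol$meta
  out_dim <- as.integer(out_dim %||% vol_dim(vol))
  pts <- grid_points(out_grid, out_dim)
  q <- transform_points(transform, pts)
  v <- sample_array(vol$data, vol$meta, q, interpolation = interpolation,
                    background = 0)
  arr <- array(v, out_dim)
  if (is_labeled(vol)) storage.mode(arr) <- "integer"
  vol_like(vol, arr, out_grid)
}

#' Registration parameters
#'
#' @param levels integer downsampling factors, coarse to fine.
#' @param iterations iteration budget per level (recycled).
#' @param metric `"ssd"`, `"nmi"` or `"lcc"` (local correlation).
#' @param sigma_fluid_um Gaussian sigma (um) smoothing each demons update;
#'   NULL = one fixed-grid voxel.
#' @param sigma_field_um Gaussian sigma (um) smoothing the accumulated field;
#'   NULL = one fixed-grid voxel.
#' @param step_size demons step scaling.
#' @param bins histogram bins for the NMI metric (>= 8).
#' @param aggressive halves the smoothing sigmas, doubles iterations and
#'   switches forces to local correlation (fine-scale matching).
#' @param translation_search half-width (in coarse voxels) of the exhaustive
#'   translation search that seeds the affine optimizer; 0 disables.
#' @export
registration_params <- function(levels = c(4, 2, 1),
                                iterations = c(100, 50, 20),
                                metric = c("ssd", "nmi", "lcc"),
                                sigma_fluid_um = NULL,
                                sigma_field_um = NULL,
                                step_size = 2,
                                bins = 64L,
                                aggressive = FALSE,
                                translation_search = 4L) {
  metric <- match.arg(metric)
  if (bins < 8L) af_stop("bins must be >= 8")
  if (any(diff(levels) > 0)) af_stop("levels must go coarse to fine")
  iterations <- rep_len(iterations, length(levels))
  if (aggressive) iterations <- iterations * 2L
  structure(list(levels = as.integer(levels), iterations = as.integer(iterations),
                 metric = metric, sigma_fluid_um = sigma_fluid_um,
                 sigma_field_um = sigma_field_um, step_size = step_size,
                 bins = as.integer(bins), aggressive = isTRUE(aggressive),
                 translation_search = as.integer(translation_search)),
            class = "registration_params")
}

# --- internal engine ---------------------------------------------------------

# Channels: registration internally works on lists of arrays sharing one grid,
# so label registration can drive multiple blurred indicator images at once.

#' Prepare force/metric images for a channel list
#' @noRd
reg_normalize <- function(mov, fix, metric) {
  if (metric == "nmi") {
    # rank-normalize each image separately over its foreground: makes
    # monotone (and most smooth non-monotone) intensity relations
    # quasi-monomodal for the demons forces
    rk <- function(a) {
      fg <- a != 0
      out <- array(0, dim(a))
      if (any(fg)) out[fg] <- rank(a[fg], ties.method = "average") / sum(fg)
      out
    }
    list(mov = lapply(mov, rk), fix = lapply(fix, rk))
  } else if (metric == "lcc") {
    ln <- function(a) {
      mu <- smooth3d(a, 2)
      sd <- sqrt(pmax(smooth3d(a * a, 2) - mu^2, 0))
      (a - mu) / (sd + 1e-3 * max(sd))
    }
    list(mov = lapply(mov, ln), fix = lapply(fix, ln))
  } else {
    lo <- min(vapply(c(mov, fix), min, 0))
    hi <- max(vapply(c(mov, fix), max, 0))
    s <- if (hi > lo) 1 / (hi - lo) else 1
    list(mov = lapply(mov, function(a) (a - lo) * s),
         fix = lapply(fix, function(a) (a - lo) * s))
  }
}

#' Similarity score (higher is better) between warped-moving and fixed
#' channel lists; background-in-both voxels are excluded.
#' @noRd
reg_score <- function(warped, fix, metric, bins, mask = NULL) {
  if (metric == "nmi") {
    fg <- warped[[1]] != 0 | fix[[1]] != 0
    if (!is.null(mask)) fg <- fg & mask
    return(nmi_arrays(warped[[1]], fix[[1]], bins = bins, mask = fg))
  }
  s <- 0
  for (ci in seq_along(fix)) {
    fg <- warped[[ci]] != 0 | fix[[ci]] != 0
    if (!is.null(mask)) fg <- fg & mask
    if (!any(fg)) next
    s <- s - mean((warped[[ci]][fg] - fix[[ci]][fg])^2)
  }
  s
}

#' One demons pyramid level; field in um on the level grid
#' @noRd
demons_level <- function(mov, fix, meta, disp, iters, sigma_fluid_vox,
                         sigma_field_vox, step, metric, bins, force_imgs,
                         mask = NULL) {
  d <- dim(fix[[1]])
  vs <- meta$voxel_size
  i1 <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  gfix <- lapply(force_imgs$fix, function(a) list(grad_axis(a, 1), grad_axis(a, 2), grad_axis(a, 3)))
  # displacement components kept as a list of 3D arrays (robust to
  # singleton axes, which 4D slicing would drop)
  u_list <- lapply(1:3, function(c3) array(disp[, , , c3], d))
  warp_channels <- function(chans, u) {
    f1 <- i1 + as.vector(u[[1]]) / vs[1]
    f2 <- i2 + as.vector(u[[2]]) / vs[2]
    f3 <- i3 + as.vector(u[[3]]) / vs[3]
    lapply(chans, function(a) array(sample_frac(a, f1, f2, f3), d))
  }
  score_of <- function(u) {
    wm <- warp_channels(mov, u)
    reg_score(wm, fix, metric, bins, mask)
  }
  best <- u_list
  best_score <- score_of(best)
  strikes <- 0L
  cur_step <- step
  for (it in seq_len(iters)) {
    wmf <- warp_channels(force_imgs$mov, best)
    upd <- lapply(1:3, function(c3) array(0, d))
    for (ci in seq_along(fix)) {
      diffc <- wmf[[ci]] - force_imgs$fix[[ci]]
      g <- gfix[[ci]]
      gn2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
      den <- gn2 + diffc^2
      den[den < 1e-12] <- 1e-12
      f <- -diffc / den
      for (c3 in 1:3) upd[[c3]] <- upd[[c3]] + f * g[[c3]]
    }
    cand <- best
    for (c3 in 1:3) {
      u <- upd[[c3]] / length(fix)
      if (!is.null(mask)) u <- u * mask
      u <- smooth3d(u, sigma_fluid_vox) * vs[c3]  # per-voxel force -> um
      cand[[c3]] <- smooth3d(best[[c3]] + cur_step * u, sigma_field_vox)
    }
    sc <- score_of(cand)
    if (sc >= best_score - 1e-12) {
      best <- cand
      best_score <- sc
      strikes <- 0L
    } else {
      cur_step <- cur_step / 2
      strikes <- strikes + 1L
      if (strikes >= 3L) break
    }
  }
  out <- array(0, c(d, 3L))
  for (c3 in 1:3) out[, , , c3] <- best[[c3]]
  list(disp = out, score = best_score)
}

#' Downsample a channel list by block mean
#' @noRd
level_channels <- function(chans, meta, factor) {
  if (factor == 1L) return(list(chans = chans, meta = meta))
  vols <- lapply(chans, function(a) downsample_intensity(intensity_volume(a, meta), factor))
  list(chans = lapply(vols, function(v) v$data), meta = vols[[1]]$meta)
}

#' Multi-channel nonlinear demons driver; moving channels must already be on
#' the fixed grid.
#' @noRd
demons_multires <- function(mov, fix, meta, params, mask = NULL) {
  norm <- reg_normalize(mov, fix, params$metric)
  metric_mov <- if (params$metric == "nmi") mov else norm$mov
  metric_fix <- if (params$metric == "nmi") fix else norm$fix
  sig_scale <- if (params$aggressive) 0.5 else 1
  field <- NULL
  for (li in seq_along(params$levels)) {
    f <- params$levels[li]
    L_mov <- level_channels(metric_mov, meta, f)
    L_fix <- level_channels(metric_fix, meta, f)
    Lf_mov <- level_channels(norm$mov, meta, f)
    Lf_fix <- level_channels(norm$fix, meta, f)
    lmeta <- L_fix$meta
    d <- dim(L_fix$chans[[1]])
    lmask <- if (is.null(mask)) NULL else
      level_channels(list(mask * 1), meta, f)$chans[[1]] > 0.5
    if (is.null(field)) {
      disp <- array(0, c(d, 3L))
    } else {
      up <- as_deformation_field(field, lmeta, d)
      disp <- up$disp
    }
    sf <- (params$sigma_fluid_um %||% lmeta$voxel_size[1]) / lmeta$voxel_size * sig_scale
    sd_ <- (params$sigma_field_um %||% lmeta$voxel_size[1]) / lmeta$voxel_size * sig_scale
    res <- demons_level(L_mov$chans, L_fix$chans, lmeta, disp,
                        params$iterations[li], sf, sd_, params$step_size,
                        params$metric, params$bins,
                        list(mov = Lf_mov$chans, fix = Lf_fix$chans),
                        mask = lmask)
    field <- deformation_field(res$disp, lmeta)
  }
  if (params$levels[length(params$levels)] != 1L) {
    field <- as_deformation_field(field, meta, dim(fix[[1]]))
  }
  attr(field, "score") <- res$score
  field
}

# --- affine ------------------------------------------------------------------

rot_mat <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

params_to_affine <- function(par, dof, center) {
  t <- par[1:3]
  r <- par[4:6]
  M <- rot_mat(r)
  if (dof == "similarity") {
    M <- M * exp(par[7])
  } else if (dof == "affine") {
    S <- diag(exp(par[7:9]))
    H <- diag(3)
    H[1, 2] <- par[10]; H[1, 3] <- par[11]; H[2, 3] <- par[12]
    M <- M %*% H %*% S
  }
  affine_transform(M, center - as.numeric(M %*% center) + t)
}

n_params <- function(dof) switch(dof, rigid = 6L, similarity = 7L, affine = 12L)

#' Affine registration by multi-resolution continuous optimization
#'
#' Seeds with an exhaustive translation search at the coarsest level, then
#' refines with Nelder-Mead simplex (gradient-free) per pyramid level. The
#' whole procedure is deterministic.
#'
#' @param moving,fixed [intensity_volume()]s with overlapping fields of view;
#'   neither may be constant.
#' @param params a [registration_params()].
#' @param dof `"rigid"`, `"similarity"` or `"affine"`.
#' @param fixed_mask optional logical array on the fixed grid restricting
#'   the similarity evaluation (a metric mask).
#' @return an [affine_transform()] (fixed -> moving) with attributes `score`
#'   (final metric) and `converged`.
#' @export
register_affine <- function(moving, fixed, params = registration_params(),
                            dof = c("affine", "similarity", "rigid"),
                            fixed_mask = NULL) {
  dof <- match.arg(dof)
  register_affine_channels(list(moving$data), moving$meta,
                           list(fixed$data), fixed$meta, params, dof,
                           fixed_mask = fixed_mask)
}

#' @noRd
register_affine_channels <- function(mov, mov_meta, fix, fix_meta, params, dof,
                                     fixed_mask = NULL) {
  if (all(vapply(mov, function(a) max(a) == min(a), logical(1))) ||
      all(vapply(fix, function(a) max(a) == min(a), logical(1))))
    af_stop("degenerate (constant) input to affine registration")
  d_fix <- dim(fix[[1]])
  center <- fix_meta$origin + (d_fix - 1) / 2 * fix_meta$voxel_size
  np <- n_params(dof)
  par <- rep(0, np)
  warp_score <- function(par, fixL, fmeta, dL, movL, maskL) {
    tr <- params_to_affine(par, dof, center)
    pts <- grid_points(fmeta, dL)
    q <- transform_points(tr, pts)
    wm <- lapply(movL$chans, function(a)
      array(sample_array(a, movL$meta, q), dL))
    reg_score(wm, fixL$chans, params$metric, params$bins, maskL)
  }
  last_score <- NA_real_
  for (li in seq_along(params$levels)) {
    f <- params$levels[li]
    movL <- level_channels(mov, mov_meta, f)
    fixL <- level_channels(fix, fix_meta, f)
    dL <- dim(fixL$chans[[1]])
    fmeta <- fixL$meta
    maskL <- if (is.null(fixed_mask)) NULL else
      level_channels(list(fixed_mask * 1), fix_meta, f)$chans[[1]] > 0.5
    if (li == 1L && params$translation_search > 0L) {
      w <- params$translation_search
      steps <- seq(-w, w, by = 2) * fmeta$voxel_size[1]
      best <- par; best_s <- warp_score(par, fixL, fmeta, dL, movL, maskL)
      for (tx in steps) for (ty in steps) for (tz in steps) {
        p2 <- par; p2[1:3] <- c(tx, ty, tz)
        s <- warp_score(p2, fixL, fmeta, dL, movL, maskL)
        if (s > best_s + 1e-12) { best_s <- s; best <- p2 }
      }
      par <- best
    }
    scales <- c(rep(fmeta$voxel_size[1], 3), rep(0.02, np - 3))
    opt <- stats::optim(par, function(p) -warp_score(p, fixL, fmeta, dL, movL, maskL),
                        method = "Nelder-Mead",
                        control = list(maxit = params$iterations[li] * 10L,
                                       parscale = scales, reltol = 1e-9))
    par <- opt$par
    last_score <- -opt$value
  }
  # full-resolution guard: never return a transform that scores worse than
  # the identity start at the native resolution (coarse-level optima can
  # regress when brought back to full resolution)
  if (params$levels[length(params$levels)] != 1L) {
    movF <- list(chans = mov, meta = mov_meta)
    fixF <- list(chans = fix, meta = fix_meta)
    dF <- dim(fix[[1]])
    maskF <- fixed_mask
    sc_par <- warp_score(par, fixF, fix_meta, dF, movF, maskF)
    sc_id <- warp_score(rep(0, np), fixF, fix_meta, dF, movF, maskF)
    if (sc_id > sc_par) {
      par <- rep(0, np)
      last_score <- sc_id
    } else last_score <- sc_par
  }
  tr <- params_to_affine(par, dof, center)
  attr(tr, "score") <- last_score
  attr(tr, "converged") <- TRUE
  tr
}

#' Nonlinear (demons-style) registration
#'
#' Free-form displacement estimation: per-voxel forces from the similarity
#' gradient, Gaussian-smoothed update (fluid) composed into a running field
#' that is itself smoothed (diffusion). Steps that would decrease the metric
#' are rejected, so the reported metric is monotone non-decreasing over
#' accepted iterations.
#'
#' @param moving,fixed [intensity_volume()]s.
#' @param params a [registration_params()].
#' @param initial optional initial transform (affine, field or chain)
#'   applied before the nonlinear stage; the total mapping is then
#'   `initial(p + u(p))`.
#' @param fixed_mask optional logical array on the fixed grid restricting
#'   the similarity evaluation and the demons forces (a metric mask).
#' @return a `deformation_field` on the fixed grid, with attributes `score`
#'   and (when `initial` is supplied) `total`, the full transform chain.
#' @export
register_nonlinear <- function(moving, fixed, params = registration_params(),
                               initial = NULL, fixed_mask = NULL) {
  if (max(moving$data) == min(moving$data) || max(fixed$data) == min(fixed$data))
    af_stop("degenerate (constant) input to nonlinear registration")
  mov_on_fix <- if (is.null(initial) &&
                    identical(vol_dim(moving), vol_dim(fixed)) &&
                    isTRUE(all.equal(moving$meta$voxel_size, fixed$meta$voxel_size)) &&
                    isTRUE(all.equal(moving$meta$origin, fixed$meta$origin)))
    moving else apply_transform(moving, initial, "linear", fixed$meta, vol_dim(fixed))
  field <- demons_multires(list(mov_on_fix$data), list(fixed$data),
                           fixed$meta, params, mask = fixed_mask)
  if (!is.null(initial)) attr(field, "total") <- transform_chain(field, initial)
  field
}

#' Label-driven registration between two annotation volumes
#'
#' Shared labels are converted to Gaussian-blurred indicator channels (one per
#' label) and registered with an affine stage followed by nonlinear demons on
#' the summed-channel SSD.
#'
#' @param movingAnn,fixedAnn [labeled_volume()]s with overlapping label sets.
#' @param params a [registration_params()]; the metric is forced to `"ssd"`.
#' @param labels optional label subset; default: all shared non-background
#'   labels.
#' @param blur_vox indicator blur sigma in voxels.
#' @param dof affine degrees of freedom.
#' @return list with `affine`, `field` and `total` (transform chain
#'   fixed -> moving).
#' @export
register_labels <- function(movingAnn, fixedAnn, params = registration_params(),
                            labels = NULL, blur_vox = 1, dof = "affine") {
  shared <- labels %||% setdiff(intersect(unique(as.vector(movingAnn$data)),
                                          unique(as.vector(fixedAnn$data))), 0L)
  shared <- sort(shared)
  if (length(shared) == 0L) af_stop("no shared labels between the annotations")
  params$metric <- "ssd"
  mk <- function(ann) lapply(shared, function(l)
    smooth3d(array(as.numeric(ann$data == l), dim(ann$data)), blur_vox))
  mov <- mk(movingAnn)
  fix <- mk(fixedAnn)
  aff <- register_affine_channels(mov, movingAnn$meta, fix, fixedAnn$meta,
                                  params, dof)
  # resample moving channels through the affine onto the fixed grid
  d_fix <- dim(fixedAnn$data)
  pts <- grid_points(fixedAnn$meta, d_fix)
  q <- transform_points(aff, pts)
  mov_w <- lapply(mov, function(a)
    array(sample_array(a, movingAnn$meta, q), d_fix))
  field <- demons_multires(mov_w, fix, fixedAnn$meta, params)
  list(affine = aff, field = field, total = transform_chain(field, aff))
}
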