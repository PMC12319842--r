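# Population-average template construction: initialize from whole-brain
# volumes, register 2D sections to their anatomical planes in the fixed
# initialization, accumulate warped intensities and contribution counts, and
# normalize.

#' Voxel-wise mean of co-registered volumes
#'
#' @param volumes list of [intensity_volume()]s on the same grid.
#' @return an [intensity_volume()].
#' @export
init_average <- function(volumes) {
  if (length(volumes) < 1L) af_stop("need at least one volume")
  d <- vol_dim(volumes[[1]])
  for (v in volumes) {
    if (!identical(vol_dim(v), d)) af_stop("grid mismatch in init_average")
  }
  acc <- array(0, d)
  for (v in volumes) acc <- acc + v$data
  intensity_volume(acc / length(volumes), volumes[[1]]$meta)
}

#' Create an empty template accumulator
#'
#' @param init the initialization [intensity_volume()] (fixed reference all
#'   sections are registered to).
#' @return object of class `template_accumulator` with zero `sum` and
#'   `count` volumes.
#' @export
template_accumulator <- function(init) {
  d <- vol_dim(init)
  structure(list(sum = array(0, d), count = array(0L, d), init = init,
                 meta = init$meta, used = 0L, skipped = 0L),
            class = "template_accumulator")
}

#' @export
print.template_accumulator <- function(x, ...) {
  cat(sprintf("template_accumulator: %d sections used, %d skipped, %.1f%% voxels covered\n",
              x$used, x$skipped, 100 * mean(x$count > 0)))
  invisible(x)
}

#' Register one section to its plane and accumulate it
#'
#' The section image (moving) is registered in-plane, nonlinearly, to the
#' corresponding anatomical plane of the fixed initialization reference. The
#' warped pixel intensities are added to the sum volume at that plane and the
#' contribution count is incremented at the covered (non-background) voxels
#' only, so partial sections do not dilute voxels they miss.
#'
#' @param acc a [template_accumulator()].
#' @param sec section record: list with `image` (2D matrix), `plane_axis`,
#'   `plane_index` (see [make_sections()]).
#' @param params a [registration_params()] for the 2D registration.
#' @return the updated accumulator.
#' @export
accumulate_section <- function(acc, sec,
                               params = registration_params(levels = c(2, 1),
                                                            iterations = c(50, 30))) {
  d <- vol_dim(acc$init)
  ax <- sec$plane_axis
  s <- sec$plane_index
  if (s < 1L || s > d[ax]) af_stop("plane index %d outside the grid", s)
  if (all(sec$image == 0)) {
    acc$skipped <- acc$skipped + 1L
    return(acc)
  }
  idx <- lapply(d, seq_len)
  idx[[ax]] <- s
  inplane <- setdiff(1:3, ax)
  ref2 <- array(acc$init$data[idx[[1]], idx[[2]], idx[[3]]],
                c(d[inplane], 1L))
  mov2 <- array(sec$image, c(dim(sec$image), 1L))
  vs <- acc$meta$voxel_size[c(inplane, ax)]
  meta2 <- grid_meta(vs, c(0, 0, 0), acc$meta$axis_roles[c(inplane, ax)])
  warped2 <- if (max(ref2) == min(ref2) || max(mov2) == min(mov2)) {
    mov2  # flat reference plane: nothing to register against
  } else {
    fld <- register_nonlinear(intensity_volume(mov2, meta2),
                              intensity_volume(ref2, meta2), params)
    apply_transform(intensity_volume(mov2, meta2), fld, "linear",
                    meta2, dim(mov2))$data
  }
  covered <- warped2 != 0
  plane_sum <- array(acc$sum[idx[[1]], idx[[2]], idx[[3]]], dim(warped2))
  plane_cnt <- array(acc$count[idx[[1]], idx[[2]], idx[[3]]], dim(warped2))
  plane_sum[covered] <- plane_sum[covered] + warped2[covered]
  plane_cnt[covered] <- plane_cnt[covered] + 1L
  acc$sum[idx[[1]], idx[[2]], idx[[3]]] <- plane_sum
  acc$count[idx[[1]], idx[[2]], idx[[3]]] <- plane_cnt
  acc$used <- acc$used + 1L
  acc
}

#' Normalize an accumulator into the average template
#'
#' Each voxel becomes `(init + sum) / (1 + count)`: the initialization
#' counts as one contribution everywhere, so uncovered voxels keep their
#' initialization value.
#'
#' @param acc a [template_accumulator()].
#' @param include_init set FALSE to drop the initialization term (plain
#'   `sum / count`, init where count is zero).
#' @return an [intensity_volume()].
#' @export
normalize_template <- function(acc, include_init = TRUE) {
  if (include_init) {
    out <- (acc$init$data + acc$sum) / (1 + acc$count)
  } else {
    out <- acc$init$data
    cv <- acc$count > 0
    out[cv] <- acc$sum[cv] / acc$count[cv]
  }
  intensity_volume(out, acc$meta)
}

#' Build an average template from initialization volumes and sections
#'
#' Initializes with the voxel-wise average of the supplied whole-brain
#' volumes, registers every section to its plane of the fixed initialization
#' (so the result does not depend on section order), accumulates, and
#' normalizes by contribution counts.
#'
#' @param init_volumes list of [intensity_volume()]s.
#' @param sections list of section records (see [make_sections()]).
#' @param params 2D registration parameters.
#' @return list with `template` ([intensity_volume()]), `counts`
#'   ([labeled_volume()]-like integer volume), `accumulator`, and a `report`
#'   (sections used/skipped, per-plane counts, coverage fraction).
#' @export
build_template <- function(init_volumes, sections,
                           params = registration_params(levels = c(2, 1),
                                                        iterations = c(50, 30))) {
  init <- init_average(init_volumes)
  acc <- template_accumulator(init)
  for (sec in sections) acc <- accumulate_section(acc, sec, params)
  tmpl <- normalize_template(acc)
  planes <- vapply(sections, function(s) s$plane_index, 1L)
  report <- list(used = acc$used, skipped = acc$skipped,
                 per_plane = table(planes),
                 coverage = mean(acc$count > 0))
  list(template = tmpl, counts = acc$count, accumulator = acc, report = report)
}
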