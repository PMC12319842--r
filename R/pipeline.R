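# Region-by-region alignment orchestration: global label-driven
# initialization, masked per-region multimodal registration with hierarchical
# gap filling, the dedicated cerebellar path, the final whole-brain
# monomodal pass, and the multi-scale evaluation report.

#' Global label-driven initialization
#'
#' Registers the older annotation (moving) to the newer annotation (fixed)
#' and applies the resulting transform to the Nissl volume (linear
#' interpolation) and to the older annotation itself (nearest).
#'
#' @param nissl [intensity_volume()] on the older annotation's grid.
#' @param annV2 older [labeled_volume()] on the same grid as `nissl`.
#' @param annV3 newer [labeled_volume()]; defines the output grid.
#' @param params a [registration_params()] for the label registration.
#' @return list with `nissl_init`, `annV2_init`, `transforms` (the
#'   [register_labels()] result).
#' @export
global_label_init <- function(nissl, annV2, annV3,
                              params = registration_params(levels = c(4),
                                                           iterations = c(80))) {
  rl <- register_labels(annV2, annV3, params)
  d <- vol_dim(annV3)
  list(nissl_init = apply_transform(nissl, rl$total, "linear", annV3$meta, d),
       annV2_init = apply_transform(annV2, rl$total, "nearest", annV3$meta, d),
       transforms = rl)
}

#' @noRd
new_recon_state <- function(annV3) {
  d <- vol_dim(annV3)
  list(recon = array(0, d), written = array(FALSE, d),
       conflicts = 0L, fill = c(leaf = 0L, cerebellum = 0L, parent = 0L, global = 0L))
}

#' Register one masked region pair and write it into the reconstruction
#' @noRd
register_region_into <- function(state, nissl_init, template, mv_mask, fx_mask,
                                 params, margin, source, count_conflicts = TRUE) {
  bbox <- mask_bbox(mv_mask | fx_mask, margin)
  meta <- template$meta
  cmeta <- meta
  cmeta$origin <- meta$origin + (bbox[, 1] - 1) * meta$voxel_size
  mov_c <- intensity_volume(crop_array(nissl_init$data * mv_mask, bbox), cmeta)
  fix_c <- intensity_volume(crop_array(template$data * fx_mask, bbox), cmeta)
  if (max(mov_c$data) == min(mov_c$data) || max(fix_c$data) == min(fix_c$data))
    return(list(state = state, transform = NULL, score = NA_real_))
  aff <- register_affine(mov_c, fix_c, params, dof = "affine")
  fld <- register_nonlinear(mov_c, fix_c, params, initial = aff)
  total <- transform_chain(fld, aff)
  warped <- apply_transform(mov_c, total, "linear", cmeta, vol_dim(mov_c))
  # write only inside the fixed-space region mask (no leakage)
  fx_crop <- crop_array(fx_mask, bbox)
  tgt <- which(fx_crop)
  full_idx <- arrayInd(tgt, dim(fx_crop))
  full_idx[, 1] <- full_idx[, 1] + bbox[1, 1] - 1L
  full_idx[, 2] <- full_idx[, 2] + bbox[2, 1] - 1L
  full_idx[, 3] <- full_idx[, 3] + bbox[3, 1] - 1L
  already <- state$written[full_idx]
  if (count_conflicts) state$conflicts <- state$conflicts + sum(already)
  put <- !already
  state$recon[full_idx[put, , drop = FALSE]] <- warped$data[tgt[put]]
  state$written[full_idx[put, , drop = FALSE]] <- TRUE
  state$fill[source] <- state$fill[source] + sum(put)
  list(state = state, transform = total, score = attr(fld, "score"))
}

#' Region-by-region masked registration and reconstruction
#'
#' For each leaf-level region the initialized Nissl (moving) and the template
#' (fixed) are cropped to the union bounding box of the region masks, masked,
#' registered (affine then nonlinear multimodal), and the warped Nissl tissue
#' is written into the reconstruction strictly inside the fixed-space region
#' mask. Still-empty annotated voxels are then filled from parent-level
#' registrations and finally from the globally initialized Nissl.
#'
#' @param nissl_init,template [intensity_volume()]s on the fixed grid.
#' @param annV2_init,annV3 [labeled_volume()]s on the fixed grid.
#' @param assignment a `level_assignment` computed on
#'   `(annV2_init, annV3)`.
#' @param graph the `structure_graph`.
#' @param params a [registration_params()] for the per-region registrations.
#' @param min_voxels regions smaller than this (in either mask) are skipped
#'   with a warning and covered by their parent level.
#' @param margin bounding-box margin in voxels.
#' @param exclude_leaves leaf ids handled elsewhere (the cerebellar path).
#' @param state optional reconstruction state to continue from.
#' @param fill run the parent-level and global fill passes.
#' @return list with `recon` ([intensity_volume()]), `transforms` (class
#'   `region_transform_set`), `state`, and a `regions` data.frame log.
#' @export
regionwise_register <- function(nissl_init, template, annV2_init, annV3,
                                assignment, graph,
                                params = registration_params(levels = c(2, 1),
                                                             iterations = c(40, 20),
                                                             metric = "nmi",
                                                             bins = 32),
                                min_voxels = 50L, margin = 5L,
                                exclude_leaves = integer(0),
                                state = NULL, fill = TRUE) {
  state <- state %||% new_recon_state(annV3)
  transforms <- list()
  log <- list()
  ca <- label_counts(annV2_init)
  cb <- label_counts(annV3)
  need_parents <- assignment$parent_map
  for (id in sort(setdiff(assignment$leaf_ids, exclude_leaves))) {
    mv <- region_mask(annV2_init, graph, id, include_descendants = TRUE)
    fx <- region_mask(annV3, graph, id, include_descendants = TRUE)
    if (sum(mv) < min_voxels || sum(fx) < min_voxels) {
      af_warn("region %d below %d voxels; deferring to parent level", id, min_voxels)
      # route this leaf through the first both-supported ancestor
      for (anc in ancestors(graph, id)) {
        if (region_support(ca, graph, anc) > 0 && region_support(cb, graph, anc) > 0) {
          need_parents[as.character(id)] <- anc
          break
        }
      }
      log[[length(log) + 1L]] <- data.frame(id = id, level = "leaf",
                                            status = "skipped_small",
                                            voxels_fixed = sum(fx), score = NA_real_)
      next
    }
    res <- register_region_into(state, nissl_init, template, mv, fx, params,
                                margin, "leaf")
    state <- res$state
    if (!is.null(res$transform)) {
      transforms[[as.character(id)]] <- list(level = "leaf", transform = res$transform,
                                             score = res$score)
      log[[length(log) + 1L]] <- data.frame(id = id, level = "leaf",
                                            status = "registered",
                                            voxels_fixed = sum(fx), score = res$score)
    } else {
      log[[length(log) + 1L]] <- data.frame(id = id, level = "leaf",
                                            status = "degenerate",
                                            voxels_fixed = sum(fx), score = NA_real_)
    }
  }
  if (fill) {
    transforms_env <- new.env()
    state <- fill_from_parents(state, nissl_init, template, annV2_init, annV3,
                               graph, need_parents, params, margin,
                               transforms_env)
    for (nm in ls(transforms_env)) transforms[[nm]] <- get(nm, transforms_env)
    state <- fill_global(state, nissl_init, annV3)
  }
  structure(list(recon = intensity_volume(state$recon, annV3$meta),
                 transforms = structure(transforms, class = "region_transform_set"),
                 state = state,
                 regions = if (length(log)) do.call(rbind, log) else NULL),
            class = "regionwise_result")
}

#' @noRd
fill_from_parents <- function(state, nissl_init, template, annV2_init, annV3,
                              graph, parent_map, params, margin, transforms_env) {
  ann_fg <- annV3$data != 0L
  for (pid in sort(unique(parent_map))) {
    mv <- region_mask(annV2_init, graph, pid, include_descendants = TRUE)
    fx <- region_mask(annV3, graph, pid, include_descendants = TRUE)
    if (!any(mv) || !any(fx)) next
    if (!any(fx & !state$written & ann_fg)) next  # nothing left to fill here
    res <- register_region_into(state, nissl_init, template, mv, fx, params,
                                margin, "parent", count_conflicts = FALSE)
    state <- res$state
    if (!is.null(res$transform))
      assign(paste0("parent_", pid),
             list(level = "parent", transform = res$transform, score = res$score),
             transforms_env)
  }
  state
}

#' @noRd
fill_global <- function(state, nissl_init, annV3) {
  todo <- annV3$data != 0L & !state$written
  state$recon[todo] <- nissl_init$data[todo]
  state$written[todo] <- TRUE
  state$fill["global"] <- state$fill["global"] + sum(todo)
  state
}

#' Dedicated cerebellar lobule alignment
#'
#' Each lobule is registered independently between the two annotation
#' versions (blurred binary lobule masks; affine then aggressive nonlinear),
#' the transforms are applied to the Nissl lobule tissue, and the warped
#' lobules are merged into the reconstruction strictly inside the
#' newer-version lobule masks.
#'
#' @param nissl_init [intensity_volume()] on the fixed grid.
#' @param annV2_init,annV3 [labeled_volume()]s on the fixed grid.
#' @param graph the `structure_graph`.
#' @param lobule_ids ids of the cerebellar lobules (16 on real data, 4 on
#'   the standard phantom); each must be annotated in both versions.
#' @param params base [registration_params()]; the aggressive variant is
#'   derived from it.
#' @param margin crop margin (voxels).
#' @param state optional reconstruction state to continue from.
#' @return list `state`, `transforms`, `log`.
#' @export
cerebellum_align <- function(nissl_init, annV2_init, annV3, graph, lobule_ids,
                             params = registration_params(levels = c(2, 1),
                                                          iterations = c(40, 20),
                                                          aggressive = TRUE),
                             margin = 5L, state = NULL) {
  state <- state %||% new_recon_state(annV3)
  transforms <- list()
  log <- list()
  meta <- annV3$meta
  for (id in sort(as.integer(lobule_ids))) {
    mv <- region_mask(annV2_init, graph, id, include_descendants = TRUE)
    fx <- region_mask(annV3, graph, id, include_descendants = TRUE)
    if (!any(mv) || !any(fx))
      af_stop("lobule %d is not annotated in both versions", id)
    bbox <- mask_bbox(mv | fx, margin)
    cmeta <- meta
    cmeta$origin <- meta$origin + (bbox[, 1] - 1) * meta$voxel_size
    mov_c <- intensity_volume(smooth3d(crop_array(mv, bbox) * 1, 1), cmeta)
    fix_c <- intensity_volume(smooth3d(crop_array(fx, bbox) * 1, 1), cmeta)
    aff <- register_affine(mov_c, fix_c, params, dof = "affine")
    fld <- register_nonlinear(mov_c, fix_c, params, initial = aff)
    total <- transform_chain(fld, aff)
    # apply the mask-driven transform to the Nissl tissue of the lobule
    nis_c <- intensity_volume(crop_array(nissl_init$data * mv, bbox), cmeta)
    warped <- apply_transform(nis_c, total, "linear", cmeta, vol_dim(nis_c))
    fx_crop <- crop_array(fx, bbox)
    tgt <- which(fx_crop)
    full_idx <- arrayInd(tgt, dim(fx_crop))
    for (a in 1:3) full_idx[, a] <- full_idx[, a] + bbox[a, 1] - 1L
    already <- state$written[full_idx]
    state$conflicts <- state$conflicts + sum(already)
    put <- !already
    state$recon[full_idx[put, , drop = FALSE]] <- warped$data[tgt[put]]
    state$written[full_idx[put, , drop = FALSE]] <- TRUE
    state$fill["cerebellum"] <- state$fill["cerebellum"] + sum(put)
    # mask-overlap quality after warp
    wmask <- apply_transform(labeled_volume(array(as.integer(mv), vol_dim(annV3)), meta),
                             total, "nearest", cmeta, vol_dim(mov_c))
    dsc <- dice(wmask$data != 0L, fx_crop)
    transforms[[as.character(id)]] <- list(level = "lobule", transform = total,
                                           score = attr(fld, "score"), dice = dsc)
    log[[length(log) + 1L]] <- data.frame(id = id, dice = dsc)
  }
  list(state = state, transforms = transforms,
       log = do.call(rbind, log))
}

#' Final whole-brain monomodal pass
#'
#' One nonlinear registration of the continuous whole-brain Nissl volume
#' (moving) onto the region-wise reconstruction (fixed). The warped
#' continuous volume carries the region-wise alignment without the mosaic
#' seams (piecewise-transform discontinuities) of the reconstruction itself.
#'
#' @param nissl_cont the continuous (un-mosaicked) [intensity_volume()],
#'   typically the globally initialized Nissl.
#' @param reconstructed the region-wise reconstruction on the fixed grid.
#' @param params a [registration_params()].
#' @param initial optional initial transform applied to `nissl_cont` before
#'   the nonlinear stage.
#' @return list `aligned` ([intensity_volume()]), `transform` (mapping from
#'   fixed-grid points into `nissl_cont` space) and `field` (the estimated
#'   residual `deformation_field`).
#' @export
final_whole_brain <- function(nissl_cont, reconstructed,
                              params = registration_params(levels = c(4, 2, 1),
                                                           iterations = c(100, 60, 60)),
                              initial = NULL) {
  fld <- register_nonlinear(nissl_cont, reconstructed, params, initial = initial)
  total <- attr(fld, "total") %||% fld
  aligned <- apply_transform(nissl_cont, total, "linear", reconstructed$meta,
                             vol_dim(reconstructed))
  list(aligned = aligned, transform = total, field = fld)
}

#' Multi-scale alignment evaluation
#'
#' Whole-brain, per-region and per-slice NMI before/after, plus fiducial TRE
#' summaries when fiducial tables are supplied.
#'
#' @param before,after [intensity_volume()]s on the template grid.
#' @param template the fixed modality reference.
#' @param annV3 [labeled_volume()] defining regions.
#' @param graph the `structure_graph`.
#' @param region_ids regions for the per-region table (default: annotated
#'   leaves).
#' @param fiducials_before,fiducials_after optional fiducial sets (reference
#'   coordinates vs estimated coordinates before/after alignment).
#' @param bins histogram bins.
#' @return object of class `alignment_report`.
#' @export
evaluate_alignment <- function(before, after, template, annV3, graph,
                               region_ids = NULL,
                               fiducials_before = NULL, fiducials_after = NULL,
                               bins = 64L) {
  region_ids <- region_ids %||%
    sort(intersect(graph_leaves(graph), unique(as.vector(annV3$data))))
  pr_b <- per_region_nmi(before, template, annV3, graph, region_ids, bins)
  pr_a <- per_region_nmi(after, template, annV3, graph, region_ids, bins)
  per_region <- data.frame(id = pr_b$id, acronym = pr_b$acronym,
                           voxels = pr_b$voxels,
                           nmi_before = pr_b$nmi, nmi_after = pr_a$nmi,
                           delta = pr_a$nmi - pr_b$nmi,
                           flagged = pr_b$flagged | pr_a$flagged)
  slices <- lapply(c("coronal", "sagittal", "horizontal"), function(inc) {
    sb <- per_slice_nmi(before, template, inc, bins)
    sa <- per_slice_nmi(after, template, inc, bins)
    data.frame(incidence = inc, slice = sb$slice,
               nmi_before = sb$nmi, nmi_after = sa$nmi,
               flagged = sb$flagged | sa$flagged)
  })
  slices <- do.call(rbind, slices)
  rep_ <- list(
    whole_nmi_before = nmi(before, template, bins),
    whole_nmi_after = nmi(after, template, bins),
    per_region = per_region,
    per_slice = slices,
    tre_before = if (!is.null(fiducials_before)) tre(fiducials_before) else NULL,
    tre_after = if (!is.null(fiducials_after)) tre(fiducials_after) else NULL)
  rep_$whole_delta <- rep_$whole_nmi_after - rep_$whole_nmi_before
  structure(rep_, class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("alignment_report: whole-brain NMI %.4f -> %.4f (delta %+.4f)\n",
              x$whole_nmi_before, x$whole_nmi_after, x$whole_delta))
  ok <- !x$per_region$flagged
  cat(sprintf("  per-region NMI improved in %d/%d scored regions\n",
              sum(x$per_region$delta[ok] > 0, na.rm = TRUE), sum(ok)))
  if (!is.null(x$tre_before))
    cat(sprintf("  TRE mean: %.1f um -> %.1f um\n",
                x$tre_before$mean, x$tre_after$mean))
  invisible(x)
}

#' Serialize an alignment report to JSON (with CSV side tables)
#' @param report an `alignment_report`.
#' @param path output JSON path; `<path>_regions.csv` and
#'   `<path>_slices.csv` are written next to it.
#' @export
write_alignment_report <- function(report, path) {
  jsonlite::write_json(list(
    whole_nmi_before = report$whole_nmi_before,
    whole_nmi_after = report$whole_nmi_after,
    whole_delta = report$whole_delta,
    per_region = report$per_region,
    per_slice = report$per_slice,
    tre_mean_before = report$tre_before$mean %||% NA,
    tre_mean_after = report$tre_after$mean %||% NA),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$per_region, paste0(base, "_regions.csv"), row.names = FALSE)
  utils::write.csv(report$per_slice, paste0(base, "_slices.csv"), row.names = FALSE)
  invisible(path)
}

#' Read back a serialized alignment report
#' @param path JSON path written by [write_alignment_report()].
#' @export
read_alignment_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(whole_nmi_before = x$whole_nmi_before,
                 whole_nmi_after = x$whole_nmi_after,
                 whole_delta = x$whole_delta,
                 per_region = as.data.frame(x$per_region),
                 per_slice = as.data.frame(x$per_slice),
                 tre_before = if (!is.null(x$tre_mean_before) && !is.na(x$tre_mean_before))
                   list(mean = x$tre_mean_before) else NULL,
                 tre_after = if (!is.null(x$tre_mean_after) && !is.na(x$tre_mean_after))
                   list(mean = x$tre_mean_after) else NULL),
            class = "alignment_report")
}

#' Run the full region-wise alignment pipeline
#'
#' Orchestrates: label-driven global initialization; level assignment;
#' region-by-region registration of the non-cerebellar leaves; the dedicated
#' cerebellar lobule path; parent-level and global gap filling; the final
#' whole-brain monomodal pass; and evaluation. When fiducials with reference
#' and older-volume coordinates are supplied, post-alignment coordinates are
#' obtained by mapping the older-volume points through the inverse of the
#' end-to-end field.
#'
#' @param nissl,annV2 the older-version intensity and annotation volumes.
#' @param template,annV3 the newer-version reference pair (fixed grid).
#' @param graph the `structure_graph`.
#' @param lobule_ids cerebellar lobule leaf ids (possibly empty).
#' @param fiducials optional fiducial set: `*_ref` = reference coordinates,
#'   `*_reg` = coordinates observed in the older volume.
#' @param init_params,region_params,cb_params,final_params stage parameters.
#' @param min_voxels,margin region-wise controls.
#' @return object of class `atlas_alignment`: stage volumes, transforms, and
#'   the `alignment_report`.
#' @export
align_atlas <- function(nissl, annV2, template, annV3, graph,
                        lobule_ids = integer(0), fiducials = NULL,
                        init_params = registration_params(levels = c(4),
                                                          iterations = c(80)),
                        region_params = registration_params(levels = c(2, 1),
                                                            iterations = c(40, 20),
                                                            metric = "nmi", bins = 32),
                        cb_params = registration_params(levels = c(2, 1),
                                                        iterations = c(40, 20),
                                                        aggressive = TRUE),
                        final_params = registration_params(levels = c(4, 2, 1),
                                                           iterations = c(100, 60, 60)),
                        min_voxels = 50L, margin = 5L) {
  init <- global_label_init(nissl, annV2, annV3, init_params)
  assignment <- assign_levels(graph, init$annV2_init, annV3)
  rw <- regionwise_register(init$nissl_init, template, init$annV2_init, annV3,
                            assignment, graph, region_params,
                            min_voxels = min_voxels, margin = margin,
                            exclude_leaves = lobule_ids, fill = FALSE)
  state <- rw$state
  cb <- NULL
  if (length(lobule_ids)) {
    cb <- cerebellum_align(init$nissl_init, init$annV2_init, annV3, graph,
                           lobule_ids, cb_params, margin, state)
    state <- cb$state
  }
  env <- new.env()
  state <- fill_from_parents(state, init$nissl_init, template, init$annV2_init,
                             annV3, graph, assignment$parent_map, region_params,
                             margin, env)
  state <- fill_global(state, init$nissl_init, annV3)
  recon <- intensity_volume(state$recon, annV3$meta)
  fin <- final_whole_brain(init$nissl_init, recon, final_params)
  # end-to-end mapping: fixed-grid point -> residual field -> global init
  # chain -> older-volume point
  end_to_end <- transform_chain(fin$field, init$transforms$total)
  fid_after <- NULL
  if (!is.null(fiducials)) {
    inv <- invert_transform(end_to_end)
    reg_pts <- as.matrix(fiducials[, c("x_reg", "y_reg", "z_reg")])
    mapped <- transform_points(inv, reg_pts)
    fid_after <- fiducials
    fid_after$x_reg <- mapped[, 1]
    fid_after$y_reg <- mapped[, 2]
    fid_after$z_reg <- mapped[, 3]
  }
  report <- evaluate_alignment(init$nissl_init, fin$aligned, template, annV3,
                               graph,
                               fiducials_before = fiducials,
                               fiducials_after = fid_after)
  nmis <- c(raw = tryCatch(nmi(apply_transform(nissl, NULL, "linear",
                                               annV3$meta, vol_dim(annV3)),
                               template), error = function(e) NA_real_),
            init = nmi(init$nissl_init, template),
            regionwise = nmi(recon, template),
            final = nmi(fin$aligned, template))
  structure(list(init = init, assignment = assignment,
                 regionwise = rw, cerebellum = cb,
                 recon = recon, final = fin, end_to_end = end_to_end,
                 stage_nmi = nmis, state = state,
                 fiducials_before = fiducials, fiducials_after = fid_after,
                 report = report),
            class = "atlas_alignment")
}

#' @export
print.atlas_alignment <- function(x, ...) {
  cat("atlas_alignment\n  stage NMI vs template:\n")
  print(round(x$stage_nmi, 4))
  cat(sprintf("  fill sources (voxels): %s\n",
              paste(names(x$state$fill), x$state$fill, sep = "=", collapse = ", ")))
  cat(sprintf("  overlap conflicts: %d\n", x$state$conflicts))
  print(x$report)
  invisible(x)
}
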