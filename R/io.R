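# Volume, transform and fiducial I/O.
#
# NIfTI-1 headers store spacing in millimetres; they are converted to
# micrometres on read and back on write. NRRD headers are read as raw units
# with a `units` override (default micrometres). Axis roles are carried in an
# NRRD key-value pair and, for NIfTI, in a small JSON sidecar next to the file.

nrrd_type_map <- c(int32 = "integer", `unsigned int` = "integer",
                   uint32 = "integer", int = "integer",
                   float = "double", double = "double")

#' Read a volume from NIfTI or NRRD
#'
#' Integer-typed files load as [labeled_volume()], floating-point files as
#' [intensity_volume()], unless `as` forces a class.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param as `"auto"`, `"labels"` or `"intensity"`.
#' @param nrrd_units physical unit of NRRD spacings, `"um"` or `"mm"`.
#' @return a volume object.
#' @export
read_volume <- function(path, as = c("auto", "labels", "intensity"),
                        nrrd_units = "um") {
  as <- match.arg(as)
  if (grepl("\\.nrrd$", path)) {
    r <- read_nrrd(path, units = nrrd_units)
    arr <- r$data; meta <- r$meta; is_int <- r$is_int
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) af_stop("expected a 3D volume in %s", path)
    vs <- RNifti::pixdim(img) * 1000  # mm -> um
    if (any(vs <= 0)) af_stop("non-positive spacing in %s", path)
    xf <- RNifti::xform(img)
    origin <- as.numeric(xf[1:3, 4]) * 1000
    roles <- c("lr", "rc", "dv")
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      roles <- sc$axis_roles %||% roles
      if (!is.null(sc$origin_um)) origin <- as.numeric(sc$origin_um)
    }
    meta <- grid_meta(vs, origin, roles)
    is_int <- is.integer(arr) || RNifti::niftiHeader(img)$datatype %in% c(2, 4, 8, 256, 512, 768)
  } else af_stop("unsupported volume format: %s", path)
  want_labels <- switch(as, auto = is_int, labels = TRUE, intensity = FALSE)
  if (want_labels) labeled_volume(arr, meta) else intensity_volume(arr, meta)
}

#' Write a volume to NIfTI or NRRD
#'
#' Labeled volumes are written as 32-bit integers (lossless); writing labels
#' through a float type is refused.
#'
#' @param vol a volume object.
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "af_volume"))
  arr <- vol$data
  if (is_labeled(vol)) {
    if (!is.integer(arr)) af_stop("refusing to write labels with non-integer storage")
  } else storage.mode(arr) <- "double"
  if (grepl("\\.nrrd$", path)) {
    write_nrrd(arr, vol$meta, path, is_int = is_labeled(vol))
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr)
    vs_mm <- vol$meta$voxel_size / 1000
    RNifti::pixdim(img) <- vs_mm
    m <- diag(c(vs_mm, 1))
    m[1:3, 4] <- vol$meta$origin / 1000
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
    jsonlite::write_json(list(axis_roles = vol$meta$axis_roles,
                              origin_um = vol$meta$origin,
                              voxel_size_um = vol$meta$voxel_size),
                         paste0(path, ".meta.json"), auto_unbox = FALSE, digits = NA)
  } else af_stop("unsupported volume format: %s", path)
  invisible(path)
}

# --- minimal NRRD (raw little-endian encoding) -------------------------------

read_nrrd <- function(path, units = "um") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) af_stop("not an NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  type <- fields$type %||% af_stop("NRRD missing type")
  rtype <- nrrd_type_map[[type]] %||% af_stop("unsupported NRRD type '%s'", type)
  if (!identical(fields$encoding, "raw")) af_stop("only raw NRRD encoding supported")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) af_stop("expected 3D NRRD")
  spacing <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else rep(1, 3)
  if (any(spacing <= 0)) af_stop("non-positive NRRD spacing")
  if (units == "mm") spacing <- spacing * 1000
  origin <- if (!is.null(fields[["space origin"]]))
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]]) else c(0, 0, 0)
  if (units == "mm") origin <- origin * 1000
  roles <- if (!is.null(fields[["axis roles"]]))
    strsplit(fields[["axis roles"]], "\\s+")[[1]] else c("lr", "rc", "dv")
  n <- prod(sizes)
  raw <- readBin(con, what = if (rtype == "integer") "integer" else "double",
                 n = n, size = if (rtype == "integer") 4L else 8L,
                 endian = "little")
  data <- array(raw, sizes)
  list(data = data, meta = grid_meta(spacing, origin, roles),
       is_int = rtype == "integer")
}

write_nrrd <- function(arr, meta, path, is_int) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", if (is_int) "int32" else "double"),
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
           sprintf("spacings: %s", paste(format(meta$voxel_size, digits = 15), collapse = " ")),
           sprintf("space origin: (%s)", paste(format(meta$origin, digits = 15), collapse = ",")),
           "endian: little",
           "encoding: raw",
           sprintf("axis roles:=%s", paste(meta$axis_roles, collapse = " ")),
           "")
  writeLines(hdr, con)
  if (is_int) {
    writeBin(as.integer(arr), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

# --- transforms --------------------------------------------------------------

#' Write an affine transform as 4x4 JSON
#' @param tr an [affine_transform()].
#' @param path output path.
#' @export
write_affine <- function(tr, path) {
  m <- rbind(cbind(tr$matrix, tr$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(type = "affine", matrix_rowmajor = as.vector(t(m))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an affine transform written by [write_affine()]
#' @param path input path.
#' @export
read_affine <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(x$matrix_rowmajor, 4, 4, byrow = TRUE)
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write a deformation field as a 4D NIfTI vector volume (displacements in um)
#' @param field a `deformation_field`.
#' @param path output path.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$disp)
  RNifti::pixdim(img) <- c(field$meta$voxel_size / 1000, 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(axis_roles = field$meta$axis_roles,
                            origin_um = field$meta$origin,
                            voxel_size_um = field$meta$voxel_size),
                       paste0(path, ".meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a deformation field written by [write_field()]
#' @param path input path.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    af_stop("expected a 3-component vector volume in %s", path)
  vs <- RNifti::pixdim(img)[1:3] * 1000
  origin <- c(0, 0, 0); roles <- c("lr", "rc", "dv")
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    roles <- sc$axis_roles %||% roles
    origin <- as.numeric(sc$origin_um %||% origin)
    vs <- as.numeric(sc$voxel_size_um %||% vs)
  }
  deformation_field(arr, grid_meta(vs, origin, roles))
}

# --- fiducials ---------------------------------------------------------------

#' Read a fiducial point table from CSV
#'
#' Expected columns: `name`, optional `operator` and `group`, and the paired
#' micrometre coordinates `x_ref,y_ref,z_ref,x_reg,y_reg,z_reg`.
#'
#' @param path CSV path.
#' @return a `data.frame` of class `fiducial_set`.
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_fiducials(df)
}

#' Validate a fiducial data.frame
#' @param df data.frame with ref/reg coordinate columns.
#' @export
as_fiducials <- function(df) {
  need <- c("name", "x_ref", "y_ref", "z_ref", "x_reg", "y_reg", "z_reg")
  miss <- setdiff(need, names(df))
  if (length(miss)) af_stop("fiducials missing columns: %s", paste(miss, collapse = ", "))
  if (!"operator" %in% names(df)) df$operator <- "op1"
  if (!"group" %in% names(df)) df$group <- "all"
  coords <- df[, c("x_ref", "y_ref", "z_ref", "x_reg", "y_reg", "z_reg")]
  if (any(!is.finite(as.matrix(coords)))) af_stop("fiducial coordinates must be finite")
  if (anyDuplicated(paste(df$name, df$operator)))
    af_stop("fiducial names must be unique per operator")
  class(df) <- c("fiducial_set", "data.frame")
  df
}

#' Write fiducials to CSV
#' @param df a fiducial set.
#' @param path output CSV path.
#' @export
write_fiducials <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
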