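#' Scalar image volume
#'
#' A 3-D scalar grid with voxel geometry, the common carrier for b0 images,
#' FA maps, MT saturation maps, probability maps and the like. Axes and the
#' phase-encoding axis are 1-based inside R; the JSON sidecar written next
#' to NIfTI files uses the 0-based convention of the on-disk interface.
#'
#' @param data 3-D numeric array.
#' @param voxel_size voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param pe_axis phase-encoding axis (1, 2 or 3), or `NA` if unset.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `epi_volume`.
#' @export
epi_volume <- function(data, voxel_size = c(1, 1, 1), pe_axis = NA_integer_,
                       affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    epi_stop("volume data must be a 3-D array", "epi_argument_error")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0))
    epi_stop("all voxel sizes must be > 0", "epi_argument_error")
  if (!is.na(pe_axis)) {
    pe_axis <- as.integer(pe_axis)
    if (!pe_axis %in% 1:3)
      epi_stop("pe_axis must be 1, 2 or 3", "epi_argument_error")
    if (dim(data)[pe_axis] < 2L)
      epi_stop("grid must have >= 2 voxels along the phase-encoding axis",
               "epi_argument_error")
  }
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 pe_axis = pe_axis, affine = affine),
            class = "epi_volume")
}

#' @export
print.epi_volume <- function(x, ...) {
  cat("<epi_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm, PE axis ", x$pe_axis, "\n", sep = "")
  invisible(x)
}

#' Binary mask
#'
#' @param data 3-D logical array.
#' @param provenance free-text note on how the mask was made.
#' @return An object of class `epi_mask`.
#' @export
epi_mask <- function(data, provenance = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    epi_stop("mask data must be a 3-D array", "epi_argument_error")
  storage.mode(data) <- "logical"
  structure(list(data = data, provenance = as.character(provenance)),
            class = "epi_mask")
}

#' @export
print.epi_mask <- function(x, ...) {
  cat("<epi_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " set", if (nzchar(x$provenance))
        paste0(" (", x$provenance, ")"), "\n", sep = "")
  invisible(x)
}

#' Diffusion-weighted EPI series
#'
#' A 4-D stack of diffusion-weighted volumes with its gradient table and
#' phase-encoding polarity. `polarity` records the blip direction of the
#' acquisition: susceptibility off-resonance displaces tissue along the PE
#' axis in opposite directions for `"up"` and `"down"`; `"combined"` marks
#' data produced by combining a corrected pair.
#'
#' @param data 4-D numeric array (x, y, z, q).
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs 3 x q matrix of gradient directions (unit norm where b > 0).
#' @param polarity one of `"up"`, `"down"`, `"combined"`.
#' @param pe_axis phase-encoding axis (1, 2 or 3).
#' @param voxel_size voxel edge lengths in mm.
#' @return An object of class `epi_series`.
#' @export
epi_series <- function(data, bvals, bvecs, polarity, pe_axis,
                       voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    epi_stop("series data must be a 4-D array", "epi_format_error")
  q <- dim(data)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (length(bvals) != q)
    epi_stop(sprintf("bval count (%d) does not match volume count (%d)",
                     length(bvals), q), "epi_format_error")
  if (ncol(bvecs) != q || nrow(bvecs) != 3L)
    epi_stop(sprintf("bvec table must be 3 x %d, got %d x %d",
                     q, nrow(bvecs), ncol(bvecs)), "epi_format_error")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-3
  if (any(bad))
    epi_stop(sprintf("bvecs for b>0 volumes must have unit norm (volumes: %s)",
                     paste(which(bad), collapse = ", ")), "epi_format_error")
  polarity <- match.arg(polarity, c("up", "down", "combined"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  pe_axis <- as.integer(pe_axis)
  if (!pe_axis %in% 1:3)
    epi_stop("pe_axis must be 1, 2 or 3", "epi_argument_error")
  structure(list(data = data, bvals = bvals, bvecs = bvecs,
                 polarity = polarity, pe_axis = pe_axis,
                 voxel_size = as.numeric(voxel_size)),
            class = "epi_series")
}

#' @export
print.epi_series <- function(x, ...) {
  cat("<epi_series> ", paste(dim(x$data), collapse = " x "),
      ", polarity ", x$polarity, ", PE axis ", x$pe_axis,
      ", b-values ", paste(sort(unique(x$bvals)), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Extract one volume of a series
#' @param series an [epi_series()].
#' @param q volume index.
#' @return An [epi_volume()].
#' @export
series_volume <- function(series, q) {
  epi_volume(series$data[, , , q, drop = TRUE],
             voxel_size = series$voxel_size, pe_axis = series$pe_axis)
}

# ---------------------------------------------------------------------------
# Readers / writers. NIfTI-1 via RNifti; FSL-dialect .bval/.bvec text;
# JSON sidecar {"polarity": "up"|"down"|"combined", "pe_axis": 0|1|2}.

write_nifti_array <- function(arr, voxel_size, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(arr)) - 3L))[
    seq_along(dim(arr))]
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a diffusion EPI series from NIfTI + bval/bvec + JSON sidecar
#'
#' Accepts the FSL gradient-table dialect (bvec as 3 rows by q columns);
#' a q-by-3 table is detected and transposed. The sidecar must provide the
#' keys `polarity` and `pe_axis` (0-based on disk).
#'
#' @param image_path 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param bval_path,bvec_path whitespace-separated text gradient tables.
#' @param sidecar_path JSON sidecar.
#' @return An [epi_series()].
#' @export
read_series <- function(image_path, bval_path, bvec_path, sidecar_path) {
  img <- RNifti::readNifti(image_path)
  if (length(dim(img)) != 4L)
    epi_stop(sprintf("%s: expected a 4-D NIfTI, got %d dims",
                     image_path, length(dim(img))), "epi_format_error")
  vox <- RNifti::pixdim(img)[1:3]
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L && ncol(bvecs) != 3L)
    epi_stop(sprintf("%s: bvec table must have 3 rows (or 3 columns)",
                     bvec_path), "epi_format_error")
  if (nrow(bvecs) != 3L) bvecs <- t(bvecs)
  q <- dim(img)[4]
  if (length(bvals) != q)
    epi_stop(sprintf("%s: %d b-values for %d volumes", bval_path,
                     length(bvals), q), "epi_format_error")
  if (ncol(bvecs) != q)
    epi_stop(sprintf("%s: %d directions for %d volumes", bvec_path,
                     ncol(bvecs), q), "epi_format_error")
  side <- jsonlite::read_json(sidecar_path)
  for (key in c("polarity", "pe_axis")) {
    if (is.null(side[[key]]))
      epi_stop(sprintf("%s: missing required sidecar key '%s'",
                       sidecar_path, key), "epi_config_error")
  }
  epi_series(array(as.numeric(img), dim(img)), bvals, bvecs,
             polarity = side$polarity,
             pe_axis = as.integer(side$pe_axis) + 1L,
             voxel_size = vox)
}

#' Write a diffusion EPI series
#'
#' Image data are stored at 32-bit float precision; the sidecar records the
#' polarity and the 0-based phase-encoding axis.
#'
#' @param series an [epi_series()].
#' @inheritParams read_series
#' @return Invisibly, the four paths written.
#' @export
write_series <- function(series, image_path, bval_path, bvec_path,
                         sidecar_path) {
  stopifnot(inherits(series, "epi_series"))
  write_nifti_array(series$data, series$voxel_size, image_path)
  writeLines(paste(format(series$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  utils::write.table(series$bvecs, bvec_path, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(polarity = series$polarity,
                            pe_axis = series$pe_axis - 1L),
                       sidecar_path, auto_unbox = TRUE)
  invisible(c(image_path, bval_path, bvec_path, sidecar_path))
}

#' Read / write a scalar volume as NIfTI
#'
#' @param path NIfTI file.
#' @param pe_axis optional 1-based phase-encoding axis to attach.
#' @return `read_volume` returns an [epi_volume()].
#' @export
read_volume <- function(path, pe_axis = NA_integer_) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    epi_stop(sprintf("%s: expected a 3-D NIfTI", path), "epi_format_error")
  epi_volume(array(as.numeric(img), dim(img)),
             voxel_size = RNifti::pixdim(img)[1:3], pe_axis = pe_axis)
}

#' @rdname read_volume
#' @param vol an [epi_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "epi_volume"))
  write_nifti_array(vol$data, vol$voxel_size, path)
  invisible(path)
}

#' Read / write a displacement field map
#'
#' The field is stored as a scalar NIfTI in mm of displacement along the
#' phase-encoding axis, with a JSON sidecar `{"pe_axis": 0|1|2}` (0-based
#' on disk).
#'
#' @param nifti_path scalar NIfTI of displacements in mm.
#' @param sidecar_path JSON sidecar naming the PE axis.
#' @return `read_field_map` returns a [field_map()].
#' @export
read_field_map <- function(nifti_path, sidecar_path) {
  img <- RNifti::readNifti(nifti_path)
  side <- jsonlite::read_json(sidecar_path)
  if (is.null(side$pe_axis))
    epi_stop(sprintf("%s: missing sidecar key 'pe_axis'", sidecar_path),
             "epi_config_error")
  field_map(array(as.numeric(img), dim(img)),
            pe_axis = as.integer(side$pe_axis) + 1L,
            voxel_size = RNifti::pixdim(img)[1:3])
}

#' @rdname read_field_map
#' @param field a [field_map()].
#' @export
write_field_map <- function(field, nifti_path, sidecar_path) {
  stopifnot(inherits(field, "field_map"))
  write_nifti_array(field$b_mm, field$voxel_size, nifti_path)
  jsonlite::write_json(list(pe_axis = field$pe_axis - 1L), sidecar_path,
                       auto_unbox = TRUE)
  invisible(c(nifti_path, sidecar_path))
}
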