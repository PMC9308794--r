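#' Volumetric CT scan
#'
#' Container for a 3D grid of CT numbers (Hounsfield units) with per-axis
#' voxel spacing and the acquisition time relative to contrast injection.
#' Voxel indices are 1-based \code{(i, j, k)}; world units are mm, with the
#' centre of voxel \code{(i, j, k)} at \code{(i - 0.5) * spacing} mm.
#'
#' @param data 3D numeric array of CT numbers (HU).
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param acquisition_time seconds from injection start (>= 0), or \code{NA}.
#' @param label free-text label, e.g. \code{"V1"} or \code{"V2"}.
#' @return An object of class \code{volume_scan}.
#' @export
volume_scan <- function(data, spacing, acquisition_time = NA_real_, label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: data must be a 3D array")
  if (any(dim(data) < 1L)) stop("data shape must have three positive dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  acquisition_time <- as.numeric(acquisition_time)
  if (length(acquisition_time) != 1L ||
      (!is.na(acquisition_time) && acquisition_time < 0))
    stop("acquisition_time must be a single value >= 0 (seconds) or NA")
  structure(list(data = data, spacing = spacing,
                 acquisition_time = acquisition_time,
                 label = as.character(label)[1]),
            class = "volume_scan")
}

#' @export
print.volume_scan <- function(x, ...) {
  cat(sprintf("<volume_scan%s> %s, spacing %s mm, t = %s s, HU range [%g, %g]\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              format(x$acquisition_time),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary voxel mask
#'
#' A binary labelling (myocardium, aorta, plug, territory member) aligned to
#' a \code{\link{volume_scan}} grid: same shape, same spacing.
#'
#' @param data 3D array coercible to logical.
#' @param spacing numeric length-3 voxel size in mm.
#' @return An object of class \code{fpa_mask}.
#' @export
new_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("not a 3D volume: mask data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = spacing), class = "fpa_mask")
}

#' @export
print.fpa_mask <- function(x, ...) {
  cat(sprintf("<fpa_mask> %s, spacing %s mm, %d foreground voxels\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              sum(x$data)))
  invisible(x)
}

check_aligned <- function(v, m, what = "mask") {
  if (!identical(dim(v$data), dim(m$data)))
    stop(what, " grid shape does not match the volume")
  if (max(abs(v$spacing - m$spacing)) > 1e-5)  # NIfTI stores pixdim as float32
    stop(what, " spacing does not match the volume")
  invisible(TRUE)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a volume (NIfTI) with its acquisition metadata
#'
#' Reads a single-file NIfTI volume (\code{.nii} / \code{.nii.gz}). Voxel
#' spacing is taken from the NIfTI header; the acquisition time and label,
#' which NIfTI does not carry, are read from an optional JSON sidecar with
#' the same stem (\code{scan.nii.gz} -> \code{scan.json}).
#'
#' @param path file path to a \code{.nii}/\code{.nii.gz} volume.
#' @return A \code{\link{volume_scan}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("not a 3D volume: ", path, " has ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid voxel spacing in NIfTI header of ", path)
  t_acq <- NA_real_; label <- ""
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$acquisition_time))
      t_acq <- as.numeric(meta$acquisition_time)
    label <- as.character(meta$label %||% "")
  }
  volume_scan(array(as.numeric(img), dim = d), sp[1:3], t_acq, label)
}

#' Write a volume to NIfTI (plus JSON sidecar)
#'
#' Integer-valued grids are stored as \code{int16} so HU values round-trip
#' bit-exactly; anything else is stored as \code{double}. When the scan has
#' an acquisition time or label, a JSON sidecar is written alongside.
#'
#' @param v a \code{\link{volume_scan}}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_scan"))
  ints <- all(v$data == round(v$data)) && min(v$data) >= -32768 && max(v$data) <= 32767
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = if (ints) "int16" else "double")
  if (!is.na(v$acquisition_time) || nzchar(v$label)) {
    meta <- list(label = v$label)
    if (!is.na(v$acquisition_time)) meta$acquisition_time <- v$acquisition_time
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read / write a binary mask (NIfTI, 8-bit 0/1)
#'
#' @param path file path to a \code{.nii}/\code{.nii.gz} mask.
#' @return \code{read_mask}: an \code{\link{new_mask}} object.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("not a 3D volume: ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid voxel spacing in NIfTI header of ", path)
  new_mask(array(as.numeric(img) != 0, dim = d), sp[1:3])
}

#' @rdname read_mask
#' @param m an \code{fpa_mask}.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "fpa_mask"))
  img <- RNifti::asNifti(array(as.integer(m$data), dim = dim(m$data)))
  RNifti::pixdim(img) <- m$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Voxel volume in millilitres
#'
#' Product of the three voxel spacings (mm^3) divided by 1000.
#'
#' @param v a \code{\link{volume_scan}} or \code{fpa_mask}.
#' @return scalar voxel volume in mL.
#' @examples
#' v <- volume_scan(array(0, c(4, 4, 4)), c(0.43, 0.43, 0.50))
#' voxel_volume_ml(v)  # 9.245e-05 mL
#' @export
voxel_volume_ml <- function(v) {
  stopifnot(inherits(v, "volume_scan") || inherits(v, "fpa_mask"))
  prod(v$spacing) / 1000
}
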