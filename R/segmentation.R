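#' Volumetric region growing
#'
#' Grows the maximal connected set of voxels containing \code{seed} whose CT
#' number differs from the seed voxel's CT number by at most
#' \code{tolerance} HU. The inclusion criterion uses the fixed seed value,
#' not a running region mean, so the result is order-independent and
#' deterministic. Used to delineate the aortic blood pool and the
#' lateral-wall sample of the unenhanced myocardium.
#'
#' @param v a \code{\link{volume_scan}}.
#' @param seed 1-based voxel index \code{(i, j, k)} inside the grid.
#' @param tolerance inclusion half-width in HU (>= 0).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return An \code{\link{new_mask}} containing the grown region (always
#'   includes the seed voxel).
#' @export
region_grow <- function(v, seed, tolerance, connectivity = 6) {
  stopifnot(inherits(v, "volume_scan"))
  d <- dim(v$data)
  if (!is_index3(seed, d)) stop("seed outside grid: must be a voxel index inside ",
                                paste(d, collapse = "x"))
  seed <- as.integer(seed)
  if (!isTRUE(tolerance >= 0)) stop("tolerance must be a single HU value >= 0")
  connectivity <- match.arg(as.character(connectivity), c("6", "26"))
  offs <- neighbour_offsets(connectivity == "26")
  n_off <- nrow(offs)

  hv <- v$data[seed[1], seed[2], seed[3]]
  accept <- abs(v$data - hv) <= tolerance
  visited <- array(FALSE, d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, nrow = 1)
  nxy <- d[1] * d[2]

  while (nrow(frontier) > 0) {
    nf <- nrow(frontier)
    cand <- frontier[rep(seq_len(nf), each = n_off), , drop = FALSE] +
      offs[rep(seq_len(n_off), times = nf), , drop = FALSE]
    keep <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
            cand[, 2] >= 1L & cand[, 2] <= d[2] &
            cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * nxy
    first <- !duplicated(lin)
    cand <- cand[first, , drop = FALSE]; lin <- lin[first]
    ok <- !visited[lin] & accept[lin]
    cand <- cand[ok, , drop = FALSE]; lin <- lin[ok]
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- cand
  }
  new_mask(visited, v$spacing)
}

# linear indices of the discrete ball of radius_mm about a voxel index,
# clipped to the grid
sphere_indices <- function(center, radius_mm, spacing, d) {
  offs <- ball_offsets(radius_mm, spacing)
  co <- sweep(offs, 2, as.integer(center), "+")
  keep <- co[, 1] >= 1L & co[, 1] <= d[1] &
          co[, 2] >= 1L & co[, 2] <= d[2] &
          co[, 3] >= 1L & co[, 3] <= d[3]
  co <- co[keep, , drop = FALSE]
  co[, 1] + (co[, 2] - 1L) * d[1] + (co[, 3] - 1L) * d[1] * d[2]
}

#' Mean CT number over a spherical ROI
#'
#' Arithmetic mean of HU over the discrete ball of radius \code{radius_mm}
#' about \code{center} (voxel whose world distance from the centre voxel is
#' at most the radius). The ROI is optionally clipped to a mask (e.g. the
#' myocardium segmentation transferred from V2) and optionally trimmed to
#' voxels within \code{trim_hu} of the ROI median, a robust guard against
#' contamination by neighbouring structures when the scan has moved.
#'
#' @param v a \code{\link{volume_scan}}.
#' @param center 1-based voxel index of the ROI centre.
#' @param radius_mm ROI radius in mm (> 0).
#' @param mask optional \code{fpa_mask}; the ROI is clipped to it.
#' @param trim_hu optional HU half-width for median trimming (NULL = plain mean).
#' @return mean HU over the ROI voxels, with attribute \code{n_voxels}.
#' @export
sample_roi_mean <- function(v, center, radius_mm, mask = NULL, trim_hu = NULL) {
  stopifnot(inherits(v, "volume_scan"))
  d <- dim(v$data)
  if (!is_index3(center, d)) stop("ROI center outside grid")
  if (!isTRUE(radius_mm > 0)) stop("ROI radius must be > 0 mm")
  lin <- sphere_indices(as.integer(center), radius_mm, v$spacing, d)
  if (!is.null(mask)) {
    check_aligned(v, mask, "ROI mask")
    lin <- lin[mask$data[lin]]
  }
  if (!length(lin)) stop("ROI contains no voxels after clipping")
  vals <- v$data[lin]
  if (!is.null(trim_hu)) {
    med <- median(vals)
    vals <- vals[abs(vals - med) <= trim_hu]
  }
  structure(mean(vals), n_voxels = length(vals))
}

#' Aortic blood-pool enhancement
#'
#' Mean CT number over the region grown from a seed placed in the aortic
#' blood pool. A plausibility window (\code{hu_range}) guards against a
#' misplaced seed: if the grown-region mean falls outside it, an error is
#' raised rather than a silently wrong input-function value returned.
#'
#' @inheritParams region_grow
#' @param hu_range optional length-2 numeric; grown-region means outside
#'   this HU window are treated as a misplaced seed.
#' @return mean HU of the grown region, with attribute \code{n_voxels}.
#' @export
aortic_enhancement <- function(v, seed, tolerance = 150, connectivity = 6,
                               hu_range = NULL) {
  m <- region_grow(v, seed, tolerance, connectivity)
  vals <- v$data[m$data]
  out <- mean(vals)
  if (!is.null(hu_range) && (out < hu_range[1] || out > hu_range[2]))
    stop(sprintf("grown region mean %.1f HU outside the expected blood-pool range [%g, %g]: seed likely misplaced",
                 out, hu_range[1], hu_range[2]))
  structure(out, n_voxels = length(vals))
}

#' Morphological erosion of a mask by a spherical element
#'
#' A foreground voxel is kept when the whole ball of radius \code{radius_mm}
#' about it lies in the foreground. Used to shrink the V2-grown aortic mask
#' to a core that still samples blood pool after inter-scan displacement up
#' to the erosion radius.
#'
#' @param m an \code{fpa_mask}.
#' @param radius_mm erosion radius in mm.
#' @return the eroded \code{fpa_mask}.
#' @export
erode_mask <- function(m, radius_mm) {
  stopifnot(inherits(m, "fpa_mask"))
  d <- dim(m$data)
  fg <- which(m$data)
  if (!length(fg)) return(m)
  co <- arrayInd(fg, d)
  offs <- ball_offsets(radius_mm, m$spacing)
  keep <- rep(TRUE, nrow(co))
  nxy <- d[1] * d[2]
  for (r in seq_len(nrow(offs))) {
    ni <- co[, 1] + offs[r, 1]; nj <- co[, 2] + offs[r, 2]; nk <- co[, 3] + offs[r, 3]
    inb <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    ok <- inb
    ok[inb] <- m$data[ni[inb] + (nj[inb] - 1L) * d[1] + (nk[inb] - 1L) * nxy]
    keep <- keep & ok
    if (!any(keep)) break
  }
  out <- array(FALSE, d)
  out[fg[keep]] <- TRUE
  new_mask(out, m$spacing)
}
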