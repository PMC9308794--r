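#' Scalar normalizers of the first-pass perfusion equation
#'
#' @param c_in mean incoming aortic blood-pool contrast enhancement, in HU
#'   above the blood baseline (> 0). Because iodine mass and enhancement are
#'   related by one physical constant that cancels in ratio, the input
#'   function is carried in HU end to end.
#' @param dt_s time between the V1 and V2 acquisitions in seconds (> 0);
#'   converted to minutes only inside the perfusion math.
#' @param rho myocardial tissue density in g/mL (default 1.053).
#' @return An object of class \code{perfusion_params}.
#' @export
perfusion_params <- function(c_in, dt_s, rho = 1.053) {
  if (!isTRUE(c_in > 0)) stop("non-positive input enhancement: c_in must be > 0")
  if (!isTRUE(dt_s > 0)) stop("dt_s must be > 0 seconds")
  if (!isTRUE(rho > 0)) stop("rho must be > 0 g/mL")
  structure(list(c_in = c_in, dt_s = dt_s, rho = rho), class = "perfusion_params")
}

#' Incoming aortic contrast enhancement between V1 and V2
#'
#' Default convention: the average of the V1 and V2 aortic blood-pool CT
#' numbers above a baseline, the baseline defaulting to the V1 value itself
#' (V1 sits at the base of the aortic enhancement). Under the default this
#' equals \code{(ao_v2 - ao_v1) / 2}.
#'
#' @param ao_v1,ao_v2 mean aortic blood-pool CT numbers (HU) of V1 and V2.
#' @param baseline blood-pool baseline HU; defaults to \code{ao_v1}.
#' @return C_IN in HU above baseline (> 0, otherwise an error).
#' @export
compute_c_in <- function(ao_v1, ao_v2, baseline = NULL) {
  if (ao_v2 <= ao_v1)
    warning("ao_v2 <= ao_v1: not a valid first-pass pair (V2 should be at the aortic peak)")
  c_in <- (ao_v1 + ao_v2) / 2 - (baseline %||% ao_v1)
  if (!isTRUE(c_in > 0)) stop("non-positive input enhancement")
  c_in
}

#' Series-average incoming aortic enhancement
#'
#' When the full dynamic series is available, "the average aortic
#' enhancement between V1 and V2" can be read off the measured aortic
#' curve: the mean of the per-scan aortic blood-pool values from V1 to V2
#' inclusive, above the V1 baseline. For an enhancement curve that is
#' linear between V1 and V2 this equals the endpoint convention of
#' \code{\link{compute_c_in}}; for a curved first-pass upslope it tracks
#' the true time-average of the input function far more closely.
#'
#' @param aortic_hu per-scan aortic blood-pool means (HU); \code{NA} allowed
#'   outside the V1..V2 window.
#' @param v1_idx,v2_idx scan indices of V1 and V2.
#' @return C_IN in HU above the V1 baseline.
#' @export
compute_c_in_series <- function(aortic_hu, v1_idx, v2_idx) {
  stopifnot(v2_idx > v1_idx, v2_idx <= length(aortic_hu))
  w <- aortic_hu[v1_idx:v2_idx]
  if (anyNA(w)) stop("aortic curve has missing values between V1 and V2")
  c_in <- mean(w) - w[1]
  if (!isTRUE(c_in > 0)) stop("non-positive input enhancement")
  c_in
}

#' Integrated myocardial enhancement of a V1/V2 pair
#'
#' Summates the V2 myocardial enhancement over the segmented left-ventricular
#' myocardium and approximates the integrated V1 enhancement as the V1
#' lateral-wall mean times the myocardial voxel count, so no registration of
#' V1 is performed or required. The difference, per unit time, is the
#' enhancement-mass inflow rate \code{dmc_dt} (HU.mL/min).
#'
#' @param v2 the peak-enhancement \code{\link{volume_scan}}.
#' @param myo myocardium \code{fpa_mask} segmented from V2.
#' @param hu_v1_mean mean V1 myocardial enhancement (HU), e.g. from
#'   \code{\link{sample_roi_mean}} on the lateral wall.
#' @param dt_s V2 minus V1 acquisition time, seconds.
#' @return An \code{enhancement_summary}: \code{sum_hu_v2}, \code{n},
#'   \code{v_vox_ml}, \code{hu_v1_mean}, \code{delta_hu_avg}, \code{dmc_dt},
#'   \code{dt_s}.
#' @export
summarize_enhancement <- function(v2, myo, hu_v1_mean, dt_s) {
  stopifnot(inherits(v2, "volume_scan"))
  check_aligned(v2, myo, "myocardium mask")
  if (!isTRUE(dt_s > 0)) stop("dt_s must be > 0 seconds")
  n <- sum(myo$data)
  if (n == 0) stop("empty myocardium mask")
  sum_hu_v2 <- sum(v2$data[myo$data])
  v_vox <- voxel_volume_ml(v2)
  delta_hu_avg <- sum_hu_v2 / n - hu_v1_mean
  dmc_dt <- (sum_hu_v2 - n * hu_v1_mean) * v_vox / (dt_s / 60)
  if (delta_hu_avg <= 0)
    warning("average myocardial enhancement change <= 0 HU: not a valid first-pass pair")
  structure(list(sum_hu_v2 = sum_hu_v2, n = n, v_vox_ml = v_vox,
                 hu_v1_mean = hu_v1_mean, delta_hu_avg = delta_hu_avg,
                 dmc_dt = dmc_dt, dt_s = dt_s),
            class = "enhancement_summary")
}

#' Whole-myocardium average perfusion
#'
#' One-compartment first-pass estimate: the enhancement-mass inflow rate
#' normalized by the incoming aortic enhancement and the tissue mass,
#' \deqn{P_{AVG} = M_T^{-1} C_{IN}^{-1} \, dM_C/dt,}
#' with \eqn{M_T = n \, v_{vox} \, \rho}. Algebraically equal to
#' \code{delta_hu_avg / ((dt_s/60) * c_in * rho)}.
#'
#' @param summary an \code{\link{summarize_enhancement}} result.
#' @param params a \code{\link{perfusion_params}}.
#' @return average perfusion in mL/min/g.
#' @export
average_perfusion <- function(summary, params) {
  stopifnot(inherits(summary, "enhancement_summary"),
            inherits(params, "perfusion_params"))
  m_t <- summary$n * summary$v_vox_ml * params$rho
  if (!isTRUE(m_t > 0)) stop("non-positive tissue mass")
  summary$dmc_dt / (params$c_in * m_t)
}

perfusion_result <- function(p_avg, map, m_t, method, spacing, details = list()) {
  structure(list(p_avg = p_avg, map = map, m_t = m_t,
                 method = method, spacing = spacing, details = details),
            class = "perfusion_result")
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("<perfusion_result %s> P_AVG = %.3f mL/min/g over %d voxels (M_T = %.1f g)\n",
              x$method, x$p_avg, sum(!is.na(x$map)), x$m_t))
  invisible(x)
}

#' Motion-immune voxel-wise perfusion map
#'
#' Subtracts the scalar V1 myocardial mean from each V2 voxel
#' (\eqn{\Delta HU^* }), normalizes by the average enhancement change to
#' form a perfusion ratio map with mask-mean exactly 1, and scales by the
#' average perfusion: \eqn{P_{MI} = P_{AVG} \cdot \Delta HU^* / \Delta HU_{AVG}}.
#' V1 enters only through two scalars, so any inter-scan motion that
#' preserves the lateral-wall sample leaves the map unchanged.
#'
#' @inheritParams summarize_enhancement
#' @param p_avg average perfusion (mL/min/g), from \code{\link{average_perfusion}}.
#' @param rho tissue density g/mL (for the reported tissue mass).
#' @return A \code{perfusion_result} with method \code{"MI"}; \code{map} is a
#'   3D array in mL/min/g, \code{NA} outside the myocardium mask.
#' @export
mi_map <- function(v2, myo, hu_v1_mean, p_avg, rho = 1.053) {
  stopifnot(inherits(v2, "volume_scan"))
  check_aligned(v2, myo, "myocardium mask")
  sel <- myo$data
  n <- sum(sel)
  if (n == 0) stop("empty myocardium mask")
  delta_star <- v2$data[sel] - hu_v1_mean
  delta_avg <- mean(delta_star)
  if (delta_avg == 0) stop("degenerate enhancement: average enhancement change is zero")
  map <- array(NA_real_, dim(v2$data))
  map[sel] <- p_avg * delta_star / delta_avg
  perfusion_result(p_avg, map, n * voxel_volume_ml(v2) * rho, "MI", v2$spacing,
                   details = list(delta_hu_avg = delta_avg, n = n,
                                  hu_v1_mean = hu_v1_mean))
}

#' Motion-susceptible voxel-wise perfusion map
#'
#' The classical two-volume subtraction estimator: the V2 myocardium mask is
#' transferred to V1, V1 is subtracted voxel-by-voxel from V2, and the
#' average perfusion from the same normalizers scales the resulting ratio
#' map. Correct only when V1 and V2 are spatially aligned; inter-scan motion
#' corrupts the voxel-wise difference.
#'
#' @param v1,v2 \code{\link{volume_scan}}s on identical grids.
#' @param myo myocardium \code{fpa_mask} segmented from V2.
#' @param params a \code{\link{perfusion_params}}.
#' @return A \code{perfusion_result} with method \code{"MS"}.
#' @export
ms_map <- function(v1, v2, myo, params) {
  stopifnot(inherits(v1, "volume_scan"), inherits(v2, "volume_scan"),
            inherits(params, "perfusion_params"))
  if (!identical(dim(v1$data), dim(v2$data)))
    stop("V1 and V2 must be on identical grids")
  if (max(abs(v1$spacing - v2$spacing)) > 1e-9)
    stop("V1 and V2 must have identical spacing")
  check_aligned(v2, myo, "myocardium mask")
  sel <- myo$data
  n <- sum(sel)
  if (n == 0) stop("empty myocardium mask")
  delta <- v2$data[sel] - v1$data[sel]
  delta_avg <- mean(delta)
  if (delta_avg == 0) stop("degenerate enhancement: average enhancement change is zero")
  if (delta_avg < 0)
    warning("average myocardial enhancement change < 0 HU: not a valid first-pass pair")
  p_avg <- delta_avg / ((params$dt_s / 60) * params$c_in * params$rho)
  map <- array(NA_real_, dim(v2$data))
  map[sel] <- p_avg * delta / delta_avg
  perfusion_result(p_avg, map, n * voxel_volume_ml(v2) * params$rho, "MS",
                   v2$spacing,
                   details = list(delta_hu_avg = delta_avg, n = n))
}

#' Two-volume first-pass perfusion pipeline
#'
#' Runs the full measurement on a V1/V2 pair: aortic blood-pool enhancement
#' of both scans, the V1 lateral-wall mean, the input-function normalizer
#' C_IN, and the requested voxel-wise perfusion map.
#'
#' The V2 blood pool is delineated by seeded region growing. For V1 the
#' blood pool has little contrast against surrounding tissue, so by default
#' its mean is sampled through the V2-grown aortic mask eroded by
#' \code{erode_mm} (robust to inter-scan displacement smaller than the
#' erosion radius); set \code{v1_aorta = "region_grow"} to grow a region on
#' V1 from an operator-placed \code{v1_aorta_seed} instead.
#'
#' @param v1,v2 \code{\link{volume_scan}}s with acquisition times set.
#' @param myo myocardium mask segmented from V2.
#' @param aorta_seed voxel index in the V2 aortic blood pool.
#' @param roi_center voxel index of the V1 lateral-wall ROI centre.
#' @param roi_radius_mm lateral-wall ROI radius (default 5 mm).
#' @param method \code{"mi"} (motion-immune) or \code{"ms"} (motion-susceptible).
#' @param rho tissue density g/mL.
#' @param aorta_tolerance region-growing tolerance for the blood pool, HU.
#' @param v1_aorta \code{"eroded_v2_mask"} or \code{"region_grow"}.
#' @param erode_mm erosion radius for the V1 blood-pool core, mm.
#' @param v1_aorta_seed,v1_aorta_tolerance seed/tolerance for
#'   \code{v1_aorta = "region_grow"} (default: the V2 seed/tolerance).
#' @param trim_hu robust HU trim for the lateral-wall ROI (NULL disables).
#'   The default (15 HU) rejects voxels a displaced V1 would sample from
#'   enhanced cavity blood or extra-cardiac tissue while remaining a
#'   symmetric (hence unbiased) truncation of the CT noise.
#' @param clip_roi_to_mask clip the lateral-wall ROI to \code{myo}.
#' @param c_in override the input-function normalizer (HU); when NULL it is
#'   measured as \code{compute_c_in(ao_v1, ao_v2, c_in_baseline)}.
#' @param c_in_baseline baseline for \code{\link{compute_c_in}}.
#' @return A \code{perfusion_result}; \code{$details} carries \code{c_in},
#'   \code{ao_v1}, \code{ao_v2}, \code{hu_v1_mean}, \code{dt_s},
#'   \code{delta_hu_avg} and \code{n}.
#' @export
fpa_perfusion <- function(v1, v2, myo, aorta_seed, roi_center,
                          roi_radius_mm = 5, method = c("mi", "ms"),
                          rho = 1.053, aorta_tolerance = 150,
                          v1_aorta = c("eroded_v2_mask", "region_grow"),
                          erode_mm = 5, v1_aorta_seed = NULL,
                          v1_aorta_tolerance = NULL, trim_hu = 15,
                          clip_roi_to_mask = TRUE,
                          c_in = NULL, c_in_baseline = NULL) {
  method <- match.arg(method)
  v1_aorta <- match.arg(v1_aorta)
  dt_s <- v2$acquisition_time - v1$acquisition_time
  if (is.na(dt_s) || dt_s <= 0)
    stop("V1/V2 acquisition times must be set with t(V2) > t(V1)")

  ao2_mask <- region_grow(v2, aorta_seed, aorta_tolerance)
  ao_v2 <- mean(v2$data[ao2_mask$data])
  if (v1_aorta == "eroded_v2_mask") {
    core <- erode_mask(ao2_mask, erode_mm)
    if (!sum(core$data)) stop("aortic mask vanished under erosion; reduce erode_mm")
    ao_v1 <- mean(v1$data[core$data])
  } else {
    ao_v1 <- as.numeric(aortic_enhancement(
      v1, v1_aorta_seed %||% aorta_seed,
      v1_aorta_tolerance %||% aorta_tolerance))
  }
  c_in <- c_in %||% compute_c_in(ao_v1, ao_v2, c_in_baseline)
  params <- perfusion_params(c_in, dt_s, rho)

  hu_v1_mean <- as.numeric(sample_roi_mean(
    v1, roi_center, roi_radius_mm,
    mask = if (clip_roi_to_mask) myo else NULL, trim_hu = trim_hu))

  res <- if (method == "mi") {
    s <- summarize_enhancement(v2, myo, hu_v1_mean, dt_s)
    mi_map(v2, myo, hu_v1_mean, average_perfusion(s, params), rho)
  } else {
    ms_map(v1, v2, myo, params)
  }
  res$details <- c(res$details,
                   list(c_in = c_in, ao_v1 = ao_v1, ao_v2 = ao_v2,
                        dt_s = dt_s, rho = rho))
  if (method == "ms") res$details$hu_v1_mean <- hu_v1_mean
  res
}
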