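#' Configuration of the dynamic contrast-enhancement cardiac phantom
#'
#' Defines a labelled cardiac geometry (half-ellipsoidal left-ventricular
#' shell with cavity, cylindrical aorta), territory-wise ground-truth
#' perfusion, a first-pass arterial input function (AIF), acquisition
#' timing, CT noise and inter-scan rigid motion. Defaults emulate the
#' validation study the package is built around: ~52 g left ventricle,
#' twenty-scan dynamic series at one scan per beat (73 bpm), V1/V2 delay
#' close to 4.7 s, myocardial enhancement change of order 25 HU, hyperemic
#' anterior (LAD) perfusion swept from 3.5 down to 0.5 mL/min/g across five
#' stenosis grades (FFR 1.0 to 0.6) and resting lateral (LCx) perfusion of
#' 0.87 mL/min/g.
#'
#' @param ... named overrides of the defaults, nested lists merged field by
#'   field (e.g. \code{noise_sd_hu = 0}, \code{motion = list(max_translation_mm = 0)}).
#' @return A validated object of class \code{phantom_config}.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    dim = c(96L, 96L, 96L),
    spacing = c(1, 1, 1),            # mm
    rho = 1.053,                     # g/mL
    lv = list(outer_radii_mm = c(28, 28, 44), wall_mm = 10,
              base_z_mm = 70, target_mass_g = 52.1),
    aorta = list(radius_mm = 10, z_range_mm = c(72, 94)),
    baseline = list(tissue = 50, blood = 45, background = 30),  # HU
    perfusion = list(lcx_rest = 0.87,
                     lad_stress_by_ffr = c(`1` = 3.5, `0.9` = 2.75,
                                           `0.8` = 2, `0.7` = 1.25,
                                           `0.6` = 0.5),
                     subject_sdlog = 0.12, lcx_acq_sdlog = 0.05),
    aif = list(mode = "gamma", peak_hu = 400, alpha = 3,
               t0_s = 4.5, tp_s = 5.5,
               ramp_start_s = 4.932, ramp_end_s = 9.864,
               cavity_lead_s = 1.5, washout_margin_s = 8),
    scans = list(n = 20L, interval_s = 0.822, start_s = 0),
    noise_sd_hu = 10,
    motion = list(max_translation_mm = 4, max_rotation_deg = 3),
    study = list(n_subjects = 6L, ffr_grades = c(1, 0.9, 0.8, 0.7, 0.6)),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$dim) == 3, all(cfg$dim >= 8),
            length(cfg$spacing) == 3, all(cfg$spacing > 0),
            cfg$rho > 0, cfg$noise_sd_hu >= 0)
  lv <- cfg$lv
  if (!isTRUE(lv$wall_mm > 0)) stop("wall thickness must be > 0")
  if (lv$wall_mm >= min(lv$outer_radii_mm))
    stop("wall thickness must be smaller than the minor outer radius")
  if (any(unlist(cfg$perfusion[c("lcx_rest", "lad_stress_by_ffr")]) < 0))
    stop("perfusion values must be >= 0")
  tt <- scan_times(cfg)
  if (any(diff(tt) <= 0)) stop("scan times must be strictly increasing")
  if (cfg$aif$mode == "gamma" &&
      (cfg$aif$tp_s <= 0 || cfg$aif$alpha <= 0 || cfg$aif$peak_hu <= 0))
    stop("gamma-variate AIF requires positive peak, alpha and tp")
  if (cfg$aif$mode == "ramp" && cfg$aif$ramp_end_s <= cfg$aif$ramp_start_s)
    stop("linear-ramp AIF requires ramp_end_s > ramp_start_s")
  invisible(cfg)
}

scan_times <- function(cfg)
  cfg$scans$start_s + cfg$scans$interval_s * (seq_len(cfg$scans$n) - 1)

#' Arterial input function of the phantom
#'
#' Aortic contrast enhancement above the blood baseline, in HU, at time
#' \code{t} seconds after injection. Gamma-variate mode:
#' \eqn{A ((t - t_0)/t_p)^\alpha \exp(\alpha (1 - (t - t_0)/t_p))} for
#' \eqn{t > t_0}, else 0, peaking at exactly \eqn{A} when
#' \eqn{t = t_0 + t_p}. Linear-ramp mode rises linearly from 0 at
#' \code{ramp_start_s} to \eqn{A} at \code{ramp_end_s} and holds.
#'
#' @param t time(s) in seconds (vectorized).
#' @param cfg a \code{\link{phantom_config}}.
#' @return enhancement in HU above the blood baseline.
#' @export
aif <- function(t, cfg) {
  a <- cfg$aif
  if (a$mode == "gamma") {
    u <- (t - a$t0_s) / a$tp_s
    ifelse(u > 0, a$peak_hu * u^a$alpha * exp(a$alpha * (1 - u)), 0)
  } else if (a$mode == "ramp") {
    pmin(pmax((t - a$ramp_start_s) / (a$ramp_end_s - a$ramp_start_s), 0), 1) *
      a$peak_hu
  } else stop("unknown AIF mode: ", a$mode)
}

#' @rdname aif
#' @return \code{aif_integral}: the analytic integral
#'   \eqn{\int_0^t AIF(\tau) d\tau} in HU.s.
#' @export
aif_integral <- function(t, cfg) {
  a <- cfg$aif
  if (a$mode == "gamma") {
    u <- pmax((t - a$t0_s) / a$tp_s, 0)
    # int_0^u s^a e^{a(1-s)} tp ds = tp e^a Gamma(a+1)/a^(a+1) P(a+1, a u)
    a$peak_hu * a$tp_s * exp(a$alpha) * gamma(a$alpha + 1) /
      a$alpha^(a$alpha + 1) * pgamma(a$alpha * u, shape = a$alpha + 1, rate = 1)
  } else if (a$mode == "ramp") {
    w <- a$ramp_end_s - a$ramp_start_s
    tt <- pmax(t - a$ramp_start_s, 0)
    ifelse(tt <= w, a$peak_hu * tt^2 / (2 * w),
           a$peak_hu * w / 2 + a$peak_hu * (tt - w))
  } else stop("unknown AIF mode: ", a$mode)
}

aif_peak_time <- function(cfg) {
  if (cfg$aif$mode == "gamma") cfg$aif$t0_s + cfg$aif$tp_s else cfg$aif$ramp_end_s
}

#' Build the phantom geometry
#'
#' Voxelizes a half-ellipsoidal left-ventricular shell (apex pointing to
#' low z, base plane at \code{base_z_mm}) with blood-filled cavity, plus a
#' cylindrical aortic segment above the base, on the configured grid. The
#' myocardium is partitioned into two 180-degree angular sectors about the
#' long axis: the anterior half (low y) is the LAD territory, the lateral
#' half (high y) the LCx territory.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @return list with \code{labels} (0 background, 1 myocardium, 2 cavity,
#'   3 aorta), masks \code{myo} and \code{aorta}, integer \code{territory}
#'   array (1 LAD, 2 LCx, 0 elsewhere), \code{lv_mass_g}, and the grid
#'   world-coordinate vectors.
#' @export
build_geometry <- function(cfg) {
  d <- cfg$dim; sp <- cfg$spacing
  x <- (seq_len(d[1]) - 0.5) * sp[1]
  y <- (seq_len(d[2]) - 0.5) * sp[2]
  z <- (seq_len(d[3]) - 0.5) * sp[3]
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2
  lv <- cfg$lv
  ro <- lv$outer_radii_mm; ri <- ro - lv$wall_mm
  bz <- lv$base_z_mm
  if (bz > max(z) || bz - ro[3] < min(z) ||
      cx - ro[1] < 0 || cx + ro[1] > d[1] * sp[1] ||
      cy - ro[2] < 0 || cy + ro[2] > d[2] * sp[2])
    stop("LV geometry exceeds grid bounds")
  ao <- cfg$aorta
  if (ao$z_range_mm[2] > max(z) + sp[3] / 2)
    stop("aorta geometry exceeds grid bounds")

  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)

  qo <- ((X - cx) / ro[1])^2 + ((Y - cy) / ro[2])^2 + ((Z - bz) / ro[3])^2
  qi <- ((X - cx) / ri[1])^2 + ((Y - cy) / ri[2])^2 + ((Z - bz) / ri[3])^2
  below <- Z <= bz
  myo <- qo <= 1 & qi > 1 & below
  cavity <- qi <= 1 & below
  aorta <- (X - cx)^2 + (Y - cy)^2 <= ao$radius_mm^2 &
    Z >= ao$z_range_mm[1] & Z <= ao$z_range_mm[2]
  if (any(aorta & (myo | cavity))) stop("aorta overlaps the LV: adjust geometry")

  labels <- array(0L, d)
  labels[myo] <- 1L; labels[cavity] <- 2L; labels[aorta] <- 3L
  territory <- array(0L, d)
  territory[myo & Y < cy] <- 1L   # LAD, anterior
  territory[myo & Y >= cy] <- 2L  # LCx, lateral
  mass <- sum(myo) * prod(sp) / 1000 * cfg$rho
  if (abs(mass - lv$target_mass_g) > 0.05 * lv$target_mass_g)
    warning(sprintf("voxelized LV mass %.1f g deviates more than 5%% from the %.1f g target",
                    mass, lv$target_mass_g))
  list(labels = labels, myo = new_mask(myo, sp), aorta = new_mask(aorta, sp),
       territory = territory, lv_mass_g = mass, x = x, y = y, z = z,
       center_xy_mm = c(cx, cy))
}

# mid-wall world y at height z_mm, on the +/- y side
midwall_y <- function(cfg, z_mm, side = +1) {
  lv <- cfg$lv; ro <- lv$outer_radii_mm; ri <- ro - lv$wall_mm
  dz <- lv$base_z_mm - z_mm
  so <- sqrt(pmax(1 - (dz / ro[3])^2, 0))
  si <- sqrt(pmax(1 - (dz / ri[3])^2, 0))
  side * (ro[2] * so + ri[2] * si) / 2
}

snap_to_mask <- function(idx, mask) {
  if (mask$data[idx[1], idx[2], idx[3]]) return(idx)
  fg <- which(mask$data)
  co <- arrayInd(fg, dim(mask$data))
  w <- sweep(co, 2, as.numeric(idx))
  w <- sweep(w, 2, mask$spacing, "*")
  as.integer(co[which.min(rowSums(w^2)), ])
}

#' Operator landmarks derived from the phantom geometry
#'
#' Computes the voxel indices an operator would supply: a seed in the aortic
#' blood pool, the centre of the V1 lateral-wall ROI (mid-wall, lateral =
#' LCx side), and virtual tissue-plug centres in the proximal LAD (near the
#' base), distal LAD (near the apex) and LCx territories.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @param geom result of \code{\link{build_geometry}}.
#' @return list \code{aorta_seed}, \code{roi_center}, \code{roi_radius_mm},
#'   and \code{plug_centers} (named list of voxel indices).
#' @export
phantom_landmarks <- function(cfg, geom) {
  sp <- cfg$spacing
  c_mm <- geom$center_xy_mm
  bz <- cfg$lv$base_z_mm; cz <- cfg$lv$outer_radii_mm[3]
  seed <- world_to_vox(c(c_mm[1], c_mm[2], mean(cfg$aorta$z_range_mm)), sp)
  z_lat <- bz - 0.34 * cz            # upper-mid ventricle
  z_prox <- bz - 0.18 * cz
  z_dist <- bz - 0.73 * cz
  mk <- function(z_mm, side) {
    idx <- world_to_vox(c(c_mm[1], c_mm[2] + midwall_y(cfg, z_mm, side), z_mm), sp)
    snap_to_mask(pmin(pmax(idx, 1L), cfg$dim), geom$myo)
  }
  list(aorta_seed = seed,
       roi_center = mk(z_lat, +1), roi_radius_mm = 5,
       plug_centers = list(`proximal LAD` = mk(z_prox, -1),
                           `distal LAD` = mk(z_dist, -1),
                           `LCx` = mk(z_lat, +1)))
}

#' Ground-truth perfusion field for one acquisition
#'
#' Piecewise-constant field over the myocardium: the LAD (anterior) sector
#' carries the hyperemic perfusion of the stenosis grade, the LCx (lateral)
#' sector the resting perfusion.
#'
#' @param geom result of \code{\link{build_geometry}}.
#' @param lad_perfusion,lcx_perfusion territory perfusion in mL/min/g.
#' @return 3D array in mL/min/g (0 outside the myocardium).
#' @export
truth_field <- function(geom, lad_perfusion, lcx_perfusion) {
  f <- array(0, dim(geom$labels))
  f[geom$territory == 1L] <- lad_perfusion
  f[geom$territory == 2L] <- lcx_perfusion
  f
}

#' Forward contrast-enhancement model
#'
#' Simulates the noise-free scan at time \code{t}: aorta and cavity voxels
#' carry the blood baseline plus the AIF (the cavity leads the aorta by
#' \code{cavity_lead_s}, contrast reaching the ventricle before the aortic
#' root); each myocardial voxel accumulates contrast with no outflow,
#' \deqn{HU(v, t) = HU_{tissue} + \rho P(v) \int_0^t AIF(\tau) d\tau / 60.}
#' Times beyond the AIF peak plus \code{washout_margin_s} are refused: there
#' the no-outflow assumption would be violated and the model would need a
#' washout term.
#'
#' @param geom result of \code{\link{build_geometry}}.
#' @param field ground-truth perfusion array from \code{\link{truth_field}}.
#' @param cfg a \code{\link{phantom_config}}.
#' @param t scan time, seconds.
#' @param label scan label.
#' @return A \code{\link{volume_scan}} at acquisition time \code{t}.
#' @export
forward_volume <- function(geom, field, cfg, t, label = "") {
  if (t > aif_peak_time(cfg) + cfg$aif$washout_margin_s)
    stop(sprintf("t = %.2f s is beyond the no-washout validity window (peak %.2f s + margin %.2f s)",
                 t, aif_peak_time(cfg), cfg$aif$washout_margin_s))
  b <- cfg$baseline
  hu <- array(b$background, cfg$dim)
  blood_t <- b$blood + aif(t, cfg)
  cav_t <- b$blood + aif(t + cfg$aif$cavity_lead_s, cfg)
  hu[geom$labels == 3L] <- blood_t
  hu[geom$labels == 2L] <- cav_t
  sel <- geom$labels == 1L
  hu[sel] <- b$tissue + cfg$rho * field[sel] * aif_integral(t, cfg) / 60
  volume_scan(hu, cfg$spacing, acquisition_time = t, label = label)
}

#' Rigid motion of a volume
#'
#' Resamples the volume after moving the imaged object by a rigid transform:
#' rotation about the grid centre followed by a translation, both in world
#' mm. Inverse mapping with trilinear (default) or nearest-neighbour
#' interpolation; an integer-voxel translation under nearest-neighbour is an
#' exact voxel shift.
#'
#' @param v a \code{\link{volume_scan}}.
#' @param translation_mm length-3 translation in mm.
#' @param rotation either length-3 extrinsic x-y-z Euler angles in degrees
#'   or a 3x3 rotation matrix.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @param fill HU value for voxels pulled from outside the grid.
#' @return the moved \code{\link{volume_scan}} (same grid, spacing, time).
#' @export
apply_rigid_motion <- function(v, translation_mm = c(0, 0, 0),
                               rotation = c(0, 0, 0),
                               interpolation = c("linear", "nearest"),
                               fill = 0) {
  stopifnot(inherits(v, "volume_scan"))
  interpolation <- match.arg(interpolation)
  R <- if (is.matrix(rotation)) rotation else rot_euler_deg(rotation)
  out <- resample_rigid_cpp(as.numeric(v$data), as.integer(dim(v$data)),
                            as.numeric(v$spacing), R,
                            as.numeric(translation_mm),
                            if (interpolation == "nearest") 0L else 1L,
                            as.numeric(fill))
  dim(out) <- dim(v$data)
  # warn when clipping discards non-background signal at the grid boundary
  border <- c(v$data[c(1, dim(v$data)[1]), , ], v$data[, c(1, dim(v$data)[2]), ],
              v$data[, , c(1, dim(v$data)[3])])
  if (any(abs(border - fill) > 0.5) &&
      (any(abs(translation_mm) > 0) || !isTRUE(all.equal(R, diag(3)))))
    warning("object touches the grid boundary: rigid motion clips signal")
  volume_scan(out, v$spacing, v$acquisition_time, v$label)
}

draw_motion <- function(cfg) {
  mt <- cfg$motion
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  tr <- dir * runif(1, 0, mt$max_translation_mm)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, mt$max_rotation_deg)
  list(translation_mm = tr, rotation = rot_axis_angle(ax, ang),
       angle_deg = ang, magnitude_mm = sqrt(sum(tr^2)))
}

select_v1_v2 <- function(cfg) {
  tt <- scan_times(cfg)
  a <- aif(tt, cfg)
  # first scan reaching the aortic peak (tolerant to flat plateaus)
  v2 <- which(a >= max(a) * (1 - 1e-9))[1]
  base <- which(a <= 0.05 * max(a) & seq_along(a) < v2)
  if (!length(base)) stop("no baseline scan below 5% of the aortic peak; extend the scan series")
  list(v1 = max(base), v2 = v2, times = tt, aortic = a)
}

#' Generate a synthetic dynamic-CT perfusion study
#'
#' Simulates the full study design: \code{n_subjects} subjects, each imaged
#' at every stenosis grade with a dynamic series of \code{scans$n} volume
#' scans. Per scan, independent Gaussian CT noise is added and a random
#' rigid displacement (drawn up to the configured translation/rotation
#' bounds) is applied; motion is expressed relative to the V2 acquisition
#' frame, since the myocardium mask is segmented from V2 and only relative
#' pose matters. V1 and V2 are selected systematically from the noiseless
#' aortic enhancement curve: the last scan at or below 5\% of the peak, and
#' the scan at the peak. Per-subject perfusion heterogeneity is lognormal;
#' the stenosis grade sets the LAD (hyperemic) territory perfusion.
#'
#' Fully reproducible: all randomness derives from \code{seed}.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @param seed integer RNG seed (default \code{cfg$seed}).
#' @param keep_series keep all scans of each series (memory-heavy) instead
#'   of only V1/V2.
#' @param callback optional \code{function(acq)} called with each
#'   acquisition as it is generated; when supplied, acquisitions are not
#'   accumulated (streaming).
#' @param output_dir optional directory: writes V1/V2/mask NIfTI files, the
#'   ground-truth CSV and a config snapshot JSON.
#' Scans from V1 to V2 are always materialized so the per-scan aortic
#' blood-pool enhancement (\code{aortic_hu}, measured over the eroded aorta)
#' is available for the series-average input function; other scans are
#' materialized only with \code{keep_series}.
#'
#' @return list with \code{truth} (data.frame: subject, stenosis, territory,
#'   perfusion), \code{acquisitions} (list, unless streaming),
#'   \code{geometry}, \code{landmarks}, \code{v1_idx}, \code{v2_idx},
#'   \code{times}, \code{aortic_curve}.
#' @export
generate_study <- function(cfg = phantom_config(), seed = cfg$seed,
                           keep_series = FALSE, callback = NULL,
                           output_dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  geom <- build_geometry(cfg)
  lm <- phantom_landmarks(cfg, geom)
  sel <- select_v1_v2(cfg)
  # blood-pool core robust to inter-scan displacement: measures the per-scan
  # aortic enhancement that feeds the series-average input function
  ao_core <- erode_mask(geom$aorta, 5)
  grades <- cfg$study$ffr_grades
  n_sub <- cfg$study$n_subjects
  lad_tab <- cfg$perfusion$lad_stress_by_ffr

  subj_factor <- with_seed(seed, exp(rnorm(n_sub, 0, cfg$perfusion$subject_sdlog)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask(geom$myo, file.path(output_dir, "myocardium_mask.nii.gz"))
    snap <- unclass(cfg); snap$seed <- seed
    jsonlite::write_json(snap, file.path(output_dir, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  truth_rows <- list(); acqs <- list(); ai <- 0L
  for (i in seq_len(n_sub)) {
    for (j in seq_along(grades)) {
      ai <- ai + 1L
      acq_seed <- seed + 10000L * i + 100L * j
      lad_key <- as.character(grades[j])
      if (!lad_key %in% names(lad_tab))
        stop("no LAD perfusion configured for FFR grade ", lad_key)
      per <- with_seed(acq_seed, {
        lcx <- cfg$perfusion$lcx_rest * subj_factor[i] *
          exp(rnorm(1, 0, cfg$perfusion$lcx_acq_sdlog))
        list(lad = unname(lad_tab[lad_key]) * subj_factor[i], lcx = lcx,
             motions = lapply(seq_len(cfg$scans$n), function(k) draw_motion(cfg)))
      })
      field <- truth_field(geom, per$lad, per$lcx)
      mat_idx <- if (keep_series) seq_len(cfg$scans$n) else sel$v1:sel$v2
      series <- vector("list", cfg$scans$n)
      aortic_hu <- rep(NA_real_, cfg$scans$n)
      for (k in mat_idx) {
        vol <- forward_volume(geom, field, cfg, sel$times[k],
                              label = if (k == sel$v1) "V1"
                                      else if (k == sel$v2) "V2"
                                      else sprintf("scan%02d", k))
        if (k != sel$v2) {
          mv <- per$motions[[k]]
          vol <- apply_rigid_motion(vol, mv$translation_mm, mv$rotation,
                                    fill = cfg$baseline$background)
        }
        if (cfg$noise_sd_hu > 0) {
          vol$data <- vol$data + with_seed(acq_seed + k,
            array(rnorm(length(vol$data), 0, cfg$noise_sd_hu), dim(vol$data)))
        }
        aortic_hu[k] <- mean(vol$data[ao_core$data])
        series[[k]] <- vol
      }
      acq <- list(subject = i, stenosis = grades[j],
                  v1 = series[[sel$v1]], v2 = series[[sel$v2]],
                  myo = geom$myo, territory = geom$territory,
                  field = field,
                  truth = c(LAD = per$lad, LCx = per$lcx),
                  v1_motion = per$motions[[sel$v1]],
                  aortic_hu = aortic_hu, v1_idx = sel$v1, v2_idx = sel$v2,
                  times = sel$times,
                  series = if (keep_series) series else NULL)
      truth_rows[[ai]] <- data.frame(
        subject = i, stenosis = grades[j],
        territory = c("LAD", "LCx"),
        perfusion = c(per$lad, per$lcx))
      if (!is.null(output_dir)) {
        stem <- sprintf("subj%02d_ffr%03d", i, round(100 * grades[j]))
        write_volume(acq$v1, file.path(output_dir, paste0(stem, "_V1.nii.gz")))
        write_volume(acq$v2, file.path(output_dir, paste0(stem, "_V2.nii.gz")))
      }
      if (is.null(callback)) acqs[[ai]] <- acq else callback(acq)
    }
  }
  truth <- do.call(rbind, truth_rows)
  if (!is.null(output_dir)) {
    write.csv(truth, file.path(output_dir, "ground_truth.csv"), row.names = FALSE)
    lmx <- lm
    jsonlite::write_json(lmx, file.path(output_dir, "landmarks.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(truth = truth, acquisitions = if (is.null(callback)) acqs else NULL,
       geometry = geom, landmarks = lm, v1_idx = sel$v1, v2_idx = sel$v2,
       times = sel$times, aortic_curve = sel$aortic)
}
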