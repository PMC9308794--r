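# A coarse phantom (same physical geometry, 2 mm voxels) keeps routine
# tests fast; acceptance tests use the full-resolution default.
small_cfg <- function(...) {
  phantom_config(dim = c(48L, 48L, 48L), spacing = c(2, 2, 2), ...)
}

# one noise-free, motion-free acquisition for oracle-style checks
oracle_acquisition <- function(cfg = NULL, seed = 1) {
  cfg <- cfg %||% small_cfg(
    noise_sd_hu = 0,
    motion = list(max_translation_mm = 0, max_rotation_deg = 0),
    aif = list(mode = "ramp"),
    study = list(n_subjects = 1L, ffr_grades = 0.8),
    perfusion = list(subject_sdlog = 0, lcx_acq_sdlog = 0))
  st <- generate_study(cfg, seed = seed)
  list(cfg = cfg, st = st, acq = st$acquisitions[[1]], lmk = st$landmarks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

const_volume <- function(value, dims = c(8, 8, 8), spacing = c(1, 1, 1), ...) {
  volume_scan(array(value, dims), spacing, ...)
}

full_mask <- function(v) new_mask(array(TRUE, dim(v$data)), v$spacing)
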