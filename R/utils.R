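`%||%` <- function(a, b) if (is.null(a)) b else a

# voxel centre of 1-based index (i,j,k) in world mm
vox_to_world <- function(idx, spacing) (idx - 0.5) * spacing

world_to_vox <- function(x, spacing) as.integer(round(x / spacing + 0.5))

is_index3 <- function(x, d) {
  length(x) == 3L && all(is.finite(x)) && all(x == round(x)) &&
    all(x >= 1) && all(x <= d)
}

# 6- or 26-neighbourhood integer offsets
neighbour_offsets <- function(full26 = FALSE) {
  if (full26) {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    matrix(c(-1L, 0L, 0L, 1L, 0L, 0L,
             0L, -1L, 0L, 0L, 1L, 0L,
             0L, 0L, -1L, 0L, 0L, 1L),
           ncol = 3L, byrow = TRUE)
  }
}

# integer voxel offsets whose world displacement lies within radius_mm
ball_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- as.matrix(expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# rotation matrix from extrinsic x-y-z Euler angles in degrees
rot_euler_deg <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Rodrigues rotation about a unit axis
rot_axis_angle <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# evaluate expr under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
}

fpa_log <- function(...) {
  if (isTRUE(getOption("mifpa.quiet", FALSE))) return(invisible(NULL))
  message("[mifpa] ", ...)
}
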