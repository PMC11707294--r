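## Particle layer: de-duplication, geometry attachment, orientations,
## normal-direction projections, and missing-wedge 2D weighting.

#' Remove duplicate picks by spacing and score
#'
#' Picks are sorted by score descending (ties by (w, u, v) ascending) and
#' kept greedily if their flattened-space distance to every already-kept
#' pick is at least `min_spacing`; picks below `min_score` are then dropped
#' and the list truncated to `max_count`. The result is independent of the
#' input row order.
#'
#' @param picks data.frame with columns u, v, w, score.
#' @param min_spacing minimum allowed distance between kept picks, pixels.
#' @param min_score minimum score kept (default -Inf).
#' @param max_count maximum number of picks returned (default Inf).
#' @param metric `"3d"` (distance in (u,v,w)) or `"2d"` ((u,v) only).
#' @return Filtered data.frame.
#' @export
dedup_picks <- function(picks, min_spacing, min_score = -Inf,
                        max_count = Inf, metric = c("3d", "2d")) {
  metric <- match.arg(metric)
  stopifnot(all(c("u", "v", "w", "score") %in% names(picks)))
  df <- picks[order(-picks$score, picks$w, picks$u, picks$v), , drop = FALSE]
  cols <- if (metric == "3d") c("u", "v", "w") else c("u", "v")
  P <- as.matrix(df[, cols, drop = FALSE])
  n <- nrow(P)
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, length(cols))
  for (i in seq_len(n)) {
    if (nrow(kept) == 0 ||
        min(sqrt(colSums((t(kept) - P[i, ])^2))) >= min_spacing) {
      keep[i] <- TRUE
      kept <- rbind(kept, P[i, ])
    }
  }
  out <- df[keep & df$score >= min_score, , drop = FALSE]
  if (nrow(out) > max_count) out <- out[seq_len(max_count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach raw coordinates and membrane normals to flattened picks
#'
#' @param picks data.frame with flattened coordinates u, v, w.
#' @param flatmap a `flatmap`.
#' @return The picks with columns X, Y, Z (raw, via [flat_to_raw()]) and
#'   nx, ny, nz (interpolated unit normal). Picks outside the flatmap grid
#'   are dropped with a message.
#' @export
attach_geometry <- function(picks, flatmap) {
  nu <- dim(flatmap$S)[1]; nv <- dim(flatmap$S)[2]
  ok <- picks$u >= 0 & picks$u <= nu - 1 & picks$v >= 0 & picks$v <= nv - 1
  if (!all(ok))
    message("dropped ", sum(!ok), " pick(s) outside the flatmap grid")
  df <- picks[ok, , drop = FALSE]
  uvw <- as.matrix(df[, c("u", "v", "w")])
  raw <- flat_to_raw(flatmap, uvw)
  N <- bilin_grid(flatmap$N, uvw[, 1], uvw[, 2])
  N <- N / sqrt(rowSums(N^2))
  df$X <- raw[, 1]; df$Y <- raw[, 2]; df$Z <- raw[, 3]
  df$nx <- N[, 1]; df$ny <- N[, 2]; df$nz <- N[, 3]
  rownames(df) <- NULL
  df
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix of a membrane particle from normal and in-plane direction
#'
#' The user-labeled direction is usually not exactly perpendicular to the
#' normal, so its component perpendicular to the normal is used as the local
#' x-axis; the local z-axis is the normal; y = n x x. Columns of the result
#' are (vx, vy, n).
#'
#' @param normal unit membrane normal (3-vector).
#' @param direction in-plane direction vector, raw frame (need not be unit
#'   or exactly in-plane).
#' @return 3x3 proper rotation matrix with third column = normal.
#' @export
orientation_matrix <- function(normal, direction) {
  n <- normal / sqrt(sum(normal^2))
  vx <- direction - sum(direction * n) * n
  len <- sqrt(sum(vx^2))
  if (len < 1e-6 * sqrt(sum(direction^2)) || len == 0)
    stop("direction degenerate with normal")
  vx <- vx / len
  vy <- cross3(n, vx)
  cbind(vx, vy, n, deparse.level = 0)
}

#' Euler angles (ZYZ intrinsic, degrees) from a rotation matrix and back
#'
#' Convention: `R = Rz(rot) Ry(tilt) Rz(psi)` with angles in degrees,
#' matching STAR rlnAngleRot/Tilt/Psi; the third column of R depends only on
#' (rot, tilt), so the membrane normal fixes those two and psi is the
#' in-plane angle. Near tilt = 0 or 180 the decomposition is degenerate and
#' canonicalized to psi = 0.
#'
#' @param R 3x3 proper rotation.
#' @return `matrix_to_euler`: c(rot, tilt, psi) in degrees.
#' @export
matrix_to_euler <- function(R) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("not a proper rotation matrix")
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  st <- sin(tilt)
  if (st > 1e-9) {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {          # tilt ~ 0: R = Rz(rot + psi)
    rot <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {                      # tilt ~ 180: R = Rz(rot - psi) diag(-1,1,-1)
    rot <- atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

#' @rdname matrix_to_euler
#' @param rot,tilt,psi Euler angles in degrees.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  if (length(rot) == 3 && missing(tilt)) {
    tilt <- rot[2]; psi <- rot[3]; rot <- rot[1]
  }
  d <- pi / 180
  rotation_xyz(rz = psi * d) -> Rp
  rotation_xyz(ry = tilt * d) -> Rt
  rotation_xyz(rz = rot * d) -> Rr
  Rr %*% Rt %*% Rp
}

#' Deterministic in-plane basis perpendicular to a projection direction
#'
#' `e1 = normalize(d x z_hat)` when that cross product is non-degenerate,
#' otherwise `e1 = x_hat`; `e2 = d x e1`. (e1, e2, d) is right-handed. This
#' basis is shared between [project_particle()] and [extract_2dctf()] so
#' in-plane angles in projections and weights refer to the same axes.
#'
#' @param d unit projection direction.
#' @return list(e1, e2).
#' @export
projection_basis <- function(d) {
  d <- d / sqrt(sum(d^2))
  cz <- cross3(d, c(0, 0, 1))
  if (sqrt(sum(cz^2)) > 1e-3) e1 <- cz / sqrt(sum(cz^2)) else e1 <- c(1, 0, 0)
  e2 <- cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

#' Project a particle along a direction from the raw tomogram
#'
#' Sums `depth` trilinear samples of the raw tomogram along `direction`,
#' centered on the particle: pixel (i, j) integrates positions
#' `center + (i - c) e1 + (j - c) e2 + t d`, t = -(depth-1)/2 ... (depth-1)/2,
#' with `c = (box - 1)/2` and (e1, e2) from [projection_basis()].
#'
#' @param tomo raw [voxel_volume()].
#' @param center raw 3-vector, 0-based voxel coordinates.
#' @param direction projection direction (normalized internally).
#' @param box image side in pixels (default 70).
#' @param depth number of samples along the direction (odd; default 7).
#' @param fill value for out-of-bounds samples (default: tomogram mean).
#' @return `box` x `box` numeric matrix with attribute `clipped` = TRUE if
#'   any sample fell outside the volume.
#' @export
project_particle <- function(tomo, center, direction, box = 70, depth = 7,
                             fill = NULL) {
  stopifnot(inherits(tomo, "voxel_volume"))
  if (depth %% 2 == 0) stop("projection depth must be odd")
  if (is.null(fill)) fill <- mean(tomo$data)
  d <- direction / sqrt(sum(direction^2))
  b <- projection_basis(d)
  cc <- (box - 1) / 2
  ij <- expand.grid(i = 0:(box - 1), j = 0:(box - 1))
  base <- matrix(rep(center, each = nrow(ij)), ncol = 3) +
    outer(ij$i - cc, b$e1) + outer(ij$j - cc, b$e2)
  img <- matrix(0, box, box)
  clipped <- FALSE
  any_in <- FALSE
  for (t in seq(-(depth - 1) / 2, (depth - 1) / 2)) {
    r <- trilinear_cpp(tomo$data, base + matrix(rep(t * d, each = nrow(ij)),
                                                ncol = 3), fill)
    img <- img + matrix(r$values, box, box)
    clipped <- clipped || !all(r$valid)
    any_in <- any_in || any(r$valid)
  }
  if (!any_in) stop("projection window entirely outside the volume")
  attr(img, "clipped") <- clipped
  img
}

## ---- missing-wedge weighting --------------------------------------------

ctf1d <- function(s, defocus, voltage = 300, cs = 2.7, amp_contrast = 0.07) {
  V <- voltage * 1e3
  lambda <- 12.2639 / sqrt(V + 0.97845e-6 * V^2)    # Angstrom
  cs_A <- cs * 1e7
  chi <- pi * lambda * defocus * s^2 - pi / 2 * cs_A * lambda^3 * s^4
  -(sqrt(1 - amp_contrast^2) * sin(chi) + amp_contrast * cos(chi))
}

#' Build a simple 3D Fourier-space weight for the missing wedge (3DCTF)
#'
#' For each Fourier voxel q the weight is the maximum over tilts of a slab
#' kernel `max(0, 1 - |q . b_t|)` (b_t: beam direction at tilt t, i.e. z_hat
#' rotated about the tilt axis; half-width one Fourier voxel), optionally
#' multiplied by the 1D CTF of the tilt attaining the maximum, evaluated at
#' |q|. This is a simplified per-tomogram weighting model (no per-particle
#' dose or defocus gradient); Hermitian symmetry is enforced.
#'
#' @param size cube side in Fourier voxels; DC sits at index
#'   `floor(size/2)` (0-based).
#' @param tilts tilt angles in degrees.
#' @param tilt_axis unit tilt-axis vector (default +Y).
#' @param defocus defocus in Angstrom (positive underfocus) per tilt
#'   (recycled); `NULL` disables the CTF factor.
#' @param voltage,cs,amp_contrast microscope parameters (kV, mm, fraction).
#' @param voxel_size real-space voxel size in Angstrom (sets the frequency
#'   scale of the CTF).
#' @return object of class `wedge_ctf` with the weight cube `ctf3d`
#'   (values in [-1, 1]) and the generation parameters.
#' @export
build_3dctf <- function(size, tilts, tilt_axis = c(0, 1, 0), defocus = NULL,
                        voltage = 300, cs = 2.7, amp_contrast = 0.07,
                        voxel_size = 1) {
  stopifnot(length(tilts) >= 1)
  ax <- tilt_axis / sqrt(sum(tilt_axis^2))
  ctr <- floor(size / 2)
  f <- seq_len(size) - 1 - ctr
  grid <- expand.grid(qx = f, qy = f, qz = f)
  q <- as.matrix(grid)
  W <- rep(0, nrow(q))
  best_tilt <- rep(NA_real_, nrow(q))
  for (i in seq_along(tilts)) {
    th <- tilts[i] * pi / 180
    # z_hat rotated about `ax` by th (Rodrigues)
    z <- c(0, 0, 1)
    b <- z * cos(th) + cross3(ax, z) * sin(th) + ax * sum(ax * z) * (1 - cos(th))
    k <- pmax(0, 1 - abs(q %*% b))
    upd <- k > W
    W[upd] <- k[upd]
    best_tilt[upd] <- tilts[i]
  }
  if (!is.null(defocus)) {
    df_per_tilt <- rep_len(defocus, length(tilts))
    s <- sqrt(rowSums(q^2)) / (size * voxel_size)
    cval <- rep(1, nrow(q))
    hit <- !is.na(best_tilt)
    di <- df_per_tilt[match(best_tilt[hit], tilts)]
    cval[hit] <- ctf1d(s[hit], di, voltage, cs, amp_contrast)
    W <- W * cval
  }
  arr <- array(W, c(size, size, size))
  rev_idx <- if (size %% 2 == 0) c(1L, size:2L) else size:1L
  arr <- (arr + arr[rev_idx, rev_idx, rev_idx]) / 2
  structure(list(ctf3d = arr, tilt_axis = ax, tilts = tilts,
                 size = size, voxel_size = voxel_size,
                 has_ctf = !is.null(defocus)),
            class = "wedge_ctf")
}

#' Extract the 2D weight (2DCTF) for a projection direction
#'
#' By the central slice theorem a real-space projection along `d`
#' corresponds to the Fourier plane through the origin perpendicular to `d`;
#' this samples that plane from the 3D weight with the same in-plane basis
#' used by [project_particle()], so the 2D weight aligns with the
#' projection image axes.
#'
#' @param wedge a `wedge_ctf`.
#' @param d projection direction.
#' @param box output side in pixels (default: the cube side).
#' @return `box` x `box` matrix of weights in [-1, 1].
#' @export
extract_2dctf <- function(wedge, d, box = wedge$size) {
  d <- d / sqrt(sum(d^2))
  b <- projection_basis(d)
  ctr3 <- floor(wedge$size / 2)
  cc <- floor(box / 2)   # DC pixel, matching the cube's center convention
  ij <- expand.grid(i = 0:(box - 1), j = 0:(box - 1))
  pts <- matrix(ctr3, nrow(ij), 3, byrow = TRUE) +
    outer(ij$i - cc, b$e1) + outer(ij$j - cc, b$e2)
  r <- trilinear_cpp(wedge$ctf3d, pts, 0)
  matrix(r$values, box, box)
}

#' Orientations and 3D shifts from 2D-classification results
#'
#' Converts per-pick in-plane angles and 2D shifts from 2D classification
#' into full rotation matrices / Euler angles and raw-frame 3D shifts. The
#' in-plane angle psi' = psi + class offset defines the direction
#' `cos(psi') e1 + sin(psi') e2` in the pick's projection basis; shifts
#' (du + class du, dv + class dv) are mapped to 3D in the plane
#' perpendicular to the normal.
#'
#' @param picks data.frame with normals nx, ny, nz (see
#'   [attach_geometry()]).
#' @param assignments data.frame with one row per pick: class_id, psi
#'   (degrees), du, dv (pixels).
#' @param class_offsets optional data.frame (class_id, dpsi, du, dv); picks
#'   whose class is absent from it are dropped with a message.
#' @return picks augmented with dx, dy, dz (direction), rot, tilt, psi
#'   (degrees), shift_x/y/z, class_id.
#' @export
inplane_from_class2d <- function(picks, assignments, class_offsets = NULL) {
  stopifnot(nrow(picks) == nrow(assignments),
            all(c("nx", "ny", "nz") %in% names(picks)))
  n <- nrow(picks)
  keep <- rep(TRUE, n)
  off <- data.frame(dpsi = rep(0, n), du = rep(0, n), dv = rep(0, n))
  if (!is.null(class_offsets)) {
    idx <- match(assignments$class_id, class_offsets$class_id)
    keep <- !is.na(idx)
    if (!all(keep))
      message("dropped ", sum(!keep), " pick(s) with unknown class")
    off$dpsi[keep] <- class_offsets$dpsi[idx[keep]]
    off$du[keep] <- class_offsets$du[idx[keep]]
    off$dv[keep] <- class_offsets$dv[idx[keep]]
  }
  out <- picks[keep, , drop = FALSE]
  asg <- assignments[keep, , drop = FALSE]
  off <- off[keep, , drop = FALSE]
  m <- nrow(out)
  dir <- matrix(0, m, 3); sh <- matrix(0, m, 3)
  ang <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    nvec <- c(out$nx[i], out$ny[i], out$nz[i])
    b <- projection_basis(nvec)
    psi_eff <- (asg$psi[i] + off$dpsi[i]) * pi / 180
    dir[i, ] <- cos(psi_eff) * b$e1 + sin(psi_eff) * b$e2
    sh[i, ] <- (asg$du[i] + off$du[i]) * b$e1 + (asg$dv[i] + off$dv[i]) * b$e2
    ang[i, ] <- matrix_to_euler(orientation_matrix(nvec, dir[i, ]))
  }
  out$dx <- dir[, 1]; out$dy <- dir[, 2]; out$dz <- dir[, 3]
  out$rot <- ang[, 1]; out$tilt <- ang[, 2]; out$psi <- ang[, 3]
  out$shift_x <- sh[, 1]; out$shift_y <- sh[, 2]; out$shift_z <- sh[, 3]
  out$class_id <- asg$class_id
  rownames(out) <- NULL
  out
}

## ---- in-plane template matching -----------------------------------------

# Rotate a square image about its center by `angle` degrees (bilinear).
rotate_image <- function(img, angle) {
  n <- nrow(img)
  cc <- (n - 1) / 2
  th <- angle * pi / 180
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  # source coordinates: rotate backwards
  xs <- cos(th) * (ij$i - cc) + sin(th) * (ij$j - cc) + cc
  ys <- -sin(th) * (ij$i - cc) + cos(th) * (ij$j - cc) + cc
  arr <- array(img, c(n, n, 1))
  r <- trilinear_cpp(arr, cbind(xs, ys, 0), mean(img))
  matrix(r$values, n, n)
}

#' Exhaustive in-plane rotational matching of a projection to a template
#'
#' Rotates the template over a grid of angles and returns the angle
#' maximizing the normalized cross-correlation with the image. Serves as a
#' stand-in for external 2D classification when validating orientation
#' recovery on synthetic data.
#'
#' @param image square projection image.
#' @param template square template of the same size.
#' @param angles candidate angles in degrees (default 0..179 step 1).
#' @param max_shift also search integer translations up to this many pixels
#'   (2D classification aligns shifts as well as rotations; 0 disables).
#' @return list(angle, ncc, shift).
#' @export
match_inplane <- function(image, template, angles = seq(0, 179, by = 1),
                          max_shift = 0) {
  n <- nrow(image)
  s <- max_shift
  core <- (1 + s):(n - s)              # comparison window
  zi_w <- image[core, core]
  zi <- as.numeric(zi_w - mean(zi_w))
  zi <- zi / sqrt(sum(zi^2))
  shifts <- expand.grid(si = -s:s, sj = -s:s)
  best <- -Inf; best_a <- angles[1]; best_sh <- c(0, 0)
  for (a in angles) {
    rt <- rotate_image(template, a)
    for (k in seq_len(nrow(shifts))) {
      si <- shifts$si[k]; sj <- shifts$sj[k]
      zt_w <- rt[core - si, core - sj]
      zt <- as.numeric(zt_w - mean(zt_w))
      ncc <- sum(zi * zt) / sqrt(sum(zt^2))
      if (ncc > best) { best <- ncc; best_a <- a; best_sh <- c(si, sj) }
    }
  }
  list(angle = best_a, ncc = best, shift = best_sh)
}
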