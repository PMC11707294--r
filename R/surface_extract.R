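#' Post-process a membrane score map into a clean binary mask
#'
#' Gaussian-filters the scores, binarizes at `threshold`, then removes small
#' connected components: first 2D components per X-Y slice (8-connectivity),
#' then 3D components (26-connectivity).
#'
#' @param scores a [voxel_volume()] of membrane scores.
#' @param sigma Gaussian sigma in voxels (0 disables smoothing).
#' @param threshold binarization threshold (kept if score >= threshold).
#' @param min_2d minimum surviving 2D component size per slice, voxels.
#' @param min_3d minimum surviving 3D component size, voxels.
#' @return A binary [voxel_volume()] (values 0/1).
#' @export
postprocess_mask <- function(scores, sigma = 1, threshold = 0.5,
                             min_2d = 1, min_3d = 1) {
  stopifnot(inherits(scores, "voxel_volume"), sigma >= 0)
  s <- scores$data
  if (sigma > 0) s <- gaussian_smooth(s, sigma)
  bin <- s >= threshold
  d <- dim(bin)
  if (min_2d > 1 && any(bin)) {
    for (k in seq_len(d[3])) {
      sl <- matrix(bin[, , k], d[1], d[2])
      if (!any(sl)) next
      lab <- label2d_cpp(sl)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_2d)
      bin[, , k] <- sl & (lab %in% keep)
    }
  }
  if (min_3d > 1 && any(bin)) {
    lab <- label3d_cpp(bin, 26L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_3d)
    bin <- array(bin & (lab %in% keep), d)
  }
  if (!any(bin)) warning("post-processed mask is empty")
  voxel_volume(array(as.numeric(bin), d), scores$voxel_size, scores$origin)
}

#' Extract a single-voxel-thick boundary from a binary mask
#'
#' @param mask binary [voxel_volume()].
#' @param method `"erosion"` (boundary = mask minus its 6-connected erosion)
#'   or `"canny"` (union over X-Y slices of 2D Canny edge maps, intersected
#'   with the mask).
#' @param sigma Gaussian sigma for the Canny detector, voxels.
#' @return Binary [voxel_volume()] with the boundary.
#' @export
extract_boundary <- function(mask, method = c("erosion", "canny"), sigma = 1) {
  stopifnot(inherits(mask, "voxel_volume"))
  method <- match.arg(method)
  m <- mask$data > 0.5
  d <- dim(m)
  if (method == "erosion") {
    b <- m & !erode6(m)
  } else {
    b <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      sl <- matrix(as.numeric(m[, , k]), d[1], d[2])
      if (!any(sl > 0)) next
      b[, , k] <- canny2d(sl, sigma = sigma) & m[, , k]
    }
  }
  voxel_volume(array(as.numeric(b), d), mask$voxel_size, mask$origin)
}

# Basic 2D Canny: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, percentile-based
# hysteresis thresholds grown through 8-connected components.
canny2d <- function(img, sigma = 1, low_q = 0.5, high_q = 0.8) {
  sm <- gaussian_smooth(img, sigma)
  nx <- nrow(sm); ny <- ncol(sm)
  pad <- function(m) m[c(1, seq_len(nx), nx), c(1, seq_len(ny), ny)]
  p <- pad(sm)
  ix <- 2:(nx + 1); iy <- 2:(ny + 1)
  gx <- (p[ix + 1, iy - 1] + 2 * p[ix + 1, iy] + p[ix + 1, iy + 1] -
         p[ix - 1, iy - 1] - 2 * p[ix - 1, iy] - p[ix - 1, iy + 1]) / 8
  gy <- (p[ix - 1, iy + 1] + 2 * p[ix, iy + 1] + p[ix + 1, iy + 1] -
         p[ix - 1, iy - 1] - 2 * p[ix, iy - 1] - p[ix + 1, iy - 1]) / 8
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(FALSE, nx, ny))
  ang <- atan2(gy, gx)                      # quantize to 4 directions
  sector <- (round(ang / (pi / 4)) %% 4) + 1
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  magp <- matrix(0, nx + 2, ny + 2); magp[ix, iy] <- mag
  nms <- matrix(FALSE, nx, ny)
  for (s in 1:4) {
    o <- offs[[s]]
    nb1 <- magp[ix + o[1], iy + o[2]]
    nb2 <- magp[ix - o[1], iy - o[2]]
    sel <- sector == s
    nms[sel] <- mag[sel] >= nb1[sel] & mag[sel] >= nb2[sel]
  }
  pos <- mag[mag > 0]
  hi <- stats::quantile(pos, high_q, names = FALSE)
  lo <- stats::quantile(pos, low_q, names = FALSE)
  weak <- nms & mag >= lo
  if (!any(weak)) return(matrix(FALSE, nx, ny))
  lab <- label2d_cpp(weak)
  strong_labels <- unique(lab[weak & mag >= hi])
  weak & (lab %in% strong_labels)
}

#' Seed point on a membrane boundary
#' @param position 3-vector, 0-based voxel coordinate.
#' @param perp_axis which raw axis is most perpendicular to the membrane:
#'   "X", "Y", or "Z".
#' @export
seed_point <- function(position, perp_axis = c("X", "Y", "Z")) {
  perp_axis <- match.arg(perp_axis)
  structure(list(position = as.numeric(position), perp_axis = perp_axis),
            class = "seed_point")
}

# Permutation taking raw axes to the canonical frame in which the membrane
# is perpendicular to axis 1: X -> (X,Y,Z), Y -> (Y,X,Z), Z -> (Z,Y,X).
axis_permutation <- function(perp_axis) {
  switch(perp_axis, X = c(1L, 2L, 3L), Y = c(2L, 1L, 3L), Z = c(3L, 2L, 1L))
}

#' Extend starting points from a seed along the membrane boundary
#'
#' Implements the two-stage monotone extension. Stated here for a membrane
#' roughly perpendicular to X (other axes are handled by permuting axes):
#' first a primary chain inside the seed's x-z plane, stepping Z by one
#' voxel per step in each direction so Z changes monotonically and stopping
#' when no boundary voxel exists in the next Z line within +/-2 voxels of X;
#' then, from every primary point, secondary chains inside its x-y plane
#' stepping Y monotonically under the same rule. The nearest candidate in
#' the lateral window wins; ties break toward the smaller lateral offset,
#' then the smaller coordinate.
#'
#' @param boundary binary [voxel_volume()] from [extract_boundary()].
#' @param seed a [seed_point()], or list of them (results are unioned).
#' @param max_extent_primary,max_extent_secondary maximum steps per
#'   direction for the primary (Z) and secondary (Y) extensions.
#' @return A [point_set()] of starting points lying on the boundary.
#' @export
extend_from_seed <- function(boundary, seed, max_extent_primary = 1000,
                             max_extent_secondary = 1000) {
  stopifnot(inherits(boundary, "voxel_volume"))
  if (inherits(seed, "seed_point")) seed <- list(seed)
  all_pts <- lapply(seed, function(s)
    extend_one_seed(boundary, s, max_extent_primary, max_extent_secondary))
  pts <- unique(do.call(rbind, all_pts))
  point_set(pts, label = "starting_points")
}

extend_one_seed <- function(boundary, seed, max_primary, max_secondary) {
  perm <- axis_permutation(seed$perp_axis)
  b <- aperm(boundary$data > 0.5, perm)
  pos <- round(seed$position)[perm] + 1L      # 1-based canonical indices
  d <- dim(b)
  if (any(pos < 1 | pos > d)) stop("seed outside the volume")
  if (!b[pos[1], pos[2], pos[3]]) {
    snapped <- snap_to_boundary(b, pos)
    if (is.null(snapped))
      stop("seed off boundary: no boundary voxel within 1 voxel of (",
           paste(seed$position, collapse = ","), "); nearest boundary voxel: ",
           paste(nearest_boundary_voxel(b, pos) - 1L, collapse = ","))
    pos <- snapped
  }
  # primary chain: seed's x-z plane (axis2 fixed), walk axis3
  primary <- walk_chain(b, pos, fixed_axis = 2L, walk_axis = 3L,
                        max_steps = max_primary)
  # secondary chains: per primary point, x-y plane (axis3 fixed), walk axis2
  res <- primary
  for (r in seq_len(nrow(primary))) {
    res <- rbind(res, walk_chain(b, primary[r, ], fixed_axis = 3L,
                                 walk_axis = 2L, max_steps = max_secondary))
  }
  res <- unique(res)
  res[, order(perm), drop = FALSE] - 1       # back to raw axes, 0-based
}

snap_to_boundary <- function(b, pos) {
  d <- dim(b)
  best <- NULL; bestd <- Inf
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    p <- pos + c(di, dj, dk)
    if (any(p < 1 | p > d)) next
    if (b[p[1], p[2], p[3]]) {
      dd <- sum(c(di, dj, dk)^2)
      if (dd < bestd) { bestd <- dd; best <- p }
    }
  }
  best
}

nearest_boundary_voxel <- function(b, pos) {
  idx <- which(b, arr.ind = TRUE)
  if (!nrow(idx)) return(c(NA, NA, NA))
  dd <- colSums((t(idx) - pos)^2)
  idx[which.min(dd), ]
}

# Walk from `start` (1-based canonical indices) in both directions of
# `walk_axis`, keeping `fixed_axis` constant, lateral window +/-2 on axis 1.
walk_chain <- function(b, start, fixed_axis, walk_axis, max_steps) {
  d <- dim(b)
  pts <- matrix(start, 1, 3)
  for (dir in c(1L, -1L)) {
    cur <- start
    for (step in seq_len(max_steps)) {
      nxt_w <- cur[walk_axis] + dir
      if (nxt_w < 1 || nxt_w > d[walk_axis]) break
      cand_x <- cur[1] + (-2:2)
      cand_x <- cand_x[cand_x >= 1 & cand_x <= d[1]]
      p <- matrix(rep(cur, each = length(cand_x)), ncol = 3)
      p[, 1] <- cand_x
      p[, walk_axis] <- nxt_w
      hit <- b[p]
      if (!any(hit)) break
      lat <- abs(cand_x - cur[1])
      ord <- order(!hit, lat, cand_x)         # nearest lateral, then smaller x
      cur <- p[ord[1], ]
      pts <- rbind(pts, cur)
    }
  }
  unname(pts)
}

#' Remove point-cloud outliers by k-nearest-neighbor distance
#'
#' Computes the average distance of each point to its `knn` nearest
#' neighbors; points whose average exceeds the mean plus `nsd` standard
#' deviations of these averages are discarded. `knn` is clipped to n-1.
#'
#' @param points a [point_set()] or n x 3 matrix.
#' @param knn neighbor count (default 50).
#' @param nsd standard-deviation multiple (default 2).
#' @return Filtered [point_set()].
#' @export
remove_outliers <- function(points, knn = 50, nsd = 2) {
  m <- as_point_matrix(points)
  n <- nrow(m)
  if (n < 2) {
    warning("fewer than 2 points; returned unchanged")
    return(point_set(m, label = attr(points, "label") %||% "points"))
  }
  k <- min(knn, n - 1L)
  md <- knn_mean_dist_cpp(m, as.integer(k))
  keep <- md <= mean(md) + nsd * stats::sd(md)
  point_set(m[keep, , drop = FALSE],
            label = attr(points, "label") %||% "points")
}
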