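#' Rigid frame transform between local (x,y,z) and raw (X,Y,Z) coordinates
#'
#' Maps local coordinates to raw coordinates as `X = R x + t`, with `R` a
#' proper rotation.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t translation 3-vector.
#' @export
frame_transform <- function(R, t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R must be orthonormal with det +1")
  structure(list(R = R, t = as.numeric(t)), class = "frame_transform")
}

#' @rdname frame_transform
#' @param frame a `frame_transform`.
#' @param pts n x 3 matrix of local coordinates.
#' @export
local_to_raw <- function(frame, pts) {
  pts <- rbind3(pts)
  sweep(pts %*% t(frame$R), 2, frame$t, "+")
}

#' @rdname frame_transform
#' @export
raw_to_local <- function(frame, pts) {
  pts <- rbind3(pts)
  sweep(pts, 2, frame$t, "-") %*% frame$R
}

rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else
    matrix(as.numeric(as.matrix(p)), ncol = 3)
}

rotation_xyz <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Determine the local viewing frame for a membrane patch
#'
#' Chooses the local z-axis so the membrane appears flat from it, either by
#' total-least-squares plane fitting (normal of the best-fit plane) or by
#' maximizing the projected area of the starting points, realized as PCA:
#' the direction of smallest point-cloud variance maximizes the area of the
#' projection onto its orthogonal plane for thin sheets. The z sign is fixed
#' to have a non-negative dot product with raw +Z (tie: +X); x and y
#' complete a right-handed frame; the translation is the centroid.
#'
#' @param points [point_set()] or n x 3 matrix of raw coordinates.
#' @param method `"plane_fit"` or `"max_area"`.
#' @return A [frame_transform()].
#' @export
determine_frame <- function(points, method = c("plane_fit", "max_area")) {
  method <- match.arg(method)
  m <- as_point_matrix(points)
  if (nrow(m) < 3) stop("need at least 3 points")
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  if (method == "plane_fit") {
    sv <- svd(cm)
    zax <- sv$v[, 3]
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("points are collinear")
  } else {
    ev <- eigen(crossprod(cm) / nrow(cm), symmetric = TRUE)
    zax <- ev$vectors[, 3]
    if (ev$values[2] < 1e-18 * max(ev$values[1], 1))
      stop("points are collinear")
  }
  frame_from_zaxis(zax, ctr)
}

# Build a right-handed frame whose third column is (sign-fixed) zax.
frame_from_zaxis <- function(zax, ctr) {
  zax <- zax / sqrt(sum(zax^2))
  if (zax[3] < 0 || (zax[3] == 0 && zax[1] < 0)) zax <- -zax
  ref <- if (abs(zax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xax <- ref - sum(ref * zax) * zax
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  frame_transform(cbind(xax, yax, zax), ctr)
}

## ---- polynomial height surface ----------------------------------------

poly_exponents <- function(degree) {
  ex <- expand.grid(m = 0:degree, n = 0:degree)
  ex <- ex[ex$m + ex$n <= degree, , drop = FALSE]
  ex[order(ex$m + ex$n, ex$m), ]
}

poly_design <- function(x, y, exps) {
  X <- matrix(1, length(x), nrow(exps))
  for (j in seq_len(nrow(exps)))
    X[, j] <- x^exps$m[j] * y^exps$n[j]
  X
}

#' Fit a bivariate polynomial height surface z = f(x, y)
#'
#' Least-squares fit of `f(x,y) = sum a_mn x^m y^n` over all `m + n <= N`
#' to points already expressed in the local frame.
#'
#' @param points_local [point_set()] or n x 3 matrix of local (x, y, z).
#' @param degree polynomial degree N >= 0.
#' @return A `height_surface` (kind "polynomial") with residuals attached.
#' @export
fit_polynomial <- function(points_local, degree = 2) {
  m <- as_point_matrix(points_local)
  exps <- poly_exponents(degree)
  if (nrow(m) < nrow(exps))
    stop("need at least ", nrow(exps), " points for degree ", degree)
  X <- poly_design(m[, 1], m[, 2], exps)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient polynomial design; try a lower degree")
  coef <- qr.coef(qrX, m[, 3])
  structure(list(kind = "polynomial", degree = degree, exponents = exps,
                 coef = as.numeric(coef),
                 domain = apply(m[, 1:2, drop = FALSE], 2, range),
                 residuals = as.numeric(m[, 3] - X %*% coef)),
            class = "height_surface")
}

## ---- thin-plate spline height surface ----------------------------------

tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

tps_system_solve <- function(xy, z, lambda) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  K <- tps_kernel(D)
  P <- cbind(1, xy)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- unname(solve(A, rhs))
  list(w = sol[1:n], a = sol[n + 1:3])
}

tps_eval_core <- function(centers, w, a, x, y) {
  q <- cbind(x, y)
  out <- a[1] + a[2] * x + a[3] * y
  for (i in seq_len(nrow(centers))) {
    r <- sqrt((x - centers[i, 1])^2 + (y - centers[i, 2])^2)
    out <- out + w[i] * tps_kernel(r)
  }
  out
}

tps_grad_core <- function(centers, w, a, x, y) {
  gx <- rep(a[2], length(x)); gy <- rep(a[3], length(x))
  for (i in seq_len(nrow(centers))) {
    dx <- x - centers[i, 1]; dy <- y - centers[i, 2]
    r2 <- dx^2 + dy^2
    # d/dx r^2 log r = (2 log r + 1) dx ; zero at r = 0
    f <- ifelse(r2 > 0, log(r2) + 1, 0)     # 2 log r + 1 = log r^2 + 1
    gx <- gx + w[i] * f * dx
    gy <- gy + w[i] * f * dy
  }
  cbind(gx, gy)
}

# Grid downsampling: one representative (cell centroid) per spacing-sized
# (x, y) cell.
downsample_grid <- function(m, spacing) {
  cell <- paste(floor(m[, 1] / spacing), floor(m[, 2] / spacing))
  xs <- tapply(m[, 1], cell, mean)
  ys <- tapply(m[, 2], cell, mean)
  zs <- tapply(m[, 3], cell, mean)
  cbind(xs, ys, zs)
}

#' Fit a thin-plate-spline height surface z = f(x, y)
#'
#' Downsamples the local points on a grid (one centroid per
#' `downsample_spacing`-sized cell), solves the TPS system with kernel
#' `r^2 log r`, affine polynomial part, and diagonal smoothing `lambda`;
#' control points whose residual exceeds `refit_outlier_mult` residual
#' standard deviations are dropped and the fit repeated once.
#'
#' @param points_local [point_set()] or n x 3 matrix of local (x, y, z).
#' @param downsample_spacing grid cell size in voxels (default 12).
#' @param lambda smoothing weight, >= 0 (0 interpolates).
#' @param refit_outlier_mult residual-SD multiple for the second-round
#'   refit; `Inf` disables the refit.
#' @return A `height_surface` (kind "tps").
#' @export
fit_tps <- function(points_local, downsample_spacing = 12, lambda = 0,
                    refit_outlier_mult = 3) {
  stopifnot(downsample_spacing >= 1, lambda >= 0)
  m <- as_point_matrix(points_local)
  ds <- downsample_grid(m, downsample_spacing)
  if (nrow(ds) < 4) stop("fewer than 4 control points after downsampling")
  fit <- tps_system_solve(ds[, 1:2, drop = FALSE], ds[, 3], lambda)
  resid <- ds[, 3] - tps_eval_core(ds[, 1:2, drop = FALSE], fit$w, fit$a,
                                   ds[, 1], ds[, 2])
  if (is.finite(refit_outlier_mult) && nrow(ds) > 4) {
    s <- stats::sd(resid)
    bad <- abs(resid) > refit_outlier_mult * s
    if (any(bad) && sum(!bad) >= 4) {
      ds <- ds[!bad, , drop = FALSE]
      fit <- tps_system_solve(ds[, 1:2, drop = FALSE], ds[, 3], lambda)
      resid <- ds[, 3] - tps_eval_core(ds[, 1:2, drop = FALSE], fit$w, fit$a,
                                       ds[, 1], ds[, 2])
    }
  }
  structure(list(kind = "tps", centers = unname(ds[, 1:2, drop = FALSE]),
                 w = fit$w, a = fit$a, lambda = lambda,
                 control_z = unname(ds[, 3]),
                 domain = apply(m[, 1:2, drop = FALSE], 2, range),
                 residuals = as.numeric(resid)),
            class = "height_surface")
}

#' Evaluate a height surface and its gradient
#'
#' @param surface a `height_surface` from [fit_polynomial()] or [fit_tps()].
#' @param x,y local coordinates (vectorized).
#' @return `surface_eval`: z values. `surface_gradient`: n x 2 matrix of
#'   (df/dx, df/dy), analytic for both kinds.
#' @export
surface_eval <- function(surface, x, y) {
  stopifnot(inherits(surface, "height_surface"))
  if (surface$kind == "polynomial") {
    as.numeric(poly_design(x, y, surface$exponents) %*% surface$coef)
  } else {
    tps_eval_core(surface$centers, surface$w, surface$a, x, y)
  }
}

#' @rdname surface_eval
#' @export
surface_gradient <- function(surface, x, y) {
  stopifnot(inherits(surface, "height_surface"))
  if (surface$kind == "polynomial") {
    ex <- surface$exponents
    gx <- gy <- rep(0, length(x))
    for (j in seq_len(nrow(ex))) {
      m <- ex$m[j]; n <- ex$n[j]; a <- surface$coef[j]
      if (m > 0) gx <- gx + a * m * x^(m - 1) * y^n
      if (n > 0) gy <- gy + a * n * x^m * y^(n - 1)
    }
    cbind(gx, gy)
  } else {
    unname(tps_grad_core(surface$centers, surface$w, surface$a, x, y))
  }
}

#' Unit surface normal in raw coordinates
#'
#' The unnormalized local normal of z = f(x,y) is (-df/dx, -df/dy, 1); it is
#' normalized and rotated into the raw frame.
#'
#' @param surface a `height_surface`.
#' @param frame the [frame_transform()] of the local system.
#' @param x,y local coordinates (vectorized).
#' @return n x 3 matrix of unit normals in raw coordinates.
#' @export
normal_raw <- function(surface, frame, x, y) {
  g <- surface_gradient(surface, x, y)
  n <- cbind(-g[, 1], -g[, 2], 1)
  n <- n / sqrt(rowSums(n^2))
  n %*% t(frame$R)
}

#' @export
print.height_surface <- function(x, ...) {
  cat(sprintf("<height_surface %s> ", x$kind))
  if (x$kind == "polynomial")
    cat(sprintf("degree %d, %d coefficients", x$degree, length(x$coef)))
  else
    cat(sprintf("%d control points, lambda %.3g", nrow(x$centers), x$lambda))
  cat(sprintf(", residual RMS %.3g\n",
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

## ---- JSON sidecar serialization ----------------------------------------

#' Serialize / restore a height surface and frame as JSON
#'
#' Stores kind, frame, and coefficients or control points so flattening is
#' reproducible without refitting.
#'
#' @param surface a `height_surface`.
#' @param frame a [frame_transform()].
#' @param path JSON path.
#' @export
write_surface_json <- function(surface, frame, path) {
  obj <- list(kind = surface$kind,
              frame = list(R = as.numeric(frame$R), t = frame$t))
  if (surface$kind == "polynomial") {
    obj$degree <- surface$degree
    obj$coef <- surface$coef
  } else {
    obj$centers <- surface$centers
    obj$w <- surface$w
    obj$a <- surface$a
    obj$lambda <- surface$lambda
    obj$control_z <- surface$control_z
  }
  obj$domain <- surface$domain
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame <- frame_transform(matrix(o$frame$R, 3, 3), o$frame$t)
  domain <- matrix(as.numeric(o$domain), 2, 2)
  if (o$kind == "polynomial") {
    surf <- structure(list(kind = "polynomial", degree = o$degree,
                           exponents = poly_exponents(o$degree),
                           coef = o$coef, domain = domain,
                           residuals = numeric(0)),
                      class = "height_surface")
  } else {
    surf <- structure(list(kind = "tps",
                           centers = matrix(as.numeric(o$centers), ncol = 2),
                           w = o$w, a = o$a, lambda = o$lambda,
                           control_z = o$control_z, domain = domain,
                           residuals = numeric(0)),
                      class = "height_surface")
  }
  list(surface = surf, frame = frame)
}
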