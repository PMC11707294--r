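## Cylinder models and the (u,v) parameterization with equal arc-length
## sampling; flattened-tomogram rendering and bidirectional mapping.

poly1_eval <- function(coef, y) {
  out <- rep(coef[1], length(y))
  if (length(coef) > 1)
    for (n in 2:length(coef)) out <- out + coef[n] * y^(n - 1)
  out
}

poly1_deriv <- function(coef, y) {
  out <- rep(0, length(y))
  if (length(coef) > 1)
    for (n in 2:length(coef)) out <- out + (n - 1) * coef[n] * y^(n - 2)
  out
}

#' Polynomial open-cylinder model z = h(y)
#'
#' Describes the intermediate best-fit cylindrical surface, bent only along
#' the local y-axis, onto which the membrane is projected before unrolling.
#'
#' @param coef polynomial coefficients a_0..a_N of h(y).
#' @param y_range range of y covered by the fit; `y_range[1]` is the
#'   arc-length origin (v = 0).
#' @export
cylinder_poly <- function(coef, y_range) {
  structure(list(kind = "poly_open", coef = as.numeric(coef),
                 y_min = y_range[1], y_max = y_range[2]),
            class = "cylinder_model")
}

#' Arc length along a cylinder model and its inverse
#'
#' `arc_length` integrates `sqrt(1 + h'(y)^2)` from the model's y origin
#' (adaptive quadrature); sampling integer v therefore corresponds to equal
#' arc-length sampling on the cylindrical surface. `arc_inverse` solves
#' v(y) = v for y by bracketed root finding.
#'
#' @param cyl a `cylinder_model`.
#' @param y,v numeric vectors.
#' @export
arc_length <- function(cyl, y) {
  stopifnot(cyl$kind == "poly_open")
  f <- function(t) sqrt(1 + poly1_deriv(cyl$coef, t)^2)
  vapply(y, function(yy) {
    if (yy == cyl$y_min) return(0)
    stats::integrate(f, cyl$y_min, yy, rel.tol = 1e-10,
                     abs.tol = 1e-12)$value
  }, numeric(1))
}

#' @rdname arc_length
#' @export
arc_inverse <- function(cyl, v) {
  stopifnot(cyl$kind == "poly_open")
  span <- cyl$y_max - cyl$y_min
  vapply(v, function(vv) {
    if (vv <= 0) return(cyl$y_min + vv)   # arc ~ y below the origin
    hi <- cyl$y_max
    while (arc_length(cyl, hi) < vv) hi <- hi + 0.25 * max(span, 1)
    stats::uniroot(function(yy) arc_length(cyl, yy) - vv,
                   c(cyl$y_min, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Jointly fit the local frame and a polynomial cylinder
#'
#' Starting from [determine_frame()], rotates the frame about its local
#' z-axis so the bending direction (the in-plane principal direction of
#' largest curvature of a quadratic pre-fit) becomes the local y-axis, then
#' refines the frame rotation and the polynomial h(y) simultaneously by
#' nonlinear least squares on sum (z_i - h(y_i))^2. The polynomial
#' coefficients are solved linearly inside each residual evaluation
#' (variable projection), so the nonlinear search runs over the three frame
#' rotation angles only.
#'
#' @param points [point_set()] of raw starting points.
#' @param degree polynomial degree of h(y).
#' @param frame0 optional initial [frame_transform()] (default:
#'   `determine_frame(points)`).
#' @param bend_angle optional in-plane bend direction in radians, measured
#'   in the initial local frame; overrides the automatic choice. `NA` keeps
#'   the initial frame orientation.
#' @return list(frame, cylinder, residual, converged).
#' @export
fit_cylinder_poly <- function(points, degree = 3, frame0 = NULL,
                              bend_angle = NULL) {
  m <- as_point_matrix(points)
  if (is.null(frame0)) frame0 <- determine_frame(m)
  # bend-axis selection from a quadratic pre-fit
  loc0 <- raw_to_local(frame0, m)
  alpha <- if (is.null(bend_angle)) {
    q <- fit_polynomial(loc0, degree = 2)
    a <- stats::setNames(q$coef, paste0(q$exponents$m, q$exponents$n))
    H <- matrix(c(2 * a["20"], a["11"], a["11"], 2 * a["02"]), 2, 2)
    ev <- eigen(H, symmetric = TRUE)
    dmax <- ev$vectors[, which.max(abs(ev$values))]
    atan2(dmax[2], dmax[1])
  } else bend_angle
  R0 <- if (is.na(alpha)) frame0$R else
    frame0$R %*% rotation_xyz(rz = alpha - pi / 2)
  t0 <- frame0$t

  solve_h <- function(loc) {
    X <- outer(loc[, 2], 0:degree, `^`)
    cf <- qr.coef(qr(X), loc[, 3])
    cf[is.na(cf)] <- 0
    list(coef = cf, resid = loc[, 3] - X %*% cf)
  }
  resid_fun <- function(par) {
    R <- R0 %*% rotation_xyz(par[1], par[2], par[3])
    loc <- sweep(m, 2, t0) %*% R
    as.numeric(solve_h(loc)$resid)
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0 || fit$info == 9)
    warning("cylinder fit did not converge; returning best iterate")
  R <- R0 %*% rotation_xyz(fit$par[1], fit$par[2], fit$par[3])
  # re-fix the z sign convention after refinement
  frame <- frame_transform(R, t0)
  loc <- raw_to_local(frame, m)
  hfit <- solve_h(loc)
  cyl <- cylinder_poly(hfit$coef, range(loc[, 2]))
  list(frame = frame, cylinder = cyl,
       residual = sqrt(mean(hfit$resid^2)),
       converged = !(fit$info %in% c(0, 9)))
}

## ---- elliptic cylinder --------------------------------------------------

# Direct least-squares ellipse fit (algebraic, 4AC - B^2 = 1 constraint).
fit_ellipse_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T2 <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T2
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  a1 <- evec[, which(cond > 0)[1]]
  coef <- c(a1, T2 %*% a1)   # A B C D E F
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  # translate to the center: quadratic form M, constant F'
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  Fp <- Fc + (D * ctr[1] + E * ctr[2]) / 2
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values
  if (any(lam * (-Fp) <= 0)) stop("conic fit is not an ellipse")
  ax <- sqrt(-Fp / lam)                       # lam ascending? eigen: descending
  ord <- order(ax, decreasing = TRUE)
  a_semi <- ax[ord[1]]; b_semi <- ax[ord[2]]
  major <- ev$vectors[, ord[1]]
  phi <- atan2(major[2], major[1])
  list(center = ctr, a = a_semi, b = b_semi, phi = phi)
}

#' Fit an elliptic cylinder to starting points on a closed membrane
#'
#' The cylinder axis is the principal direction of largest point-cloud
#' variance; the points are projected onto the orthogonal plane and an
#' ellipse is fitted by direct algebraic least squares. The returned model
#' carries the equal arc-length coordinate system on the elliptic cylinder:
#' u runs along the axis, v is the circumferential arc length from the
#' ellipse's major axis.
#'
#' @param points [point_set()] of raw starting points surrounding a closed
#'   cross-section.
#' @return A `cylinder_model` of kind `elliptic_closed`.
#' @export
fit_cylinder_elliptic <- function(points) {
  m <- as_point_matrix(points)
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  ev <- eigen(crossprod(cm) / nrow(cm), symmetric = TRUE)
  # the axis is the covariance eigenvector whose orthogonal projection of
  # the points is best explained by an ellipse (smallest radial residual)
  best <- NULL
  for (cand in 1:3) {
    axis <- ev$vectors[, cand]
    bas <- ev$vectors[, -cand, drop = FALSE]
    q <- cm %*% bas
    el <- tryCatch(fit_ellipse_2d(q), error = function(e) NULL)
    if (is.null(el)) next
    rel <- sweep(q, 2, el$center)
    phi <- atan2(rel[, 2], rel[, 1]) - el$phi
    rell <- el$a * el$b / sqrt(el$b^2 * cos(phi)^2 + el$a^2 * sin(phi)^2)
    res <- sqrt(mean((sqrt(rowSums(rel^2)) - rell)^2))
    if (is.null(best) || res < best$res)
      best <- list(res = res, cand = cand)
  }
  if (is.null(best)) stop("no candidate axis admits an ellipse fit")
  axis <- ev$vectors[, best$cand]
  if (axis[1] < 0) axis <- -axis
  rest <- ev$vectors[, -best$cand, drop = FALSE]
  b1 <- rest[, 1]; b2 <- rest[, 2]
  if (det(cbind(axis, b1, b2)) < 0) b2 <- -b2
  q <- cbind(cm %*% b1, cm %*% b2)
  el <- fit_ellipse_2d(q)
  ang <- sort(atan2(q[, 2] - el$center[2], q[, 1] - el$center[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  if (max(gaps) > pi)
    warning("angular coverage < 180 degrees; an open polynomial cylinder ",
            "is recommended")
  e1p <- c(cos(el$phi), sin(el$phi))      # ellipse axes in (b1, b2) coords
  e2p <- c(-sin(el$phi), cos(el$phi))
  e1 <- b1 * e1p[1] + b2 * e1p[2]
  e2 <- b1 * e2p[1] + b2 * e2p[2]
  center3 <- ctr + el$center[1] * b1 + el$center[2] * b2
  structure(list(kind = "elliptic_closed", center = center3, axis = axis,
                 e1 = e1, e2 = e2, a = el$a, b = el$b),
            class = "cylinder_model")
}

# Arc length around an ellipse from theta = 0 (major axis).
ellipse_arc <- function(cyl, theta) {
  f <- function(t) sqrt(cyl$a^2 * sin(t)^2 + cyl$b^2 * cos(t)^2)
  vapply(theta, function(th)
    stats::integrate(f, 0, th, rel.tol = 1e-10)$value, numeric(1))
}

ellipse_arc_inverse <- function(cyl, v) {
  circ <- ellipse_arc(cyl, 2 * pi)
  vapply(v, function(vv) {
    vv <- vv %% circ
    if (vv == 0) return(0)
    stats::uniroot(function(th) ellipse_arc(cyl, th) - vv,
                   c(0, 2 * pi), tol = 1e-10)$root
  }, numeric(1))
}

#' Circumference of a fitted elliptic cylinder
#' @param cyl an `elliptic_closed` cylinder model.
#' @export
ellipse_circumference <- function(cyl) ellipse_arc(cyl, 2 * pi)

# Point and outward unit normal on the elliptic cylinder at (s, theta).
ellipse_surface_point <- function(cyl, s, theta) {
  E <- outer(cos(theta) * cyl$a, cyl$e1) + outer(sin(theta) * cyl$b, cyl$e2)
  P <- matrix(rep(cyl$center, each = length(s)), ncol = 3) +
    outer(s, cyl$axis) + E
  nrm <- outer(cos(theta) / cyl$a, cyl$e1) + outer(sin(theta) / cyl$b, cyl$e2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  list(P = P, normal = nrm)
}

#' Express raw points in elliptic-cylinder surface coordinates
#'
#' Returns (x = axial coordinate, y = circumferential arc length, z = signed
#' radial offset along the local outward normal) for each point, the
#' coordinate system in which the height surface is fitted for closed
#' membranes.
#'
#' @param cyl an `elliptic_closed` cylinder model.
#' @param points [point_set()] or n x 3 matrix of raw coordinates.
#' @export
elliptic_local_coords <- function(cyl, points) {
  m <- as_point_matrix(points)
  rel <- sweep(m, 2, cyl$center)
  s <- rel %*% cyl$axis
  q1 <- rel %*% cyl$e1; q2 <- rel %*% cyl$e2
  theta <- atan2(q2 / cyl$b, q1 / cyl$a) %% (2 * pi)
  v <- ellipse_arc(cyl, theta)
  sp <- ellipse_surface_point(cyl, as.numeric(s), as.numeric(theta))
  z <- rowSums((m - sp$P) * sp$normal)
  cbind(x = as.numeric(s), y = as.numeric(v), z = as.numeric(z))
}

## ---- FlatMap ------------------------------------------------------------

new_flatmap <- function(S, N, u0, v0, wt, valid = NULL, meta = list()) {
  d <- dim(S)[1:2]
  wt <- as.numeric(wt)
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  structure(list(S = S, N = N, u0 = u0, v0 = v0, wt = wt, wc = wt,
                 valid = valid, meta = meta),
            class = "flatmap")
}

#' @export
print.flatmap <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf("<flatmap> %d x %d grid, slab thickness %d (w_c = %d, 0-based)\n",
              d[1], d[2], 2 * x$wt + 1, x$wc))
  invisible(x)
}

# Unit normals from central differences of S over the (u,v) grid (Eq. of
# the cross product of the numerical tangents); one-sided at edges.
normals_from_grid <- function(S) {
  nu <- dim(S)[1]; nv <- dim(S)[2]
  du <- array(0, dim(S)); dv <- array(0, dim(S))
  iu <- seq_len(nu); iv <- seq_len(nv)
  up <- pmin(iu + 1, nu); um <- pmax(iu - 1, 1)
  vp <- pmin(iv + 1, nv); vm <- pmax(iv - 1, 1)
  for (c in 1:3) {
    du[, , c] <- (S[up, , c] - S[um, , c]) / (up - um)
    dv[, , c] <- (S[, vp, c] - S[, vm, c]) /
      matrix(vp - vm, nu, nv, byrow = TRUE)
  }
  N <- array(0, dim(S))
  N[, , 1] <- du[, , 2] * dv[, , 3] - du[, , 3] * dv[, , 2]
  N[, , 2] <- du[, , 3] * dv[, , 1] - du[, , 1] * dv[, , 3]
  N[, , 3] <- du[, , 1] * dv[, , 2] - du[, , 2] * dv[, , 1]
  len <- sqrt(N[, , 1]^2 + N[, , 2]^2 + N[, , 3]^2)
  for (c in 1:3) N[, , c] <- N[, , c] / len
  N
}

#' Build the (u,v) surface sample grid and normals
#'
#' Samples the fitted surface on an integer (u,v) grid with 1-pixel spacing:
#' u = local x, v = circumferential arc length along the intermediate
#' cylinder (so equidistant v corresponds to equal arc length on the
#' cylinder), z = f(x, y(v)); points are rotated to raw coordinates and unit
#' normals are computed by central differences of the sampled grid.
#'
#' @param surface `height_surface` fitted in the frame's local coordinates
#'   (open pathway) or in elliptic surface coordinates (closed pathway).
#' @param frame the [frame_transform()] for the open pathway; ignored for
#'   an elliptic cylinder.
#' @param cyl `cylinder_model`; for the open pathway a [cylinder_poly()]
#'   (use coefficient 0 for a pure plane projection).
#' @param wt slab half-thickness in pixels (>= 0).
#' @return A `flatmap` with S(u,v), N(u,v), slab parameters, and grid
#'   offsets. The flattened voxel (0,0,w_c) corresponds to the first grid
#'   node; w is 0-based with central slice w_c = w_t.
#' @export
build_flatmap <- function(surface, frame, cyl, wt = 15) {
  stopifnot(inherits(surface, "height_surface"), wt >= 0)
  dom <- surface$domain
  if (cyl$kind == "poly_open") {
    u_vals <- seq(ceiling(dom[1, 1]), floor(dom[2, 1]))
    v_max <- arc_length(cyl, min(dom[2, 2], cyl$y_max))
    v_min <- arc_length(cyl, max(dom[1, 2], cyl$y_min))
    v_vals <- seq(ceiling(v_min), floor(v_max))
    if (!length(u_vals) || !length(v_vals)) stop("surface footprint is empty")
    y_of_v <- arc_inverse(cyl, v_vals)
    S <- array(0, c(length(u_vals), length(v_vals), 3))
    for (j in seq_along(v_vals)) {
      x <- u_vals; y <- rep(y_of_v[j], length(x))
      z <- surface_eval(surface, x, y)
      S[, j, ] <- local_to_raw(frame, cbind(x, y, z))
    }
  } else {
    u_vals <- seq(ceiling(dom[1, 1]), floor(dom[2, 1]))
    circ <- ellipse_circumference(cyl)
    v_hi <- min(floor(dom[2, 2]), floor(circ))
    v_vals <- seq(max(0, ceiling(dom[1, 2])), v_hi)
    if (!length(u_vals) || !length(v_vals)) stop("surface footprint is empty")
    theta <- ellipse_arc_inverse(cyl, v_vals)
    S <- array(0, c(length(u_vals), length(v_vals), 3))
    for (j in seq_along(v_vals)) {
      s <- u_vals
      f <- surface_eval(surface, s, rep(v_vals[j], length(s)))
      sp <- ellipse_surface_point(cyl, s, rep(theta[j], length(s)))
      S[, j, ] <- sp$P + f * sp$normal
    }
  }
  N <- normals_from_grid(S)
  new_flatmap(S, N, u0 = u_vals[1], v0 = v_vals[1], wt = wt,
              meta = list(cylinder = cyl$kind, surface = surface$kind))
}

# Bilinear interpolation of a [nu, nv, 3] grid array at continuous 0-based
# grid coordinates; returns an n x 3 matrix.
bilin_grid <- function(A, u, v) {
  nu <- dim(A)[1]; nv <- dim(A)[2]
  u <- pmin(pmax(u, 0), nu - 1); v <- pmin(pmax(v, 0), nv - 1)
  i0 <- pmin(floor(u), nu - 2); j0 <- pmin(floor(v), nv - 2)
  if (nu == 1) i0 <- rep(0, length(u))
  if (nv == 1) j0 <- rep(0, length(v))
  fu <- u - i0; fv <- v - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  i1 <- pmin(i0 + 1, nu); j1 <- pmin(j0 + 1, nv)
  out <- matrix(0, length(u), 3)
  for (c in 1:3) {
    M <- A[, , c]
    out[, c] <-
      M[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
      M[cbind(i1, j0)] * fu * (1 - fv) +
      M[cbind(i0, j1)] * (1 - fu) * fv +
      M[cbind(i1, j1)] * fu * fv
  }
  out
}

#' Map flattened coordinates to raw tomogram coordinates
#'
#' Applies `X(u,v,w) = S(u,v) + (w - w_c) N(u,v)` with S and N bilinearly
#' interpolated between grid nodes (N re-normalized after interpolation).
#' All coordinates are 0-based flattened voxel coordinates.
#'
#' @param flatmap a `flatmap`.
#' @param uvw n x 3 matrix (or length-3 vector) of (u, v, w).
#' @return n x 3 matrix of raw (X, Y, Z).
#' @export
flat_to_raw <- function(flatmap, uvw) {
  uvw <- rbind3(uvw)
  nu <- dim(flatmap$S)[1]; nv <- dim(flatmap$S)[2]
  if (any(uvw[, 1] < -1e-9 | uvw[, 1] > nu - 1 + 1e-9 |
          uvw[, 2] < -1e-9 | uvw[, 2] > nv - 1 + 1e-9))
    stop("(u,v) outside the flatmap grid")
  S <- bilin_grid(flatmap$S, uvw[, 1], uvw[, 2])
  N <- bilin_grid(flatmap$N, uvw[, 1], uvw[, 2])
  N <- N / sqrt(rowSums(N^2))
  S + (uvw[, 3] - flatmap$wc) * N
}

#' Map raw tomogram coordinates to flattened coordinates
#'
#' Seeds at the nearest surface grid node and refines (u, v) by 2D
#' Gauss-Newton so the tangential residual of
#' `P - S(u,v) - ((P - S) . N) N` vanishes; then `w = w_c + (P - S) . N`.
#' Points whose final tangential residual exceeds `tol` or that lie beyond
#' the slab are flagged unmappable.
#'
#' @param flatmap a `flatmap`.
#' @param xyz n x 3 matrix (or 3-vector) of raw coordinates.
#' @param tol success tolerance on the tangential residual, voxels.
#' @return data.frame with u, v, w, residual, ok.
#' @export
raw_to_flat <- function(flatmap, xyz, tol = 0.5) {
  P <- rbind3(xyz)
  nu <- dim(flatmap$S)[1]; nv <- dim(flatmap$S)[2]
  nodes <- matrix(flatmap$S, ncol = 3)
  seed <- nearest_node_cpp(nodes, P) - 1L
  u <- seed %% nu; v <- seed %/% nu
  h <- 0.05
  for (iter in 1:40) {
    S <- bilin_grid(flatmap$S, u, v)
    N <- bilin_grid(flatmap$N, u, v)
    N <- N / sqrt(rowSums(N^2))
    e <- P - S
    w_off <- rowSums(e * N)
    tang <- e - w_off * N
    Su1 <- bilin_grid(flatmap$S, pmin(u + h, nu - 1), v)
    Su0 <- bilin_grid(flatmap$S, pmax(u - h, 0), v)
    Sv1 <- bilin_grid(flatmap$S, u, pmin(v + h, nv - 1))
    Sv0 <- bilin_grid(flatmap$S, u, pmax(v - h, 0))
    Ju <- (Su1 - Su0) / (pmin(u + h, nu - 1) - pmax(u - h, 0))
    Jv <- (Sv1 - Sv0) / (pmin(v + h, nv - 1) - pmax(v - h, 0))
    a11 <- rowSums(Ju * Ju); a12 <- rowSums(Ju * Jv); a22 <- rowSums(Jv * Jv)
    b1 <- rowSums(Ju * tang); b2 <- rowSums(Jv * tang)
    det <- a11 * a22 - a12^2
    det[det < 1e-12] <- 1e-12
    du <- (a22 * b1 - a12 * b2) / det
    dv <- (a11 * b2 - a12 * b1) / det
    step_cap <- 2
    du <- pmin(pmax(du, -step_cap), step_cap)
    dv <- pmin(pmax(dv, -step_cap), step_cap)
    u <- pmin(pmax(u + du, 0), nu - 1)
    v <- pmin(pmax(v + dv, 0), nv - 1)
    if (max(abs(c(du, dv))) < 1e-10) break
  }
  S <- bilin_grid(flatmap$S, u, v)
  N <- bilin_grid(flatmap$N, u, v)
  N <- N / sqrt(rowSums(N^2))
  e <- P - S
  w_off <- rowSums(e * N)
  resid <- sqrt(rowSums((e - w_off * N)^2))
  ok <- resid < tol & abs(w_off) <= flatmap$wt + 0.5
  data.frame(u = u, v = v, w = flatmap$wc + w_off, residual = resid, ok = ok)
}

#' Render the flattened tomogram
#'
#' Samples the raw tomogram by trilinear interpolation at
#' `S(u,v) + (w - w_c) N(u,v)` for every flattened voxel. Source locations
#' outside the raw volume receive the raw volume's mean value and are
#' flagged in the validity mask.
#'
#' @param tomo raw [voxel_volume()].
#' @param flatmap a `flatmap`.
#' @param fill fill value for out-of-bounds samples (default: mean of the
#'   raw tomogram).
#' @return list with `volume` (a [voxel_volume()] of dims
#'   (n_u, n_v, 2 w_t + 1)) and `valid` (logical array of the same dims).
#' @export
render_flattened <- function(tomo, flatmap, fill = NULL) {
  stopifnot(inherits(tomo, "voxel_volume"), inherits(flatmap, "flatmap"))
  if (is.null(fill)) fill <- mean(tomo$data)
  nu <- dim(flatmap$S)[1]; nv <- dim(flatmap$S)[2]
  nw <- 2L * flatmap$wt + 1L
  out <- array(0, c(nu, nv, nw))
  valid <- array(FALSE, c(nu, nv, nw))
  Smat <- matrix(flatmap$S, ncol = 3)
  Nmat <- matrix(flatmap$N, ncol = 3)
  for (w in seq_len(nw) - 1L) {
    pts <- Smat + (w - flatmap$wc) * Nmat
    r <- trilinear_cpp(tomo$data, pts, fill)
    out[, , w + 1L] <- r$values
    valid[, , w + 1L] <- r$valid
  }
  list(volume = voxel_volume(out, tomo$voxel_size),
       valid = valid, flatmap = flatmap)
}

#' Triangulate a flattened-tomogram slice as a 3D mesh
#'
#' Vertices are `S(u,v) + (w - w_c) N(u,v)` over the flatmap grid; texture
#' coordinates are the 0-based (u, v) grid coordinates, so the mesh renders
#' the slice as the curved surface it came from.
#'
#' @param flatmap a `flatmap`.
#' @param w slice index (0-based, within the slab).
#' @return A [param_mesh()] with `n_u * n_v` vertices and
#'   `2 (n_u - 1)(n_v - 1)` faces.
#' @export
slice_to_mesh <- function(flatmap, w = flatmap$wc) {
  nu <- dim(flatmap$S)[1]; nv <- dim(flatmap$S)[2]
  V <- matrix(flatmap$S, ncol = 3) + (w - flatmap$wc) * matrix(flatmap$N, ncol = 3)
  tc <- cbind(rep(0:(nu - 1), nv), rep(0:(nv - 1), each = nu))
  idx <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1), nv - 1)
  j <- rep(seq_len(nv - 1), each = nu - 1)
  f1 <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
  f2 <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  param_mesh(V, rbind(f1, f2), tc)
}

## ---- UV-mesh pathway ----------------------------------------------------

point_in_hull <- function(pts, hull) {
  # hull: counter-clockwise polygon vertices (k x 2)
  inside <- rep(TRUE, nrow(pts))
  k <- nrow(hull)
  for (i in seq_len(k)) {
    a <- hull[i, ]; b <- hull[if (i == k) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= -1e-9
  }
  inside
}

#' Flatten a membrane given as a UV-parameterized triangle mesh
#'
#' Fits three TPS coordinate functions X(u,v), Y(u,v), Z(u,v) to the mesh
#' vertices over their texture coordinates, samples them on the integer
#' (u,v) grid inside the convex hull of the texture coordinates, computes
#' normals by central differences, and renders the slab exactly like the
#' direct pathway.
#'
#' @param tomo raw [voxel_volume()].
#' @param mesh a [param_mesh()].
#' @param wt slab half-thickness in pixels.
#' @param uv_scale factor applied to the texture coordinates so that one uv
#'   unit corresponds to about one voxel of surface arc (1 if the
#'   parameterization is already in voxel units).
#' @param lambda TPS smoothing (default 0: mesh vertices are interpolated).
#' @param max_control cap on TPS control points; denser meshes are grid
#'   downsampled in (u, v).
#' @return list(flatmap, flat = render_flattened() result).
#' @export
flatten_mesh <- function(tomo, mesh, wt = 15, uv_scale = 1, lambda = 0,
                         max_control = 700) {
  stopifnot(inherits(mesh, "param_mesh"))
  uv <- mesh$texcoords * uv_scale
  V <- mesh$vertices
  area3d <- mesh_area3d(mesh)
  areauv <- mesh_area_uv(mesh) * uv_scale^2
  if (areauv < 1e-3 * area3d)
    stop("collapsed parameterization: uv area is vanishingly small ",
         "compared to the 3D surface area (severe distortion)")
  n <- nrow(V)
  if (n > max_control) {
    spacing <- sqrt(areauv / max_control)
    keep <- !duplicated(paste(floor(uv[, 1] / spacing),
                              floor(uv[, 2] / spacing)))
    uv_c <- uv[keep, , drop = FALSE]; V_c <- V[keep, , drop = FALSE]
  } else { uv_c <- uv; V_c <- V }
  fits <- lapply(1:3, function(c)
    tps_system_solve(uv_c, V_c[, c], lambda))
  u_vals <- seq(ceiling(min(uv[, 1])), floor(max(uv[, 1])))
  v_vals <- seq(ceiling(min(uv[, 2])), floor(max(uv[, 2])))
  if (!length(u_vals) || !length(v_vals)) stop("surface footprint is empty")
  g <- cbind(rep(u_vals, length(v_vals)), rep(v_vals, each = length(u_vals)))
  hull_idx <- grDevices::chull(uv)
  hull <- uv[rev(hull_idx), , drop = FALSE]    # chull is clockwise
  inside <- point_in_hull(g, hull)
  S <- array(0, c(length(u_vals), length(v_vals), 3))
  for (c in 1:3)
    S[, , c] <- tps_eval_core(uv_c, fits[[c]]$w, fits[[c]]$a, g[, 1], g[, 2])
  N <- normals_from_grid(S)
  fm <- new_flatmap(S, N, u0 = u_vals[1], v0 = v_vals[1], wt = wt,
                    valid = matrix(inside, length(u_vals), length(v_vals)),
                    meta = list(cylinder = "mesh", surface = "tps",
                                uv_scale = uv_scale))
  list(flatmap = fm, flat = render_flattened(tomo, fm))
}

mesh_area3d <- function(mesh) {
  f <- mesh$faces; V <- mesh$vertices
  a <- V[f[, 2], ] - V[f[, 1], ]; b <- V[f[, 3], ] - V[f[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

mesh_area_uv <- function(mesh) {
  f <- mesh$faces; tc <- mesh$texcoords
  a <- tc[f[, 2], ] - tc[f[, 1], ]; b <- tc[f[, 3], ] - tc[f[, 1], ]
  sum(abs(a[, 1] * b[, 2] - a[, 2] * b[, 1])) / 2
}

## ---- high-level orchestration ------------------------------------------

#' Flatten a membrane around a tomogram from starting points
#'
#' Orchestrates the direct pathway: determine the local frame (with bend
#' axis selection), fit the intermediate cylinder (or use a pure plane
#' projection), fit the height surface, build the flatmap, and render.
#'
#' @param tomo raw [voxel_volume()].
#' @param points [point_set()] of starting points on the membrane.
#' @param mode `"cylinder"` (polynomial cylinder + unrolling), `"plane"`
#'   (direct projection along the local z-axis), or `"elliptic"` (closed
#'   membranes).
#' @param surface_kind `"tps"` or `"polynomial"` height surface.
#' @param wt slab half-thickness in pixels (default 15).
#' @param cyl_degree polynomial degree of the cylinder h(y).
#' @param poly_degree degree when `surface_kind = "polynomial"`.
#' @param spacing TPS downsample spacing in voxels.
#' @param lambda TPS smoothing.
#' @return list(flat, valid, flatmap, frame, cylinder, surface).
#' @export
flatten_tomogram <- function(tomo, points,
                             mode = c("cylinder", "plane", "elliptic"),
                             surface_kind = c("tps", "polynomial"),
                             wt = 15, cyl_degree = 3, poly_degree = 4,
                             spacing = 12, lambda = 0) {
  mode <- match.arg(mode); surface_kind <- match.arg(surface_kind)
  pts <- as_point_matrix(points)
  if (mode == "elliptic") {
    cyl <- fit_cylinder_elliptic(pts)
    loc <- elliptic_local_coords(cyl, pts)
    frame <- NULL
  } else if (mode == "cylinder") {
    cf <- fit_cylinder_poly(pts, degree = cyl_degree)
    cyl <- cf$cylinder; frame <- cf$frame
    loc <- raw_to_local(frame, pts)
  } else {
    frame <- determine_frame(pts)
    loc <- raw_to_local(frame, pts)
    cyl <- cylinder_poly(0, range(loc[, 2]))
  }
  surface <- if (surface_kind == "tps")
    fit_tps(loc, downsample_spacing = spacing, lambda = lambda)
  else fit_polynomial(loc, degree = poly_degree)
  fm <- build_flatmap(surface, frame, cyl, wt = wt)
  rend <- render_flattened(tomo, fm)
  list(flat = rend$volume, valid = rend$valid, flatmap = fm,
       frame = frame, cylinder = cyl, surface = surface)
}

#' Serialize / restore a flatmap as a JSON sidecar
#'
#' Stores the full S and N grids, slab parameters, grid offsets, validity
#' mask, and provenance, so coordinate conversions are reproducible without
#' refitting.
#'
#' @param flatmap a `flatmap`.
#' @param path JSON path.
#' @export
write_flatmap <- function(flatmap, path) {
  obj <- list(dims = dim(flatmap$S)[1:2],
              S = as.numeric(flatmap$S), N = as.numeric(flatmap$N),
              u0 = flatmap$u0, v0 = flatmap$v0, wt = flatmap$wt,
              valid = as.logical(flatmap$valid), meta = flatmap$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_flatmap
#' @export
read_flatmap <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(o$dims)
  new_flatmap(array(o$S, c(d, 3)), array(o$N, c(d, 3)),
              u0 = o$u0, v0 = o$v0, wt = o$wt,
              valid = matrix(o$valid, d[1], d[2]),
              meta = as.list(o$meta))
}
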