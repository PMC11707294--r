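test_that("polynomial cylinder fitting recovers a known parabolic sheet", {
  set.seed(14)
  g <- as.matrix(expand.grid(x = seq(-40, 40, 2), y = seq(-40, 40, 2)))
  pts <- cbind(g[, 1] + 60, g[, 2] + 60, 0.01 * g[, 2]^2 + 30)
  cf <- fit_cylinder_poly(point_set(pts), degree = 2)
  expect_lt(cf$residual, 1e-6)
  expect_equal(abs(cf$cylinder$coef[3]), 0.01, tolerance = 1e-4)

  # planar points with a linear cylinder fit exactly
  flat <- cbind(g + 50, 0.3 * g[, 2] + 20)
  cfl <- fit_cylinder_poly(point_set(flat), degree = 1)
  expect_lt(cfl$residual, 1e-8)

  # pre-rotating the parabola about X is undone by the joint fit
  th <- 10 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  rot <- sweep(sweep(pts, 2, c(60, 60, 30)) %*% t(Rx), 2, c(60, 60, 30), "+")
  cfr <- fit_cylinder_poly(point_set(rot), degree = 2)
  expect_lt(cfr$residual, 1e-4)
  expect_equal(abs(cfr$cylinder$coef[3]), 0.01, tolerance = 1e-3)
  # the recovered local frame views the rotated sheet exactly as z = h(y):
  # its z-axis must equal the rotated sheet normal at the apex within 0.1 deg
  n_apex <- Rx %*% c(0, 0, 1)
  ang <- acos(min(1, abs(sum(cfr$frame$R[, 3] * n_apex)))) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("arc length obeys closed forms and inverts exactly", {
  flat <- cylinder_poly(c(5), c(-20, 20))
  expect_equal(arc_length(flat, c(-20, 0, 13.5)), c(0, 20, 33.5))

  slope1 <- cylinder_poly(c(0, 1), c(-10, 30))
  expect_equal(arc_length(slope1, c(-10, 5, 30)),
               sqrt(2) * c(0, 15, 40), tolerance = 1e-9)

  quad <- cylinder_poly(c(0, 0, 1), c(-3, 3))   # h = y^2
  ys <- seq(-3, 3, 0.5)
  oracle <- vapply(ys, function(y)
    simpson(function(t) sqrt(1 + 4 * t^2), -3, y, n = 4000), numeric(1))
  expect_equal(arc_length(quad, ys), oracle, tolerance = 1e-6)
  # composition y(v(y)) = y
  expect_equal(arc_inverse(quad, arc_length(quad, ys)), ys, tolerance = 1e-6)
  expect_true(all(diff(arc_length(quad, ys)) > 0))
})

test_that("elliptic cylinder fitting recovers analytic cross sections", {
  ph <- make_phantom("circular_cylinder", dims = c(64, 140, 140), radius = 50,
                     center = c(69.5, 69.5), angular_range = c(-180, 180),
                     seed = 5)
  cyl <- fit_cylinder_elliptic(ph$surface_truth)
  expect_equal(cyl$a, 50, tolerance = 0.01 * 50)
  expect_equal(cyl$b, 50, tolerance = 0.01 * 50)

  ph2 <- make_phantom("elliptic_cylinder", dims = c(64, 160, 120),
                      semi_axes = c(60, 40), center = c(79.5, 59.5), seed = 4)
  cyl2 <- fit_cylinder_elliptic(ph2$surface_truth)
  expect_equal(cyl2$a, 60, tolerance = 0.01 * 60)
  expect_equal(cyl2$b, 40, tolerance = 0.01 * 40)

  # circumference against a quadrature oracle on the fixture ellipse
  circ <- ellipse_circumference(cyl2)
  oracle <- simpson(function(t) sqrt(60^2 * sin(t)^2 + 40^2 * cos(t)^2),
                    0, 2 * pi, n = 4000)
  expect_equal(circ, oracle, tolerance = 0.005 * oracle)

  # under-coverage triggers a warning recommending the open pathway
  ph3 <- make_phantom("circular_cylinder", dims = c(64, 140, 90), radius = 50,
                      center = c(69.5, 20), angular_range = c(40, 140),
                      seed = 6)
  expect_warning(fit_cylinder_elliptic(ph3$surface_truth), "coverage")
})

test_that("flatmap construction: planar identity and cylinder normals", {
  # planar surface, identity-like frame
  g <- as.matrix(expand.grid(x = seq(5, 55), y = seq(5, 45)))
  pts <- cbind(g, 12)
  fr <- determine_frame(point_set(pts))
  surf <- fit_polynomial(raw_to_local(fr, pts), degree = 1)
  fm <- build_flatmap(surf, fr, cylinder_poly(0, range(raw_to_local(fr, pts)[, 2])),
                      wt = 3)
  expect_equal(dim(fm$S)[3], 3)
  expect_lt(max(abs(fm$S[, , 3] - 12)), 1e-9)
  expect_lt(max(abs(fm$N[, , 1])), 1e-9)
  expect_equal(fm$N[1, 1, ], c(0, 0, 1), tolerance = 1e-9)
  # S steps by exactly one voxel in u and v
  expect_equal(fm$S[2, 1, ] - fm$S[1, 1, ], c(1, 0, 0), tolerance = 1e-9)

  cc <- cylinder_case()
  fm2 <- cc$flatmap
  S <- matrix(fm2$S, ncol = 3); N <- matrix(fm2$N, ncol = 3)
  radial <- cbind(0, S[, 2] - cc$center[1], S[, 3] - cc$center[2])
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, abs(rowSums(N * radial)))) * 180 / pi
  expect_lt(max(ang), 1)
  expect_lt(max(abs(sqrt(rowSums(N^2)) - 1)), 1e-6)

  # equal arc-length: successive v nodes are 1.0 +/- 0.02 voxels apart in 3D
  dv <- sqrt(apply((fm2$S[, -1, ] - fm2$S[, -dim(fm2$S)[2], ])^2, c(1, 2), sum))
  expect_true(all(abs(dv - 1) < 0.02))
  # grid continuity in u as well
  du <- sqrt(apply((fm2$S[-1, , ] - fm2$S[-dim(fm2$S)[1], , ])^2, c(1, 2), sum))
  expect_true(all(du < 3))
})

test_that("rendering has the stated slab shape and interpolates trilinearly", {
  cc <- cylinder_case()
  fm <- cc$flatmap
  expect_equal(dim(fm$S)[3], 3)

  # wt = 15 gives 31 slices
  fm15 <- build_flatmap(cc$surface, cc$fit$frame, cc$fit$cylinder, wt = 15)
  out15 <- render_flattened(cc$ph$tomo, fm15)
  expect_equal(dim(out15$volume$data)[3], 31)

  # constant tomogram renders constant wherever valid
  const <- voxel_volume(array(2.5, dim(cc$ph$tomo$data)))
  rc <- render_flattened(const, fm)
  expect_true(all(abs(rc$volume$data[rc$valid] - 2.5) < 1e-12))

  # wt = 0 renders exactly the sampled central surface
  fm0 <- build_flatmap(cc$surface, cc$fit$frame, cc$fit$cylinder, wt = 0)
  r0 <- render_flattened(cc$ph$tomo, fm0)
  oracle <- tri_oracle(cc$ph$tomo$data, matrix(fm0$S, ncol = 3),
                       fill = mean(cc$ph$tomo$data))
  expect_equal(as.numeric(r0$volume$data), oracle, tolerance = 1e-12)
})

test_that("flat_to_raw applies the normal extension exactly at nodes", {
  cc <- cylinder_case()
  fm <- cc$flatmap
  u0 <- 7; v0 <- 9
  S <- fm$S[u0 + 1, v0 + 1, ]; N <- fm$N[u0 + 1, v0 + 1, ]
  expect_equal(as.numeric(flat_to_raw(fm, c(u0, v0, fm$wc))), S,
               tolerance = 1e-12)
  expect_equal(as.numeric(flat_to_raw(fm, c(u0, v0, fm$wc + 5))), S + 5 * N,
               tolerance = 1e-9)
  # linearity in w is exact at grid nodes
  d1 <- flat_to_raw(fm, c(u0, v0, 4)) - flat_to_raw(fm, c(u0, v0, 3))
  expect_equal(as.numeric(d1), N, tolerance = 1e-12)
  expect_error(flat_to_raw(fm, c(-5, 2, 0)), "outside")
})

test_that("raw_to_flat inverts the mapping and matches a grid-search oracle", {
  cc <- cylinder_case()
  fm <- cc$flatmap
  nu <- dim(fm$S)[1]; nv <- dim(fm$S)[2]

  # grid node inverts exactly
  r <- raw_to_flat(fm, fm$S[8, 11, ])
  expect_equal(c(r$u, r$v, r$w), c(7, 10, fm$wc), tolerance = 1e-6)

  # +/- wt along the normal
  for (s in c(-1, 1)) {
    P <- fm$S[8, 11, ] + s * fm$wt * fm$N[8, 11, ]
    r2 <- raw_to_flat(fm, P)
    expect_equal(r2$w, fm$wc + s * fm$wt, tolerance = 1e-3)
    expect_true(r2$ok)
  }

  # grid-search + quadratic-refinement oracle on random in-slab points
  set.seed(15)
  n <- 60
  uvw <- cbind(runif(n, 2, nu - 3), runif(n, 2, nv - 3),
               runif(n, 0, 2 * fm$wt))
  P <- flat_to_raw(fm, uvw)
  est <- raw_to_flat(fm, P)
  oracle_uv <- t(vapply(seq_len(n), function(i) {
    obj <- function(p) {
      p <- pmin(pmax(p, 0), c(nu - 1, nv - 1))
      X <- flat_to_raw(fm, c(p, fm$wc))
      e <- P[i, ] - X
      nrm <- e - sum(e * (flat_to_raw(fm, c(p, fm$wc + 1)) - X)) *
        (flat_to_raw(fm, c(p, fm$wc + 1)) - X)
      sum(nrm^2)
    }
    # coarse exhaustive grid, then Nelder-Mead refinement
    gr <- as.matrix(expand.grid(u = seq(0, nu - 1, 2), v = seq(0, nv - 1, 2)))
    vals <- apply(gr, 1, obj)
    p0 <- gr[which.min(vals), ]
    optim(p0, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 500))$par
  }, numeric(2)))
  expect_lt(max(abs(est$u - oracle_uv[, 1])), 0.05)
  expect_lt(max(abs(est$v - oracle_uv[, 2])), 0.05)
  expect_lt(max(abs(cbind(est$u, est$v, est$w) - uvw)), 0.5)
})

test_that("slice meshes triangulate the slab surfaces", {
  cc <- cylinder_case()
  fm <- cc$flatmap
  nu <- dim(fm$S)[1]; nv <- dim(fm$S)[2]
  msh <- slice_to_mesh(fm, fm$wc)
  expect_equal(nrow(msh$vertices), nu * nv)
  expect_equal(nrow(msh$faces), 2 * (nu - 1) * (nv - 1))
  r <- sqrt((msh$vertices[, 2] - cc$center[1])^2 +
              (msh$vertices[, 3] - cc$center[2])^2)
  expect_lt(max(abs(r - cc$radius)), 0.1)

  # planar flatmap at the central slice gives a flat mesh congruent to the grid
  g <- as.matrix(expand.grid(x = seq(5, 25), y = seq(5, 25)))
  fr <- determine_frame(point_set(cbind(g, 7)))
  surf <- fit_polynomial(raw_to_local(fr, cbind(g, 7)), degree = 1)
  fmp <- build_flatmap(surf, fr, cylinder_poly(0, c(-10, 10)), wt = 2)
  mp <- slice_to_mesh(fmp, fmp$wc)
  expect_lt(max(abs(mp$vertices[, 3] - 7)), 1e-9)
  d01 <- sqrt(sum((mp$vertices[2, ] - mp$vertices[1, ])^2))
  expect_equal(d01, 1, tolerance = 1e-9)
})

test_that("UV-mesh pathway agrees with the direct cylindrical pathway", {
  ph <- make_phantom("circular_cylinder", dims = c(96, 128, 96), radius = 40,
                     center = c(63.5, 20), angular_range = c(40, 140),
                     seed = 2, with_mesh = TRUE)
  res <- flatten_mesh(ph$tomo, ph$mesh, wt = 8)
  fmm <- res$flatmap
  expect_lt(max(abs(sqrt(apply(fmm$N^2, c(1, 2), sum)) - 1)), 1e-6)

  cc <- cylinder_case()
  fmd <- cc$flatmap
  set.seed(16)
  sp <- ph$geometry$point_on_surface(runif(150, 15, 80),
                                     runif(150, 48 * pi / 180,
                                           132 * pi / 180))$P
  a <- raw_to_flat(fmm, sp); b <- raw_to_flat(fmd, sp)
  expect_true(all(a$ok & b$ok))
  # the two parameterizations agree up to an in-plane isometry
  # (translation and possible axis reversal)
  align <- function(x, y) {
    s <- if (cor(x, y) >= 0) 1 else -1
    y * s + median(x - s * y)
  }
  expect_lt(max(abs(a$u - align(a$u, b$u))), 0.5)
  expect_lt(max(abs(a$v - align(a$v, b$v))), 0.5)

  # planar mesh with identity texcoords -> identity flatmap
  gm <- make_phantom("plane", dims = c(48, 48, 32), offset = 12, seed = 1,
                     with_mesh = TRUE)
  rp <- flatten_mesh(gm$tomo, gm$mesh, wt = 2)
  Sp <- rp$flatmap$S
  expect_lt(max(abs(Sp[, , 3] - 12)), 1e-6)
  expect_equal(Sp[2, 1, 1] - Sp[1, 1, 1], 1, tolerance = 1e-6)

  # collapsed parameterization errors out
  bad <- gm$mesh
  bad$texcoords <- bad$texcoords * 1e-4
  expect_error(flatten_mesh(gm$tomo, bad, wt = 2), "collapsed")
})

test_that("sphere mesh with equirectangular texcoords flattens with finite distortion", {
  ph <- make_phantom("sphere", dims = c(110, 110, 80), radius = 36,
                     center = c(54.5, 54.5, 10), cap_angle = 55, seed = 3,
                     with_mesh = TRUE)
  res <- flatten_mesh(ph$tomo, ph$mesh, wt = 2)
  fm <- res$flatmap
  expect_lt(max(abs(sqrt(apply(fm$N^2, c(1, 2), sum)) - 1)), 1e-6)
  dm <- distortion_map(fm)
  inside <- fm$valid & !dm$edge
  expect_true(all(is.finite(dm$area[inside])))
  # equirectangular stretching grows away from the reference latitude
  expect_gt(max(dm$area[inside]), 1.05)
})

test_that("flatmaps survive the JSON sidecar round trip", {
  cc <- cylinder_case()
  p <- withr::local_tempfile(fileext = ".json")
  write_flatmap(cc$flatmap, p)
  back <- read_flatmap(p)
  expect_equal(back$S, cc$flatmap$S, tolerance = 1e-12)
  expect_equal(back$N, cc$flatmap$N, tolerance = 1e-12)
  expect_equal(back$wt, cc$flatmap$wt)
  r1 <- flat_to_raw(back, c(5.5, 6.5, 3))
  expect_equal(r1, flat_to_raw(cc$flatmap, c(5.5, 6.5, 3)), tolerance = 1e-12)
})
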