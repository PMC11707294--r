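## Synthetic tomograms, masks, meshes, and ground-truth tables.

#' Fourier-space missing-wedge filter
#'
#' Binary pass mask over the FFT layout of a volume of the given dims (DC at
#' [1,1,1]): a Fourier component is kept iff some tilt in
#' `[-tilt_range, +tilt_range]` measures it, i.e. iff the angle of (qx, qz)
#' from the qx axis is at most `tilt_range`; equivalently the zeroed region
#' is the double wedge of half-angle `90 - tilt_range` degrees about the qz
#' axis (tilt axis = Y). Applying the mask twice equals applying it once.
#'
#' @param dims volume dims (nx, ny, nz).
#' @param tilt_range half tilt range in degrees (90 = all-pass).
#' @return 0/1 array of `dims` in FFT layout.
#' @export
make_wedge_filter <- function(dims, tilt_range) {
  stopifnot(tilt_range > 0, tilt_range <= 90)
  signed_freq <- function(n) {
    k <- 0:(n - 1)
    ifelse(k > n / 2, k - n, k) / n
  }
  fx <- signed_freq(dims[1]); fz <- signed_freq(dims[3])
  FX <- matrix(fx, dims[1], dims[3])
  FZ <- matrix(fz, dims[1], dims[3], byrow = TRUE)
  phi <- atan2(abs(FX), abs(FZ)) * 180 / pi
  pass2d <- phi >= (90 - tilt_range) | (FX == 0 & FZ == 0)
  out <- array(0, dims)
  for (k in seq_len(dims[3]))
    out[, , k] <- matrix(as.numeric(pass2d[, k]), dims[1], dims[2])
  out
}

#' Apply a missing-wedge filter to a volume in Fourier space
#' @param vol [voxel_volume()] or 3D array.
#' @param tilt_range half tilt range in degrees.
#' @export
apply_wedge <- function(vol, tilt_range) {
  arr <- if (inherits(vol, "voxel_volume")) vol$data else vol
  w <- make_wedge_filter(dim(arr), tilt_range)
  res <- Re(stats::fft(stats::fft(arr) * w, inverse = TRUE)) / length(arr)
  if (inherits(vol, "voxel_volume"))
    voxel_volume(res, vol$voxel_size, vol$origin) else res
}

# Analytic description of a phantom membrane: signed-distance field,
# surface sampler, and normals.
phantom_geometry <- function(shape, dims, offset, coef, amplitude, period,
                             radius, center, semi_axes, angular_range,
                             cap_angle) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  Xv <- 0:(nx - 1); Yv <- 0:(ny - 1); Zv <- 0:(nz - 1)
  mid <- (dims - 1) / 2
  sheet <- function(fmat, gxmat, gymat) {
    invs <- 1 / sqrt(1 + gxmat^2 + gymat^2)
    list(
      dist = function() {
        arr <- array(0, dims)
        for (k in seq_len(nz)) arr[, , k] <- (Zv[k] - fmat) * invs
        arr
      },
      sample_surface = function(step) {
        xs <- seq(2, nx - 3, by = step); ys <- seq(2, ny - 3, by = step)
        g <- expand.grid(x = xs, y = ys)
        cbind(g$x, g$y, fmat[cbind(g$x + 1, g$y + 1)])
      },
      point_on_surface = function(x, y) {
        f <- fval(x, y); gx <- gxval(x, y); gy <- gyval(x, y)
        n <- cbind(-gx, -gy, 1)
        n <- n / sqrt(rowSums(n^2))
        list(P = cbind(x, y, f), normal = n)
      })
  }
  if (shape %in% c("plane", "poly_sheet", "sinusoid_sheet")) {
    if (shape == "plane") {
      z0 <- offset %||% mid[3]
      fval <- function(x, y) rep(z0, length(x))
      gxval <- function(x, y) rep(0, length(x))
      gyval <- function(x, y) rep(0, length(x))
    } else if (shape == "poly_sheet") {
      cf <- coef  # c(c0, cx, cy, cxx, cxy, cyy) about the volume center
      fval <- function(x, y) {
        dx <- x - mid[1]; dy <- y - mid[2]
        cf[1] + cf[2] * dx + cf[3] * dy + cf[4] * dx^2 + cf[5] * dx * dy +
          cf[6] * dy^2
      }
      gxval <- function(x, y) {
        dx <- x - mid[1]; dy <- y - mid[2]
        cf[2] + 2 * cf[4] * dx + cf[5] * dy
      }
      gyval <- function(x, y) {
        dx <- x - mid[1]; dy <- y - mid[2]
        cf[3] + cf[5] * dx + 2 * cf[6] * dy
      }
    } else {
      z0 <- offset %||% mid[3]
      fval <- function(x, y) z0 + amplitude * sin(2 * pi * y / period)
      gxval <- function(x, y) rep(0, length(x))
      gyval <- function(x, y) amplitude * 2 * pi / period *
        cos(2 * pi * y / period)
    }
    fmat <- outer(Xv, Yv, fval)
    gxm <- outer(Xv, Yv, gxval); gym <- outer(Xv, Yv, gyval)
    return(c(sheet(fmat, gxm, gym), list(kind = "sheet")))
  }
  if (shape == "circular_cylinder") {
    ctr <- center %||% c(mid[2], mid[3])
    ar <- angular_range * pi / 180
    dmat <- sqrt(outer((Yv - ctr[1])^2, (Zv - ctr[2])^2, `+`)) - radius
    amat <- atan2(outer(rep(1, ny), Zv - ctr[2]),
                  outer(Yv - ctr[1], rep(1, nz)))
    inpatch <- amat >= ar[1] & amat <= ar[2]
    return(list(kind = "cylinder",
      dist = function() {
        arr <- array(0, dims)
        for (k in seq_len(nz)) {
          col <- ifelse(inpatch[, k], dmat[, k], Inf)
          arr[, , k] <- matrix(rep(col, each = nx), nx, ny)
        }
        arr
      },
      sample_surface = function(step) {
        xs <- seq(2, nx - 3, by = step)
        phis <- seq(ar[1], ar[2], by = step / radius)
        g <- expand.grid(x = xs, phi = phis)
        cbind(g$x, ctr[1] + radius * cos(g$phi), ctr[2] + radius * sin(g$phi))
      },
      point_on_surface = function(x, phi) {
        list(P = cbind(x, ctr[1] + radius * cos(phi),
                       ctr[2] + radius * sin(phi)),
             normal = cbind(0 * phi, cos(phi), sin(phi)))
      },
      angular_range = ar, radius = radius, center = ctr))
  }
  if (shape == "elliptic_cylinder") {
    ctr <- center %||% c(mid[2], mid[3])
    a <- semi_axes[1]; b <- semi_axes[2]
    rho <- sqrt(outer((Yv - ctr[1])^2, (Zv - ctr[2])^2, `+`))
    phi <- atan2(outer(rep(1, ny), Zv - ctr[2]),
                 outer(Yv - ctr[1], rep(1, nz)))
    rell <- a * b / sqrt(b^2 * cos(phi)^2 + a^2 * sin(phi)^2)
    dmat <- rho - rell
    return(list(kind = "elliptic",
      dist = function() {
        arr <- array(0, dims)
        for (k in seq_len(nz))
          arr[, , k] <- matrix(rep(dmat[, k], each = nx), nx, ny)
        arr
      },
      sample_surface = function(step) {
        xs <- seq(2, nx - 3, by = step)
        ths <- seq(0, 2 * pi, by = step / max(a, b))
        g <- expand.grid(x = xs, th = ths)
        cbind(g$x, ctr[1] + a * cos(g$th), ctr[2] + b * sin(g$th))
      },
      point_on_surface = function(x, th) {
        n <- cbind(0 * th, cos(th) / a, sin(th) / b)
        n <- n / sqrt(rowSums(n^2))
        list(P = cbind(x, ctr[1] + a * cos(th), ctr[2] + b * sin(th)),
             normal = n)
      },
      a = a, b = b, center = ctr))
  }
  if (shape == "sphere") {
    ctr <- center %||% mid
    cap <- cap_angle * pi / 180
    return(list(kind = "sphere",
      dist = function() {
        arr <- array(0, dims)
        base <- outer((Xv - ctr[1])^2, (Yv - ctr[2])^2, `+`)
        capcos <- cos(cap)
        for (k in seq_len(nz)) {
          r <- sqrt(base + (Zv[k] - ctr[3])^2)
          d <- r - radius
          # restrict the shell to the polar cap about +Z
          cosang <- (Zv[k] - ctr[3]) / pmax(r, 1e-9)
          d[cosang < capcos] <- Inf
          arr[, , k] <- d
        }
        arr
      },
      sample_surface = function(step) {
        dphi <- step / radius
        phis <- seq(0, cap, by = dphi)
        out <- NULL
        for (p in phis) {
          nth <- max(1, ceiling(2 * pi * radius * sin(p) / step))
          th <- seq(0, 2 * pi, length.out = nth + 1)[-1]
          out <- rbind(out, cbind(
            ctr[1] + radius * sin(p) * cos(th),
            ctr[2] + radius * sin(p) * sin(th),
            ctr[3] + radius * cos(p)))
        }
        out
      },
      point_on_surface = function(phi, th) {
        n <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
        list(P = matrix(rep(ctr, each = length(phi)), ncol = 3) + radius * n,
             normal = n)
      },
      radius = radius, center = ctr, cap = cap))
  }
  stop("unknown shape: ", shape)
}

#' Generate a synthetic membrane tomogram with ground truth
#'
#' Renders an analytic membrane as a dark bilayer (two parallel Gaussian
#' sheets separated by `membrane_sep` voxels, cryoET negative contrast),
#' optionally plants anisotropic dark particle blobs at a fixed offset along
#' the local normal with known in-plane angles, and optionally adds Gaussian
#' noise and a missing-wedge filter. All randomness is controlled by `seed`.
#'
#' @param shape one of "plane", "poly_sheet", "sinusoid_sheet",
#'   "circular_cylinder", "elliptic_cylinder", "sphere".
#' @param dims volume dims (nx, ny, nz).
#' @param offset sheet height z0 (default: volume mid-plane).
#' @param coef poly_sheet coefficients c(c0, cx, cy, cxx, cxy, cyy), about
#'   the volume center.
#' @param amplitude,period sinusoid amplitude and period, voxels.
#' @param radius cylinder/sphere radius, voxels.
#' @param center shape center: (cy, cz) for cylinders, (cx, cy, cz) for the
#'   sphere (default: volume center).
#' @param semi_axes elliptic cylinder (a, b).
#' @param angular_range cylinder patch in degrees (default upper half-ish).
#' @param cap_angle sphere polar cap half-angle about +Z, degrees.
#' @param membrane_sep,membrane_sigma,membrane_amp bilayer leaflet
#'   separation, leaflet width (Gaussian sigma), and depth of each dark
#'   leaflet.
#' @param n_particles planted particle count.
#' @param particle_offset distance of the blob center from the membrane
#'   surface along the outward normal, voxels.
#' @param particle_amp blob darkness.
#' @param particle_sigma c(long, short, normal) Gaussian sigmas of the
#'   anisotropic blob; the long axis encodes the in-plane angle psi.
#' @param particle_min_sep minimum particle spacing, voxels (resampled up
#'   to a retry cap, then error).
#' @param noise_sigma additive Gaussian noise SD.
#' @param wedge_degrees half tilt range for missing-wedge filtering
#'   (`NULL` disables).
#' @param seed mandatory RNG seed.
#' @param voxel_size voxel size in Angstrom.
#' @param with_mesh also return an analytic UV-parameterized mesh (plane:
#'   identity texcoords; cylinder: (x, r theta); sphere: equirectangular
#'   (R longitude, R latitude)).
#' @param mesh_spacing mesh vertex spacing, voxels.
#' @param surface_step spacing of the exact surface_truth points, voxels.
#' @return list(tomo, mask, surface_truth, particles, mesh, geometry).
#' @export
make_phantom <- function(shape, dims = c(96, 96, 64), offset = NULL,
                         coef = c(0, 0, 0, 0, 0, 0), amplitude = 5,
                         period = 40, radius = 40, center = NULL,
                         semi_axes = c(60, 40),
                         angular_range = c(30, 150), cap_angle = 60,
                         membrane_sep = 5, membrane_sigma = 1.2,
                         membrane_amp = 1, n_particles = 0,
                         particle_offset = 8, particle_amp = 2,
                         particle_sigma = c(3, 1.5, 1.5),
                         particle_min_sep = 12, noise_sigma = 0,
                         wedge_degrees = NULL, seed = 1, voxel_size = 1,
                         with_mesh = FALSE, mesh_spacing = 4,
                         surface_step = 2) {
  if (is.null(seed)) stop("seed is mandatory")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  geo <- phantom_geometry(shape, dims, offset, coef, amplitude, period,
                          radius, center, semi_axes, angular_range, cap_angle)
  d <- geo$dist()
  tomo <- -membrane_amp * (exp(-(d - membrane_sep / 2)^2 /
                                 (2 * membrane_sigma^2)) +
                             exp(-(d + membrane_sep / 2)^2 /
                                   (2 * membrane_sigma^2)))
  tomo[!is.finite(d)] <- 0
  mask <- array(as.numeric(abs(d) <= membrane_sep / 2 + membrane_sigma &
                             is.finite(d)), dims)

  particles <- NULL
  if (n_particles > 0) {
    particles <- plant_particles(tomo, geo, shape, dims, n_particles,
                                 particle_offset, particle_amp,
                                 particle_sigma, particle_min_sep)
    tomo <- particles$tomo
    particles <- particles$table
  }
  if (noise_sigma > 0)
    tomo <- tomo + array(stats::rnorm(length(tomo), sd = noise_sigma), dims)
  if (!is.null(wedge_degrees)) tomo <- apply_wedge(tomo, wedge_degrees)

  st <- geo$sample_surface(surface_step)
  inb <- st[, 1] >= 0 & st[, 1] <= dims[1] - 1 &
    st[, 2] >= 0 & st[, 2] <= dims[2] - 1 &
    st[, 3] >= 0 & st[, 3] <= dims[3] - 1
  mesh <- if (with_mesh) phantom_mesh(geo, shape, dims, mesh_spacing) else NULL
  list(tomo = voxel_volume(tomo, voxel_size),
       mask = voxel_volume(mask, voxel_size),
       surface_truth = point_set(st[inb, , drop = FALSE], "surface_truth"),
       particles = particles, mesh = mesh, geometry = geo)
}

plant_particles <- function(tomo, geo, shape, dims, n, offset, amp, sig,
                            min_sep) {
  sample_one <- function() {
    if (geo$kind == "sheet") {
      x <- stats::runif(1, 10, dims[1] - 11)
      y <- stats::runif(1, 10, dims[2] - 11)
      geo$point_on_surface(x, y)
    } else if (geo$kind %in% c("cylinder", "elliptic")) {
      x <- stats::runif(1, 8, dims[1] - 9)
      ar <- geo$angular_range %||% c(0, 2 * pi)
      pad <- 0.12 * (ar[2] - ar[1])
      phi <- stats::runif(1, ar[1] + pad, ar[2] - pad)
      geo$point_on_surface(x, phi)
    } else {
      phi <- acos(stats::runif(1, cos(max(geo$cap - 0.15, 0.05)), 1))
      th <- stats::runif(1, 0, 2 * pi)
      geo$point_on_surface(phi, th)
    }
  }
  placed <- matrix(numeric(0), 0, 3)
  rows <- list()
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > 2000 * n)
      stop("could not place ", n, " particles with min separation ", min_sep)
    s <- sample_one()
    P <- s$P[1, ]; nv <- s$normal[1, ]
    ctr <- P + offset * nv
    if (any(ctr < 6) || any(ctr > dims - 7)) next
    if (nrow(placed) &&
        min(sqrt(colSums((t(placed) - ctr)^2))) < min_sep) next
    psi <- stats::runif(1, 0, 180)
    placed <- rbind(placed, ctr)
    rows[[length(rows) + 1]] <-
      data.frame(X = ctr[1], Y = ctr[2], Z = ctr[3],
                 sX = P[1], sY = P[2], sZ = P[3],
                 nx = nv[1], ny = nv[2], nz = nv[3], psi_true = psi)
  }
  tab <- do.call(rbind, rows)
  # paint anisotropic blobs
  reach <- ceiling(4 * max(sig))
  for (i in seq_len(nrow(tab))) {
    ctr <- c(tab$X[i], tab$Y[i], tab$Z[i])
    nv <- c(tab$nx[i], tab$ny[i], tab$nz[i])
    b <- projection_basis(nv)
    psi <- tab$psi_true[i] * pi / 180
    dlong <- cos(psi) * b$e1 + sin(psi) * b$e2
    dshort <- cross3(nv, dlong)
    lo <- pmax(floor(ctr - reach), 0)
    hi <- pmin(ceiling(ctr + reach), dims - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    g <- expand.grid(x = xs, y = ys, z = zs)
    rel <- cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
    tl <- rel %*% dlong; ts <- rel %*% dshort; tn <- rel %*% nv
    blob <- amp * exp(-0.5 * (tl^2 / sig[1]^2 + ts^2 / sig[2]^2 +
                                tn^2 / sig[3]^2))
    tomo[cbind(g$x + 1, g$y + 1, g$z + 1)] <-
      tomo[cbind(g$x + 1, g$y + 1, g$z + 1)] - blob
  }
  list(tomo = tomo, table = tab)
}

phantom_mesh <- function(geo, shape, dims, spacing) {
  grid_mesh <- function(us, vs, fP, ftc) {
    g <- expand.grid(u = us, v = vs)
    V <- fP(g$u, g$v)
    tc <- ftc(g$u, g$v)
    nu <- length(us); nv <- length(vs)
    idx <- function(i, j) (j - 1L) * nu + i
    i <- rep(seq_len(nu - 1), nv - 1)
    j <- rep(seq_len(nv - 1), each = nu - 1)
    f1 <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f2 <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    param_mesh(V, rbind(f1, f2), tc)
  }
  if (geo$kind == "sheet") {
    us <- seq(2, dims[1] - 3, by = spacing)
    vs <- seq(2, dims[2] - 3, by = spacing)
    grid_mesh(us, vs,
              function(u, v) geo$point_on_surface(u, v)$P,
              function(u, v) cbind(u, v))
  } else if (geo$kind == "cylinder") {
    r <- geo$radius; ar <- geo$angular_range
    us <- seq(2, dims[1] - 3, by = spacing)
    vs <- seq(ar[1], ar[2], by = spacing / r)
    grid_mesh(us, vs,
              function(u, phi) geo$point_on_surface(u, phi)$P,
              function(u, phi) cbind(u, r * phi))
  } else if (geo$kind == "sphere") {
    R <- geo$radius
    phis <- seq(0.05, geo$cap, by = spacing / R)     # latitude from pole
    ths <- seq(0, 2 * pi, by = spacing / R)
    grid_mesh(ths, phis,
              function(th, phi) geo$point_on_surface(phi, th)$P,
              function(th, phi) cbind(R * th, R * phi))
  } else stop("no analytic mesh for this shape")
}
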