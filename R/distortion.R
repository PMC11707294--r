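## First-fundamental-form distortion of the flattening map.

#' First fundamental form of a flattened slice
#'
#' Tangent vectors `r_u`, `r_v` of the w-offset surface are taken by central
#' differences of the raw-space positions at the four neighbors
#' (u0 +/- 1, v0 +/- 1), one-sided at grid edges; E, F, G are their dot
#' products.
#'
#' @param flatmap a `flatmap`.
#' @param w slice index (0-based; default the central slice).
#' @return list of matrices E, F, G over the (u,v) grid, plus `edge`
#'   flagging nodes computed with one-sided differences.
#' @export
fundamental_form <- function(flatmap, w = flatmap$wc) {
  P <- flatmap$S + (w - flatmap$wc) * flatmap$N
  nu <- dim(P)[1]; nv <- dim(P)[2]
  iu <- seq_len(nu); iv <- seq_len(nv)
  up <- pmin(iu + 1, nu); um <- pmax(iu - 1, 1)
  vp <- pmin(iv + 1, nv); vm <- pmax(iv - 1, 1)
  ru <- array(0, dim(P)); rv <- array(0, dim(P))
  for (c in 1:3) {
    ru[, , c] <- (P[up, , c] - P[um, , c]) / (up - um)
    rv[, , c] <- (P[, vp, c] - P[, vm, c]) /
      matrix(vp - vm, nu, nv, byrow = TRUE)
  }
  E <- ru[, , 1]^2 + ru[, , 2]^2 + ru[, , 3]^2
  G <- rv[, , 1]^2 + rv[, , 2]^2 + rv[, , 3]^2
  Fm <- ru[, , 1] * rv[, , 1] + ru[, , 2] * rv[, , 2] + ru[, , 3] * rv[, , 3]
  # off-central slices also inherit the one-sided normal band at the rim,
  # so the edge flag widens to a two-node band there
  band <- if (w == flatmap$wc) 1 else 2
  edge <- outer(iu <= band | iu > nu - band, iv <= band | iv > nv - band, `|`)
  list(E = E, F = Fm, G = G, edge = edge)
}

#' Singular values of the local flattening map
#'
#' sigma1^2 and sigma2^2 are the eigenvalues of `[[E, F], [F, G]]`; closed
#' form `(E + G)/2 +/- sqrt(((E - G)/2)^2 + F^2)`. They are the semi-axes of
#' the ellipse that a unit circle on the flattened slice maps to in 3D.
#'
#' @param E,F,G first-fundamental-form entries (vectorized).
#' @return list(sigma1, sigma2) with sigma1 >= sigma2.
#' @export
singular_values <- function(E, F, G) {
  if (any(E <= 0) || any(G <= 0) || any(E * G - F^2 <= 0))
    stop("degenerate mapping: first fundamental form not positive definite")
  h <- (E + G) / 2
  r <- sqrt(((E - G) / 2)^2 + F^2)
  list(sigma1 = sqrt(h + r), sigma2 = sqrt(pmax(h - r, 0)))
}

#' Per-pixel distortion maps of a flattened slice
#'
#' Area distortion is the unit-ellipse area change sigma1*sigma2, recorded
#' as-is when >= 1 (expansion) and as its reciprocal with a contraction flag
#' when < 1, so the reported value is always >= 1. Shape distortion is the
#' axis ratio sigma1/sigma2 (>= 1).
#'
#' @param flatmap a `flatmap`.
#' @param w slice index (0-based; default central).
#' @return object of class `distortion_map`: matrices `area` (>= 1),
#'   `shape` (>= 1), `sign` (+1 expansion / -1 contraction), `sigma1`,
#'   `sigma2`, `edge`.
#' @export
distortion_map <- function(flatmap, w = flatmap$wc) {
  ff <- fundamental_form(flatmap, w)
  sv <- singular_values(ff$E, ff$F, ff$G)
  prod <- sv$sigma1 * sv$sigma2
  expansion <- prod >= 1
  area <- ifelse(expansion, prod, 1 / prod)
  structure(list(area = area, shape = sv$sigma1 / sv$sigma2,
                 sign = ifelse(expansion, 1L, -1L),
                 sigma1 = sv$sigma1, sigma2 = sv$sigma2,
                 edge = ff$edge, w = w),
            class = "distortion_map")
}

#' @export
print.distortion_map <- function(x, ...) {
  cat(sprintf(paste0("<distortion_map> slice %d: area distortion median ",
                     "%.3f (max %.3f), shape median %.3f (max %.3f)\n"),
              x$w, stats::median(x$area), max(x$area),
              stats::median(x$shape), max(x$shape)))
  invisible(x)
}

#' Write distortion maps as MRC slices
#'
#' Two float maps (area, shape) plus an integer-valued sign plane (+1
#' expansion, -1 contraction) written as single-section MRC volumes.
#'
#' @param dmap a `distortion_map`.
#' @param path_area,path_shape,path_sign output paths (`NULL` skips).
#' @param voxel_size voxel size recorded in the headers.
#' @export
write_distortion <- function(dmap, path_area, path_shape, path_sign = NULL,
                             voxel_size = 1) {
  as_vol <- function(m) voxel_volume(array(m, c(dim(m), 1)), voxel_size)
  write_volume(as_vol(dmap$area), path_area)
  write_volume(as_vol(dmap$shape), path_shape)
  if (!is.null(path_sign)) write_volume(as_vol(dmap$sign), path_sign)
  invisible(NULL)
}

#' Parameterization distortion energy
#'
#' The symmetric Dirichlet-style energy `sigma1^2 + sigma2^2 + sigma1^-2 +
#' sigma2^-2`, minimized (= 4) exactly at an isometry (sigma1 = sigma2 = 1).
#' Used as a diagnostic of mesh parameterization quality.
#'
#' @param sigma1,sigma2 positive singular values (vectorized).
#' @export
optcuts_energy <- function(sigma1, sigma2) {
  stopifnot(all(sigma1 > 0), all(sigma2 > 0))
  sigma1^2 + sigma2^2 + sigma1^-2 + sigma2^-2
}
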