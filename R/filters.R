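## Separable Gaussian smoothing via banded matrix products (BLAS-bound).

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense convolution matrix with truncated-and-renormalized edges.
conv_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in seq(-half, half)) {
    i <- seq_len(n)
    j <- i + off
    keep <- j >= 1 & j <= n
    K[cbind(i[keep], j[keep])] <- kernel[off + half + 1L]
  }
  sweep(K, 1, rowSums(K), "/")
}

# Smooth a 2D or 3D array along every axis with an isotropic Gaussian.
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  kern <- gaussian_kernel(sigma)
  d <- dim(arr)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    K <- conv_matrix(da[1], kern)
    a <- array(K %*% matrix(a, nrow = da[1]), dim = da)
    arr <- aperm(a, order(perm))
  }
  arr
}

# Logical array shifted by (di, dj, dk); vacated cells become FALSE.
shift3d <- function(m, di, dj, dk) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  sx <- src$x - di; sy <- src$y - dj; sz <- src$z - dk
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[src$x[okx], src$y[oky], src$z[okz]] <-
    m[sx[okx], sy[oky], sz[okz], drop = FALSE]
  out
}

# 6-connected binary erosion; voxels outside the array count as background.
erode6 <- function(mask) {
  er <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    er <- er & shift3d(mask, s[1], s[2], s[3])
  er
}
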