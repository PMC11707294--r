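# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written without calling the package's own
# implementation of the operation it checks.

# R-level trilinear interpolation (independent of the C++ kernel).
tri_oracle <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  vapply(seq_len(nrow(pts)), function(p) {
    x <- pts[p, 1]; y <- pts[p, 2]; z <- pts[p, 3]
    if (x < 0 || x > d[1] - 1 || y < 0 || y > d[2] - 1 ||
        z < 0 || z > d[3] - 1) return(fill)
    i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
    k0 <- min(floor(z), d[3] - 2)
    if (d[1] == 1) i0 <- 0
    if (d[2] == 1) j0 <- 0
    if (d[3] == 1) k0 <- 0
    fx <- x - i0; fy <- y - j0; fz <- z - k0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wgt <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
        (if (dk) fz else 1 - fz)
      acc <- acc + wgt * arr[min(i0 + di, d[1] - 1) + 1,
                             min(j0 + dj, d[2] - 1) + 1,
                             min(k0 + dk, d[3] - 1) + 1]
    }
    acc
  }, numeric(1))
}

# Brute-force flood fill component sizes (26- or 8-connectivity).
flood_sizes_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  sizes <- integer(0)
  idx_all <- which(mask)
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- length(sizes) + 1L
    queue <- s
    lab[s] <- cur
    n <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      n <- n + 1L
      co <- arrayInd(v, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        p <- co + c(di, dj, dk)
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
    sizes <- c(sizes, n)
  }
  list(labels = lab, sizes = sizes)
}

# Brute-force 6-connected erosion.
erosion_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    ok <- TRUE
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
      p <- c(i, j, k) + s
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        ok <- FALSE; break
      }
    }
    out[i, j, k] <- ok
  }
  out
}

# O(n^2) mean k-NN distance.
knn_oracle <- function(pts, k) {
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
}

# Greedy score-ordered duplicate removal.
dedup_oracle <- function(picks, min_spacing, metric = "3d") {
  df <- picks[order(-picks$score, picks$w, picks$u, picks$v), , drop = FALSE]
  cols <- if (metric == "3d") c("u", "v", "w") else c("u", "v")
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in kept) {
      if (sqrt(sum((as.numeric(df[i, cols]) -
                    as.numeric(df[j, cols]))^2)) < min_spacing) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- df[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Composite Simpson quadrature.
simpson <- function(f, a, b, n = 2000) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  h <- (b - a) / n
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * f(x)) * h / 3
}

# Minimal independent MRC2014 writer (mode 2), optionally with permuted
# axis order on disk, used as the cross-writer fixture generator.
mrc_write_oracle <- function(arr, path, voxel_size = 1, mapcrs = 1:3) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  disk <- aperm(arr, mapcrs)       # axis i on disk holds coordinate mapcrs[i]
  d <- dim(disk)
  wi(d); wi(2L); wi(c(0L, 0L, 0L)); wi(d)
  wf(d * voxel_size); wf(c(90, 90, 90)); wi(mapcrs)
  wf(c(min(arr), max(arr), mean(arr)))
  wi(c(1L, 0L))
  writeBin(raw(100), con)
  wf(c(0, 0, 0))
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(arr)); wi(0L)
  writeBin(raw(800), con)
  wf(as.numeric(disk))
  invisible(NULL)
}

# Minimal STAR loop parser (independent of read_star).
star_parse_oracle <- function(path) {
  ln <- trimws(readLines(path))
  tags <- sub("^_([^ #]+).*", "\\1", grep("^_", ln, value = TRUE))
  body <- ln[!grepl("^_|^data_|^loop_", ln) & nzchar(ln)]
  m <- do.call(rbind, strsplit(body, "[[:space:]]+"))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- tags
  df[] <- lapply(df, function(x) as.numeric(x))
  df
}

# Independent dense TPS solve (kernel r^2 log r, affine part), returning a
# predictor function; structured differently from the package code.
tps_oracle <- function(xy, z, lambda = 0) {
  n <- nrow(xy)
  U <- function(r2) ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)  # r^2 log r
  R2 <- outer(rowSums(xy^2), rowSums(xy^2), `+`) - 2 * tcrossprod(xy)
  R2[R2 < 0] <- 0
  A <- rbind(cbind(U(R2) + diag(lambda, n), cbind(1, xy)),
             cbind(t(cbind(1, xy)), matrix(0, 3, 3)))
  sol <- solve(A, c(z, 0, 0, 0))
  function(px, py) {
    r2 <- outer(px^2 + py^2, rowSums(xy^2), `+`) -
      2 * (cbind(px, py) %*% t(xy))
    r2[r2 < 0] <- 0
    as.numeric(U(r2) %*% sol[1:n] + sol[n + 1] + sol[n + 2] * px +
                 sol[n + 3] * py)
  }
}

# Shared heavier fixture: cylinder phantom flattened through the direct
# polynomial-cylinder pathway (cached per test file).
cylinder_case <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ph <- make_phantom("circular_cylinder", dims = c(96, 128, 96),
                       radius = 40, center = c(63.5, 20),
                       angular_range = c(40, 140), seed = 2)
    cf <- fit_cylinder_poly(ph$surface_truth, degree = 6)
    loc <- raw_to_local(cf$frame, ph$surface_truth)
    surf <- fit_polynomial(loc, degree = 8)
    fm <- build_flatmap(surf, cf$frame, cf$cylinder, wt = 10)
    cache <<- list(ph = ph, fit = cf, surface = surf, flatmap = fm,
                   radius = 40, center = c(63.5, 20))
    cache
  }
})
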