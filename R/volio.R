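#' Construct a voxel volume
#'
#' A `voxel_volume` is the shared container for raw tomograms, masks, score
#' maps, and flattened tomograms: a 3D scalar grid indexed (X, Y, Z) with an
#' isotropic voxel size in Angstrom per pixel. Voxel indices are 0-based in
#' all coordinate arithmetic: the center of voxel (0,0,0) is position
#' (0.0, 0.0, 0.0).
#'
#' @param data 3D numeric array, indexed `[X, Y, Z]` (X fastest).
#' @param voxel_size isotropic voxel size in Angstrom (> 0).
#' @param origin 3-vector origin in Angstrom (header metadata only).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  if (!all(is.finite(data)))
    stop("volume values must be finite")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d, voxel %.4g A, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

## ---- MRC2014 ----------------------------------------------------------

mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC2014 volume
#'
#' Accepts modes 0/1/2/6 (promoted to double). The data model is normalized
#' to X-fastest/Z-slowest regardless of the on-disk section order given by
#' the `mapc`/`mapr`/`maps` header words. Anisotropic voxel sizes are
#' rejected: all downstream geometry assumes one pixel unit.
#'
#' @param path MRC file path.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h_int <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  h_flt <- function(n) readBin(con, "double", n, size = 4L, endian = "little")
  nxyz <- h_int(3)
  mode <- h_int(1)
  if (any(nxyz <= 0)) stop("malformed MRC header: non-positive nx/ny/nz")
  if (!as.character(mode) %in% names(mrc_modes))
    stop("malformed MRC header: unsupported mode ", mode)
  h_int(3)                       # nxstart/nystart/nzstart
  mxyz <- h_int(3)
  cella <- h_flt(3)
  h_flt(3)                       # cellb
  mapcrs <- h_int(3)
  h_flt(3)                       # dmin/dmax/dmean
  h_int(2)                       # ispg, nsymbt
  nsymbt <- 0L                   # we wrote 0; re-read below for foreign files
  seek(con, 92)
  nsymbt <- h_int(1)
  seek(con, 196)
  origin <- h_flt(3)
  seek(con, 1024 + nsymbt)
  if (any(mxyz <= 0)) mxyz <- nxyz
  vs <- cella / mxyz
  vs[!is.finite(vs) | vs == 0] <- 1
  if (diff(range(vs)) > 1e-4 * mean(vs))
    stop("malformed MRC header: anisotropic voxel size (cella/mx) not supported")
  n <- prod(nxyz)
  raw_data <- switch(as.character(mode),
    `0` = as.double(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    `1` = as.double(readBin(con, "integer", n, size = 2L, signed = TRUE,
                            endian = "little")),
    `2` = readBin(con, "double", n, size = 4L, endian = "little"),
    `6` = as.double(readBin(con, "integer", n, size = 2L, signed = FALSE,
                            endian = "little")))
  if (length(raw_data) != n) stop("malformed MRC file: truncated data block")
  arr <- array(raw_data, dim = nxyz)
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    if (!setequal(mapcrs, 1:3))
      stop("malformed MRC header: mapc/mapr/maps = ",
           paste(mapcrs, collapse = ","))
    # arr axis i holds coordinate mapcrs[i]; permute so axis i holds coord i
    arr <- aperm(arr, order(mapcrs))
  }
  voxel_volume(arr, voxel_size = vs[1], origin = origin)
}

#' Write a volume as MRC2014 (mode 2, 32-bit float)
#'
#' Header statistics (min/max/mean/rms) are recomputed from the data.
#'
#' @param vol a [voxel_volume()].
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  w_int <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  d <- dim(vol$data)
  w_int(d)                                  # nx ny nz
  w_int(2L)                                 # mode 2
  w_int(c(0L, 0L, 0L))                      # nxstart
  w_int(d)                                  # mx my mz
  w_flt(d * vol$voxel_size)                 # cella
  w_flt(c(90, 90, 90))                      # cellb
  w_int(1:3)                                # mapc mapr maps
  w_flt(c(min(vol$data), max(vol$data), mean(vol$data)))
  w_int(c(1L, 0L))                          # ispg, nsymbt
  writeBin(raw(8), con)                     # extra words 25-26
  writeChar("MRCO", con, 4, eos = NULL)     # exttyp
  w_int(20140L)                             # nversion
  writeBin(raw(84), con)                    # rest of extra space
  w_flt(vol$origin)                         # origin (bytes 197-208)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  w_flt(stats::sd(vol$data))                # rms
  w_int(1L)                                 # nlabl
  lab <- sprintf("%-80s", "memflat")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeBin(raw(80 * 9), con)
  w_flt(as.numeric(vol$data))
  invisible(NULL)
}

## ---- Wavefront OBJ with texture coordinates ---------------------------

#' Construct a UV-parameterized triangle mesh
#'
#' @param vertices n x 3 matrix of 3D vertex coordinates (X, Y, Z).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param texcoords n x 2 matrix of per-vertex (u, v) texture coordinates.
#' @return An object of class `param_mesh`.
#' @export
param_mesh <- function(vertices, faces, texcoords) {
  vertices <- as.matrix(vertices); texcoords <- as.matrix(texcoords)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || ncol(texcoords) != 2 || ncol(faces) != 3)
    stop("bad mesh component shapes")
  if (nrow(texcoords) != nrow(vertices))
    stop("every vertex must have a texture coordinate")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face references an invalid vertex")
  structure(list(vertices = vertices, faces = faces, texcoords = texcoords),
            class = "param_mesh")
}

#' Read a UV-parameterized mesh from Wavefront OBJ
#'
#' Requires `v`, `vt`, and `f v/vt` records; a face lacking texture indices
#' is an error ("mesh not parameterized"). The per-vertex association of
#' texture coordinates is reconstructed from the face records.
#'
#' @param path OBJ file path.
#' @return A [param_mesh()].
#' @export
read_mesh <- function(path) {
  ln <- readLines(path, warn = FALSE)
  tok <- strsplit(trimws(ln), "[[:space:]]+")
  keys <- vapply(tok, function(t) if (length(t)) t[1] else "", "")
  num3 <- function(ts) t(vapply(ts, function(t) as.numeric(t[2:4]), numeric(3)))
  num2 <- function(ts) t(vapply(ts, function(t) as.numeric(t[2:3]), numeric(2)))
  vs <- tok[keys == "v"]; vts <- tok[keys == "vt"]; fs <- tok[keys == "f"]
  if (!length(vs) || !length(fs)) stop("not a usable OBJ: needs v and f records")
  V <- num3(vs)
  if (!length(vts)) stop("mesh not parameterized: OBJ has no vt records")
  VT <- num2(vts)
  faces <- matrix(0L, length(fs), 3)
  tex_of_vertex <- rep(NA_integer_, nrow(V))
  for (i in seq_along(fs)) {
    ref <- fs[[i]][-1]
    if (length(ref) != 3) stop("only triangle faces are supported (face ", i, ")")
    parts <- strsplit(ref, "/", fixed = TRUE)
    for (j in 1:3) {
      p <- parts[[j]]
      if (length(p) < 2 || !nzchar(p[2]))
        stop("mesh not parameterized: face ", i, " lacks texture indices")
      vi <- as.integer(p[1]); ti <- as.integer(p[2])
      faces[i, j] <- vi
      if (!is.na(tex_of_vertex[vi]) && tex_of_vertex[vi] != ti)
        stop("vertex ", vi, " maps to multiple texture coordinates; ",
             "cut the mesh so the parameterization is single-valued")
      tex_of_vertex[vi] <- ti
    }
  }
  used <- !is.na(tex_of_vertex)
  TC <- matrix(NA_real_, nrow(V), 2)
  TC[used, ] <- VT[tex_of_vertex[used], , drop = FALSE]
  if (anyNA(TC[unique(as.vector(faces)), ]))
    stop("mesh not parameterized: some face vertices lack texture coordinates")
  param_mesh(V, faces, TC)
}

#' Write a UV-parameterized mesh as Wavefront OBJ
#' @param mesh a [param_mesh()].
#' @param path output path.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "param_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# memflat mesh", con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vt %.17g %.17g", mesh$texcoords[, 1],
                     mesh$texcoords[, 2]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d/%d %d/%d %d/%d",
                     f[, 1], f[, 1], f[, 2], f[, 2], f[, 3], f[, 3]), con)
  invisible(NULL)
}

## ---- point and particle tables ----------------------------------------

parse_numeric_table <- function(path, ncol_expect = NULL) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
  if (!length(ln)) return(matrix(numeric(0), 0, ncol_expect %||% 3))
  split_row <- function(s) strsplit(trimws(s), "[,[:space:]]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(ln[1])))
  start <- if (anyNA(first)) 2L else 1L   # header line allowed
  header <- if (start == 2L) split_row(ln[1]) else NULL
  rows <- lapply(seq(start, length.out = length(ln) - start + 1L), function(i) {
    cells <- split_row(ln[i])
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop("non-numeric cell at line ", i, " of ", path, ": ",
           paste(cells[is.na(vals)], collapse = ", "))
    vals
  })
  nc <- unique(lengths(rows))
  if (length(nc) != 1) stop("ragged table in ", path)
  m <- do.call(rbind, rows)
  if (!is.null(header) && length(header) == ncol(m)) colnames(m) <- header
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 3-column table of 0-based voxel coordinates
#' @param path CSV/TSV/whitespace table; a header line and `#` comments allowed.
#' @param label free-text label attached to the point set.
#' @return n x 3 numeric matrix of class `point_set` (columns X, Y, Z).
#' @export
read_points <- function(path, label = "points") {
  m <- parse_numeric_table(path)
  if (nrow(m) && ncol(m) != 3) stop("expected 3 coordinate columns in ", path)
  point_set(m, label = label)
}

#' @rdname read_points
#' @param points a `point_set` or n x 3 matrix.
#' @export
write_points <- function(points, path) {
  m <- as_point_matrix(points)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("x,y,z", con)
  if (nrow(m))
    writeLines(sprintf("%.17g,%.17g,%.17g", m[, 1], m[, 2], m[, 3]), con)
  invisible(NULL)
}

#' Point set in raw voxel coordinates
#' @param points n x 3 numeric matrix (X, Y, Z), 0-based voxel coordinates.
#' @param label free text, e.g. "starting_points".
#' @export
point_set <- function(points, label = "points") {
  m <- as.matrix(points)
  if (length(m) == 0) m <- matrix(numeric(0), 0, 3)
  if (ncol(m) != 3) stop("points must be n x 3")
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  structure(m, class = c("point_set", "matrix", "array"), label = label)
}

as_point_matrix <- function(p) {
  m <- unclass(p)
  attr(m, "label") <- NULL
  matrix(as.numeric(m), ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set '%s'> %d points\n", attr(x, "label") %||% "",
              nrow(x)))
  invisible(x)
}

#' Read / write a particle table as CSV
#'
#' Particle tables are plain data frames with any subset of the columns
#' `u,v,w` (flattened, 0-based voxel), `X,Y,Z` (raw, 0-based voxel), `score`,
#' `nx,ny,nz` (unit membrane normal), `dx,dy,dz` (in-plane direction, raw
#' frame), `rot,tilt,psi` (degrees, ZYZ intrinsic), `class_id`,
#' `shift_x,shift_y,shift_z`. Numeric values round-trip exactly as text
#' (written with 17 significant digits).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_particles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in names(df)) {
    if (nm == "class_id") next
    if (!is.numeric(df[[nm]]))
      stop("non-numeric column '", nm, "' in ", path)
  }
  df
}

#' @rdname read_particles
#' @param particles data.frame of particle records.
#' @export
write_particles <- function(particles, path) {
  df <- as.data.frame(particles)
  out <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(NULL)
}

## ---- STAR export ------------------------------------------------------

star_column_map <- c(X = "rlnCoordinateX", Y = "rlnCoordinateY",
                     Z = "rlnCoordinateZ", rot = "rlnAngleRot",
                     tilt = "rlnAngleTilt", psi = "rlnAnglePsi",
                     score = "rlnAutopickFigureOfMerit",
                     class_id = "rlnClassNumber")

#' Write particle metadata as a STAR file
#'
#' Exports `rlnCoordinateX/Y/Z` (0-based voxel coordinates; 1-based
#' consumers must shift by one) and `rlnAngleRot/Tilt/Psi` in degrees, plus
#' score/class columns when present.
#'
#' @param particles data.frame with columns X, Y, Z and rot, tilt, psi.
#' @param path output path.
#' @param block data block name.
#' @export
write_star <- function(particles, path, block = "particles") {
  df <- as.data.frame(particles)
  cols <- intersect(names(star_column_map), names(df))
  if (!all(c("X", "Y", "Z") %in% cols))
    stop("STAR export needs raw coordinates X, Y, Z")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", star_column_map[cols], seq_along(cols)), con)
  body <- vapply(cols, function(cl) {
    v <- df[[cl]]
    if (is.numeric(v)) sprintf("%.6f", v) else as.character(v)
  }, character(nrow(df)))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1)
  if (nrow(df)) writeLines(apply(body, 1, paste, collapse = "\t"), con)
  writeLines("", con)
  invisible(NULL)
}

#' Read a single-block STAR loop into a data.frame
#' @param path STAR file path.
#' @return data.frame with the rln* column names.
#' @export
read_star <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  loop_at <- which(ln == "loop_")[1]
  if (is.na(loop_at)) stop("no loop_ block in ", path)
  rest <- ln[(loop_at + 1):length(ln)]
  is_tag <- grepl("^_", rest)
  tags <- sub("^_([^ #]+).*$", "\\1", rest[seq_len(which.min(is_tag) - 1)])
  body <- rest[(length(tags) + 1):length(rest)]
  body <- body[nzchar(body) & !grepl("^data_|^loop_|^_", body)]
  if (!length(body)) return(stats::setNames(as.data.frame(
    matrix(numeric(0), 0, length(tags))), tags))
  cells <- strsplit(body, "[[:space:]]+")
  m <- do.call(rbind, cells)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- tags
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (!anyNA(v)) df[[nm]] <- v
  }
  df
}
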