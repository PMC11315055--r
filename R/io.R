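# Standard-format I/O shared by all modules: 8-bit PNG images, 32-bit float
# TIFF depth maps, ASCII PLY clouds/meshes, and the plain-text camera format.

#' Read an 8-bit PNG image
#' @param path file path
#' @return (H, W) or (H, W, C) array in \[0, 1\]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, " does not exist")
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("corrupt or unreadable PNG at ",
                                           path, ": ", conditionMessage(e)))
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8L)
    stop(path, ": ", info$bit.depth,
         "-bit PNG is not supported (8-bit dialect only)")
  attr(img, "info") <- NULL
  img
}

#' Write an image as 8-bit PNG
#'
#' Values are clipped to \[0, 1\] and quantized to 256 levels (rounding).
#'
#' @param img (H, W) or (H, W, C) array
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  img <- clip01(img)
  img <- round(img * 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Write a depth map as single-strip 32-bit IEEE-float grayscale TIFF
#'
#' Depths are stored as-is in world units (the `tiff` package clamps float
#' samples to \[0, 1\], so the strip is written directly).
#'
#' @param depth depth matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_depth <- function(depth, path) {
  H <- nrow(depth); W <- ncol(depth)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)      # header, IFD at 8
  entries <- list(
    c(256L, 3L, 1L, W),            # ImageWidth
    c(257L, 3L, 1L, H),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # Compression: none
    c(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),           # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),           # SamplesPerPixel
    c(278L, 3L, 1L, H),            # RowsPerStrip
    c(279L, 4L, 1L, 4L * H * W),   # StripByteCounts
    c(339L, 3L, 1L, 3L))           # SampleFormat: IEEE float
  strip_off <- 8L + 2L + 12L * length(entries) + 4L
  entries[[6]][4] <- strip_off
  w2(length(entries))
  for (e in entries) { w2(e[1]); w2(e[2]); w4(e[3]); w4(e[4]) }
  w4(0L)                                               # next IFD: none
  writeBin(as.numeric(t(depth)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 32-bit float TIFF depth map written by [write_depth()]
#' @param path file path
#' @return depth matrix in world units (0 = invalid)
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) stop("cannot read depth map: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "II"))
    stop(path, ": not a little-endian TIFF")
  r2 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                           endian = "little")
  r4 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (r2() != 42L) stop(path, ": bad TIFF magic")
  seek(con, r4())
  n <- r2()
  tags <- list()
  for (i in seq_len(n)) {
    tag <- r2(); typ <- r2(); cnt <- r4(); val <- r4()
    tags[[as.character(tag)]] <- val
  }
  W <- tags[["256"]]; H <- tags[["257"]]
  if (is.null(W) || is.null(H)) stop(path, ": missing image dimensions")
  if (!identical(tags[["339"]], 3L) || !identical(tags[["258"]], 32L))
    stop(path, ": only the 32-bit float depth dialect is supported")
  seek(con, tags[["273"]])
  vals <- readBin(con, "numeric", H * W, size = 4L, endian = "little")
  matrix(vals, H, W, byrow = TRUE)
}

#' Write ground-truth cameras in the plain-text format
#'
#' One header line `fx fy cx cy H W`, then one line per view
#' `name qw qx qy qz tx ty tz` (unit quaternion, world-to-camera).
#'
#' @param poses list of `camera_pose`
#' @param intr a `camera_intrinsics`
#' @param path output path
#' @param names view names (default `view_001` ...)
#' @return `path`, invisibly
#' @export
write_cameras <- function(poses, intr, path, names = NULL) {
  names <- names %||% sprintf("view_%03d", seq_along(poses))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.9g %.9g %.9g %.9g %d %d", intr$fx, intr$fy,
                     intr$cx, intr$cy, intr$height, intr$width), con)
  for (i in seq_along(poses)) {
    q <- rot_to_quat(poses[[i]]$R)
    writeLines(paste(names[i],
                     paste(sprintf("%.9g", c(q, poses[[i]]$t)),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read a camera file written by [write_cameras()]
#' @param path file path
#' @return list with `intrinsics` and `poses` (named list of `camera_pose`)
#' @export
read_cameras <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 1L) stop("empty camera file: ", path)
  hd <- suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]]))
  if (length(hd) != 6L || anyNA(hd))
    stop("camera file ", path, ": malformed header line")
  intr <- camera_intrinsics(hd[1], hd[2], hd[3], hd[4], hd[5], hd[6])
  poses <- list()
  for (i in seq_along(ln)[-1]) {
    if (!nzchar(trimws(ln[i]))) next
    tok <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    if (length(tok) != 8L)
      stop("camera file ", path, " line ", i, ": expected 8 fields")
    v <- as.numeric(tok[-1])
    poses[[tok[1]]] <- camera_pose(quat_to_rot(v[1:4]), v[5:7])
  }
  list(intrinsics = intr, poses = poses)
}

# ---- ASCII PLY -------------------------------------------------------------

#' Write a point cloud or triangle mesh as ASCII PLY
#'
#' Points are written as `x y z [nx ny nz] [red green blue]`; meshes add a
#' face element with vertex index lists.  Coordinates are printed with 9
#' significant digits.
#'
#' @param obj an `oriented_cloud` or `triangle_mesh`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ply <- function(obj, path) {
  is_mesh <- !is.null(obj$faces)
  V <- if (is_mesh) obj$vertices else obj$points
  has_norm <- !is.null(obj$normals) && NROW(obj$normals) == nrow(V)
  has_col <- !is.null(obj$colors) && NROW(obj$colors) == nrow(V)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(V)),
           "property float x", "property float y", "property float z")
  if (has_norm) hdr <- c(hdr, "property float nx", "property float ny",
                         "property float nz")
  if (has_col) hdr <- c(hdr, "property uchar red", "property uchar green",
                        "property uchar blue")
  if (is_mesh) hdr <- c(hdr, paste("element face", nrow(obj$faces)),
                        "property list uchar int vertex_indices")
  writeLines(c(hdr, "end_header"), con)
  num <- function(m) apply(m, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " "))
  lines <- num(V)
  if (has_norm) lines <- paste(lines, num(obj$normals))
  if (has_col) lines <- paste(lines, apply(obj$colors, 1, function(r)
    paste(pmin(255L, pmax(0L, as.integer(round(r * 255)))), collapse = " ")))
  writeLines(lines, con)
  if (is_mesh)
    writeLines(paste(3L, obj$faces[, 1] - 1L, obj$faces[, 2] - 1L,
                     obj$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file written by [write_ply()]
#'
#' Binary PLY is rejected; malformed headers raise an error naming the line.
#' A cloud without normals is returned with `has_normals = FALSE` rather
#' than zero-filled normals.
#'
#' @param path file path
#' @return an `oriented_cloud` (no face element) or `triangle_mesh`
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3L || trimws(ln[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic in ", path)
  if (!grepl("^format\\s+ascii", trimws(ln[2])))
    stop("PLY parse error at line 2: only the ASCII dialect is supported")
  nv <- 0L; nf <- 0L; props <- character(0)
  i <- 3L; elem <- ""
  while (i <= length(ln)) {
    t <- trimws(ln[i])
    if (t == "end_header") break
    tok <- strsplit(t, "\\s+")[[1]]
    if (tok[1] == "element") {
      elem <- tok[2]
      if (elem == "vertex") nv <- as.integer(tok[3])
      else if (elem == "face") nf <- as.integer(tok[3])
      else stop("PLY parse error at line ", i, ": unknown element ", elem)
    } else if (tok[1] == "property" && elem == "vertex" &&
               tok[2] != "list") {
      props <- c(props, tok[3])
    } else if (tok[1] %in% c("comment", "property")) {
      # face list property or comment: accepted
    } else stop("PLY parse error at line ", i, ": unexpected '", t, "'")
    i <- i + 1L
  }
  if (i > length(ln)) stop("PLY parse error: no end_header in ", path)
  body <- ln[(i + 1L):length(ln)]
  if (length(body) < nv + nf) stop("PLY parse error: truncated body in ", path)
  vm <- do.call(rbind, lapply(seq_len(nv), function(k) {
    as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]])
  }))
  if (ncol(vm) != length(props))
    stop("PLY parse error: vertex row width ", ncol(vm),
         " does not match ", length(props), " declared properties")
  colnames(vm) <- props
  P <- vm[, c("x", "y", "z"), drop = FALSE]
  has_norm <- all(c("nx", "ny", "nz") %in% props)
  has_col <- all(c("red", "green", "blue") %in% props)
  Nn <- if (has_norm) vm[, c("nx", "ny", "nz"), drop = FALSE]
  Cc <- if (has_col) vm[, c("red", "green", "blue"), drop = FALSE] / 255
  dimnames(P) <- NULL
  if (!is.null(Nn)) dimnames(Nn) <- NULL
  if (!is.null(Cc)) dimnames(Cc) <- NULL
  if (nf > 0L) {
    Fm <- do.call(rbind, lapply(seq_len(nf), function(k) {
      v <- as.integer(strsplit(trimws(body[nv + k]), "\\s+")[[1]])
      if (v[1] != 3L) stop("PLY parse error: non-triangle face at body row ",
                           nv + k)
      v[2:4] + 1L
    }))
    structure(list(vertices = P, faces = Fm, normals = Nn, colors = Cc,
                   has_normals = has_norm),
              class = "triangle_mesh")
  } else {
    structure(list(points = P, normals = Nn, colors = Cc,
                   has_normals = has_norm,
                   view_id = rep(1L, nrow(P))),
              class = "oriented_cloud")
  }
}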