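# Surface extraction from an oriented point cloud: a regular-grid screened
# Poisson indicator solve (grad chi ~ splatted normal field, with a data term
# pulling chi toward 1/2 at the samples), followed by marching-tetrahedra
# iso-surface extraction over the translation-consistent 6-tetrahedron cube
# decomposition, and distance trimming to the input samples.

# trilinear splat of per-point vectors into three (nx, ny, nz) grids
splat_field <- function(P, Vec, orig, h, dims) {
  gx <- (P[, 1] - orig[1]) / h
  gy <- (P[, 2] - orig[2]) / h
  gz <- (P[, 3] - orig[3]) / h
  f <- array(0, dim = c(dims, 3L))
  wsum <- array(0, dim = dims)
  x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ix <- x0 + dx + 1L; iy <- y0 + dy + 1L; iz <- z0 + dz + 1L
    ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
      iz >= 1 & iz <= dims[3]
    if (!any(ok)) next
    idx <- cbind(ix[ok], iy[ok], iz[ok])
    lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] +
      (idx[, 3] - 1L) * dims[1] * dims[2]
    for (c in 1:3) {
      add <- w[ok] * Vec[ok, c]
      acc <- rowsum(add, lin)
      off <- (c - 1L) * prod(dims)
      f[off + as.integer(rownames(acc))] <- f[off + as.integer(rownames(acc))] +
        acc[, 1]
    }
    accw <- rowsum(w[ok], lin)
    wsum[as.integer(rownames(accw))] <- wsum[as.integer(rownames(accw))] +
      accw[, 1]
  }
  list(field = f, weight = wsum)
}

# separable 1-2-1 smoothing applied `times` times along every axis
smooth3 <- function(a, times = 2L) {
  d <- dim(a)
  for (t in seq_len(times)) {
    a <- (2 * a +
            a[c(1, 1:(d[1] - 1)), , , drop = FALSE] +
            a[c(2:d[1], d[1]), , , drop = FALSE]) / 4
    a <- (2 * a +
            a[, c(1, 1:(d[2] - 1)), , drop = FALSE] +
            a[, c(2:d[2], d[2]), , drop = FALSE]) / 4
    a <- (2 * a +
            a[, , c(1, 1:(d[3] - 1)), drop = FALSE] +
            a[, , c(2:d[3], d[3]), drop = FALSE]) / 4
  }
  a
}

# 7-point Laplacian (Neumann) times a vector, on the flattened grid
laplacian_apply <- function(x, dims) {
  a <- array(x, dim = dims)
  s <- -6 * a
  s <- s + a[c(1, 1:(dims[1] - 1)), , , drop = FALSE] +
    a[c(2:dims[1], dims[1]), , , drop = FALSE] +
    a[, c(1, 1:(dims[2] - 1)), , drop = FALSE] +
    a[, c(2:dims[2], dims[2]), , drop = FALSE] +
    a[, , c(1, 1:(dims[3] - 1)), drop = FALSE] +
    a[, , c(2:dims[3], dims[3]), drop = FALSE]
  as.numeric(s)
}

# conjugate gradient for A x = b with A = -L + alpha*diag(w) (SPD)
screened_cg <- function(b, w, alpha, dims, tol = 1e-6, max_iter = 400L) {
  Ax <- function(x) -laplacian_apply(x, dims) + alpha * w * x
  x <- numeric(length(b))
  r <- b
  M <- 6 + alpha * w                       # Jacobi preconditioner
  z <- r / M
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  iters <- 0L
  for (it in seq_len(max_iter)) {
    Ap <- Ax(p)
    a <- rz / sum(p * Ap)
    x <- x + a * p
    r <- r - a * Ap
    iters <- it
    if (sqrt(sum(r^2)) < tol * b2) break
    z <- r / M
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, resid = sqrt(sum(r^2)) / b2, iters = iters)
}

#' Screened-Poisson surface reconstruction on a regular grid
#'
#' Splats the oriented normals into a smoothed grid vector field V, solves
#' the screened Poisson equation (Laplacian of the indicator equals div V,
#' with a data term pulling the indicator toward 1/2 at the samples) by
#' preconditioned conjugate gradients, and extracts the iso-surface at the
#' mean indicator value over the sample cells with marching tetrahedra.
#' Triangles farther than `trim_dist` voxels from any input point are
#' trimmed.
#'
#' @param cloud an `oriented_cloud` (or list with `points` and `normals`)
#' @param grid_resolution cells along the longest bounding-box axis, or
#'   `"auto"` to set the voxel size from the median nearest-neighbour point
#'   spacing (resolution follows sampling density, clamped to \[24, 96\])
#' @param screening_weight weight of the sample data term
#' @param trim_dist trimming radius in voxels; `Inf` disables trimming
#' @param keep_largest keep only the largest connected mesh component
#'   (suppresses spurious blobs in weakly sampled regions)
#' @param verbose print solver diagnostics
#' @return object of class `triangle_mesh`: `vertices` (V x 3), `faces`
#'   (F x 3, 1-based), `colors` (V x 3, interpolated from nearest input
#'   point if available), plus solver info in attributes
#' @export
poisson_surface <- function(cloud, grid_resolution = "auto",
                            screening_weight = 4, trim_dist = 3,
                            keep_largest = TRUE, verbose = FALSE) {
  P <- matrix(cloud$points, ncol = 3)
  N <- matrix(cloud$normals, ncol = 3)
  if (nrow(P) < 100L) stop("need at least 100 oriented points")
  if (max(abs(sqrt(rowSums(N^2)) - 1)) > 1e-3)
    stop("normals must be unit length")
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  ext <- hi - lo
  if (identical(grid_resolution, "auto")) {
    sub <- P[round(seq(1L, nrow(P), length.out = min(800L, nrow(P)))), ,
             drop = FALSE]
    d2 <- as.matrix(stats::dist(sub))
    diag(d2) <- Inf
    spacing <- stats::median(apply(d2, 1, min))
    h <- max(spacing * 2, max(ext) / 96)
    res <- ceiling(max(ext) / h)
    res <- max(24L, min(96L, res))
  } else res <- as.integer(grid_resolution)
  h <- max(ext) / res
  pad <- 4L
  orig <- lo - pad * h
  dims <- pmax(8L, as.integer(ceiling(ext / h)) + 2L * pad)
  nvox <- prod(dims)
  if (nvox > 4e6) stop("Poisson grid too large: ", paste(dims, collapse = "x"))
  sp <- splat_field(P, N, orig, h, dims)
  f <- sp$field
  for (c in 1:3) f[, , , c] <- smooth3(f[, , , c], 2L)
  # divergence by central differences (grid units)
  dv <- array(0, dim = dims)
  cd <- function(a, axis) {
    d <- dim(a)
    switch(axis,
           (a[c(2:d[1], d[1]), , , drop = FALSE] -
              a[c(1, 1:(d[1] - 1)), , , drop = FALSE]) / 2,
           (a[, c(2:d[2], d[2]), , drop = FALSE] -
              a[, c(1, 1:(d[2] - 1)), , drop = FALSE]) / 2,
           (a[, , c(2:d[3], d[3]), drop = FALSE] -
              a[, , c(1, 1:(d[3] - 1)), drop = FALSE]) / 2)
  }
  dv <- cd(f[, , , 1], 1L) + cd(f[, , , 2], 2L) + cd(f[, , , 3], 3L)
  wocc <- array(0, dim = dims)
  wocc[sp$weight > 0] <- 1
  wocc <- smooth3(wocc, 1L)
  # A chi = b with A = -L + alpha W, b = -div V + alpha W * 1/2
  alpha <- screening_weight
  b <- -as.numeric(dv) + alpha * as.numeric(wocc) * 0.5
  sol <- screened_cg(b, as.numeric(wocc), alpha, dims)
  if (verbose)
    message(sprintf("screened Poisson: grid %s, CG %d iters, resid %.2e",
                    paste(dims, collapse = "x"), sol$iters, sol$resid))
  chi <- array(sol$x, dim = dims)
  # iso level: mean indicator over cells that received samples
  iso <- stats::weighted.mean(sol$x, as.numeric(sp$weight))
  mesh <- marching_tetrahedra(chi, iso, orig, h)
  if (nrow(mesh$faces) == 0L) stop("iso-surface extraction found no surface")
  if (is.finite(trim_dist)) {
    occ <- array(FALSE, dim = dims)
    occ[sp$weight > 0] <- TRUE
    occ <- dilate3(occ, as.integer(ceiling(trim_dist)))
    cent <- (mesh$vertices[mesh$faces[, 1], ] +
               mesh$vertices[mesh$faces[, 2], ] +
               mesh$vertices[mesh$faces[, 3], ]) / 3
    ci <- floor(sweep(cent, 2, orig) / h) + 1L
    ci[, 1] <- pmin(pmax(ci[, 1], 1L), dims[1])
    ci[, 2] <- pmin(pmax(ci[, 2], 1L), dims[2])
    ci[, 3] <- pmin(pmax(ci[, 3], 1L), dims[3])
    keep <- occ[ci]
    mesh$faces <- mesh$faces[keep, , drop = FALSE]
    mesh <- drop_unused_vertices(mesh)
  }
  if (keep_largest && nrow(mesh$faces) > 0L)
    mesh <- largest_component(mesh)
  if (!is.null(cloud$colors) && nrow(mesh$vertices) > 0L) {
    mesh$colors <- nearest_point_colors(mesh$vertices, P, cloud$colors)
  } else mesh$colors <- matrix(0.7, nrow(mesh$vertices), 3)
  attr(mesh, "cg_resid") <- sol$resid
  attr(mesh, "grid_dims") <- dims
  attr(mesh, "voxel") <- h
  attr(mesh, "iso") <- iso
  class(mesh) <- "triangle_mesh"
  mesh
}

# binary dilation by a box of radius r (Chebyshev)
dilate3 <- function(a, r) {
  for (t in seq_len(r)) {
    d <- dim(a)
    a <- a |
      a[c(1, 1:(d[1] - 1)), , , drop = FALSE] | a[c(2:d[1], d[1]), , , drop = FALSE] |
      a[, c(1, 1:(d[2] - 1)), , drop = FALSE] | a[, c(2:d[2], d[2]), , drop = FALSE] |
      a[, , c(1, 1:(d[3] - 1)), drop = FALSE] | a[, , c(2:d[3], d[3]), drop = FALSE]
  }
  a
}

nearest_point_colors <- function(V, P, colors) {
  out <- matrix(0.7, nrow(V), 3)
  blk <- max(1L, floor(2e6 / nrow(P)))
  sqP <- rowSums(P^2)
  for (s in seq(1L, nrow(V), by = blk)) {
    e <- min(nrow(V), s + blk - 1L)
    D2 <- outer(rowSums(V[s:e, , drop = FALSE]^2), sqP, "+") -
      2 * V[s:e, , drop = FALSE] %*% t(P)
    out[s:e, ] <- colors[max.col(-D2, ties.method = "first"), , drop = FALSE]
  }
  out
}

# Kuhn 6-tetrahedron decomposition of the unit cube; corners numbered by
# bits (x, y, z).  The decomposition is identical in every cell, so shared
# faces triangulate consistently and the extracted surface is watertight.
.tets6 <- matrix(c(0, 1, 3, 7,
                   0, 3, 2, 7,
                   0, 2, 6, 7,
                   0, 6, 4, 7,
                   0, 4, 5, 7,
                   0, 5, 1, 7), ncol = 4, byrow = TRUE)

#' Marching-tetrahedra iso-surface of a scalar grid
#'
#' Splits every grid cell into 6 tetrahedra (Kuhn decomposition), classifies
#' tetra corners against the iso level, and emits 1 or 2 triangles per mixed
#' tetrahedron with vertices linearly interpolated along the crossing edges.
#' Edge vertices are shared across tetrahedra and cells, so a closed iso
#' surface yields a watertight, consistently oriented mesh (normals point
#' toward decreasing field values).
#'
#' @param vol 3-d numeric array
#' @param iso iso level
#' @param orig world coordinates of grid vertex (1, 1, 1)
#' @param h voxel edge length
#' @return list with `vertices` (V x 3) and `faces` (F x 3, 1-based)
#' @export
marching_tetrahedra <- function(vol, iso, orig = c(0, 0, 0), h = 1) {
  dims <- dim(vol)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # cells whose 8 corners straddle the iso level
  inside <- vol >= iso
  corner_off <- cbind(x = bitwAnd(0:7, 1L),
                      y = bitwShiftR(bitwAnd(0:7, 2L), 1L),
                      z = bitwShiftR(bitwAnd(0:7, 4L), 2L))
  cell_any <- inside[1:(nx - 1), 1:(ny - 1), 1:(nz - 1), drop = FALSE]
  cell_all <- cell_any
  for (k in 2:8) {
    sl <- inside[corner_off[k, 1] + 1:(nx - 1),
                 corner_off[k, 2] + 1:(ny - 1),
                 corner_off[k, 3] + 1:(nz - 1), drop = FALSE]
    cell_any <- cell_any | sl
    cell_all <- cell_all & sl
  }
  mixed <- which(cell_any & !cell_all, arr.ind = TRUE)
  if (nrow(mixed) == 0L)
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  vkey <- new.env(parent = emptyenv())
  verts <- list()
  edge_vertex <- function(g0, g1, v0, v1) {
    key <- if (g0 < g1) paste0(g0, "_", g1) else paste0(g1, "_", g0)
    id <- vkey[[key]]
    if (!is.null(id)) return(id)
    t <- (iso - v0) / (v1 - v0)
    p0 <- corner_xyz(g0); p1 <- corner_xyz(g1)
    verts[[length(verts) + 1L]] <<- p0 + t * (p1 - p0)
    id <- length(verts)
    vkey[[key]] <- id
    id
  }
  corner_xyz <- function(g) {
    g <- g - 1L
    i <- g %% nx
    j <- (g %/% nx) %% ny
    k <- g %/% (nx * ny)
    c(i, j, k)
  }
  faces <- list()
  emit <- function(a, b, c, pin) {
    # orient so the normal points from the inside (>= iso) corner outward
    pa <- verts[[a]]; pb <- verts[[b]]; pc <- verts[[c]]
    n <- cross3(pb - pa, pc - pa)
    ctr <- (pa + pb + pc) / 3
    if (sum(n * (ctr - pin)) < 0) faces[[length(faces) + 1L]] <<- c(a, c, b)
    else faces[[length(faces) + 1L]] <<- c(a, b, c)
  }
  for (m in seq_len(nrow(mixed))) {
    i <- mixed[m, 1]; j <- mixed[m, 2]; k <- mixed[m, 3]
    gids <- (i + corner_off[, 1]) +
      (j + corner_off[, 2] - 1L) * nx +
      (k + corner_off[, 3] - 1L) * nx * ny
    vals <- vol[gids]
    for (tt in 1:6) {
      tc <- .tets6[tt, ] + 1L
      g4 <- gids[tc]; v4 <- vals[tc]
      ins <- v4 >= iso
      ni <- sum(ins)
      if (ni == 0L || ni == 4L) next
      if (ni == 1L || ni == 3L) {
        solo <- if (ni == 1L) which(ins) else which(!ins)
        oth <- setdiff(1:4, solo)
        e1 <- edge_vertex(g4[solo], g4[oth[1]], v4[solo], v4[oth[1]])
        e2 <- edge_vertex(g4[solo], g4[oth[2]], v4[solo], v4[oth[2]])
        e3 <- edge_vertex(g4[solo], g4[oth[3]], v4[solo], v4[oth[3]])
        pin <- if (ni == 1L) corner_xyz(g4[solo]) else corner_xyz(g4[oth[1]])
        emit(e1, e2, e3, pin)
      } else {
        ii <- which(ins); oo <- which(!ins)
        a <- edge_vertex(g4[ii[1]], g4[oo[1]], v4[ii[1]], v4[oo[1]])
        b <- edge_vertex(g4[ii[1]], g4[oo[2]], v4[ii[1]], v4[oo[2]])
        c2 <- edge_vertex(g4[ii[2]], g4[oo[2]], v4[ii[2]], v4[oo[2]])
        d2 <- edge_vertex(g4[ii[2]], g4[oo[1]], v4[ii[2]], v4[oo[1]])
        pin <- corner_xyz(g4[ii[1]])
        emit(a, b, c2, pin)
        emit(a, c2, d2, pin)
      }
    }
  }
  V <- do.call(rbind, verts)
  V <- sweep(V * h, 2, orig, "+")
  Fm <- do.call(rbind, faces)
  storage.mode(Fm) <- "integer"
  # drop exact-degenerate faces (can arise when iso hits a grid value)
  ok <- !(Fm[, 1] == Fm[, 2] | Fm[, 2] == Fm[, 3] | Fm[, 1] == Fm[, 3])
  list(vertices = V, faces = Fm[ok, , drop = FALSE])
}

# keep the faces of the largest vertex-connected component
largest_component <- function(mesh) {
  V <- nrow(mesh$vertices)
  parent <- seq_len(V)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3])
  for (e in seq_len(nrow(ed))) {
    ra <- find(ed[e, 1]); rb <- find(ed[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(V), function(v) as.integer(find(v)), integer(1))
  froot <- roots[mesh$faces[, 1]]
  main <- as.integer(names(which.max(table(froot))))
  mesh$faces <- mesh$faces[froot == main, , drop = FALSE]
  drop_unused_vertices(mesh)
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  if (!is.null(mesh$colors)) mesh$colors <- mesh$colors[used, , drop = FALSE]
  mesh$faces <- matrix(remap[as.integer(mesh$faces)], ncol = 3)
  mesh
}
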