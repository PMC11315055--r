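# Mesh summary metrics and small mesh utilities.

#' Summary metrics of a triangle mesh
#'
#' Vertex and face counts, total surface area, vertex density (vertices per
#' unit surface area), and the number of texture blocks: connected
#' same-color regions of the vertex graph after quantizing per-vertex color
#' to `quant_levels` levels per channel (a proxy for texture-chart counts,
#' meaningful in relative comparisons).
#'
#' @param mesh a `triangle_mesh` (list with `vertices`, `faces`, optional
#'   `colors`)
#' @param quant_levels color quantization levels per channel
#' @return object of class `mesh_metrics`: `vertices`, `faces`, `area`,
#'   `density`, `texture_blocks`
#' @export
mesh_metrics <- function(mesh, quant_levels = 16L) {
  V <- mesh$vertices; Fm <- mesh$faces
  if (is.null(V) || nrow(V) == 0L || is.null(Fm) || nrow(Fm) == 0L) {
    warning("empty mesh: metrics are zero")
    return(structure(list(vertices = 0L, faces = 0L, area = 0,
                          density = 0, texture_blocks = 0L),
                     class = "mesh_metrics"))
  }
  if (max(Fm) > nrow(V)) stop("face index exceeds vertex count")
  a <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  b <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  tb <- texture_blocks(mesh, quant_levels)
  structure(list(vertices = nrow(V), faces = nrow(Fm), area = area,
                 density = if (area > 0) nrow(V) / area else 0,
                 texture_blocks = tb),
            class = "mesh_metrics")
}

#' @export
print.mesh_metrics <- function(x, ...) {
  cat(sprintf(paste0("mesh: %d vertices, %d faces, area %.4f, ",
                     "density %.2f vertices/area, %d texture blocks\n"),
              x$vertices, x$faces, x$area, x$density, x$texture_blocks))
  invisible(x)
}

# connected components of the vertex graph restricted to edges whose two
# endpoints share the same quantized color
texture_blocks <- function(mesh, quant_levels = 16L) {
  V <- nrow(mesh$vertices)
  if (V == 0L) return(0L)
  colors <- mesh$colors %||% matrix(0.7, V, 3)
  q <- matrix(pmin(quant_levels - 1L, pmax(0L, floor(colors * quant_levels))),
              V, 3)
  code <- q[, 1] * quant_levels^2 + q[, 2] * quant_levels + q[, 3]
  parent <- seq_len(V)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(1, 3)])
  same <- code[edges[, 1]] == code[edges[, 2]]
  for (e in which(same)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(V), function(v) as.integer(find(v)),
                       integer(1))))
}

#' Euler characteristic V - E + F of a triangle mesh
#' @param mesh a `triangle_mesh`
#' @return integer Euler characteristic (2 for a closed genus-0 surface)
#' @export
euler_characteristic <- function(mesh) {
  Fm <- mesh$faces
  e <- rbind(Fm[, 1:2], Fm[, 2:3], Fm[, c(1, 3)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(mesh$vertices) - length(unique(ek)) + nrow(Fm)
}

#' Is every edge of the mesh shared by exactly two faces?
#' @param mesh a `triangle_mesh`
#' @return logical
#' @export
is_closed_mesh <- function(mesh) {
  Fm <- mesh$faces
  e <- rbind(Fm[, 1:2], Fm[, 2:3], Fm[, c(1, 3)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(ek) == 2L)
}

#' Axis-aligned unit cube mesh (8 vertices, 12 triangles)
#' @return a `triangle_mesh`
#' @export
cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(V) <- NULL
  Fm <- matrix(c(1L, 3L, 2L, 2L, 3L, 4L,    # z = 0
                 5, 6, 7, 6, 8, 7,    # z = 1
                 1, 2, 5, 2, 6, 5,    # y = 0
                 3, 7, 4, 4, 7, 8,    # y = 1
                 1, 5, 3, 3, 5, 7,    # x = 0
                 2, 4, 6, 4, 8, 6),   # x = 1
               ncol = 3, byrow = TRUE)
  storage.mode(Fm) <- "integer"
  structure(list(vertices = V * 1.0, faces = Fm,
                 colors = matrix(0.7, 8, 3)),
            class = "triangle_mesh")
}

#' Loop-style 1-to-4 subdivision of every face (no smoothing)
#' @param mesh a `triangle_mesh`
#' @return subdivided `triangle_mesh`
#' @export
subdivide_mesh <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  mid_env <- new.env(parent = emptyenv())
  verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- mid_env[[key]]
    if (!is.null(id)) return(id)
    verts[[length(verts) + 1L]] <<- (V[a, ] + V[b, ]) / 2
    id <- length(verts)
    mid_env[[key]] <- id
    id
  }
  faces <- list()
  for (f in seq_len(nrow(Fm))) {
    a <- Fm[f, 1]; b <- Fm[f, 2]; c <- Fm[f, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    faces[[length(faces) + 1L]] <- c(a, ab, ca)
    faces[[length(faces) + 1L]] <- c(ab, b, bc)
    faces[[length(faces) + 1L]] <- c(ca, bc, c)
    faces[[length(faces) + 1L]] <- c(ab, bc, ca)
  }
  Vn <- do.call(rbind, verts)
  Fn <- do.call(rbind, faces)
  storage.mode(Fn) <- "integer"
  structure(list(vertices = Vn, faces = Fn,
                 colors = matrix(0.7, nrow(Vn), 3)),
            class = "triangle_mesh")
}

#' Deterministic quasi-uniform sample of the unit sphere with exact normals
#' @param n number of points
#' @return `oriented_cloud` on the unit sphere (outward normals)
#' @export
sphere_cloud <- function(n = 2000L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)                 # Fibonacci sphere
  theta <- pi * (1 + sqrt(5)) * i
  P <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  structure(list(points = P, normals = P,
                 colors = matrix(0.7, n, 3), view_id = rep(1L, n)),
            class = "oriented_cloud")
}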