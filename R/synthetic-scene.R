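# Rendered multi-view interior scenes with exact ground-truth cameras and
# depth.  Surfaces are simple analytic interiors (tube, sphere, plane) carrying
# an endoscopy-like texture; lighting is Lambertian and attached to the
# surface, so the same surface point has identical intensity in every view and
# photo-consistency is exact by construction.

#' Specification of a synthetic multi-view scene
#'
#' @param surface one of `"tube_interior"`, `"sphere_interior"`,
#'   `"textured_plane"`.
#' @param surface_params named list: `radius` and `z_range` for the tube,
#'   `radius` for the sphere, `depth` and `extent` for the plane.
#' @param texture a [texture_spec()] for the surface albedo.
#' @param trajectory list of `list(center =, target =)` camera waypoints; if
#'   `NULL` a sensible default for the surface is generated.
#' @param n_views number of views (>= 2); used when `trajectory` is `NULL`.
#' @param seed integer seed for the default trajectory jitter.
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(surface = c("tube_interior", "sphere_interior",
                                   "textured_plane"),
                       surface_params = NULL, texture = texture_spec(),
                       trajectory = NULL, n_views = 5L, seed = 1L) {
  surface <- match.arg(surface)
  defaults <- switch(surface,
    tube_interior  = list(radius = 1, z_range = c(0, 6)),
    sphere_interior = list(radius = 2),
    textured_plane = list(depth = 2, extent = c(2, 2)))
  surface_params <- utils::modifyList(defaults, surface_params %||% list())
  if (is.null(trajectory))
    trajectory <- default_trajectory(surface, surface_params, n_views, seed)
  n_views <- length(trajectory)
  if (n_views < 2L) stop("a scene needs at least 2 views")
  for (i in seq_len(n_views - 1L)) {
    d <- sqrt(sum((trajectory[[i + 1]]$center - trajectory[[i]]$center)^2))
    if (d < 1e-9) stop("consecutive camera centers must be distinct")
  }
  structure(list(surface = surface, surface_params = surface_params,
                 texture = texture, trajectory = trajectory,
                 n_views = n_views, seed = as.integer(seed)),
            class = "scene_spec")
}

default_trajectory <- function(surface, sp, n_views, seed) {
  with_seed(derive_seed(seed, "trajectory"), {
    lapply(seq_len(n_views), function(i) {
      f <- (i - 1) / max(1, n_views - 1)
      switch(surface,
        tube_interior = {
          # advance along the axis with a little lateral sway, look ahead
          c0 <- c(0.22 * sin(2 * pi * f), 0.22 * cos(2 * pi * f),
                  0.6 + 1.2 * f)
          list(center = c0, target = c(0.08 * sin(5 * f), 0.08 * cos(5 * f),
                                       c0[3] + 2.5))
        },
        sphere_interior = {
          c0 <- c(0.35 * sin(0.9 * f), 0.1 * f, 0.35 * (cos(0.9 * f) - 1))
          list(center = c0, target = c0 + c(0.25 * sin(0.35 * f),
                                            0.15 * f, 1))
        },
        textured_plane = {
          c0 <- c(-0.35 + 0.7 * f, 0.12 * sin(3 * f), 0.15 * sin(2 * f))
          list(center = c0, target = c(0.1 * f, 0, sp$depth))
        })
    })
  })
}

# bilinear texture sample with wrap-around addressing; yy, xx in 0-based
# continuous texture coordinates
tex_sample <- function(tex, yy, xx) {
  H <- nrow(tex); W <- ncol(tex)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  iy0 <- (y0 %% H) + 1L; iy1 <- ((y0 + 1) %% H) + 1L
  ix0 <- (x0 %% W) + 1L; ix1 <- ((x0 + 1) %% W) + 1L
  tex[cbind(iy0, ix0)] * (1 - fy) * (1 - fx) +
    tex[cbind(iy1, ix0)] * fy * (1 - fx) +
    tex[cbind(iy0, ix1)] * (1 - fy) * fx +
    tex[cbind(iy1, ix1)] * fy * fx
}

# surface intersection + shading for a bundle of rays; returns depth (0 where
# no hit) and intensity.  Rays: origin C (3), directions dirs (Nx3) scaled so
# that depth along the ray equals the camera-frame z of the hit point.
intersect_surface <- function(surface, sp, tex, C, dirs) {
  N <- nrow(dirs)
  s <- rep(0, N)
  if (surface == "tube_interior") {
    a <- dirs[, 1]^2 + dirs[, 2]^2
    b <- 2 * (C[1] * dirs[, 1] + C[2] * dirs[, 2])
    cc <- C[1]^2 + C[2]^2 - sp$radius^2
    disc <- b^2 - 4 * a * cc
    ok <- disc > 0 & a > 1e-14
    s[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])   # inside: cc < 0
    s[s <= 1e-9] <- 0
    # finite textured segment: beyond z_range the lumen is untextured
    z <- C[3] + dirs[, 3] * s
    s[z < sp$z_range[1] | z > sp$z_range[2]] <- 0
  } else if (surface == "sphere_interior") {
    a <- rowSums(dirs^2)
    b <- 2 * as.numeric(dirs %*% C)
    cc <- sum(C^2) - sp$radius^2
    disc <- b^2 - 4 * a * cc
    ok <- disc > 0
    s[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])
    s[s <= 1e-9] <- 0
  } else {                                             # textured_plane z = d
    dz <- dirs[, 3]
    ok <- abs(dz) > 1e-14
    s[ok] <- (sp$depth - C[3]) / dz[ok]
    s[s <= 1e-9] <- 0
  }
  hit <- s > 0
  P <- sweep(dirs * s, 2, C, "+")
  intens <- rep(0, N)
  if (any(hit)) {
    Ph <- P[hit, , drop = FALSE]
    uvn <- surface_uv_normal(surface, sp, Ph, nrow(tex), ncol(tex))
    alb <- tex_sample(tex, uvn$ty, uvn$tx)
    light <- c(0.3, 0.5, 0.81)
    light <- light / sqrt(sum(light^2))
    lam <- pmax(0, uvn$normal %*% light)
    intens[hit] <- clip01(alb * (0.72 + 0.28 * as.numeric(lam)))
  }
  list(depth = s, intensity = intens)
}

# texture coordinates (0-based, wrap) and inward surface normal per point
surface_uv_normal <- function(surface, sp, P, tH, tW) {
  if (surface == "tube_interior") {
    theta <- atan2(P[, 2], P[, 1])
    tx <- (theta + pi) / (2 * pi) * (tW - 1)
    ty <- (P[, 3] - sp$z_range[1]) / (sp$z_range[2] - sp$z_range[1]) * (tH - 1)
    n <- cbind(-P[, 1], -P[, 2], 0)
    n <- n / sqrt(rowSums(n^2))
  } else if (surface == "sphere_interior") {
    r <- sqrt(rowSums(P^2))
    theta <- atan2(P[, 2], P[, 1])
    phi <- acos(pmin(1, pmax(-1, P[, 3] / r)))
    tx <- (theta + pi) / (2 * pi) * (tW - 1)
    ty <- phi / pi * (tH - 1)
    n <- -P / r
  } else {
    tx <- (P[, 1] / sp$extent[1] + 0.5) * (tW - 1)
    ty <- (P[, 2] / sp$extent[2] + 0.5) * (tH - 1)
    n <- matrix(rep(c(0, 0, -1), each = nrow(P)), ncol = 3)
  }
  list(tx = tx, ty = ty, normal = n)
}

#' Render the views of a synthetic scene
#'
#' Ray-traces the analytic surface for every camera of the trajectory.  Depth
#' is the exact camera-frame z of the ray-surface intersection; intensity is
#' surface albedo times a fixed Lambertian term, so co-visible surface points
#' agree across views.
#'
#' @param scene a [scene_spec()]
#' @param intr a [camera_intrinsics()]
#' @param supersample integer antialiasing factor; each pixel averages
#'   `supersample^2` sub-rays (depth keeps the central ray, exactly)
#' @return list of rendered views, each `list(image, depth_gt, pose,
#'   intrinsics)`; `depth_gt` is 0 where no surface is hit
#' @export
render_views <- function(scene, intr, supersample = 2L) {
  tex <- generate_texture(scene$texture)
  H <- intr$height; W <- intr$width
  # 0-based pixel grid, pixel centers at integers; ray dirs scaled to z_cam=1
  g <- expand.grid(v = seq_len(H) - 1L, u = seq_len(W) - 1L)
  dcam <- cbind((g$u - intr$cx) / intr$fx, (g$v - intr$cy) / intr$fy, 1)
  ss <- max(1L, as.integer(supersample))
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss            # sub-pixel offsets
  views <- vector("list", scene$n_views)
  for (i in seq_len(scene$n_views)) {
    wp <- scene$trajectory[[i]]
    pose <- pose_lookat(wp$center, wp$target)
    C <- pose_center(pose)
    dirs <- dcam %*% pose$R                            # = t(R) applied rowwise
    hit <- intersect_surface(scene$surface, scene$surface_params, tex, C, dirs)
    intens <- hit$intensity
    nhit <- as.numeric(hit$depth > 0)
    if (ss > 1L) {
      for (du in offs) for (dv in offs) {
        if (du == 0 && dv == 0) next
        dsub <- cbind((g$u + du - intr$cx) / intr$fx,
                      (g$v + dv - intr$cy) / intr$fy, 1) %*% pose$R
        hs <- intersect_surface(scene$surface, scene$surface_params, tex,
                                C, dsub)
        intens <- intens + hs$intensity
        nhit <- nhit + (hs$depth > 0)
      }
      intens <- ifelse(nhit > 0, intens / nhit, 0)
    }
    if (mean(hit$depth > 0) < 0.3)
      stop("view ", i, " sees less than 30% of the surface; ",
           "camera is outside or behind the scene")
    views[[i]] <- list(image = matrix(intens, H, W),
                       depth_gt = matrix(hit$depth, H, W),
                       pose = pose, intrinsics = intr)
  }
  views
}

#' Cross-view photo-consistency of rendered ground truth
#'
#' Back-projects every surface pixel of view `a` with its ground-truth depth,
#' reprojects into view `b`, and compares intensities where both views see the
#' surface.  Used to validate the renderer.
#'
#' @param va,vb rendered views from [render_views()]
#' @param tol intensity agreement tolerance
#' @return fraction of co-visible pixels agreeing within `tol`
#' @export
photo_consistency <- function(va, vb, tol = 0.05) {
  intr <- va$intrinsics
  H <- intr$height; W <- intr$width
  g <- expand.grid(v = seq_len(H) - 1L, u = seq_len(W) - 1L)
  d <- as.numeric(va$depth_gt)
  ok <- d > 0
  Xw <- backproject_pixels(cbind(g$u[ok], g$v[ok]), d[ok], va$pose, intr)
  pr <- project_points(Xw, vb$pose, intr)
  inb <- pr$depth > 0 &
    pr$uv[, 1] >= 0 & pr$uv[, 1] <= W - 1 &
    pr$uv[, 2] >= 0 & pr$uv[, 2] <= H - 1
  if (!any(inb)) return(NA_real_)
  ib <- tex_sample(vb$image, pr$uv[inb, 2], pr$uv[inb, 1])
  # occlusion guard: require the reprojected depth to match view b's depth
  db <- tex_sample(vb$depth_gt, pr$uv[inb, 2], pr$uv[inb, 1])
  vis <- abs(db - pr$depth[inb]) < 0.02 * pr$depth[inb]
  ia <- va$image[cbind(g$v[ok][inb] + 1L, g$u[ok][inb] + 1L)]
  mean(abs(ia[vis] - ib[vis]) <= tol)
}
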