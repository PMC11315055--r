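# NCC, plane-sweep depth, depth-map fusion and normal estimation.

test_that("ncc matches the printed formula on hand fixtures", {
  set.seed(1)
  a <- matrix(runif(49), 7, 7)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, -a + 0.3), -1)
  # positive affine invariance to numerical precision
  expect_lt(abs(ncc(a, 2.5 * a + 0.1) - 1), 1e-9)
  expect_lt(abs(ncc(a, 0.01 * a - 3) - 1), 1e-9)
  # both patches constant: defined sentinel with a flag
  s <- ncc(matrix(1, 3, 3), matrix(2, 3, 3))
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  expect_error(ncc(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
  # bounded for arbitrary inputs
  for (i in 1:10) {
    x <- matrix(rnorm(25), 5); y <- matrix(rnorm(25), 5)
    v <- ncc(x, y)
    expect_true(v >= -1 && v <= 1)
    # scalar formula, written out
    dx <- x - mean(x); dy <- y - mean(y)
    expect_equal(as.numeric(v),
                 sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)))
  }
})

test_that("plane sweep nails a fronto-parallel plane and rejects no-texture", {
  intr <- test_intrinsics(60L, 80L, f = 90)
  tex <- texture_spec(size_hr = c(256L, 256L), n_vessels = 20L,
                      n_spots = 800L, noise_sigma = 0, seed = 5L)
  sc <- scene_spec("textured_plane", texture = tex,
                   surface_params = list(depth = 2, extent = c(2.4, 2)),
                   trajectory = list(
                     list(center = c(0, 0, 0), target = c(0, 0, 2)),
                     list(center = c(0.3, 0.05, 0), target = c(0.05, 0, 2))))
  vp <- render_views(sc, intr)
  K <- intrinsics_matrix(intr)
  n_planes <- 32L
  dm <- depth_map_plane_sweep(vp[[1]]$image, vp[[1]]$pose,
                              list(vp[[2]]$image), list(vp[[2]]$pose),
                              K, 1, 4, n_planes = n_planes)
  ok <- dm$depth > 0
  expect_gt(mean(ok), 0.5)
  # one inverse-depth plane spacing at depth 2, evaluated away from the
  # image border where the NCC window has full support
  spacing <- 2^2 * (1 / 1 - 1 / 4) / (n_planes - 1L)
  interior <- dm$depth[5:56, 5:76]
  oki <- interior > 0
  expect_gte(mean(abs(interior[oki] - 2) <= spacing), 0.9)

  flat <- matrix(0.5, 60, 80)
  dmc <- suppressWarnings(
    depth_map_plane_sweep(flat, vp[[1]]$pose, list(flat),
                          list(vp[[2]]$pose), K, 1, 4, n_planes = 8L))
  expect_equal(dmc$n_valid, 0L)
})

test_that("plane sweep depth error on the rendered tube stays under 5%", {
  vs <- tube_scene_views()
  K <- intrinsics_matrix(vs[[1]]$intrinsics)
  dm <- depth_map_plane_sweep(vs[[3]]$image, vs[[3]]$pose,
                              list(vs[[2]]$image, vs[[4]]$image),
                              list(vs[[2]]$pose, vs[[4]]$pose),
                              K, 0.8, 6, n_planes = 64L)
  gt <- vs[[3]]$depth_gt
  ok <- dm$depth > 0 & gt > 0
  rel <- abs(dm$depth[ok] - gt[ok]) / gt[ok]
  expect_lt(stats::median(rel), 0.05)
})

test_that("fusion keeps consistent points and culls contradicting maps", {
  # two noiseless synthetic depth maps of the plane z = 2
  intr <- test_intrinsics(40L, 50L, f = 60)
  K <- intrinsics_matrix(intr)
  p1 <- camera_pose(diag(3), c(0, 0, 0))
  p2 <- camera_pose(diag(3), c(-0.2, 0, 0))    # shifted right in world
  mk_depth <- function(pose) matrix(2 - pose$t[3], 40, 50) * 0 + 2
  d1 <- matrix(2, 40, 50); d2 <- matrix(2, 40, 50)
  cl <- fuse_depth_maps(list(d1, d2), list(p1, p2), K,
                        consistency_views = 1L, tol = 0.01, stride = 2L)
  expect_gt(nrow(cl$points), 100L)
  expect_lt(max(abs(cl$points[, 3] - 2)), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(cl$normals^2)) - 1)), 1e-6)

  # a third map that contradicts everything contributes no survivors
  d3 <- matrix(0.5, 40, 50)
  cl3 <- fuse_depth_maps(list(d1, d2, d3), list(p1, p2,
                                                camera_pose(diag(3),
                                                            c(0.2, 0, 0))),
                         K, consistency_views = 1L, tol = 0.01, stride = 2L)
  expect_equal(sum(cl3$view_id == 3L), 0L)

  # survivor count equals a brute-force per-point consistency check
  maps <- list(d1, d2)
  poses <- list(p1, p2)
  brute <- 0L
  for (v in 1:2) {
    D <- maps[[v]]
    sel <- expand.grid(y = seq(1L, 40L, 2L), x = seq(1L, 50L, 2L))
    for (r in seq_len(nrow(sel))) {
      dep <- D[sel$y[r], sel$x[r]]
      if (dep <= 0) next
      Xw <- backproject_pixels(cbind(sel$x[r] - 1L, sel$y[r] - 1L), dep,
                               poses[[v]], intr)
      nok <- 0L
      for (w in 1:2) {
        if (w == v) next
        pr <- project_points(Xw, poses[[w]], intr)
        iu <- round(pr$uv[1, 1]) + 1L; iv <- round(pr$uv[1, 2]) + 1L
        if (iu >= 1 && iu <= 50 && iv >= 1 && iv <= 40 && pr$depth[1] > 0) {
          dw <- maps[[w]][iv, iu]
          if (dw > 0 && abs(dw - pr$depth[1]) <= 0.01 * pr$depth[1])
            nok <- nok + 1L
        }
      }
      if (nok >= 1L) brute <- brute + 1L
    }
  }
  expect_equal(nrow(cl$points), brute)
})

test_that("normals recover planes and spheres with unit length", {
  # plane z = 0
  set.seed(4)
  P <- cbind(runif(300, -1, 1), runif(300, -1, 1), 0)
  N <- estimate_normals(P, k_neighbors = 8L, viewpoints = c(0, 0, 5))
  expect_lt(max(abs(sqrt(rowSums(N^2)) - 1)), 1e-6)
  expect_gt(mean(N[, 3]), 0.999)                 # oriented toward the camera

  # sphere samples: normals align with the radial direction
  sc <- sphere_cloud(600L)
  Ns <- estimate_normals(sc$points, k_neighbors = 10L,
                         viewpoints = sc$points * 3)
  agree <- rowSums(Ns * sc$points)
  expect_gt(mean(agree), 0.95)
})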