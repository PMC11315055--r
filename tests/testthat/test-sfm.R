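# Scale space, keypoints, descriptors, matching, two-view geometry, PnP,
# triangulation, bundle adjustment and the incremental pipeline.

test_that("scale space blurs correctly: DC, analytic kernel, semigroup", {
  const <- matrix(0.42, 32, 32)
  ss <- build_scale_space(const, n_octaves = 2L)
  expect_lt(max(abs(ss$octaves[[1]]$gauss[[1]] - 0.42)), 1e-12)

  # Gaussian of a centered impulse matches the closed-form kernel
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  sig <- 2.0
  got <- endosr:::gaussian_blur(imp, sig)
  xs <- (-16):16
  ref1 <- exp(-xs^2 / (2 * sig^2)); ref1 <- ref1 / sum(ref1)
  ref <- outer(ref1, ref1)
  expect_lt(max(abs(got - ref)), 1e-4)

  # semigroup: two blurs compose like one blur of the root-sum-square width
  set.seed(1)
  img <- matrix(runif(48 * 48), 48, 48)
  ab <- endosr:::gaussian_blur(endosr:::gaussian_blur(img, 1.2), 1.6)
  direct <- endosr:::gaussian_blur(img, sqrt(1.2^2 + 1.6^2))
  inner <- 6:43
  expect_lt(sqrt(mean((ab[inner, inner] - direct[inner, inner])^2)), 1e-3)
})

test_that("keypoints: none on constant images, blobs found, extrema exact", {
  ss0 <- build_scale_space(matrix(0.5, 48, 48))
  expect_equal(nrow(detect_keypoints(ss0)), 0L)

  # a dark Gaussian blob of radius ~4 is found near center at similar scale
  g <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  blob <- 0.8 - 0.5 * exp(-g / (2 * 4^2))
  kps <- detect_keypoints(build_scale_space(blob))
  expect_gte(nrow(kps), 1L)
  best <- kps[which.min((kps$x - 31)^2 + (kps$y - 31)^2), ]
  expect_lt(sqrt((best$x - 31)^2 + (best$y - 31)^2), 2)
  expect_gt(best$sigma, 2)
  expect_lt(best$sigma, 8)

  # raw extrema equal a brute-force 27-neighbour scan on a small fixture
  set.seed(6)
  img <- matrix(0.5, 32, 32)
  for (k in 1:12) {
    cy <- runif(1, 5, 28); cx <- runif(1, 5, 28); r <- runif(1, 1.5, 3)
    img <- img + sample(c(-1, 1), 1) * 0.3 *
      exp(-outer((1:32 - cy)^2, (1:32 - cx)^2, "+") / (2 * r^2))
  }
  img <- matrix(pmin(1, pmax(0, img)), 32, 32)
  ss <- build_scale_space(img, n_octaves = 1L)
  d0 <- ss$octaves[[1]]$dog[[2]]
  d1 <- ss$octaves[[1]]$dog[[3]]
  d2 <- ss$octaves[[1]]$dog[[4]]
  thr <- 1e-3
  got <- endosr:::local_extrema_mask(d0, d1, d2, thr)
  ref <- list()
  for (i in 2:31) for (j in 2:31) {
    c0 <- d1[i, j]
    if (abs(c0) <= thr) next
    nb <- c(d0[(i - 1):(i + 1), (j - 1):(j + 1)],
            d1[(i - 1):(i + 1), (j - 1):(j + 1)],
            d2[(i - 1):(i + 1), (j - 1):(j + 1)])
    nb <- nb[-14]                       # drop the center of the middle slice
    if (all(c0 > nb) || all(c0 < nb))
      ref[[length(ref) + 1L]] <- c(i, j)
  }
  ref <- do.call(rbind, ref)
  expect_gt(NROW(ref), 0L)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
  storage.mode(ref) <- "integer"
  expect_equal(unname(got), unname(ref))
})

test_that("descriptors are 128-long, unit norm and rotation-equivariant", {
  vs <- tube_scene_views()
  fe <- extract_features(vs[[1]]$image, contrast_thresh = 0.005)
  expect_gt(nrow(fe$desc), 20L)
  expect_equal(ncol(fe$desc), 128L)
  expect_lt(max(abs(sqrt(rowSums(fe$desc^2)) - 1)), 1e-6)

  # rotate image and keypoint orientation together by 90 degrees
  img <- vs[[1]]$image
  rot <- t(img)[ncol(img):1, ]                      # 90 deg CCW
  ss1 <- build_scale_space(img)
  ss2 <- build_scale_space(rot)
  # first-octave keypoint: full-resolution sampling support for the check
  k1 <- fe$kps[fe$kps$octave == 1L, ]
  kp <- k1[which.max(k1$sigma), ]
  H <- nrow(img)
  kp2 <- kp
  kp2$x <- kp$y
  kp2$y <- ncol(img) - 1 - kp$x
  kp2$xo <- kp$yo
  kp2$yo <- ncol(img) / (2^(kp$octave - 1)) - 1 - kp$xo
  kp2$orientation <- kp$orientation - pi / 2
  d1 <- compute_descriptors(ss1, kp)
  d2 <- compute_descriptors(ss2, kp2)
  skip_if(nrow(d1$desc) == 0L || nrow(d2$desc) == 0L)
  expect_lt(sqrt(sum((d1$desc - d2$desc)^2)), 0.05)
})

test_that("matching distances and filters equal a brute-force oracle", {
  set.seed(8)
  A <- matrix(rnorm(5 * 128), 5)
  A <- A / sqrt(rowSums(A^2))
  B <- matrix(rnorm(7 * 128), 7)
  B <- B / sqrt(rowSums(B^2))
  got <- match_descriptors(A, B, ratio_threshold = 0.95)
  # scalar-loop distances + mutual-NN + ratio filter
  D <- matrix(0, 5, 7)
  for (i in 1:5) for (j in 1:7) D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  kept <- list()
  for (i in 1:5) {
    j <- which.min(D[i, ])
    if (which.min(D[, j]) != i) next
    r <- D[i, j] / min(D[i, -j])
    if (r <= 0.95) kept[[length(kept) + 1L]] <- c(i, j, D[i, j], r)
  }
  ref <- do.call(rbind, kept)
  if (is.null(ref)) {
    expect_equal(nrow(got), 0L)
  } else {
    expect_equal(as.matrix(got[, c("index_i", "index_j")]),
                 ref[, 1:2, drop = FALSE], ignore_attr = TRUE)
    expect_equal(got$distance, ref[, 3])
  }

  # identical sets: all self-matches kept at zero distance
  self <- match_descriptors(A, A, ratio_threshold = 0.8)
  expect_equal(nrow(self), 5L)
  expect_true(all(self$index_i == self$index_j))
  expect_lt(max(self$distance), 1e-6)

  # unit basis vectors: distance sqrt(2) by hand
  e1 <- diag(128)[1, , drop = FALSE]
  e2 <- diag(128)[2, , drop = FALSE]
  both <- rbind(e1, e2)
  D2 <- match_descriptors(both, both, ratio_threshold = 1)
  expect_equal(D2$distance, c(0, 0))
  d12 <- sqrt(sum((e1 - e2)^2))
  expect_equal(d12, sqrt(2))
})

test_that("descriptor distances satisfy the metric axioms exhaustively", {
  set.seed(12)
  S <- matrix(rnorm(6 * 128), 6)
  S <- S / sqrt(rowSums(S^2))
  D <- as.matrix(stats::dist(S))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D[i, j], D[j, i])
    expect_gte(D[i, j], 0)
    for (k in 1:6) expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("relative pose is recovered exactly on a synthetic two-view scene", {
  set.seed(5)
  K <- matrix(c(100, 0, 0, 0, 100, 0, 64, 48, 1), 3, 3)
  Rg <- endosr:::aa_to_rot(c(0.03, -0.06, 0.02))
  tg <- c(0.4, -0.1, 0.15); tg <- tg / sqrt(sum(tg^2))
  pose0 <- camera_pose(diag(3), c(0, 0, 0))
  pose1 <- camera_pose(Rg, tg)
  X <- cbind(runif(100, -1, 1), runif(100, -0.8, 0.8), runif(100, 2.5, 5))
  p0 <- project_points(X, pose0, endosr:::intr_from_K(K))
  p1 <- project_points(X, pose1, endosr:::intr_from_K(K))
  mm <- data.frame(index_i = 1:100, index_j = 1:100)
  rel <- estimate_relative_pose(mm, data.frame(x = p0$uv[, 1], y = p0$uv[, 2]),
                                data.frame(x = p1$uv[, 1], y = p1$uv[, 2]),
                                K, seed = 3L)
  expect_lt(rotation_angle_deg(rel$R, Rg), 1)
  expect_lt(acos(abs(sum(rel$t * tg))) * 180 / pi, 3)
  expect_gte(mean(rel$inliers), 0.9)

  # epipolar constraint on the inliers in normalized coordinates
  xa <- endosr:::to_norm_coords(p0$uv, K)
  xb <- endosr:::to_norm_coords(p1$uv, K)
  E <- endosr:::skew3(rel$t) %*% rel$R
  resid <- abs(rowSums((cbind(xb, 1) %*% E) * cbind(xa, 1)))
  expect_lt(max(resid[rel$inliers]), 1e-6)

  # pure noise must fail loudly, not return a silent pose
  set.seed(9)
  rnd1 <- data.frame(x = runif(60, 0, 128), y = runif(60, 0, 96))
  rnd2 <- data.frame(x = runif(60, 0, 128), y = runif(60, 0, 96))
  expect_error(estimate_relative_pose(data.frame(index_i = 1:60,
                                                 index_j = 1:60),
                                      rnd1, rnd2, K, seed = 2L), "failed")
  expect_error(estimate_relative_pose(mm[1:5, ], rnd1, rnd2, K), "8 matches")
})

test_that("PnP recovers poses exactly, degrades gracefully with noise", {
  set.seed(7)
  K <- matrix(c(100, 0, 0, 0, 100, 0, 64, 48, 1), 3, 3)
  Rg <- endosr:::aa_to_rot(c(0.1, 0.2, -0.05))
  tg <- c(0.3, -0.2, 0.1)
  pose <- camera_pose(Rg, tg)
  X <- cbind(runif(50, -1, 1), runif(50, -1, 1), runif(50, 2, 5))
  uv <- project_points(X, pose, endosr:::intr_from_K(K))$uv
  fit <- solve_pnp(X, uv, K)
  expect_lt(rotation_angle_deg(fit$pose$R, Rg), 1e-4 * 180 / pi)
  expect_lt(max(abs(fit$pose$t - tg)), 1e-4)
  expect_lt(fit$rms_px, 1e-6)

  # identity-pose fixed point
  id_uv <- project_points(X, camera_pose(diag(3), c(0, 0, 0)),
                          endosr:::intr_from_K(K))$uv
  fit0 <- solve_pnp(X, id_uv, K)
  expect_lt(rotation_angle_deg(fit0$pose$R, diag(3)), 1e-6)
  expect_lt(max(abs(fit0$pose$t)), 1e-6)

  # half-pixel noise: rms near the noise level, sub-degree rotation error
  uvn <- uv + matrix(rnorm(100, 0, 0.5), ncol = 2)
  fitn <- solve_pnp(X, uvn, K)
  expect_lt(fitn$rms_px, 1.2)
  expect_lt(rotation_angle_deg(fitn$pose$R, Rg), 0.5)
  expect_error(solve_pnp(X[1:4, ], uv[1:4, ], K), ">= 6")
})

test_that("triangulation is exact, symmetric and cheirality-aware", {
  K <- matrix(c(100, 0, 0, 0, 100, 0, 64, 48, 1), 3, 3)
  pose0 <- camera_pose(diag(3), c(0, 0, 0))
  pose1 <- camera_pose(endosr:::aa_to_rot(c(0.05, -0.04, 0.01)),
                       c(0.5, 0.1, -0.05))
  X <- c(0.3, -0.2, 3.4)
  u0 <- project_points(matrix(X, 1), pose0, endosr:::intr_from_K(K))$uv[1, ]
  u1 <- project_points(matrix(X, 1), pose1, endosr:::intr_from_K(K))$uv[1, ]
  tp <- triangulate_point(pose0, pose1, K, u0, u1)
  expect_true(tp$ok)
  expect_lt(max(abs(tp$X - X)), 1e-6)
  expect_lt(tp$residual_px, 1e-6)

  tp2 <- triangulate_point(pose1, pose0, K, u1, u0)
  expect_lt(max(abs(tp2$X - tp$X)), 1e-8)

  # a point behind the cameras is flagged, not silently returned
  Xb <- c(0.1, 0.1, -2)
  ub0 <- c(100, 50); ub1 <- c(90, 52)
  tpb <- triangulate_point(pose0, pose1, K, ub0, ub1)
  if (!tpb$ok) expect_match(tpb$reason, "cheirality|low_angle")

  # near-parallel rays are flagged low confidence
  posep <- camera_pose(diag(3), c(1e-5, 0, 0))
  tpp <- triangulate_point(pose0, posep, K, u0, u0)
  expect_false(tpp$ok)
})

test_that("bundle adjustment is stationary at truth and non-increasing", {
  set.seed(10)
  K <- matrix(c(100, 0, 0, 0, 100, 0, 64, 48, 1), 3, 3)
  poses <- list(camera_pose(diag(3), c(0, 0, 0)))
  for (v in 2:3)
    poses[[v]] <- camera_pose(endosr:::aa_to_rot(rnorm(3, 0, 0.03)),
                              c(0.4 * (v - 1), rnorm(1, 0, 0.05), 0))
  X <- cbind(runif(40, -1, 1), runif(40, -1, 1), runif(40, 2.5, 4.5))
  tracks <- lapply(seq_len(40), function(i) {
    uv <- do.call(rbind, lapply(poses, function(p)
      project_points(X[i, , drop = FALSE], p,
                     endosr:::intr_from_K(K))$uv[1, ]))
    list(X = X[i, ], views = 1:3, uv = uv)
  })
  cloud <- structure(list(tracks = tracks, poses = poses, K = K,
                          registered = 1:3), class = "sparse_cloud")

  # objective equals a scalar-loop evaluation of the summed squared residuals
  obj <- reprojection_objective(cloud)
  ref <- 0
  for (tr in tracks) for (v in 1:3) {
    Xc <- poses[[v]]$R %*% tr$X + poses[[v]]$t
    u <- K[1, 1] * Xc[1] / Xc[3] + K[1, 3]
    w <- K[2, 2] * Xc[2] / Xc[3] + K[2, 3]
    ref <- ref + (u - tr$uv[v, 1])^2 + (w - tr$uv[v, 2])^2
  }
  expect_equal(obj, ref)
  expect_lt(obj, 1e-18)

  # at ground truth nothing moves
  ba0 <- bundle_adjust(cloud, max_iter = 5L)
  for (v in 1:3)
    expect_lt(rotation_angle_deg(ba0$poses[[v]]$R, poses[[v]]$R), 1e-7)
  expect_lt(ba0$mean_reproj_px, 1e-8)

  # perturb poses by ~1 degree / 1% translation, adjust, recover
  pert <- cloud
  for (v in 2:3) {
    pert$poses[[v]] <- camera_pose(
      endosr:::aa_to_rot(rnorm(3, 0, 0.017 / sqrt(3))) %*% poses[[v]]$R,
      poses[[v]]$t * 1.01)
  }
  for (ti in seq_along(pert$tracks))
    pert$tracks[[ti]]$X <- pert$tracks[[ti]]$X + rnorm(3, 0, 0.01)
  ba <- bundle_adjust(pert, max_iter = 40L)
  expect_lt(ba$mean_reproj_px, 1e-3)
  tr <- attr(ba, "objective_trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("incremental reconstruction recovers the rendered scene", {
  vs <- tube_scene_views()
  K <- intrinsics_matrix(vs[[1]]$intrinsics)
  cl <- reconstruct_sparse(lapply(vs, `[[`, "image"), K, seed = 1L,
                           contrast_thresh = 0.005)
  expect_s3_class(cl, "sparse_cloud")
  expect_length(cl$registered, 5L)
  expect_true(all(vapply(cl$tracks, function(tr)
    length(tr$views) >= 2L, logical(1))))
  expect_lt(cl$mean_reproj_px, 1)
  al <- align_to_ground_truth(cl, vs)
  expect_lt(max(al$rot_err_deg, na.rm = TRUE), 2)

  # duplicated image pair is rejected as a zero-baseline degeneracy
  imgs <- lapply(vs, `[[`, "image")
  imgs[[2]] <- imgs[[1]]
  expect_error(reconstruct_sparse(imgs, K, seed = 1L,
                                  contrast_thresh = 0.005), "identical")
})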