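# Two-view geometry, PnP, triangulation, bundle adjustment and the
# incremental sparse-reconstruction pipeline.  Reprojection error is always
# the objective: sum_i || x_i - pi(K, R, t, X_i) ||^2.

normalize_pts <- function(x) {
  # Hartley normalisation: zero centroid, mean distance sqrt(2)
  m <- colMeans(x)
  xc <- sweep(x, 2, m)
  s <- sqrt(2) / mean(sqrt(rowSums(xc^2)))
  Tm <- matrix(c(s, 0, 0, 0, s, 0, -s * m[1], -s * m[2], 1), 3, 3)
  list(x = xc * s, T = Tm)
}

# essential matrix from >= 8 normalised-coordinate correspondences
eight_point <- function(xa, xb) {
  na <- normalize_pts(xa); nb <- normalize_pts(xb)
  a <- na$x; b <- nb$x
  A <- cbind(b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1],
             b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2],
             a[, 1], a[, 2], 1)
  sv <- svd(A, nv = 9L)
  E <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  E <- t(nb$T) %*% E %*% na$T
  # project onto the essential manifold: two equal singular values
  se <- svd(E)
  se$u %*% diag(c(1, 1, 0)) %*% t(se$v)
}

sampson_error <- function(E, xa, xb) {
  # xa, xb: Nx2 normalised camera coordinates
  ha <- cbind(xa, 1); hb <- cbind(xb, 1)
  Ex <- ha %*% t(E)          # row i = E x_a
  Etx <- hb %*% E            # row i = E' x_b
  num <- rowSums(hb * Ex)^2
  num / (Ex[, 1]^2 + Ex[, 2]^2 + Etx[, 1]^2 + Etx[, 2]^2)
}

to_norm_coords <- function(uv, K) {
  cbind((uv[, 1] - K[1, 3]) / K[1, 1], (uv[, 2] - K[2, 3]) / K[2, 2])
}

#' Estimate the relative pose of two views from matched keypoints
#'
#' Normalised 8-point essential-matrix estimation inside RANSAC on the
#' Sampson error, followed by the cheirality-checked decomposition into
#' rotation and unit translation.
#'
#' @param matches match data frame from [match_descriptors()]
#' @param kpsA,kpsB keypoint data frames (columns `x`, `y`)
#' @param K 3x3 intrinsics matrix
#' @param iters RANSAC iterations
#' @param thresh_px inlier threshold in pixels
#' @param seed RANSAC seed
#' @return list with `R`, `t` (unit norm), `E`, `inliers` (logical mask) or
#'   an error if fewer than 8 matches / no valid pose survives
#' @export
estimate_relative_pose <- function(matches, kpsA, kpsB, K, iters = 2000L,
                                   thresh_px = 1.5, seed = 1L) {
  if (nrow(matches) < 8L) stop("need at least 8 matches for the 8-point solver")
  uvA <- cbind(kpsA$x[matches$index_i], kpsA$y[matches$index_i])
  uvB <- cbind(kpsB$x[matches$index_j], kpsB$y[matches$index_j])
  xa <- to_norm_coords(uvA, K)
  xb <- to_norm_coords(uvB, K)
  f <- mean(c(K[1, 1], K[2, 2]))
  th2 <- (thresh_px / f)^2
  n <- nrow(xa)
  min_support <- max(10L, as.integer(ceiling(0.2 * n)))
  best <- NULL; best_n <- 0L
  with_seed(seed, {
    for (it in seq_len(iters)) {
      idx <- sample.int(n, 8L)
      E <- tryCatch(eight_point(xa[idx, , drop = FALSE],
                                xb[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(E)) next
      inl <- sampson_error(E, xa, xb) < th2
      if (sum(inl) > best_n) { best <- E; best_n <- sum(inl) }
    }
  })
  if (is.null(best) || best_n < min_support)
    stop("relative pose estimation failed: only ", best_n,
         " inliers out of ", n, " matches")
  inl <- sampson_error(best, xa, xb) < th2
  # refit on the consensus set; keep the refit only if it does not shrink it
  E2 <- eight_point(xa[inl, , drop = FALSE], xb[inl, , drop = FALSE])
  inl2 <- sampson_error(E2, xa, xb) < th2
  E <- if (sum(inl2) >= sum(inl)) { inl <- inl2; E2 } else best
  if (sum(inl) < min_support)
    stop("relative pose estimation failed after refit: ", sum(inl), " inliers")
  dec <- decompose_essential(E, xa[inl, , drop = FALSE],
                             xb[inl, , drop = FALSE])
  if (is.null(dec))
    stop("essential-matrix decomposition found no cheirality-consistent pose")
  list(R = dec$R, t = dec$t, E = E, inliers = inl)
}

# four-fold (R, t) ambiguity resolved by triangulating and counting points
# in front of both cameras
decompose_essential <- function(E, xa, xb) {
  sv <- svd(E)
  if (det(sv$u) < 0) sv$u <- -sv$u
  if (det(sv$v) < 0) sv$v <- -sv$v
  Wm <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cands <- list()
  for (R in list(sv$u %*% Wm %*% t(sv$v), sv$u %*% t(Wm) %*% t(sv$v)))
    for (tsign in c(1, -1))
      cands[[length(cands) + 1L]] <- list(R = R, t = tsign * sv$u[, 3])
  best <- NULL; best_n <- -1L
  P0 <- cbind(diag(3), 0)
  for (cd in cands) {
    P1 <- cbind(cd$R, cd$t)
    X <- triangulate_linear_batch(P0, P1, xa, xb)
    z0 <- X[, 3]
    z1 <- (X %*% t(cd$R))[, 3] + cd$t[3]
    ok <- sum(z0 > 0 & z1 > 0)
    if (ok > best_n) { best <- cd; best_n <- ok }
  }
  if (best_n < max(2L, nrow(xa) %/% 4L)) return(NULL)
  best
}

# DLT triangulation of many points from two normalised projection matrices
triangulate_linear_batch <- function(P0, P1, xa, xb) {
  n <- nrow(xa)
  X <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    A <- rbind(xa[i, 1] * P0[3, ] - P0[1, ],
               xa[i, 2] * P0[3, ] - P0[2, ],
               xb[i, 1] * P1[3, ] - P1[1, ],
               xb[i, 2] * P1[3, ] - P1[2, ])
    v <- svd(A)$v[, 4]
    X[i, ] <- v[1:3] / v[4]
  }
  X
}

#' Triangulate one point from two views
#'
#' Linear (DLT) triangulation refined by Gauss-Newton on the two-view
#' reprojection error; flags points behind either camera or from
#' near-parallel rays.
#'
#' @param poseA,poseB `camera_pose` objects
#' @param K 3x3 intrinsics matrix
#' @param xA,xB length-2 pixel coordinates (0-based)
#' @param min_angle_deg minimum triangulation angle
#' @return list with `X` (length-3), `residual_px` (RMS over the two views),
#'   `ok`, and `reason` when flagged
#' @export
triangulate_point <- function(poseA, poseB, K, xA, xB, min_angle_deg = 1.5) {
  PA <- cbind(poseA$R, poseA$t)
  PB <- cbind(poseB$R, poseB$t)
  na <- to_norm_coords(matrix(xA, 1), K)
  nb <- to_norm_coords(matrix(xB, 1), K)
  X <- triangulate_linear_batch(PA, PB, na, nb)[1, ]
  # ray angle check
  ca <- pose_center(poseA); cb <- pose_center(poseB)
  ra <- X - ca; rb <- X - cb
  ang <- acos(pmin(1, pmax(-1, sum(ra * rb) /
                             (sqrt(sum(ra^2)) * sqrt(sum(rb^2)))))) * 180 / pi
  za <- (poseA$R %*% X + poseA$t)[3]
  zb <- (poseB$R %*% X + poseB$t)[3]
  if (za <= 0 || zb <= 0)
    return(list(X = X, residual_px = Inf, ok = FALSE, reason = "cheirality"))
  if (ang < min_angle_deg)
    return(list(X = X, residual_px = Inf, ok = FALSE, reason = "low_angle"))
  # Gauss-Newton refinement of the 3D point on pixel reprojection error
  obs <- rbind(xA, xB); poses <- list(poseA, poseB)
  for (it in 1:10) {
    J <- matrix(0, 4, 3); r <- numeric(4)
    for (v in 1:2) {
      pj <- project_point_jacobian(X, poses[[v]], K)
      r[(2 * v - 1):(2 * v)] <- pj$uv - obs[v, ]
      J[(2 * v - 1):(2 * v), ] <- pj$dX
    }
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    X <- X - as.numeric(step)
    if (max(abs(step)) < 1e-12) break
  }
  res2 <- vapply(1:2, function(v)
    sum((project_point_jacobian(X, poses[[v]], K)$uv - obs[v, ])^2),
    numeric(1))
  list(X = X, residual_px = sqrt(mean(res2)), ok = TRUE, reason = NULL)
}

# projection of one point with Jacobians wrt the point and the pose
# (angle-axis increment on the left of R, plus translation)
project_point_jacobian <- function(X, pose, K) {
  Xc <- as.numeric(pose$R %*% X + pose$t)
  z <- Xc[3]
  u <- K[1, 1] * Xc[1] / z + K[1, 3]
  v <- K[2, 2] * Xc[2] / z + K[2, 3]
  duv_dXc <- rbind(c(K[1, 1] / z, 0, -K[1, 1] * Xc[1] / z^2),
                   c(0, K[2, 2] / z, -K[2, 2] * Xc[2] / z^2))
  list(uv = c(u, v),
       dX = duv_dXc %*% pose$R,            # wrt world point
       dw = duv_dXc %*% (-skew3(Xc)),      # wrt rotation increment
       dt = duv_dXc,                       # wrt translation
       z = z)
}

#' Solve the Perspective-n-Point problem
#'
#' Minimises the reprojection error over (R, t) by Gauss-Newton with
#' angle-axis increments, started from a DLT linear initialisation (or a
#' caller-supplied pose).
#'
#' @param points3d Nx3 world points
#' @param points2d Nx2 pixel observations (0-based)
#' @param K 3x3 intrinsics matrix
#' @param initial_pose optional `camera_pose` to refine
#' @return list with `pose` (a `camera_pose`) and `rms_px`
#' @export
solve_pnp <- function(points3d, points2d, K, initial_pose = NULL) {
  X <- matrix(points3d, ncol = 3); x <- matrix(points2d, ncol = 2)
  n <- nrow(X)
  if (is.null(initial_pose)) {
    if (n < 6L) stop("PnP linear initialisation needs >= 6 correspondences")
    pose <- pnp_dlt(X, x, K)
  } else pose <- initial_pose
  if (is.null(pose)) stop("PnP initialisation failed (degenerate geometry)")
  R <- pose$R; t <- pose$t
  prev_cost <- Inf
  for (it in 1:30) {
    J <- matrix(0, 2 * n, 6); r <- numeric(2 * n)
    for (i in seq_len(n)) {
      pj <- project_point_jacobian(X[i, ], camera_pose(R, t), K)
      if (pj$z <= 0) next
      rows <- (2 * i - 1):(2 * i)
      r[rows] <- pj$uv - x[i, ]
      J[rows, ] <- cbind(pj$dw, pj$dt)
    }
    cost <- sum(r^2)
    step <- tryCatch(solve(crossprod(J) + 1e-9 * diag(6), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    R <- aa_to_rot(-as.numeric(step[1:3])) %*% R
    # re-orthonormalise to stay on SO(3)
    sv <- svd(R); R <- sv$u %*% t(sv$v)
    if (det(R) < 0) R <- -R
    t <- t - as.numeric(step[4:6])
    if (abs(prev_cost - cost) < 1e-14 * (1 + cost)) break
    prev_cost <- cost
  }
  pose <- camera_pose(R, t)
  pr <- project_points(X, pose, intr_from_K(K))
  rms <- sqrt(mean(rowSums((pr$uv - x)^2)))
  list(pose = pose, rms_px = rms)
}

intr_from_K <- function(K, height = 1e6L, width = 1e6L) {
  structure(list(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3], cy = K[2, 3],
                 height = height, width = width), class = "camera_intrinsics")
}

# DLT estimate of [R|t] from >= 6 points (camera resectioning)
pnp_dlt <- function(X, x, K) {
  xn <- to_norm_coords(x, K)
  n <- nrow(X)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xi <- c(X[i, ], 1)
    A[2 * i - 1, ] <- c(Xi, rep(0, 4), -xn[i, 1] * Xi)
    A[2 * i, ] <- c(rep(0, 4), Xi, -xn[i, 2] * Xi)
  }
  P <- matrix(svd(A)$v[, 12], 3, 4, byrow = TRUE)
  M <- P[, 1:3]
  if (det(M) < 0) P <- -P
  sc <- (svd(M)$d)[2]                      # middle singular value as scale
  P <- P / sc
  sv <- svd(P[, 1:3])
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) return(NULL)
  t <- as.numeric(P[, 4])
  # ensure points are in front; flip if the majority are behind
  z <- (X %*% t(R))[, 3] + t[3]
  if (mean(z > 0) < 0.5) return(NULL)
  camera_pose(R, t)
}

# PnP with outlier resistance: try the DLT, a prior-pose initialisation and
# RANSAC over minimal DLT subsets, iterate residual trimming around each,
# and keep the solution with the best inlier RMS provided it retains at
# least half the correspondences under 5 px.  NULL when nothing qualifies.
robust_pnp <- function(X3m, x2m, K, prior_pose = NULL, ransac_iters = 400L,
                       seed = 7L) {
  n <- nrow(X3m)
  inits <- list(tryCatch(solve_pnp(X3m, x2m, K), error = function(e) NULL))
  if (!is.null(prior_pose))
    inits <- c(inits, list(tryCatch(
      solve_pnp(X3m, x2m, K, initial_pose = prior_pose),
      error = function(e) NULL)))
  if (n >= 8L) {
    rb <- NULL; rb_n <- 0L
    with_seed(seed, {
      for (it in seq_len(ransac_iters)) {
        idx <- sample.int(n, 6L)
        cand <- tryCatch(pnp_dlt(X3m[idx, , drop = FALSE],
                                 x2m[idx, , drop = FALSE], K),
                         error = function(e) NULL)
        if (is.null(cand)) next
        pr <- project_points(X3m, cand, intr_from_K(K))
        ninl <- sum(pr$depth > 0 & sqrt(rowSums((pr$uv - x2m)^2)) < 5)
        if (ninl > rb_n) { rb <- cand; rb_n <- ninl }
      }
    })
    # enter the trimming loop from the raw consensus pose: refining on the
    # full set first would let gross outliers drag the solution away
    if (!is.null(rb) && rb_n >= 6L)
      inits <- c(inits, list(list(pose = rb, rms_px = NA_real_)))
  }
  best <- NULL
  for (cand in inits) {
    if (is.null(cand)) next
    for (round in 1:3) {
      pr <- project_points(X3m, cand$pose, intr_from_K(K))
      resid <- sqrt(rowSums((pr$uv - x2m)^2))
      keep <- resid < pmax(3, 3 * stats::median(resid))
      if (sum(keep) < 6L) break
      cand <- tryCatch(solve_pnp(X3m[keep, , drop = FALSE],
                                 x2m[keep, , drop = FALSE], K,
                                 initial_pose = cand$pose),
                       error = function(e) NULL)
      if (is.null(cand)) break
    }
    if (is.null(cand)) next
    pr <- project_points(X3m, cand$pose, intr_from_K(K))
    resid <- sqrt(rowSums((pr$uv - x2m)^2))
    good <- resid < 5
    score <- list(pose = cand$pose, inliers = sum(good),
                  rms_px = if (any(good)) sqrt(mean(resid[good]^2)) else Inf,
                  rms_all = sqrt(mean(resid^2)))
    if (is.null(best) || score$inliers > best$inliers ||
        (score$inliers == best$inliers && score$rms_all < best$rms_all))
      best <- score
  }
  # a young cloud can be distorted enough that no pose fits tightly before
  # bundle adjustment; accept anything non-catastrophic and let BA refine
  if (is.null(best) || !is.finite(best$rms_all) || best$rms_all > 50)
    return(NULL)
  best
}

#' Bundle adjustment: joint refinement of poses and points
#'
#' Levenberg-Marquardt on the total squared reprojection error over all
#' observations; the first pose is held fixed as gauge, intrinsics are fixed.
#' Iterations that would increase the objective are rejected (damping is
#' increased instead), so the accepted objective is non-increasing.
#'
#' @param cloud a `sparse_cloud` (see [reconstruct_sparse()])
#' @param max_iter maximum LM iterations
#' @return the adjusted `sparse_cloud` with updated `mean_reproj_px` and an
#'   `objective_trace` attribute (accepted objective values)
#' @export
bundle_adjust <- function(cloud, max_iter = 25L) {
  poses <- cloud$poses; tracks <- cloud$tracks; K <- cloud$K
  np <- length(tracks)
  views_used <- sort(unique(unlist(lapply(tracks, function(tr) tr$views))))
  if (length(views_used) < 2L) stop("bundle adjustment needs at least two views")
  nv <- length(views_used)
  slot <- integer(max(views_used))
  slot[views_used] <- seq_len(nv)            # 1 = gauge view (held fixed)
  obs <- do.call(rbind, lapply(seq_len(np), function(ti) {
    tr <- tracks[[ti]]
    cbind(ti, tr$views, tr$uv)
  }))
  objective <- function(poses, pts) {
    s <- 0
    for (k in seq_len(nrow(obs))) {
      pj <- project_points(matrix(pts[obs[k, 1], ], 1),
                           poses[[obs[k, 2]]], intr_from_K(K))
      s <- s + sum((pj$uv - obs[k, 3:4])^2)
    }
    s
  }
  pts <- do.call(rbind, lapply(tracks, function(tr) tr$X))
  lambda <- 1e-3
  obj <- objective(poses, pts)
  trace <- obj
  npar <- 6L * (nv - 1L) + 3L * np
  pose_idx <- function(v) 6L * (slot[v] - 2L) + 1:6      # slot >= 2
  pt_idx <- function(ti) 6L * (nv - 1L) + 3L * (ti - 1L) + 1:3
  for (it in seq_len(max_iter)) {
    JtJ <- matrix(0, npar, npar)
    Jtr <- numeric(npar)
    for (k in seq_len(nrow(obs))) {
      ti <- obs[k, 1]; v <- obs[k, 2]
      pj <- project_point_jacobian(pts[ti, ], poses[[v]], K)
      r <- pj$uv - obs[k, 3:4]
      cols <- pt_idx(ti)
      JtJ[cols, cols] <- JtJ[cols, cols] + crossprod(pj$dX)
      Jtr[cols] <- Jtr[cols] + crossprod(pj$dX, r)
      if (slot[v] >= 2L) {
        pcols <- pose_idx(v)
        Jp <- cbind(pj$dw, pj$dt)
        JtJ[pcols, pcols] <- JtJ[pcols, pcols] + crossprod(Jp)
        JtJ[pcols, cols] <- JtJ[pcols, cols] + crossprod(Jp, pj$dX)
        JtJ[cols, pcols] <- JtJ[cols, pcols] + crossprod(pj$dX, Jp)
        Jtr[pcols] <- Jtr[pcols] + crossprod(Jp, r)
      }
    }
    accepted <- FALSE
    for (try in 1:8) {
      step <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ) + 1e-9),
                             Jtr), error = function(e) NULL)
      if (!is.null(step)) {
        new_poses <- poses
        for (v in views_used[-1]) {
          s <- step[pose_idx(v)]
          Rn <- aa_to_rot(-s[1:3]) %*% poses[[v]]$R
          sv <- svd(Rn); Rn <- sv$u %*% t(sv$v)
          if (det(Rn) < 0) Rn <- -Rn
          new_poses[[v]] <- camera_pose(Rn, poses[[v]]$t - s[4:6])
        }
        new_pts <- pts
        for (ti in seq_len(np)) new_pts[ti, ] <- pts[ti, ] - step[pt_idx(ti)]
        new_obj <- objective(new_poses, new_pts)
        if (is.finite(new_obj) && new_obj <= obj) {
          poses <- new_poses; pts <- new_pts
          lambda <- max(lambda / 3, 1e-9)
          obj <- new_obj
          trace <- c(trace, obj)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break
    if (length(trace) >= 2L &&
        (trace[length(trace) - 1L] - obj) < 1e-10 * (1 + obj)) break
  }
  for (ti in seq_len(np)) cloud$tracks[[ti]]$X <- pts[ti, ]
  cloud$poses <- poses
  cloud$mean_reproj_px <- mean_reproj_error(cloud)
  attr(cloud, "objective_trace") <- trace
  cloud
}

#' Total squared reprojection error of a sparse cloud
#' @param cloud a `sparse_cloud`
#' @return sum over all observations of squared pixel residuals
#' @export
reprojection_objective <- function(cloud) {
  s <- 0
  for (tr in cloud$tracks) for (k in seq_along(tr$views)) {
    pj <- project_points(matrix(tr$X, 1), cloud$poses[[tr$views[k]]],
                         intr_from_K(cloud$K))
    s <- s + sum((pj$uv - tr$uv[k, ])^2)
  }
  s
}

mean_reproj_error <- function(cloud) {
  e <- c(); n <- 0L
  for (tr in cloud$tracks) for (k in seq_along(tr$views)) {
    pj <- project_points(matrix(tr$X, 1), cloud$poses[[tr$views[k]]],
                         intr_from_K(cloud$K))
    e <- c(e, sqrt(sum((pj$uv - tr$uv[k, ])^2)))
  }
  mean(e)
}

#' Incremental sparse reconstruction from an ordered image set
#'
#' Features, pairwise matching, essential-matrix initialisation of the best
#' pair, incremental PnP registration of the remaining views, multi-view
#' track triangulation, and a closing bundle adjustment.
#'
#' @param images list of grayscale matrices sharing intrinsics
#' @param K 3x3 intrinsics matrix
#' @param seed seed for the RANSAC stages
#' @param min_track_views minimum observations per kept track
#' @param verbose print per-stage progress
#' @param ... feature extraction options
#' @return object of class `sparse_cloud`: `tracks` (each with world point
#'   `X`, `views`, pixel observations `uv`), `poses`, `K`,
#'   `mean_reproj_px`, `registered` (view indices), and per-stage `log`
#' @export
reconstruct_sparse <- function(images, K, seed = 1L, min_track_views = 2L,
                               match_ratio = 0.85, verbose = FALSE, ...) {
  nv <- length(images)
  if (nv < 2L) stop("need at least two images")
  logmsg <- character(0)
  say <- function(...) {
    m <- sprintf(...)
    logmsg <<- c(logmsg, m)
    if (verbose) message(m)
  }
  feats <- lapply(images, extract_features, ...)
  for (i in seq_len(nv))
    say("view %d: %d keypoints", i, nrow(feats[[i]]$kps))
  # duplicate-image guard: zero-baseline pairs break triangulation
  pairs <- utils::combn(nv, 2L)
  matches <- vector("list", ncol(pairs))
  nmatch <- integer(ncol(pairs))
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    if (identical(images[[i]], images[[j]]))
      stop("views ", i, " and ", j, " are identical images: ",
           "zero-baseline pair cannot be reconstructed")
    m <- match_descriptors(feats[[i]]$desc, feats[[j]]$desc, match_ratio)
    matches[[pi]] <- m
    nmatch[pi] <- nrow(m)
    say("pair (%d,%d): %d matches", i, j, nrow(m))
  }
  # init-pair selection: among well-matched pairs prefer a wide baseline
  # (median triangulation angle), not just the raw match count — the
  # best-matched pair is typically the nearest one and conditions poorly
  ord <- order(-nmatch)
  cand <- ord[nmatch[ord] >= 15L]
  init <- NULL; best_ang <- -Inf
  for (pi in utils::head(cand, 6L)) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    rel <- tryCatch(estimate_relative_pose(matches[[pi]], feats[[i]]$kps,
                                           feats[[j]]$kps, K,
                                           seed = derive_seed(seed, "init")),
                    error = function(e) NULL)
    if (is.null(rel)) next
    uvA <- cbind(feats[[i]]$kps$x, feats[[i]]$kps$y)[matches[[pi]]$index_i, ]
    uvB <- cbind(feats[[j]]$kps$x, feats[[j]]$kps$y)[matches[[pi]]$index_j, ]
    xa <- to_norm_coords(uvA[rel$inliers, , drop = FALSE], K)
    xb <- to_norm_coords(uvB[rel$inliers, , drop = FALSE], K)
    X <- triangulate_linear_batch(cbind(diag(3), 0), cbind(rel$R, rel$t),
                                  xa, xb)
    c2 <- -as.numeric(crossprod(rel$R, rel$t))
    num <- rowSums(X * sweep(X, 2, c2))
    ang <- acos(pmin(1, pmax(-1, num /
                               (sqrt(rowSums(X^2)) *
                                  sqrt(rowSums(sweep(X, 2, c2)^2))))))
    score <- stats::median(ang) * 180 / pi
    say("init candidate (%d,%d): %d inliers, %.2f deg median angle",
        i, j, sum(rel$inliers), score)
    # sanity bound: implausibly wide median angles signal a wrong pose,
    # vanishing ones a zero baseline; first usable candidate (candidates
    # are already ordered by match count) wins
    if (score >= 1 && score <= 15) {
      init <- list(pi = pi, i = i, j = j, rel = rel)
      break
    }
  }
  if (is.null(init))
    stop("initialisation failed: no image pair yields a valid relative pose")
  say("init pair (%d,%d) with %d inliers", init$i, init$j,
      sum(init$rel$inliers))
  poses <- vector("list", nv)
  poses[[init$i]] <- camera_pose(diag(3), c(0, 0, 0))
  poses[[init$j]] <- camera_pose(init$rel$R, init$rel$t)
  registered <- c(init$i, init$j)
  # union-find track merging over (view, keypoint) nodes
  uf <- uf_new()
  key <- function(v, k) paste0(v, "_", k)
  for (pi in seq_len(ncol(pairs))) {
    m <- matches[[pi]]
    if (nrow(m) == 0L) next
    i <- pairs[1, pi]; j <- pairs[2, pi]
    for (r in seq_len(nrow(m)))
      uf_union(uf, key(i, m$index_i[r]), key(j, m$index_j[r]))
  }
  comp <- uf_components(uf)
  tracks_raw <- list()
  for (cidx in seq_along(comp)) {
    nodes <- comp[[cidx]]
    if (length(nodes) < 2L) next
    vs <- as.integer(sub("_.*", "", nodes))
    ks <- as.integer(sub(".*_", "", nodes))
    if (anyDuplicated(vs)) next              # inconsistent track, drop
    tracks_raw[[length(tracks_raw) + 1L]] <- list(views = vs, kp = ks)
  }
  say("%d consistent candidate tracks", length(tracks_raw))
  kp_uv <- function(v, k) c(feats[[v]]$kps$x[k], feats[[v]]$kps$y[k])
  triangulate_track <- function(tr) {
    vs <- tr$views[tr$views %in% registered]
    if (length(vs) < 2L) return(NULL)
    v1 <- vs[1]; v2 <- vs[length(vs)]
    k1 <- tr$kp[match(v1, tr$views)]; k2 <- tr$kp[match(v2, tr$views)]
    tp <- triangulate_point(poses[[v1]], poses[[v2]], K,
                            kp_uv(v1, k1), kp_uv(v2, k2))
    if (!tp$ok || tp$residual_px > 4) return(NULL)
    keepv <- tr$views %in% registered
    list(X = tp$X, views = tr$views[keepv],
         uv = do.call(rbind, lapply(which(keepv), function(q)
           kp_uv(tr$views[q], tr$kp[q]))))
  }
  # iterate: triangulate what is visible, register one more view by PnP;
  # a view that will not register is skipped (with a log entry) rather
  # than aborting the whole reconstruction
  tracks <- list()
  failed <- integer(0)
  repeat {
    tracks <- Filter(Negate(is.null), lapply(tracks_raw, triangulate_track))
    remaining <- setdiff(seq_len(nv), c(registered, failed))
    if (length(remaining) == 0L) break
    # pick the unregistered view with most 2D-3D correspondences
    counts <- vapply(remaining, function(v)
      sum(vapply(tracks_raw, function(tr)
        v %in% tr$views && sum(tr$views %in% registered) >= 2L, logical(1))),
      integer(1))
    vnext <- remaining[which.max(counts)]
    X3 <- list(); x2 <- list()
    for (q in seq_along(tracks_raw)) {
      tr <- tracks_raw[[q]]
      if (!(vnext %in% tr$views)) next
      tt <- triangulate_track(tr)
      if (is.null(tt)) next
      X3[[length(X3) + 1L]] <- tt$X
      x2[[length(x2) + 1L]] <- kp_uv(vnext, tr$kp[match(vnext, tr$views)])
    }
    pnp <- NULL
    if (length(X3) >= 6L) {
      near <- registered[which.min(abs(registered - vnext))]
      X3m <- do.call(rbind, X3); x2m <- do.call(rbind, x2)
      pnp <- robust_pnp(X3m, x2m, K, poses[[near]],
                        seed = derive_seed(seed, paste0("pnp", vnext)))
    }
    if (is.null(pnp)) {
      failed <- c(failed, vnext)
      say("view %d not registered (%d correspondences, no supported pose)",
          vnext, length(X3))
      next
    }
    poses[[vnext]] <- pnp$pose
    registered <- c(registered, vnext)
    say("registered view %d by PnP (rms %.3f px, %d points)",
        vnext, pnp$rms_px, length(X3))
    # local refinement after each registration keeps drift from accumulating
    tmp <- Filter(Negate(is.null), lapply(tracks_raw, triangulate_track))
    if (length(tmp) >= 6L) {
      ba <- bundle_adjust(structure(list(tracks = tmp, poses = poses, K = K),
                                    class = "sparse_cloud"), max_iter = 8L)
      poses <- ba$poses
    }
  }
  if (length(failed) > 0L)
    say("%d of %d views could not be registered", length(failed), nv)
  tracks <- Filter(function(tr) length(tr$views) >= min_track_views, tracks)
  # depth sanity: shallow-angle triangulations can land implausibly far away
  zs <- vapply(tracks, function(tr)
    (poses[[tr$views[1]]]$R %*% tr$X + poses[[tr$views[1]]]$t)[3], numeric(1))
  zmed <- stats::median(zs[zs > 0])
  keep <- zs > 0.1 * zmed & zs < 8 * zmed
  if (any(!keep)) say("depth sanity: dropped %d far/near outlier tracks",
                      sum(!keep))
  tracks <- tracks[keep]
  if (length(tracks) == 0L) stop("no tracks survived triangulation")
  cloud <- structure(list(tracks = tracks, poses = poses, K = K,
                          registered = sort(registered),
                          mean_reproj_px = NA_real_, log = logmsg),
                     class = "sparse_cloud")
  cloud$mean_reproj_px <- mean_reproj_error(cloud)
  say("pre-BA mean reprojection error %.4f px over %d tracks",
      cloud$mean_reproj_px, length(tracks))
  cloud <- bundle_adjust(cloud)
  # drop gross-outlier observations (bad matches) and adjust once more
  kept <- list()
  for (tr in cloud$tracks) {
    res <- vapply(seq_along(tr$views), function(k)
      sqrt(sum((project_point_jacobian(tr$X, cloud$poses[[tr$views[k]]],
                                       K)$uv - tr$uv[k, ])^2)), numeric(1))
    keep <- res < 3
    if (sum(keep) >= min_track_views && sum(keep) >= 2L)
      kept[[length(kept) + 1L]] <- list(X = tr$X, views = tr$views[keep],
                                        uv = tr$uv[keep, , drop = FALSE])
  }
  if (length(kept) >= 6L && length(kept) < length(cloud$tracks)) {
    say("outlier trim: %d -> %d tracks", length(cloud$tracks), length(kept))
    cloud$tracks <- kept
    cloud <- bundle_adjust(cloud)
  }
  cloud$mean_reproj_px <- mean_reproj_error(cloud)
  # gauge: monocular scale is arbitrary, so normalise the reconstruction to
  # unit total trajectory length (makes runs and branches comparable)
  centers <- t(vapply(cloud$registered, function(v)
    pose_center(cloud$poses[[v]]), numeric(3)))
  traj <- sum(sqrt(rowSums(diff(centers)^2)))
  if (is.finite(traj) && traj > 1e-12) {
    s <- 1 / traj
    for (ti in seq_along(cloud$tracks))
      cloud$tracks[[ti]]$X <- cloud$tracks[[ti]]$X * s
    for (v in cloud$registered)
      cloud$poses[[v]] <- camera_pose(cloud$poses[[v]]$R,
                                      cloud$poses[[v]]$t * s)
  }
  cloud$log <- c(logmsg, sprintf("post-BA mean reprojection error %.4f px",
                                 cloud$mean_reproj_px))
  cloud
}

#' Align a sparse reconstruction to rendered ground truth
#'
#' Reconstructed geometry is defined up to a similarity; this helper builds
#' point correspondences (each track against the ground-truth back-projection
#' of its first observation through the rendered depth map), solves the
#' closed-form similarity, and reports pose and point errors in the
#' ground-truth frame.
#'
#' @param cloud a `sparse_cloud` from [reconstruct_sparse()]
#' @param views the rendered views ([render_views()]) the cloud was built from
#' @return list with the similarity (`s`, `R`, `t`), `rot_err_deg` per
#'   registered view, `center_rms`, `point_rms`, and `n_points` used
#' @export
align_to_ground_truth <- function(cloud, views) {
  est <- list(); gt <- list()
  for (tr in cloud$tracks) {
    v <- tr$views[1]
    uv <- tr$uv[1, ]
    dep <- views[[v]]$depth_gt[round(uv[2]) + 1L, round(uv[1]) + 1L]
    if (dep <= 0) next
    est[[length(est) + 1L]] <- tr$X
    gt[[length(gt) + 1L]] <- backproject_pixels(matrix(uv, 1), dep,
                                                views[[v]]$pose,
                                                views[[v]]$intrinsics)[1, ]
  }
  if (length(est) < 3L) stop("too few ground-truth correspondences to align")
  E <- do.call(rbind, est); Gt <- do.call(rbind, gt)
  # robust fit: gross triangulation outliers would collapse the LS scale,
  # so prefilter by spread and iterate a trimmed fit
  medE <- apply(E, 2, stats::median)
  dE <- sqrt(rowSums(sweep(E, 2, medE)^2))
  keep <- dE < 6 * stats::median(dE) + 1e-12
  for (it in 1:3) {
    al <- align_similarity(E[keep, , drop = FALSE], Gt[keep, , drop = FALSE])
    res <- sqrt(rowSums((t(al$s * al$R %*% t(E)) +
                           matrix(al$t, nrow(E), 3, byrow = TRUE) - Gt)^2))
    keep_new <- res < 3 * stats::median(res) + 1e-12
    if (sum(keep_new) < 3L || identical(keep_new, keep)) break
    keep <- keep_new
  }
  al <- align_similarity(E[keep, , drop = FALSE], Gt[keep, , drop = FALSE])
  pt_rms <- sqrt(mean(rowSums((al$Xa - Gt[keep, , drop = FALSE])^2)))
  rot <- rep(NA_real_, length(cloud$poses))
  cen <- matrix(NA_real_, length(cloud$poses), 3)
  for (v in cloud$registered) {
    rot[v] <- rotation_angle_deg(cloud$poses[[v]]$R %*% t(al$R),
                                 views[[v]]$pose$R)
    cen[v, ] <- al$s * as.numeric(al$R %*% pose_center(cloud$poses[[v]])) +
      al$t - pose_center(views[[v]]$pose)
  }
  list(s = al$s, R = al$R, t = al$t,
       rot_err_deg = rot,
       center_rms = sqrt(mean(rowSums(cen[cloud$registered, , drop = FALSE]^2))),
       point_rms = pt_rms, n_points = sum(keep))
}

# ---- tiny union-find over string keys -------------------------------------

uf_new <- function() new.env(parent = emptyenv())

uf_find <- function(uf, x) {
  p <- uf[[x]]
  if (is.null(p)) { uf[[x]] <- x; return(x) }
  if (p == x) return(x)
  r <- uf_find(uf, p)
  uf[[x]] <- r
  r
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[ra]] <- rb
  invisible(NULL)
}

uf_components <- function(uf) {
  keys <- ls(uf)
  roots <- vapply(keys, function(k) uf_find(uf, k), character(1))
  split(keys, roots)
}
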