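# Dense reconstruction: NCC plane-sweep depth maps over inverse-depth
# hypotheses, multi-view consistency fusion into an oriented point cloud, and
# PCA normal estimation.

#' Normalized cross-correlation of two equally sized patches
#'
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`; invariant to positive affine intensity maps and
#' bounded in \[-1, 1\].  If either patch is constant the score is undefined;
#' a sentinel 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param a,b numeric patches of identical size
#' @return NCC score in \[-1, 1\]
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("ncc: patch size mismatch")
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0)
    return(structure(0, degenerate = TRUE))
  s <- sum(da * db) / sqrt(va * vb)
  max(-1, min(1, s))
}

# running box sum over a w x w window (same size, zero padded)
box_sum <- function(m, w) {
  r <- (w - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  cs <- apply(m, 2, cumsum)
  up <- rbind(matrix(0, 1, W), cs)
  rows <- up[pmin(H, seq_len(H) + r) + 1L, , drop = FALSE] -
    up[pmax(0, seq_len(H) - r - 1L) + 1L, , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  left <- cbind(0, cs2)
  left[, pmin(W, seq_len(W) + r) + 1L, drop = FALSE] -
    left[, pmax(0, seq_len(W) - r - 1L) + 1L, drop = FALSE]
}

# windowed NCC map between two images (same size); counts use the same box
# so borders are handled consistently
ncc_map <- function(A, B, w, valid = NULL) {
  one <- matrix(1, nrow(A), ncol(A))
  if (!is.null(valid)) { A <- A * valid; B <- B * valid; one <- valid }
  n <- box_sum(one, w)
  n[n < 1e-9] <- NA
  mA <- box_sum(A, w) / n
  mB <- box_sum(B, w) / n
  vA <- box_sum(A * A, w) / n - mA^2
  vB <- box_sum(B * B, w) / n - mB^2
  cov <- box_sum(A * B, w) / n - mA * mB
  den <- sqrt(pmax(vA, 0) * pmax(vB, 0))
  out <- cov / den
  out[!is.finite(out)] <- NA
  pmax(-1, pmin(1, out))
}

# bilinear sampling of image at (0-based) coordinates; NA outside
bilinear_sample <- function(img, xx, yy) {
  H <- nrow(img); W <- ncol(img)
  ok <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
  out <- rep(NA_real_, length(xx))
  if (!any(ok)) return(out)
  x <- pmin(xx[ok], W - 1 - 1e-9); y <- pmin(yy[ok], H - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  out[ok] <- img[i00] * (1 - fy) * (1 - fx) +
    img[i00 + c(1, 0)] * fy * (1 - fx) +
    img[i00 + c(0, 1)] * (1 - fy) * fx +
    img[i00 + c(1, 1)] * fy * fx
  out
}

#' Plane-sweep depth map for a reference view
#'
#' Tests `n_planes` fronto-parallel depth hypotheses (uniform in inverse
#' depth), warps each neighbour view onto the reference through the plane
#' homography, scores windowed NCC averaged over neighbours, and keeps the
#' best-scoring depth per pixel.  Confidence is the best mean NCC rectified
#' to \[0, 1\]; pixels under `conf_floor` are invalidated (depth 0).
#'
#' @param ref_img reference grayscale image
#' @param ref_pose reference `camera_pose`
#' @param nb_imgs,nb_poses lists of neighbour images and poses
#' @param K 3x3 intrinsics matrix
#' @param depth_min,depth_max swept depth range (camera-frame z)
#' @param n_planes number of hypotheses
#' @param window NCC window size (odd)
#' @param conf_floor minimum confidence kept
#' @return list with `depth` (H x W, 0 = invalid), `confidence` (H x W) and
#'   `n_valid`
#' @export
depth_map_plane_sweep <- function(ref_img, ref_pose, nb_imgs, nb_poses, K,
                                  depth_min, depth_max, n_planes = 64L,
                                  window = 7L, conf_floor = 0.6) {
  stopifnot(depth_min > 0, depth_min < depth_max, length(nb_imgs) >= 1L)
  H <- nrow(ref_img); W <- ncol(ref_img)
  g <- expand.grid(v = seq_len(H) - 1L, u = seq_len(W) - 1L)
  # ray directions in the reference camera frame (z = 1)
  dray <- cbind((g$u - K[1, 3]) / K[1, 1], (g$v - K[2, 3]) / K[2, 2], 1)
  invd <- seq(1 / depth_max, 1 / depth_min, length.out = n_planes)
  dinv <- invd[2] - invd[1]
  Rr <- ref_pose$R; Cr <- pose_center(ref_pose)
  scores <- array(-Inf, dim = c(H, W, n_planes))
  for (p in seq_len(n_planes)) {
    d <- 1 / invd[p]
    Xw <- t(crossprod(Rr, t(dray * d)) + Cr)      # world points at depth d
    acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
    for (i in seq_along(nb_imgs)) {
      Xc <- t(nb_poses[[i]]$R %*% t(Xw) + nb_poses[[i]]$t)
      z <- Xc[, 3]
      uu <- K[1, 1] * Xc[, 1] / z + K[1, 3]
      vv <- K[2, 2] * Xc[, 2] / z + K[2, 3]
      uu[z <= 0] <- -1e9
      warped <- matrix(bilinear_sample(nb_imgs[[i]], uu, vv), H, W)
      valid <- !is.na(warped)
      warped[!valid] <- 0
      sc <- ncc_map(ref_img, warped, window, valid = valid * 1)
      ok <- is.finite(sc) & valid
      acc[ok] <- acc[ok] + sc[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    scores[, , p] <- ifelse(cnt > 0, acc / cnt, -Inf)
  }
  smat <- matrix(scores, H * W, n_planes)
  ibest <- max.col(smat, ties.method = "first")
  best_score <- smat[cbind(seq_len(H * W), ibest)]
  # parabolic refinement along the inverse-depth axis: quantized depth
  # shells would otherwise dominate the fused cloud's normal noise
  off <- numeric(H * W)
  interior <- ibest > 1L & ibest < n_planes
  if (any(interior)) {
    ii <- which(interior)
    s0 <- smat[cbind(ii, ibest[ii] - 1L)]
    s1 <- best_score[ii]
    s2 <- smat[cbind(ii, ibest[ii] + 1L)]
    den <- s0 - 2 * s1 + s2
    o <- ifelse(is.finite(s0) & is.finite(s2) & den < 0,
                0.5 * (s0 - s2) / den, 0)
    off[ii] <- pmax(-0.5, pmin(0.5, o))
  }
  best_depth <- matrix(1 / (invd[ibest] + off * dinv), H, W)
  conf <- matrix(pmax(0, pmin(1, (best_score + 1) / 2)), H, W)
  invalid <- !is.finite(best_score) | conf < conf_floor
  best_depth[invalid] <- 0
  conf[invalid] <- 0
  if (all(best_depth == 0))
    warning("plane sweep produced an all-invalid depth map (no overlap?)")
  list(depth = best_depth, confidence = conf, n_valid = sum(best_depth > 0))
}

#' Fuse per-view depth maps into an oriented, colored point cloud
#'
#' Back-projects every valid pixel and keeps points whose depth re-observed
#' in at least `consistency_views` other maps agrees within `tol` relative
#' error.  Colors are sampled from the reference images; normals are added
#' with [estimate_normals()].
#'
#' @param depth_maps list of H x W depth matrices (0 = invalid)
#' @param poses list of `camera_pose`
#' @param K 3x3 intrinsics matrix
#' @param images list of grayscale images for coloring (optional)
#' @param consistency_views minimum number of agreeing other views
#' @param tol relative depth agreement tolerance
#' @param stride pixel subsampling stride (1 = every pixel)
#' @param k_normals neighbourhood size for normal estimation
#' @param max_points deterministic cap on the fused cloud size
#' @return object of class `oriented_cloud`: `points` (N x 3), `normals`
#'   (N x 3 unit), `colors` (N x 3), `view_id` (length N)
#' @export
fuse_depth_maps <- function(depth_maps, poses, K, images = NULL,
                            consistency_views = 1L, tol = 0.01,
                            stride = 1L, k_normals = 12L,
                            max_points = 20000L) {
  nv <- length(depth_maps)
  stopifnot(nv >= 2L, length(poses) == nv)
  pts <- list(); cols <- list(); vids <- list(); cams <- list()
  for (v in seq_len(nv)) {
    D <- depth_maps[[v]]
    H <- nrow(D); W <- ncol(D)
    sel <- expand.grid(y = seq(1L, H, by = stride), x = seq(1L, W, by = stride))
    d <- D[cbind(sel$y, sel$x)]
    ok <- d > 0
    if (!any(ok)) next
    uv <- cbind(sel$x[ok] - 1L, sel$y[ok] - 1L)
    d <- d[ok]
    Xw <- backproject_pixels(uv, d, poses[[v]], intr_from_K(K))
    nok <- rep(0L, nrow(Xw))
    for (w in seq_len(nv)) {
      if (w == v) next
      pr <- project_points(Xw, poses[[w]], intr_from_K(K))
      Dw <- depth_maps[[w]]
      iu <- round(pr$uv[, 1]) + 1L; iv <- round(pr$uv[, 2]) + 1L
      inb <- iu >= 1L & iu <= ncol(Dw) & iv >= 1L & iv <= nrow(Dw) &
        pr$depth > 0
      dw <- rep(0, nrow(Xw))
      dw[inb] <- Dw[cbind(iv[inb], iu[inb])]
      agree <- inb & dw > 0 & abs(dw - pr$depth) <= tol * pr$depth
      nok <- nok + agree
    }
    keep <- nok >= consistency_views
    if (!any(keep)) next
    pts[[length(pts) + 1L]] <- Xw[keep, , drop = FALSE]
    vids[[length(vids) + 1L]] <- rep(v, sum(keep))
    cols[[length(cols) + 1L]] <- if (!is.null(images)) {
      gv <- images[[v]][cbind(uv[keep, 2] + 1L, uv[keep, 1] + 1L)]
      cbind(gv, gv, gv)
    } else matrix(0.5, sum(keep), 3)
  }
  if (length(pts) == 0L) {
    warning("depth-map fusion kept no points")
    return(structure(list(points = matrix(0, 0, 3),
                          normals = matrix(0, 0, 3),
                          colors = matrix(0, 0, 3), view_id = integer(0)),
                     class = "oriented_cloud"))
  }
  P <- do.call(rbind, pts)
  vid <- unlist(vids)
  colm <- do.call(rbind, cols)
  if (nrow(P) > max_points) {                 # deterministic thinning
    sel <- round(seq(1L, nrow(P), length.out = max_points))
    P <- P[sel, , drop = FALSE]
    vid <- vid[sel]
    colm <- colm[sel, , drop = FALSE]
  }
  centers <- t(vapply(poses, pose_center, numeric(3)))
  N <- estimate_normals(P, k_neighbors = k_normals,
                        viewpoints = centers[vid, , drop = FALSE])
  structure(list(points = P, normals = N, colors = colm, view_id = vid),
            class = "oriented_cloud")
}

#' Estimate unit normals by local PCA plane fits
#'
#' For each point, fits a plane to its `k_neighbors` nearest neighbours (the
#' smallest-eigenvalue eigenvector of the local covariance) and orients the
#' normal toward the observing viewpoint when given.
#'
#' @param points N x 3 matrix
#' @param k_neighbors neighbourhood size (>= 3)
#' @param viewpoints N x 3 matrix of camera centers (or a single center) used
#'   to orient normals; `NULL` leaves orientation arbitrary
#' @return N x 3 matrix of unit normals
#' @export
estimate_normals <- function(points, k_neighbors = 12L, viewpoints = NULL) {
  P <- matrix(points, ncol = 3)
  n <- nrow(P)
  stopifnot(n >= k_neighbors, k_neighbors >= 3L)
  if (!is.null(viewpoints)) {
    viewpoints <- matrix(viewpoints, ncol = 3)
    if (nrow(viewpoints) == 1L)
      viewpoints <- viewpoints[rep(1L, n), , drop = FALSE]
  }
  # block-wise kNN by exact distances (memory-bounded)
  normals <- matrix(0, n, 3)
  blk <- max(1L, floor(2e6 / n))
  sq <- rowSums(P^2)
  for (s in seq(1L, n, by = blk)) {
    e <- min(n, s + blk - 1L)
    D2 <- outer(sq[s:e], sq, "+") - 2 * P[s:e, , drop = FALSE] %*% t(P)
    for (i in seq_len(e - s + 1L)) {
      kth <- sort.int(D2[i, ], partial = k_neighbors)[k_neighbors]
      idx <- which(D2[i, ] <= kth)
      if (length(idx) > k_neighbors)
        idx <- idx[order(D2[i, idx])][seq_len(k_neighbors)]
      Q <- P[idx, , drop = FALSE]
      Qc <- sweep(Q, 2, colMeans(Q))
      C <- crossprod(Qc)
      if (sum(abs(C)) < 1e-24) { normals[s + i - 1L, ] <- c(0, 0, 1); next }
      ev <- eigen(C, symmetric = TRUE)
      nv <- ev$vectors[, 3]
      gi <- s + i - 1L
      if (!is.null(viewpoints)) {
        tocam <- viewpoints[gi, ] - P[gi, ]
        if (sum(nv * tocam) < 0) nv <- -nv
      }
      normals[gi, ] <- nv / sqrt(sum(nv^2))
    }
  }
  normals
}
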