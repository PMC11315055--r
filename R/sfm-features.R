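# Scale-space feature detection and description: Gaussian pyramid,
# difference-of-Gaussian extrema with sub-pixel refinement and edge/contrast
# filtering, orientation assignment, and 4x4x8 = 128-component gradient
# histogram descriptors matched by Euclidean distance with a mutual
# nearest-neighbour ratio test.

# separable Gaussian blur with edge-clamped, renormalised taps
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_dim <- function(n) {
    Wm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- pmin(n, pmax(1L, i + (-r:r)))
      for (mix in seq_along(js)) Wm[i, js[mix]] <- Wm[i, js[mix]] + k[mix]
    }
    Wm
  }
  blur_dim(nrow(m)) %*% m %*% t(blur_dim(ncol(m)))
}

#' Build a Gaussian scale space and its difference-of-Gaussian stack
#'
#' `L(x, y, sigma) = G(sigma) * I`, with sigma increasing geometrically by
#' `2^(1/scales_per_octave)` and a factor-2 downsample between octaves.
#'
#' @param img grayscale image matrix, intensities in \[0, 1\]
#' @param n_octaves number of octaves
#' @param scales_per_octave scale samples per octave (s); each octave holds
#'   s + 3 Gaussian levels and s + 2 DoG levels
#' @param sigma0 base smoothing of the first level, in pixels
#' @param assumed_blur blur already present in the input image
#' @param upsample_first start one octave below the input (2x bicubic
#'   upsampling of the base image), which roughly doubles the number of
#'   detectable keypoints on small images
#' @return object of class `scale_space`: per-octave Gaussian and DoG stacks
#'   with their sigmas and sampling step relative to the input
#' @export
build_scale_space <- function(img, n_octaves = 3L, scales_per_octave = 3L,
                              sigma0 = 1.6, assumed_blur = 0.5,
                              upsample_first = FALSE) {
  img <- to_gray(img)
  if (min(dim(img)) < 16L) stop("image too small for the scale space")
  s <- scales_per_octave
  step0 <- 1
  if (upsample_first) {
    img <- resize_bicubic(img, 2L * nrow(img), 2L * ncol(img))
    assumed_blur <- 2 * assumed_blur
    step0 <- 0.5
    n_octaves <- n_octaves + 1L
  }
  base <- gaussian_blur(img, sqrt(max(0, sigma0^2 - assumed_blur^2)))
  octaves <- vector("list", n_octaves)
  cur <- base
  for (o in seq_len(n_octaves)) {
    levels <- vector("list", s + 3L)
    sigmas <- sigma0 * 2^((0:(s + 2L)) / s)
    levels[[1]] <- cur
    for (i in 2:(s + 3L)) {
      dsig <- sqrt(sigmas[i]^2 - sigmas[i - 1]^2)
      levels[[i]] <- gaussian_blur(levels[[i - 1]], dsig)
    }
    dogs <- lapply(seq_len(s + 2L), function(i) levels[[i + 1]] - levels[[i]])
    octaves[[o]] <- list(gauss = levels, dog = dogs, sigmas = sigmas,
                         step = step0 * 2^(o - 1L))
    nxt <- levels[[s + 1L]]                       # sigma doubled level
    cur <- nxt[seq(1L, nrow(nxt), by = 2L), seq(1L, ncol(nxt), by = 2L)]
    if (min(dim(cur)) < 12L) { octaves <- octaves[seq_len(o)]; break }
  }
  structure(list(octaves = octaves, s = s, sigma0 = sigma0), class = "scale_space")
}

# 26-neighbour local extrema of a 3-level DoG sandwich, vectorised by shifts
local_extrema_mask <- function(d0, d1, d2, thresh) {
  H <- nrow(d1); W <- ncol(d1)
  inner <- function(m, dy, dx)
    m[(2L + dy):(H - 1L + dy), (2L + dx):(W - 1L + dx)]
  c1 <- inner(d1, 0L, 0L)
  is_max <- abs(c1) > thresh
  is_min <- is_max
  for (lev in list(d0, d1, d2)) for (dy in -1:1) for (dx in -1:1) {
    if (identical(lev, d1) && dy == 0L && dx == 0L) next
    nb <- inner(lev, dy, dx)
    is_max <- is_max & (c1 > nb)
    is_min <- is_min & (c1 < nb)
  }
  which(is_max | is_min, arr.ind = TRUE) + 1L      # back to full-image coords
}

#' Detect scale-space keypoints from the DoG stack
#'
#' Local extrema over 3 x 3 x 3 DoG neighbourhoods, refined to sub-pixel by a
#' quadratic fit, with low-contrast and edge-like responses rejected.
#'
#' @param ss a [build_scale_space()] result
#' @param contrast_thresh minimum refined |DoG| response
#' @param edge_ratio maximum principal-curvature ratio r (Hessian
#'   trace-squared over determinant test)
#' @return data frame of keypoints: `x`, `y` (0-based pixels in the input
#'   image), `sigma` (pixels), `orientation` (radians), plus octave/level
#'   bookkeeping columns
#' @export
detect_keypoints <- function(ss, contrast_thresh = 0.03, edge_ratio = 10) {
  out <- list()
  for (o in seq_along(ss$octaves)) {
    oct <- ss$octaves[[o]]
    nd <- length(oct$dog)
    H <- nrow(oct$dog[[1]]); W <- ncol(oct$dog[[1]])
    if (H < 5L || W < 5L) next
    for (li in 2:(nd - 1L)) {
      d0 <- oct$dog[[li - 1L]]; d1 <- oct$dog[[li]]; d2 <- oct$dog[[li + 1L]]
      ext <- local_extrema_mask(d0, d1, d2, 0.8 * contrast_thresh)
      if (length(ext) == 0L) next
      for (k in seq_len(nrow(ext))) {
        r0 <- ext[k, 1]; c0 <- ext[k, 2]
        ref <- refine_extremum(d0, d1, d2, r0, c0, contrast_thresh, edge_ratio)
        if (is.null(ref)) next
        sig_oct <- ss$sigma0 * 2^((li - 1L + ref$ds) / ss$s)
        kp <- list(
          x = (c0 - 1 + ref$dc) * oct$step,
          y = (r0 - 1 + ref$dr) * oct$step,
          sigma = sig_oct * oct$step,
          octave = o, level = li,
          xo = c0 - 1 + ref$dc, yo = r0 - 1 + ref$dr, sigma_oct = sig_oct)
        for (th in keypoint_orientations(oct$gauss[[li]], kp$xo, kp$yo,
                                         kp$sigma_oct)) {
          kp$orientation <- th
          out[[length(out) + 1L]] <- kp
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      orientation = numeric(0), octave = integer(0),
                      level = integer(0), xo = numeric(0), yo = numeric(0),
                      sigma_oct = numeric(0)))
  do.call(rbind, lapply(out, as.data.frame))
}

# quadratic sub-pixel refinement of one extremum; NULL if rejected
refine_extremum <- function(d0, d1, d2, r, c, contrast_thresh, edge_ratio) {
  H <- nrow(d1); W <- ncol(d1)
  dr <- dc <- ds <- 0
  for (it in 1:5) {
    if (r < 2L || r > H - 1L || c < 2L || c > W - 1L) return(NULL)
    g <- c((d1[r, c + 1] - d1[r, c - 1]) / 2,
           (d1[r + 1, c] - d1[r - 1, c]) / 2,
           (d2[r, c] - d0[r, c]) / 2)
    Hxx <- d1[r, c + 1] + d1[r, c - 1] - 2 * d1[r, c]
    Hyy <- d1[r + 1, c] + d1[r - 1, c] - 2 * d1[r, c]
    Hss <- d2[r, c] + d0[r, c] - 2 * d1[r, c]
    Hxy <- (d1[r + 1, c + 1] - d1[r + 1, c - 1] -
              d1[r - 1, c + 1] + d1[r - 1, c - 1]) / 4
    Hxs <- (d2[r, c + 1] - d2[r, c - 1] - d0[r, c + 1] + d0[r, c - 1]) / 4
    Hys <- (d2[r + 1, c] - d2[r - 1, c] - d0[r + 1, c] + d0[r - 1, c]) / 4
    Hm <- matrix(c(Hxx, Hxy, Hxs, Hxy, Hyy, Hys, Hxs, Hys, Hss), 3, 3)
    off <- tryCatch(-solve(Hm, g), error = function(e) NULL)
    if (is.null(off)) return(NULL)
    if (all(abs(off) < 0.5)) {
      val <- d1[r, c] + 0.5 * sum(g * off)
      if (abs(val) < contrast_thresh) return(NULL)
      tr <- Hxx + Hyy; det2 <- Hxx * Hyy - Hxy^2
      if (det2 <= 0 || tr^2 / det2 >= (edge_ratio + 1)^2 / edge_ratio)
        return(NULL)
      return(list(dr = off[2], dc = off[1], ds = off[3]))
    }
    r <- r + as.integer(round(off[2]))
    c <- c + as.integer(round(off[1]))
    # stay on this DoG sandwich; large scale moves are abandoned
    if (abs(off[3]) > 0.8 && it == 5L) return(NULL)
  }
  NULL
}

# dominant gradient orientations (up to 2 peaks >= 0.8 of max) in a
# Gaussian-weighted neighbourhood; x, y 0-based in octave coords
keypoint_orientations <- function(L, x, y, sigma_oct) {
  H <- nrow(L); W <- ncol(L)
  r <- max(2L, as.integer(round(4.5 * sigma_oct)))
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  ys <- max(2L, yi + 1L - r):min(H - 1L, yi + 1L + r)
  xs <- max(2L, xi + 1L - r):min(W - 1L, xi + 1L + r)
  if (length(ys) < 3L || length(xs) < 3L) return(0)
  gx <- (L[ys, xs + 1L] - L[ys, xs - 1L]) / 2
  gy <- (L[ys + 1L, xs] - L[ys - 1L, xs]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  dy <- (ys - 1L) - y; dx <- (xs - 1L) - x
  wgt <- exp(-outer(dy^2, dx^2, "+") / (2 * (1.5 * sigma_oct)^2))
  bins <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1
  hist36 <- vapply(1:36, function(b) sum((mag * wgt)[bins == b]), numeric(1))
  for (sm in 1:2)                                   # circular smoothing
    hist36 <- (hist36 + c(utils::tail(hist36, 1), utils::head(hist36, -1)) +
                 c(utils::tail(hist36, -1), utils::head(hist36, 1))) / 3
  pk <- max(hist36)
  if (pk <= 0) return(0)
  keep <- which(hist36 >= 0.8 * pk &
                  hist36 > c(utils::tail(hist36, 1), utils::head(hist36, -1)) &
                  hist36 >= c(utils::tail(hist36, -1), utils::head(hist36, 1)))
  keep <- utils::head(keep[order(-hist36[keep])], 2L)
  (keep - 0.5) / 36 * 2 * pi - pi
}

#' Compute 128-component descriptors for keypoints
#'
#' Gradient histograms over 4 x 4 spatial cells and 8 orientation bins in
#' each keypoint's scaled and rotated frame; L2-normalised, clipped at 0.2
#' and renormalised.  Keypoints whose support window leaves the image are
#' skipped (their row indices are returned in `skipped`).
#'
#' @param ss the [build_scale_space()] used for detection
#' @param kps keypoint data frame from [detect_keypoints()]
#' @return list with `desc` (n x 128 matrix), `kps` (the described rows) and
#'   `skipped` (row indices of dropped keypoints)
#' @export
compute_descriptors <- function(ss, kps) {
  n <- nrow(kps)
  # half-sample spacing: denser support halves the interpolation noise and
  # keeps descriptors stable under rotation
  grid <- expand.grid(gy = seq(-7.75, 7.75, by = 0.5),
                      gx = seq(-7.75, 7.75, by = 0.5))
  desc <- matrix(0, n, 128L)
  ok <- logical(n)
  for (i in seq_len(n)) {
    oct <- ss$octaves[[kps$octave[i]]]
    L <- oct$gauss[[kps$level[i]]]
    d <- descriptor_one(L, kps$xo[i], kps$yo[i], kps$sigma_oct[i],
                        kps$orientation[i], grid)
    if (!is.null(d)) { desc[i, ] <- d; ok[i] <- TRUE }
  }
  list(desc = desc[ok, , drop = FALSE], kps = kps[ok, , drop = FALSE],
       skipped = which(!ok))
}

descriptor_one <- function(L, x, y, sigma, theta, grid) {
  H <- nrow(L); W <- ncol(L)
  sp <- 0.75 * sigma                      # sample spacing in octave pixels
  ct <- cos(theta); st <- sin(theta)
  # rotated sample locations (0-based octave coords)
  sx <- x + sp * (ct * grid$gx - st * grid$gy)
  sy <- y + sp * (st * grid$gx + ct * grid$gy)
  # tolerate a fringe of out-of-image samples (they get zero weight);
  # reject only when the support loses more than 30% of its mass
  inb <- sx >= 2 & sx <= W - 3 & sy >= 2 & sy <= H - 3
  if (mean(inb) < 0.7) return(NULL)
  sx <- pmin(W - 3, pmax(2, sx))
  sy <- pmin(H - 3, pmax(2, sy))
  # bilinear gradient at the sample points
  bil <- function(M, yy, xx) {
    y0 <- floor(yy); x0 <- floor(xx)
    fy <- yy - y0; fx <- xx - x0
    i00 <- cbind(y0 + 1, x0 + 1)
    M[i00] * (1 - fy) * (1 - fx) + M[i00 + c(1, 0)] * fy * (1 - fx) +
      M[i00 + c(0, 1)] * (1 - fy) * fx + M[i00 + c(1, 1)] * fy * fx
  }
  gx <- (bil(L, sy, sx + 1) - bil(L, sy, sx - 1)) / 2
  gy <- (bil(L, sy + 1, sx) - bil(L, sy - 1, sx)) / 2
  # rotate gradients into the keypoint frame
  rgx <- ct * gx + st * gy
  rgy <- -st * gx + ct * gy
  mag <- sqrt(rgx^2 + rgy^2) * exp(-(grid$gx^2 + grid$gy^2) / (2 * 8^2)) * inb
  ang <- atan2(rgy, rgx)
  # trilinear soft assignment: bilinear over the 4 x 4 spatial cells and
  # linear over the 8 orientation bins
  cy <- (grid$gy + 8) / 4 - 0.5
  cx <- (grid$gx + 8) / 4 - 0.5
  y0 <- floor(cy); x0 <- floor(cx)
  fy <- cy - y0; fx <- cx - x0
  ob <- (ang + pi) / (2 * pi) * 8
  b0 <- floor(ob - 0.5)
  fb <- ob - 0.5 - b0
  d <- numeric(128L)
  for (k in seq_along(mag)) {
    if (mag[k] == 0) next
    for (dy in 0:1) for (dx in 0:1) {
      ry <- y0[k] + dy; rx <- x0[k] + dx
      if (ry < 0 || ry > 3 || rx < 0 || rx > 3) next
      wsp <- (if (dy) fy[k] else 1 - fy[k]) * (if (dx) fx[k] else 1 - fx[k])
      if (wsp == 0) next
      base <- (ry * 4 + rx) * 8
      i0 <- base + (b0[k] %% 8) + 1
      i1 <- base + ((b0[k] + 1) %% 8) + 1
      d[i0] <- d[i0] + mag[k] * wsp * (1 - fb[k])
      d[i1] <- d[i1] + mag[k] * wsp * fb[k]
    }
  }
  nv <- sqrt(sum(d^2))
  if (nv < 1e-12) return(NULL)
  d <- pmin(d / nv, 0.2)
  d / sqrt(sum(d^2))
}

#' Detect and describe features of one image
#'
#' The pyramid starts one octave below the input only for small frames
#' (min dimension under `upsample_below` px), where the extra octave is
#' needed to reach a workable keypoint count; on larger frames it would
#' mostly add poorly localised detections.
#'
#' @param img grayscale image matrix
#' @param ... passed to [build_scale_space()]
#' @param contrast_thresh,edge_ratio keypoint filtering thresholds
#' @param upsample_below size threshold for the extra upsampled octave
#' @return list with `kps` and `desc`
#' @export
extract_features <- function(img, contrast_thresh = 0.03, edge_ratio = 10,
                             upsample_below = 120L, ...) {
  img <- to_gray(img)
  args <- list(...)
  if (is.null(args$upsample_first))
    args$upsample_first <- min(dim(img)) < upsample_below
  ss <- do.call(build_scale_space, c(list(img), args))
  kps <- detect_keypoints(ss, contrast_thresh, edge_ratio)
  compute_descriptors(ss, kps)
}

#' Match descriptor sets by Euclidean distance
#'
#' Exhaustive distances `D(i, j) = sqrt(sum_k (d_ik - d_jk)^2)`, keeping
#' mutual nearest neighbours that pass the nearest / second-nearest ratio
#' test.
#'
#' @param descA,descB descriptor matrices (rows = keypoints)
#' @param ratio_threshold Lowe ratio threshold in (0, 1\]
#' @return data frame with `index_i`, `index_j`, `distance`, `ratio`
#' @export
match_descriptors <- function(descA, descB, ratio_threshold = 0.8) {
  if (nrow(descA) == 0L || nrow(descB) == 0L)
    return(data.frame(index_i = integer(0), index_j = integer(0),
                      distance = numeric(0), ratio = numeric(0)))
  d2 <- outer(rowSums(descA^2), rowSums(descB^2), "+") -
    2 * tcrossprod(descA, descB)
  D <- sqrt(matrix(pmax(0, d2), nrow(descA), nrow(descB)))
  nnB <- apply(D, 1L, which.min)
  nnA <- apply(D, 2L, which.min)
  out <- list()
  for (i in seq_len(nrow(D))) {
    j <- nnB[i]
    if (nnA[j] != i) next                  # mutual nearest neighbour
    d1 <- D[i, j]
    d2nd <- if (ncol(D) > 1L) min(D[i, -j]) else Inf
    ratio <- if (is.finite(d2nd) && d2nd > 0) d1 / d2nd else 1
    if (ratio <= ratio_threshold)
      out[[length(out) + 1L]] <- data.frame(index_i = i, index_j = j,
                                            distance = d1, ratio = ratio)
  }
  if (length(out) == 0L)
    return(data.frame(index_i = integer(0), index_j = integer(0),
                      distance = numeric(0), ratio = numeric(0)))
  do.call(rbind, out)
}
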