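# Endoscopy-like synthetic textures and their low-resolution degradations.
# The generator emulates what makes endoscopic frames hard for SR: a smooth,
# bright mucosa-like background, dark curvilinear vascular structures, radial
# vignetting from the scope optics, and sensor noise.

#' Specification of a synthetic endoscopy-like texture
#'
#' @param size_hr integer length-2 vector (H, W) of the high-resolution image;
#'   both must be divisible by 4 so that x2 and x4 scales stay integral.
#' @param n_vessels number of dark curvilinear vessel-like structures.
#' @param vessel_width_px stroke width of the vessels, in pixels.
#' @param n_spots number of soft round spots (mucosal pit / speck analogues,
#'   dark or bright) overlaid on the background.
#' @param shading_strength amplitude in \[0, 1\] of the smooth low-frequency
#'   illumination field multiplying the background.
#' @param vignette_strength amplitude in \[0, 1\] of the radial vignette.
#' @param noise_sigma standard deviation of additive Gaussian sensor noise,
#'   in intensity units.
#' @param seed integer seed; the generator is a pure function of it.
#' @return an object of class `texture_spec`
#' @export
texture_spec <- function(size_hr = c(128L, 128L), n_vessels = 10L,
                         vessel_width_px = 3, n_spots = 30L,
                         shading_strength = 0.25,
                         vignette_strength = 0.35, noise_sigma = 0.01,
                         seed = 1L) {
  size_hr <- as.integer(size_hr)
  if (length(size_hr) != 2L || any(size_hr < 8L))
    stop("size_hr must be two integers >= 8")
  if (any(size_hr %% 4L != 0L))
    stop("size_hr dimensions must be divisible by 4 (got ",
         paste(size_hr, collapse = "x"), ")")
  for (s in c(shading_strength, vignette_strength))
    if (s < 0 || s > 1) stop("strength parameters must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(size_hr = size_hr, n_vessels = as.integer(n_vessels),
                 vessel_width_px = vessel_width_px,
                 n_spots = as.integer(n_spots),
                 shading_strength = shading_strength,
                 vignette_strength = vignette_strength,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "texture_spec")
}

# smooth random field in [-1, 1]: coarse Gaussian grid upsampled bicubically
smooth_field <- function(H, W, coarse = 6L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  f <- resize_bicubic(g, H, W)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate an endoscopy-like high-resolution texture
#'
#' Produces a bright smooth background modulated by a low-frequency shading
#' field and a radial vignette, overlaid with `n_vessels` dark curvilinear
#' structures (random smooth walks stamped with a round brush), plus additive
#' Gaussian noise.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [texture_spec()]
#' @return (H, W) matrix of intensities in \[0, 1\]
#' @export
generate_texture <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  H <- spec$size_hr[1]; W <- spec$size_hr[2]
  with_seed(spec$seed, {
    img <- matrix(0.78, H, W)
    if (spec$shading_strength > 0)
      img <- img * (1 + 0.5 * spec$shading_strength * smooth_field(H, W))
    # fine mucosa-like mottling so the surface is textured everywhere
    if (spec$shading_strength > 0)
      img <- img * (1 + 0.15 * spec$shading_strength * smooth_field(H, W, coarse = 24L))
    if (spec$n_vessels > 0) {
      brush <- vessel_brush(spec$vessel_width_px)
      for (v in seq_len(spec$n_vessels)) {
        path <- vessel_path(H, W)
        depthv <- stats::runif(1, 0.35, 0.55)
        img <- stamp_path(img, path, brush, depthv)
      }
    }
    if (spec$n_spots > 0) {
      scale_px <- min(H, W) / 128
      for (s in seq_len(spec$n_spots)) {
        cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
        r <- stats::runif(1, 2, 7) * scale_px
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.1, 0.3)
        k <- as.integer(ceiling(r))
        ys <- max(1, floor(cy) - k):min(H, floor(cy) + k)
        xs <- max(1, floor(cx) - k):min(W, floor(cx) + k)
        d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
        w <- exp(-d2 / (2 * (r / 2)^2))
        img[ys, xs] <- img[ys, xs] * (1 + amp * w)
      }
    }
    if (spec$vignette_strength > 0) {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      r2 <- outer(((seq_len(H) - cy) / (H / 2))^2,
                  ((seq_len(W) - cx) / (W / 2))^2, "+")
      img <- img * (1 - spec$vignette_strength * pmin(1, r2 / 2))
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    clip01(img)
  })
}

# smooth random-walk polyline across the image (sub-pixel coordinates)
vessel_path <- function(H, W) {
  n <- 6L + sample.int(5L, 1L)
  # random smooth control polygon, then dense resampling through a spline
  side <- sample.int(4L, 1L)
  p0 <- switch(side,
               c(1, stats::runif(1, 1, W)),
               c(H, stats::runif(1, 1, W)),
               c(stats::runif(1, 1, H), 1),
               c(stats::runif(1, 1, H), W))
  ang <- stats::runif(1, 0, 2 * pi)
  step <- 0.22 * min(H, W)
  pts <- matrix(0, n, 2)
  pts[1, ] <- p0
  for (i in 2:n) {
    ang <- ang + stats::rnorm(1, 0, 0.7)
    pts[i, ] <- pts[i - 1, ] + step * c(sin(ang), cos(ang))
  }
  tt <- seq_len(n)
  td <- seq(1, n, length.out = max(40L, as.integer(2.5 * step * n / 3)))
  cbind(stats::spline(tt, pts[, 1], xout = td)$y,
        stats::spline(tt, pts[, 2], xout = td)$y)
}

vessel_brush <- function(width_px) {
  r <- max(1, width_px / 2)
  k <- as.integer(ceiling(r))
  d <- outer((-k:k)^2, (-k:k)^2, "+")
  # soft-edged round brush: 1 in the core, cosine falloff over half a pixel
  w <- matrix(clip01(r + 0.5 - sqrt(d)), nrow(d), ncol(d))
  list(mask = w, k = k)
}

stamp_path <- function(img, path, brush, depthv) {
  H <- nrow(img); W <- ncol(img); k <- brush$k
  dark <- matrix(0, H, W)
  for (i in seq_len(nrow(path))) {
    y <- round(path[i, 1]); x <- round(path[i, 2])
    if (y < 1 - k || y > H + k || x < 1 - k || x > W + k) next
    ys <- max(1, y - k):min(H, y + k)
    xs <- max(1, x - k):min(W, x + k)
    my <- ys - (y - k) + 1L; mx <- xs - (x - k) + 1L
    dark[ys, xs] <- pmax(dark[ys, xs], brush$mask[my, mx])
  }
  img * (1 - depthv * dark)
}

# ---- bicubic resampling ----------------------------------------------------

# Catmull-Rom cubic kernel (a = -0.5)
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# row-weight matrix mapping n_in samples to n_out samples; when downscaling
# the kernel is widened by the scale factor (anti-alias prefilter)
bicubic_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  support <- if (scale > 1) 2 * scale else 2
  Wm <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    # pixel centers at integer coordinates, 0-based
    src <- (i - 1 + 0.5) * scale - 0.5
    lo <- floor(src - support) ; hi <- ceiling(src + support)
    js <- lo:hi
    x <- (src - js)
    w <- if (scale > 1) cubic_kernel(x / scale) else cubic_kernel(x)
    jc <- pmin(n_in - 1, pmax(0, js))          # replicate borders
    for (m in seq_along(js)) Wm[i, jc[m] + 1] <- Wm[i, jc[m] + 1] + w[m]
    Wm[i, ] <- Wm[i, ] / sum(Wm[i, ])
  }
  Wm
}

#' Bicubic (Catmull-Rom) resampling with anti-alias prefilter on downscale
#'
#' @param img (H, W) or (H, W, C) array
#' @param out_h,out_w output size in pixels
#' @return resampled array of the requested size, same channel count
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  d <- dim(img)
  Wr <- bicubic_weights(d[1], out_h)
  Wc <- bicubic_weights(d[2], out_w)
  one <- function(m) Wr %*% m %*% t(Wc)
  if (length(d) == 2L) return(one(img))
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- one(img[, , c])
  out
}

#' Degrade a high-resolution image to low resolution
#'
#' Anti-aliased bicubic downsampling by an integer scale factor, the standard
#' degradation model for paired SR training data.
#'
#' @param hr (H, W) or (H, W, C) image with intensities in \[0, 1\]
#' @param scale integer downscale factor, 2 or 4
#' @return image of size (H/scale, W/scale), clipped to \[0, 1\]
#' @export
degrade <- function(hr, scale) {
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4")
  d <- dim(hr)
  if (d[1] %% scale != 0L || d[2] %% scale != 0L)
    stop("image size ", d[1], "x", d[2], " not divisible by scale ", scale)
  out <- resize_bicubic(hr, d[1] %/% scale, d[2] %/% scale)
  clip01(out)
}

#' Bicubic upscaling (no anti-alias), the comparison baseline for SR
#' @param lr low-resolution image
#' @param scale integer upscale factor
#' @return image of size (H*scale, W*scale), clipped to \[0, 1\]
#' @export
upscale_bicubic <- function(lr, scale) {
  d <- dim(lr)
  clip01(resize_bicubic(lr, d[1] * scale, d[2] * scale))
}

#' Build a paired LR/HR super-resolution dataset
#'
#' Generates `n` textures from per-item seeds derived from `seed`, degrades
#' each by `scale`, and emits a deterministic train/validation split.
#'
#' @param n number of image pairs
#' @param spec a [texture_spec()]; its `seed` field is overridden per item
#' @param scale integer downscale factor, 2 or 4
#' @param seed integer master seed
#' @param val_fraction fraction of items held out for validation
#' @return list with `pairs` (each `list(lr, hr, scale)`), `train_idx`,
#'   `val_idx`
#' @export
make_sr_dataset <- function(n, spec, scale = 2L, seed = 1L, val_fraction = 0.2) {
  stopifnot(n >= 1)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- derive_seed(seed, paste0("sr_item_", i))
    hr <- generate_texture(sp)
    pairs[[i]] <- list(lr = degrade(hr, scale), hr = hr, scale = scale)
  }
  n_val <- max(1L, as.integer(round(n * val_fraction)))
  if (n == 1L) n_val <- 0L
  val_idx <- if (n_val > 0) seq(n, n - n_val + 1L) else integer(0)
  list(pairs = pairs, train_idx = setdiff(seq_len(n), val_idx),
       val_idx = sort(val_idx))
}
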