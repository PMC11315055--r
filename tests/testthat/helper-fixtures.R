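# Shared fixtures and independent oracles used across the suite.

# small camera for geometry tests
test_intrinsics <- function(H = 96L, W = 128L, f = 110) {
  camera_intrinsics(fx = f, fy = f, cx = (W - 1) / 2, cy = (H - 1) / 2,
                    height = H, width = W)
}

# the richly textured tube scene used for SfM/MVS recovery checks
tube_scene_views <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    intr <- camera_intrinsics(fx = 150, fy = 150, cx = 95.5, cy = 71.5,
                              height = 144L, width = 192L)
    tex <- texture_spec(size_hr = c(768L, 768L), n_vessels = 60L,
                        vessel_width_px = 8, n_spots = 2200L,
                        noise_sigma = 0, seed = 3L)
    sc <- scene_spec("tube_interior", texture = tex, n_views = 5L, seed = 2L)
    cache <<- render_views(sc, intr)
    cache
  }
})

# independent row-wise softmax (scalar loops)
softmax_rows_oracle <- function(M) {
  t(apply(M, 1, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }))
}

# flood-fill count of 4-connected components of a logical mask
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nc <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nc <- nc + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nc
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nc
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  nc
}

# direct 2-d "same" convolution with zero padding (scalar loops)
conv2d_loop_oracle <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  n <- nrow(k); r <- (n - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      ii <- i + a - 1L - r; jj <- j + b - 1L - r
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj] * k[a, b]
    }
    out[i, j] <- s
  }
  out
}

# random square rotation for geometry fixtures
random_pose <- function(seed, tmax = 0.5) {
  set.seed(seed)
  camera_pose(endosr:::aa_to_rot(stats::rnorm(3, 0, 0.2)),
              stats::runif(3, -tmax, tmax))
}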