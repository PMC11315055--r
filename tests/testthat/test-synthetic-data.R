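# Texture generation, bicubic degradation and the multi-view renderer.

test_that("texture generation is deterministic and respects its contract", {
  sp <- texture_spec(size_hr = c(128L, 128L), n_vessels = 12L, seed = 1L)
  t1 <- generate_texture(sp)
  t2 <- generate_texture(sp)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))
  expect_equal(dim(t1), c(128L, 128L))

  # degenerate spec: no structure at all -> constant image
  flat <- generate_texture(texture_spec(n_vessels = 0L, n_spots = 0L,
                                        noise_sigma = 0,
                                        shading_strength = 0,
                                        vignette_strength = 0))
  expect_equal(max(flat) - min(flat), 0)

  expect_error(texture_spec(size_hr = c(130L, 128L)), "divisible by 4")
  expect_error(texture_spec(shading_strength = 1.5), "\\[0, 1\\]")
})

test_that("vessel count shows up as dark connected components", {
  sp <- texture_spec(size_hr = c(128L, 128L), n_vessels = 12L, n_spots = 0L,
                     noise_sigma = 0, seed = 7L)
  img <- generate_texture(sp)
  thr <- stats::quantile(img, 0.10)
  n <- flood_fill_components(img < thr)
  # vessels may cross, merging components; most must stay separate
  expect_gte(n, 8L)
})

test_that("bicubic degradation has the right shape, DC and kernel values", {
  expect_equal(dim(degrade(matrix(0.5, 640, 480), 2L)), c(320L, 240L))
  expect_equal(dim(degrade(matrix(0.5, 64, 64), 4L)), c(16L, 16L))
  expect_error(degrade(matrix(0, 63, 64), 2L), "not divisible")
  expect_error(degrade(matrix(0, 64, 64), 3L), "scale")

  # low-pass preserves a constant exactly
  lr <- degrade(matrix(0.37, 64, 48), 2L)
  expect_lt(max(abs(lr - 0.37)), 1e-12)

  # checkerboard: compare against a scalar-loop evaluation of the same
  # anti-aliased Catmull-Rom kernel (independent implementation)
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  got <- endosr::resize_bicubic(cb, 4L, 4L)
  kern <- function(x) {
    a <- -0.5; x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
    else 0
  }
  resample_1d_oracle <- function(v, n_out) {
    n_in <- length(v)
    s <- n_in / n_out
    out <- numeric(n_out)
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * s - 0.5
      js <- floor(src - 2 * s):ceiling(src + 2 * s)
      w <- vapply(js, function(j) kern((src - j) / s), numeric(1))
      jc <- pmin(n_in - 1, pmax(0, js))
      out[i] <- sum(w * v[jc + 1]) / sum(w)
    }
    out
  }
  ref <- t(apply(apply(cb, 2, resample_1d_oracle, n_out = 4L), 1,
                 resample_1d_oracle, n_out = 4L))
  expect_lt(max(abs(got - ref)), 1e-12)
})

test_that("SR dataset pairs are consistent, deterministic and splittable", {
  sp <- texture_spec(size_hr = c(64L, 64L))
  ds <- make_sr_dataset(10L, sp, scale = 2L, seed = 11L)
  expect_length(ds$pairs, 10L)
  for (p in ds$pairs) {
    expect_equal(dim(p$hr), 2L * dim(p$lr))
    expect_identical(p$lr, degrade(p$hr, 2L))
  }
  expect_length(intersect(ds$train_idx, ds$val_idx), 0L)
  expect_setequal(c(ds$train_idx, ds$val_idx), 1:10)

  ds2 <- make_sr_dataset(10L, sp, scale = 2L, seed = 11L)
  expect_identical(ds, ds2)

  # bicubic upscaling gives a finite, positive PSNR baseline
  p <- ds$pairs[[1]]
  base <- psnr(upscale_bicubic(p$lr, 2L), p$hr)
  expect_true(is.finite(base) && base > 0)
})

test_that("rendered views have exact geometry and photo-consistency", {
  vs <- tube_scene_views()
  v1 <- vs[[1]]
  intr <- v1$intrinsics

  # exact back-projection/projection round trip on every surface pixel
  H <- intr$height; W <- intr$width
  g <- expand.grid(v = seq_len(H) - 1L, u = seq_len(W) - 1L)
  d <- as.numeric(v1$depth_gt)
  ok <- d > 0
  Xw <- backproject_pixels(cbind(g$u[ok], g$v[ok]), d[ok], v1$pose, intr)
  pr <- project_points(Xw, v1$pose, intr)
  expect_lt(max(abs(pr$uv - cbind(g$u[ok], g$v[ok]))), 1e-6)
  expect_lt(max(abs(pr$depth - d[ok])), 1e-9)

  # stored pose equals the requested look-at pose for view 1
  sc <- scene_spec("tube_interior", n_views = 5L, seed = 2L)
  wp <- sc$trajectory[[1]]
  expect_equal(v1$pose$R %*% wp$center + v1$pose$t, matrix(0, 3, 1),
               tolerance = 1e-9)

  # >= 95% of co-visible pixels agree within 0.05 intensity
  for (j in c(2L, 4L)) {
    pc <- photo_consistency(vs[[1]], vs[[j]], tol = 0.05)
    expect_gte(pc, 0.95)
  }
})

test_that("a fronto-parallel plane renders constant ground-truth depth", {
  intr <- test_intrinsics(60L, 80L, f = 70)
  sc <- scene_spec("textured_plane",
                   trajectory = list(
                     list(center = c(0, 0, 0), target = c(0, 0, 2)),
                     list(center = c(0.1, 0, 0), target = c(0.1, 0, 2))))
  vp <- render_views(sc, intr)
  expect_equal(max(abs(vp[[1]]$depth_gt - 2)), 0)
  # camera behind the plane sees nothing and is rejected
  bad <- scene_spec("textured_plane",
                    trajectory = list(
                      list(center = c(0, 0, 5), target = c(0, 0, 6)),
                      list(center = c(0.1, 0, 5), target = c(0, 0, 6))))
  expect_error(render_views(bad, intr), "outside or behind")
})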