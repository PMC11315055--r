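# OSA attention, partitions, LCB, DAFM, DEAF, OSAG and the full forward pass.

test_that("osa_attention matches a scalar-arithmetic oracle and its limits", {
  # 2 tokens x 2 channels, identity projections: full hand computation
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  proj <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2), d_k = 2)
  r <- osa_attention(X, proj, act = "gelu")
  As_ref <- softmax_rows_oracle((X %*% t(X)) / sqrt(2))
  Ac_ref <- softmax_rows_oracle((t(X) %*% X) / sqrt(2))
  pre <- As_ref %*% X + t(Ac_ref %*% t(X))
  Y_ref <- pre * stats::pnorm(pre)
  expect_lt(max(abs(r$Y - Y_ref)), 1e-10)
  expect_lt(max(abs(r$A_s - As_ref)), 1e-10)
  expect_lt(max(abs(r$A_c - Ac_ref)), 1e-10)

  # single token: spatial attention is exactly [[1]]
  r1 <- osa_attention(matrix(rnorm(3), 1, 3),
                      list(Wq = diag(3), Wk = diag(3), Wv = diag(3)))
  expect_identical(dim(r1$A_s), c(1L, 1L))
  expect_equal(as.numeric(r1$A_s), 1)

  # zero query/key weights: uniform attention, spatial branch = column means
  set.seed(4)
  X4 <- matrix(rnorm(8), 4, 2)
  r2 <- osa_attention(X4, list(Wq = matrix(0, 2, 2), Wk = matrix(0, 2, 2),
                               Wv = diag(2)))
  expect_lt(max(abs(r2$A_s - 0.25)), 1e-12)

  expect_error(osa_attention(matrix(c(1, NA), 1, 2),
                             list(Wq = diag(2), Wk = diag(2), Wv = diag(2))),
               "finite")
  expect_error(osa_attention(X, list(Wq = diag(3), Wk = diag(2),
                                     Wv = diag(2))), "projection")
})

test_that("attention rows always sum to 1 on randomized batched inputs", {
  set.seed(11)
  for (rep in 1:5) {
    B <- sample(1:4, 1); N <- sample(2:9, 1); C <- sample(2:6, 1)
    X <- array(rnorm(B * N * C), c(B, N, C))
    proj <- list(Wq = matrix(rnorm(C * C), C), Wk = matrix(rnorm(C * C), C),
                 Wv = matrix(rnorm(C * C), C))
    for (mode in c("additive", "sequential")) {
      r <- osa_attention(X, proj, mode = mode)
      expect_lt(max(abs(apply(r$A_s, c(1, 2), sum) - 1)), 1e-5)
      expect_lt(max(abs(apply(r$A_c, c(1, 2), sum) - 1)), 1e-5)
      expect_true(all(r$A_s >= 0 & r$A_s <= 1))
      expect_true(all(r$A_c >= 0 & r$A_c <= 1))
      expect_equal(dim(r$Y), dim(X))
    }
  }
})

test_that("window partition follows the printed shape algebra and inverts", {
  X <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  bl <- window_partition(X, 4L)
  expect_equal(dim(bl), c(4L, 16L, 3L))          # (HW/P^2, P^2, C)
  expect_identical(window_merge(bl, 8L, 8L, 4L), X)

  # index oracle: token n of window b maps to an independently derived pixel
  for (b in 1:4) for (n in 1:16) {
    wi <- (b - 1) %/% 2; wj <- (b - 1) %% 2
    pi <- (n - 1) %/% 4; pj <- (n - 1) %% 4
    expect_identical(bl[b, n, 2], X[wi * 4 + pi + 1, wj * 4 + pj + 1, 2])
  }
  expect_error(window_partition(X, 0L), "positive")
  expect_error(window_partition(X, 3L), "divisible")
})

test_that("grid partition strides by (H/G, W/G) and inverts", {
  X <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  gb <- grid_partition(X, 2L)
  expect_equal(dim(gb), c(16L, 4L, 3L))          # HW/G^2 blocks of G^2 tokens
  expect_identical(grid_merge(gb, 8L, 8L, 2L), X)
  # token (gi, gj) of block (a, b) = pixel (gi*H/G + a, gj*W/G + b)
  for (b in 1:16) for (n in 1:4) {
    a <- (b - 1) %/% 4; bb <- (b - 1) %% 4
    gi <- (n - 1) %/% 2; gj <- (n - 1) %% 2
    expect_identical(gb[b, n, 1], X[gi * 4 + a + 1, gj * 4 + bb + 1, 1])
  }
  expect_error(grid_partition(X, -1L), "positive")
})

test_that("LCB reduces to the residual with zero weights and keeps shape", {
  C <- 4L; e <- 8L; r <- max(4L, e %/% 4L)
  zero_params <- list(expand_w = array(0, c(1, 1, C, e)),
                      expand_b = numeric(e),
                      dw_w = array(0, c(3, 3, e)), dw_b = numeric(e),
                      se_w1 = matrix(0, r, e), se_b1 = numeric(r),
                      se_w2 = matrix(0, e, r), se_b2 = numeric(e),
                      proj_w = array(0, c(1, 1, e, C)), proj_b = numeric(C))
  X <- array(rnorm(6 * 5 * C), c(6, 5, C))
  expect_equal(lcb_forward(X, zero_params), X)

  m <- sr_model(sr_config(channels = 8L, n_groups = 1L), seed = 2L)
  gp <- endosr:::group_params(endosr:::model_param_arrays(m), 1L)
  lp <- gp[startsWith(names(gp), "lcb_")]
  names(lp) <- substring(names(lp), 5L)
  X8 <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  expect_equal(dim(lcb_forward(X8, lp)), dim(X8))
})

test_that("depthwise convolution reproduces the kernel stencil on an impulse", {
  k <- matrix(c(0.5, -1, 2, 0.25, 3, -0.5, 1, 0, -2), 3, 3)
  X <- array(0, c(7, 7, 1))
  X[4, 4, 1] <- 1
  out <- ag_data(endosr:::ag_dwconv2d(endosr:::ag_input(X),
                                      endosr:::ag_input(array(k, c(3, 3, 1))),
                                      endosr:::ag_input(0)))
  expect_equal(out[, , 1], conv2d_loop_oracle(X[, , 1], k))
})

test_that("DAFM fusion weights normalize and match a hand computation", {
  set.seed(9)
  X <- matrix(rnorm(6), 3, 2)
  at <- osa_attention(X, list(Wq = diag(2), Wk = diag(2), Wv = diag(2),
                              d_k = 2))
  pars <- list(Wf1 = matrix(rnorm(4), 2, 2), bf1 = rnorm(2),
               Wf2 = matrix(rnorm(4), 2, 2), bf2 = rnorm(2), beta = 0)
  got <- dafm_forward(X, at$A_s, at$A_c, NULL, pars)
  expect_equal(sum(got$W), 1, tolerance = 1e-6)
  expect_true(all(got$W >= 0))

  # scalar-loop oracle of the pooled two-layer predictor and the gate
  pooled <- colMeans(X)
  z <- pmax(0, pars$Wf1 %*% pooled + pars$bf1)
  wv <- as.numeric(pars$Wf2 %*% z + pars$bf2)
  wv <- exp(wv - max(wv)); wv <- wv / sum(wv)
  gate <- pmax(0, pmax(0, wv[1] * (at$A_s %*% X)) +
                 pmax(0, wv[2] * (X %*% t(at$A_c))))
  ref <- 1 / (1 + exp(-(X * gate)))
  expect_lt(max(abs(got$out - ref)), 1e-10)
  expect_lt(max(abs(got$W - wv)), 1e-10)

  # beta is inert at t = 0: prev = NULL equals prev = 0 with beta > 0
  pars2 <- pars; pars2$beta <- 0.3
  a <- dafm_forward(X, at$A_s, at$A_c, NULL, pars)
  b <- dafm_forward(X, at$A_s, at$A_c, matrix(0, 3, 2), pars2)
  expect_equal(a$out, b$out)
  expect_error(dafm_forward(X, at$A_s, at$A_c, matrix(0, 2, 2), pars),
               "prev shape")
})

test_that("DEAF is exact identity at zero kernel and matches direct conv", {
  C <- 3L
  X <- array(rnorm(6 * 6 * C), c(6, 6, C))
  expect_identical(deaf_forward(X, list(w = array(0, c(3, 3, C)),
                                        b = numeric(C))), X)
  expect_error(deaf_forward(X, list(w = array(0, c(4, 4, C)),
                                    b = numeric(C))), "odd")

  # constant image, zero-sum Laplacian kernel: zero response in the interior
  lap <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
  Xc <- array(0.6, c(8, 8, 1))
  out <- deaf_forward(Xc, list(w = array(lap, c(3, 3, 1)), b = 0))
  expect_lt(max(abs(out[2:7, 2:7, 1] - 0.6)), 1e-12)

  # vertical step edge: response equals the loop-coded convolution
  step <- array(rep(c(0, 0, 0, 1, 1, 1), each = 6), c(6, 6, 1))
  out2 <- deaf_forward(step, list(w = array(lap, c(3, 3, 1)), b = 0))
  ref <- step[, , 1] + conv2d_loop_oracle(step[, , 1], lap)
  expect_equal(out2[, , 1], ref)
})

test_that("OSAG preserves shape and chains like repeated application", {
  cfg <- sr_config(channels = 8L, n_groups = 2L, window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 5L)
  pa <- endosr:::model_param_arrays(m)
  g1 <- endosr:::group_params(pa, 1L)
  g2 <- endosr:::group_params(pa, 2L)
  X <- array(rnorm(16 * 16 * 8, sd = 0.3), c(16, 16, 8))
  y1 <- osag_forward(X, cfg, g1)
  expect_equal(dim(y1), dim(X))
  # chaining two groups = composing the per-group maps
  y12 <- osag_forward(y1, cfg, g2)
  expect_equal(osag_forward(osag_forward(X, cfg, g1), cfg, g2), y12)
})

test_that("network forward obeys the exact scale contract and determinism", {
  cfg <- sr_config(scale = 2L, channels = 8L, n_groups = 1L,
                   window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 1L)
  lr <- generate_texture(texture_spec(size_hr = c(32L, 32L), seed = 5L))
  hr <- network_forward(lr, m)
  expect_equal(dim(hr), c(64L, 64L))
  expect_true(all(is.finite(hr)))
  expect_identical(network_forward(lr, m), hr)

  # reflect-pad path: sizes not divisible by the partition granularity
  odd <- lr[1:30, 1:27]
  expect_equal(dim(network_forward(odd, m)), c(60L, 54L))

  cfg4 <- sr_config(scale = 4L, channels = 8L, n_groups = 1L,
                    window = 4L, grid = 4L)
  m4 <- sr_model(cfg4, seed = 1L)
  expect_equal(dim(network_forward(lr, m4)), c(128L, 128L))
  expect_error(sr_config(scale = 3L), "scale")
})

test_that("DEAF at zero equals removing the stage from the full network", {
  cfg <- sr_config(scale = 2L, channels = 8L, n_groups = 1L,
                   window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 3L)
  lr <- matrix(runif(32 * 32), 32, 32)
  base <- network_forward(lr, m)
  m$params$deaf_w$data[] <- 0
  m$params$deaf_b$data[] <- 0
  no_deaf <- network_forward(lr, m)
  # with a zero edge kernel the stage is an exact identity on features
  expect_false(identical(base, no_deaf))   # the original kernel did something
  m2 <- sr_model(cfg, seed = 3L)
  m2$params$deaf_w$data[] <- 0
  m2$params$deaf_b$data[] <- 0
  expect_identical(network_forward(lr, m2), no_deaf)
})

test_that("checkpoints round-trip the model exactly", {
  cfg <- sr_config(scale = 2L, channels = 8L, n_groups = 1L,
                   window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 7L)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$config, m$config)
  lr <- matrix(runif(16 * 16), 16, 16)
  expect_equal(network_forward(lr, m2), network_forward(lr, m),
               tolerance = 1e-12)
})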