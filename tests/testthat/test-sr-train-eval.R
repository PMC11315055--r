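# PSNR/SSIM metrics, the training loop and the evaluation report.

test_that("psnr matches closed forms and a scalar-loop oracle", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(psnr(a, a), Inf)                       # identical -> sentinel
  b <- matrix(0.4, 8, 8)
  expect_equal(psnr(b, b + 0.1), 20)                  # MSE 0.01 -> 20 dB
  set.seed(2)
  x <- matrix(runif(100), 10, 10)
  y <- matrix(runif(100), 10, 10)
  mse <- 0
  for (i in 1:100) mse <- mse + (x[i] - y[i])^2
  expect_equal(psnr(x, y), 10 * log10(1 / (mse / 100)))
  expect_equal(psnr(x, y), psnr(y, x))
  expect_error(psnr(x, matrix(0, 9, 10)), "shape")
})

test_that("ssim satisfies its fixed points and closed forms", {
  set.seed(3)
  a <- matrix(runif(20 * 24), 20, 24)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, a + 0), ssim(a + 0, a))
  # inverted image: structure anti-correlates
  expect_lt(ssim(a, 1 - a), 0.5)
  # two uniform images: only the luminance term remains
  u1 <- matrix(0.3, 16, 16); u2 <- matrix(0.7, 16, 16)
  C1 <- 0.01^2
  expect_equal(ssim(u1, u2), (2 * 0.3 * 0.7 + C1) / (0.3^2 + 0.7^2 + C1),
               tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("training is deterministic, seed-faithful and inert at lr -> 0", {
  cfg <- sr_config(scale = 2L, channels = 8L, n_groups = 1L,
                   window = 4L, grid = 4L)
  ds <- make_sr_dataset(3L, texture_spec(size_hr = c(32L, 32L)),
                        scale = 2L, seed = 5L)
  m1 <- sr_model(cfg, seed = 1L)
  r1 <- sr_train(m1, ds, train_config(epochs = 2L, batch_size = 2L, seed = 9L))
  m2 <- sr_model(cfg, seed = 1L)
  r2 <- sr_train(m2, ds, train_config(epochs = 2L, batch_size = 2L, seed = 9L))
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_length(r1$loss_trace, 2L)

  # zero learning rate leaves every weight bit-identical
  m3 <- sr_model(cfg, seed = 1L)
  w_before <- lapply(endosr:::model_param_arrays(m3), identity)
  sr_train(m3, ds, train_config(epochs = 1L, batch_size = 3L,
                                learning_rate = 0, seed = 9L))
  expect_identical(endosr:::model_param_arrays(m3), w_before)
})

test_that("a tiny model overfits a single image", {
  cfg <- sr_config(scale = 2L, channels = 32L, n_groups = 1L,
                   window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 2L)
  hr <- generate_texture(texture_spec(size_hr = c(32L, 32L), seed = 8L))
  ds <- list(pairs = list(list(lr = degrade(hr, 2L), hr = hr, scale = 2L)),
             train_idx = 1L)
  r <- sr_train(m, ds, train_config(epochs = 200L, batch_size = 1L,
                                    learning_rate = 2e-3, lr_decay = 0.6,
                                    decay_every = 50L, seed = 3L))
  expect_lt(r$loss_trace[200], 0.1 * r$loss_trace[1])
})

test_that("evaluation reports per-image and mean metrics for both branches", {
  cfg <- sr_config(scale = 2L, channels = 8L, n_groups = 1L,
                   window = 4L, grid = 4L)
  m <- sr_model(cfg, seed = 1L)
  ds <- make_sr_dataset(4L, texture_spec(size_hr = c(32L, 32L)),
                        scale = 2L, seed = 6L)
  rep <- sr_evaluate(m, list(pairs = ds$pairs, val_idx = 1:4))
  expect_length(rep$psnr_db, 4L)
  expect_length(rep$baseline_ssim, 4L)
  expect_equal(rep$mean_psnr_db, mean(rep$psnr_db))
  expect_equal(rep$mean_baseline_psnr_db, mean(rep$baseline_psnr_db))
  expect_true(all(rep$ssim <= 1))
  # scale mismatch between model and data is rejected
  ds4 <- make_sr_dataset(1L, texture_spec(size_hr = c(32L, 32L)),
                         scale = 4L, seed = 6L)
  expect_error(sr_evaluate(m, list(pairs = ds4$pairs, val_idx = 1L)),
               "does not match")
})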