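# Training and evaluation: L1/L2 optimisation with Adam over the autograd
# tape, and PSNR/SSIM against references plus a bicubic baseline.

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX = 1`; identical images return `Inf`.
#'
#' @param a,b images of identical shape, intensities in \[0, 1\]
#' @return PSNR in decibels
#' @export
psnr <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("psnr: shape mismatch")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable "valid" filtering of a matrix with a 1-d kernel
filter_valid <- function(m, k) {
  n <- length(k)
  H <- nrow(m); W <- ncol(m)
  Kr <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) Kr[i, i:(i + n - 1)] <- k
  Kc <- matrix(0, W - n + 1, W)
  for (i in seq_len(W - n + 1)) Kc[i, i:(i + n - 1)] <- k
  Kr %*% m %*% t(Kc)
}

#' Structural similarity index between two images
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5) with the
#' standard stabilisers k1 = 0.01, k2 = 0.03 and dynamic range 1.  RGB inputs
#' are converted to luminance first.
#'
#' @param a,b images of identical shape, intensities in \[0, 1\]
#' @param window,sigma Gaussian window size and width
#' @return SSIM in \[-1, 1\]
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  a <- to_gray(a); b <- to_gray(b)
  if (nrow(a) < window || ncol(a) < window)
    stop("image smaller than the SSIM window")
  k <- gaussian_kernel_1d(window, sigma)
  C1 <- (0.01)^2; C2 <- (0.03)^2
  mu1 <- filter_valid(a, k); mu2 <- filter_valid(b, k)
  s11 <- filter_valid(a * a, k) - mu1^2
  s22 <- filter_valid(b * b, k) - mu2^2
  s12 <- filter_valid(a * b, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set
#' @param batch_size images per optimisation step
#' @param patch_size HR patch size in pixels (must be divisible by
#'   `scale * lcm(window, grid)` of the model); `NULL` trains on full images
#' @param learning_rate Adam step size
#' @param lr_decay multiplicative decay applied every `decay_every` epochs
#' @param decay_every epochs between decays
#' @param loss `"L1"` or `"L2"`
#' @param seed integer seed controlling shuffling and patch sampling
#' @return object of class `train_config`
#' @export
train_config <- function(epochs = 10L, batch_size = 2L, patch_size = NULL,
                         learning_rate = 2e-3, lr_decay = 0.6,
                         decay_every = 8L, loss = c("L1", "L2"), seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patch_size = patch_size, learning_rate = learning_rate,
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 loss = match.arg(loss), seed = as.integer(seed)),
            class = "train_config")
}

as_hwc <- function(img) {
  if (length(dim(img)) == 2L) array(img, dim = c(dim(img), 1L)) else img
}

#' Train the SR network on paired LR/HR data
#'
#' Adam on the configured loss, deterministic for a fixed seed.  Aborts with
#' a diagnostic if the loss becomes non-finite.
#'
#' @param model an [sr_model()] (updated in place and also returned)
#' @param dataset result of [make_sr_dataset()] or a list with `pairs` and
#'   `train_idx`
#' @param config a [train_config()]
#' @return list with `model` and `loss_trace` (mean training loss per epoch)
#' @export
sr_train <- function(model, dataset, config = train_config()) {
  pairs <- dataset$pairs[dataset$train_idx %||% seq_along(dataset$pairs)]
  if (length(pairs) == 0L) stop("empty training set")
  params <- model$params
  opt <- adam_init(params, lr = config$learning_rate)
  lossfn <- if (config$loss == "L1") ag_l1_loss else ag_l2_loss
  scale <- model$config$scale
  ps <- config$patch_size
  trace <- numeric(config$epochs)
  with_seed(config$seed, {
    lr_now <- config$learning_rate
    for (ep in seq_len(config$epochs)) {
      if (ep > 1L && (ep - 1L) %% config$decay_every == 0L)
        lr_now <- lr_now * config$lr_decay
      ord <- sample.int(length(pairs))
      ep_loss <- 0; nstep <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        ag_tape_start()
        zero_grads(params)
        total <- NULL
        for (i in idx) {
          lrim <- as_hwc(pairs[[i]]$lr)
          hrim <- as_hwc(pairs[[i]]$hr)
          if (!is.null(ps)) {
            hp <- ps; lp <- ps %/% scale
            oy <- sample.int(dim(lrim)[1] - lp + 1L, 1L) - 1L
            ox <- sample.int(dim(lrim)[2] - lp + 1L, 1L) - 1L
            lrim <- lrim[oy + seq_len(lp), ox + seq_len(lp), , drop = FALSE]
            hrim <- hrim[scale * oy + seq_len(hp), scale * ox + seq_len(hp), ,
                         drop = FALSE]
          }
          pred <- network_forward_ag(ag_input(lrim), model)
          li <- lossfn(pred, hrim)
          total <- if (is.null(total)) li else ag_add(total, li)
        }
        total <- ag_scale(total, 1 / length(idx))
        if (!is.finite(ag_data(total)))
          stop("training aborted: non-finite loss at epoch ", ep)
        ag_backward(total)
        opt <- adam_step(opt, params, lr = lr_now)
        ag_tape_clear()
        ep_loss <- ep_loss + ag_data(total); nstep <- nstep + 1L
      }
      trace[ep] <- ep_loss / nstep
    }
  })
  list(model = model, loss_trace = trace)
}

#' Evaluate a model and the bicubic baseline on paired data
#'
#' Computes per-image and mean PSNR/SSIM of the network output and of plain
#' bicubic upscaling against the HR references.  Metrics are computed on the
#' luminance channel with a border crop of `scale` pixels by default.
#'
#' @param model an [sr_model()]
#' @param dataset dataset list with `pairs`; evaluation uses `idx`
#' @param idx indices of the pairs to evaluate (default: `val_idx` if
#'   present, else all)
#' @param border crop this many pixels from every side before scoring
#'   (default: the scale factor; set 0 to disable)
#' @return object of class `eval_report`: per-image vectors and means for
#'   model and baseline
#' @export
sr_evaluate <- function(model, dataset, idx = NULL, border = NULL) {
  idx <- idx %||% dataset$val_idx %||% seq_along(dataset$pairs)
  if (length(idx) == 0L) idx <- seq_along(dataset$pairs)
  scale <- model$config$scale
  border <- border %||% scale
  crop <- function(img) {
    if (border == 0) return(img)
    d <- dim(img)
    img[(border + 1):(d[1] - border), (border + 1):(d[2] - border)]
  }
  n <- length(idx)
  mp <- ms <- bp <- bs <- numeric(n)
  for (k in seq_len(n)) {
    pr <- dataset$pairs[[idx[k]]]
    if (pr$scale != scale)
      stop("dataset scale ", pr$scale, " does not match model scale ", scale)
    hr <- crop(to_gray(pr$hr))
    pred <- crop(to_gray(network_forward(pr$lr, model, clip = TRUE)))
    base <- crop(to_gray(upscale_bicubic(pr$lr, scale)))
    mp[k] <- psnr(pred, hr); ms[k] <- ssim(pred, hr)
    bp[k] <- psnr(base, hr); bs[k] <- ssim(base, hr)
  }
  structure(list(psnr_db = mp, ssim = ms,
                 baseline_psnr_db = bp, baseline_ssim = bs,
                 mean_psnr_db = mean(mp), mean_ssim = mean(ms),
                 mean_baseline_psnr_db = mean(bp),
                 mean_baseline_ssim = mean(bs),
                 n = n, scale = scale, border = border),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("SR evaluation on %d image(s), x%d (border crop %d px)\n",
              x$n, x$scale, x$border))
  cat(sprintf("  model    : PSNR %7.4f dB  SSIM %.4f\n",
              x$mean_psnr_db, x$mean_ssim))
  cat(sprintf("  bicubic  : PSNR %7.4f dB  SSIM %.4f\n",
              x$mean_baseline_psnr_db, x$mean_baseline_ssim))
  cat(sprintf("  gain     : %+.4f dB PSNR  %+.4f SSIM\n",
              x$mean_psnr_db - x$mean_baseline_psnr_db,
              x$mean_ssim - x$mean_baseline_ssim))
  invisible(x)
}
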