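# Finite-difference validation of the reverse-mode engine the network
# trains on.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

grad_check <- function(build, xdim, seed) {
  set.seed(seed)
  x0 <- array(rnorm(prod(xdim)), dim = xdim)
  ws <- NULL
  endosr:::ag_tape_start()
  xn <- endosr:::ag_param(x0)
  out <- build(xn)
  ws <- array(rnorm(length(out$data)),
              dim = dim(out$data) %||% length(out$data))
  loss <- endosr:::ag_node(sum(out$data * ws), list(out),
                           function(g) list(endosr:::keep_dim(
                             as.numeric(g) * ws, out$data)))
  endosr:::ag_backward(loss)
  got <- xn$grad
  endosr:::ag_tape_clear()
  f <- function(xd) sum(endosr:::ag_data(
    endosr:::ag_no_grad(build(endosr:::ag_input(xd)))) * ws)
  max(abs(num_grad(f, x0) - got))
}

test_that("gradients of every network building block match finite differences", {
  ag <- asNamespace("endosr")
  W <- matrix(rnorm(9), 3, 3)
  expect_lt(grad_check(function(x) ag$ag_matmul(x, ag$ag_input(W)),
                       c(4, 3), 1), 1e-6)
  expect_lt(grad_check(function(x) ag$ag_softmax(x), c(2, 3, 4), 2), 1e-6)
  expect_lt(grad_check(function(x) ag$ag_gelu(x), c(3, 3), 3), 1e-6)
  expect_lt(grad_check(function(x) ag$ag_sigmoid(x), c(3, 3), 4), 1e-6)
  kw <- array(rnorm(3 * 3 * 2 * 4) * 0.3, c(3, 3, 2, 4))
  kb <- rnorm(4)
  expect_lt(grad_check(function(x)
    ag$ag_conv2d(x, ag$ag_input(kw), ag$ag_input(kb)), c(5, 6, 2), 5),
    1e-5)
  dk <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  db <- rnorm(2)
  expect_lt(grad_check(function(x)
    ag$ag_dwconv2d(x, ag$ag_input(dk), ag$ag_input(db)), c(5, 4, 2), 6),
    1e-5)
  expect_lt(grad_check(function(x) ag$ag_gap(x), c(4, 5, 3), 7), 1e-6)
  sv <- rnorm(3)
  expect_lt(grad_check(function(x) ag$ag_channel_scale(x, ag$ag_input(sv)),
                       c(4, 5, 3), 8), 1e-6)
  expect_lt(grad_check(function(x) ag$ag_pixel_shuffle(x, 2L),
                       c(3, 4, 8), 9), 1e-6)
  B3 <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_lt(grad_check(function(x) ag$ag_bmm(x, ag$ag_input(B3)),
                       c(2, 4, 3), 10), 1e-6)
  B4 <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  expect_lt(grad_check(function(x) ag$ag_bmm(x, ag$ag_input(B4), tb = TRUE),
                       c(2, 4, 3), 11), 1e-6)
})

test_that("the whole-network loss gradient matches finite differences", {
  # end-to-end check through every block on a miniature model
  cfg <- sr_config(scale = 2L, channels = 4L, n_groups = 1L,
                   window = 2L, grid = 2L, dafm_hidden = 2L)
  m <- sr_model(cfg, seed = 2L)
  set.seed(3)
  lr <- array(runif(4 * 4), c(4, 4, 1))
  hr <- array(runif(8 * 8), c(8, 8, 1))
  loss_at <- function() {
    out <- endosr:::ag_no_grad(
      endosr:::network_forward_ag(endosr:::ag_input(lr), m))
    mean(abs(endosr:::ag_data(out) - hr))
  }
  endosr:::ag_tape_start()
  pred <- endosr:::network_forward_ag(endosr:::ag_input(lr), m)
  loss <- endosr:::ag_l1_loss(pred, hr)
  endosr:::ag_backward(loss)
  endosr:::ag_tape_clear()
  eps <- 1e-6
  for (pn in c("head_w", "g1_meso_Wq", "g1_lcb_dw_w", "deaf_w", "rec_up_w")) {
    p <- m$params[[pn]]
    worst <- 0
    idx <- round(seq(1, length(p$data), length.out = 5))
    for (i in idx) {
      orig <- p$data[i]
      p$data[i] <- orig + eps; up <- loss_at()
      p$data[i] <- orig - eps; dn <- loss_at()
      p$data[i] <- orig
      worst <- max(worst, abs((up - dn) / (2 * eps) - p$grad[i]))
    }
    expect_lt(worst, 1e-4)
  }
})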