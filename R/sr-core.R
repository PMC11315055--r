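# The SR network: omnidirectional self-attention (OSA) computed in both the
# spatial and channel dimensions, multi-scale aggregation groups (OSAG)
# combining a local convolution block (LCB), windowed meso attention and
# dilated-grid global attention, a dual-stream adaptive focus mechanism (DAFM)
# that predicts normalized fusion weights for the two attention streams, and a
# dynamic edge adjustment stage (DEAF) that adds a learned edge response back
# to the deep features before reconstruction.
#
# Every block is written over autograd nodes (R/autograd.R) so a single code
# path serves both inference and training; the exported wrappers accept plain
# arrays and return plain arrays.

#' Network hyperparameter configuration
#'
#' @param scale integer upscale factor (2 or 4)
#' @param channels feature channels C
#' @param n_groups number of OSAG blocks
#' @param window meso window size P (pixels)
#' @param grid global grid count G (dilated sampling)
#' @param lcb_expansion inverted-bottleneck expansion ratio
#' @param dafm_hidden hidden width of the DAFM weight predictor (default C/4)
#' @param beta DAFM temporal feedback coefficient in \[0, 1)
#' @param d_k attention scaling dimension (default C)
#' @param act_attn activation after the attention combination
#' @param act_dafm activation closing the DAFM gate
#' @param attn_mode `"additive"` (spatial + channel as printed) or
#'   `"sequential"` (spatial then channel)
#' @param deaf_k odd edge-detection kernel size
#' @param in_channels image channels (1 = grayscale)
#' @return object of class `sr_config`
#' @export
sr_config <- function(scale = 2L, channels = 32L, n_groups = 2L,
                      window = 4L, grid = 4L, lcb_expansion = 2L,
                      dafm_hidden = NULL, beta = 0.1, d_k = NULL,
                      act_attn = "gelu", act_dafm = "sigmoid",
                      attn_mode = c("additive", "sequential"),
                      deaf_k = 3L, in_channels = 1L) {
  if (!scale %in% c(2L, 4L)) stop("scale must be 2 or 4")
  if (window < 2L || grid < 2L) stop("window and grid must be >= 2")
  if (deaf_k %% 2L == 0L) stop("deaf_k must be odd")
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  structure(list(scale = as.integer(scale), channels = as.integer(channels),
                 n_groups = as.integer(n_groups), window = as.integer(window),
                 grid = as.integer(grid),
                 lcb_expansion = as.integer(lcb_expansion),
                 dafm_hidden = as.integer(dafm_hidden %||%
                                            max(4L, channels %/% 4L)),
                 beta = beta, d_k = as.integer(d_k %||% channels),
                 act_attn = act_attn, act_dafm = act_dafm,
                 attn_mode = match.arg(attn_mode),
                 deaf_k = as.integer(deaf_k),
                 in_channels = as.integer(in_channels)),
            class = "sr_config")
}

# least common multiple of window and grid (padding granularity)
lcm2 <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  a %/% g(a, b) * b
}

# ---- parameter initialisation ---------------------------------------------

rnd <- function(..., sd = 0.05) array(stats::rnorm(prod(c(...)), 0, sd), dim = c(...))

# 3x3 identity-passthrough kernel: channel j of the output reads channel
# `from` of the input through a centred delta, others start small
delta_conv <- function(k, cin, cout, from = 1L, gain = 1, sd = 0.02) {
  w <- rnd(k, k, cin, cout, sd = sd)
  c0 <- (k + 1L) %/% 2L
  for (j in seq_len(cout)) {
    src <- if (from > 0L) from else j
    if (src <= cin) w[c0, c0, src, j] <- w[c0, c0, src, j] + gain
  }
  w
}

init_osa_params <- function(C, sd = 0.05) {
  list(Wq = rnd(C, C, sd = sd), Wk = rnd(C, C, sd = sd),
       Wv = diag(C) + rnd(C, C, sd = sd))
}

init_dafm_params <- function(C, hidden, beta) {
  list(Wf1 = rnd(hidden, C), bf1 = numeric(hidden),
       Wf2 = rnd(2L, hidden), bf2 = numeric(2L), beta = beta)
}

init_lcb_params <- function(C, expansion) {
  e <- C * expansion
  r <- max(4L, e %/% 4L)
  list(expand_w = delta_conv(1L, C, e, from = 0L),
       expand_b = numeric(e),
       dw_w = rnd(3L, 3L, e, sd = 0.05), dw_b = numeric(e),
       se_w1 = rnd(r, e), se_b1 = numeric(r),
       se_w2 = rnd(e, r), se_b2 = rep(2, e),     # gate starts mostly open
       proj_w = delta_conv(1L, e, C, from = 0L),
       proj_b = numeric(C))
}

# sub-pixel convolution initialised as the separable Catmull-Rom
# interpolator reading the luminance channel: the untrained reconstruction
# tail is then already a bicubic upsampler and training refines detail
bicubic_up_init <- function(C, in_channels, scale) {
  w <- rnd(3L, 3L, C, in_channels * scale^2, sd = 0.01)
  taps <- function(o) {
    v <- cubic_kernel(o - (-1:1))
    v / sum(v)
  }
  for (ic in seq_len(in_channels)) for (dy in 0:(scale - 1)) {
    for (dx in 0:(scale - 1)) {
      wy <- taps((dy + 0.5) / scale - 0.5)
      wx <- taps((dx + 0.5) / scale - 0.5)
      ch <- (ic - 1L) * scale^2 + dy * scale + dx + 1L
      w[, , ic, ch] <- w[, , ic, ch] + outer(wy, wx)
    }
  }
  w
}

init_se_params <- function(C) {
  r <- max(4L, C %/% 4L)
  list(w1 = rnd(r, C), b1 = numeric(r), w2 = rnd(C, r), b2 = rep(2, C))
}

#' Create an SR model with freshly initialised weights
#'
#' Convolutions on the main path are initialised as identity-passthrough
#' deltas plus small noise and the sub-pixel reconstruction tail starts as a
#' bicubic interpolator of the luminance channel, so the untrained network is
#' already a competent upsampler and training spends its capacity on
#' recovering detail beyond interpolation.
#'
#' @param config an [sr_config()]
#' @param seed integer seed for weight initialisation
#' @return object of class `sr_model`: `list(config, params)` where `params`
#'   is a named list of `ag_param` nodes
#' @export
sr_model <- function(config = sr_config(), seed = 1L) {
  C <- config$channels
  with_seed(seed, {
    p <- list()
    p$head_w <- delta_conv(3L, config$in_channels, C, from = 1L)
    p$head_b <- numeric(C)
    for (g in seq_len(config$n_groups)) {
      pre <- paste0("g", g, "_")
      lcb <- init_lcb_params(C, config$lcb_expansion)
      for (nm in names(lcb)) p[[paste0(pre, "lcb_", nm)]] <- lcb[[nm]]
      for (stage in c("meso", "glob")) {
        osa <- init_osa_params(C)
        for (nm in names(osa)) p[[paste0(pre, stage, "_", nm)]] <- osa[[nm]]
        dafm <- init_dafm_params(C, config$dafm_hidden, config$beta)
        for (nm in setdiff(names(dafm), "beta"))
          p[[paste0(pre, stage, "_dafm_", nm)]] <- dafm[[nm]]
      }
      # groups start as small perturbations: the deep path then refines the
      # shallow-feature upsampling instead of overwhelming it at step 0
      p[[paste0(pre, "tail_w")]] <- delta_conv(3L, C, C, from = 0L,
                                               gain = 0.1, sd = 0.01)
      p[[paste0(pre, "tail_b")]] <- numeric(C)
      se <- init_se_params(C)
      for (nm in names(se)) p[[paste0(pre, "se_", nm)]] <- se[[nm]]
    }
    # DEAF: Laplacian-like depthwise kernel (center 4, cross neighbours -1)
    # scaled by a small gain so the untrained edge response is gentle
    lap <- matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3)
    p$deaf_w <- array(rep(lap * 0.05, C), dim = c(3L, 3L, C))
    p$deaf_b <- numeric(C)
    r2 <- config$scale^2
    p$rec_a_w <- delta_conv(3L, C, C, from = 0L)
    p$rec_a_b <- numeric(C)
    p$rec_up_w <- bicubic_up_init(C, config$in_channels, config$scale)
    p$rec_up_b <- numeric(config$in_channels * r2)
    p$rec_out_w <- delta_conv(3L, config$in_channels, config$in_channels,
                              from = 0L)
    p$rec_out_b <- numeric(config$in_channels)
    structure(list(config = config,
                   params = lapply(p, ag_param)),
              class = "sr_model")
  })
}

model_param_arrays <- function(model) lapply(model$params, function(p) p$data)

# ---- partitions ------------------------------------------------------------

win_index <- function(H, W, C, P) {
  B <- (H %/% P) * (W %/% P); N <- P * P
  g <- expand.grid(b = 0:(B - 1), n = 0:(N - 1), c = 0:(C - 1))
  wpr <- W %/% P
  wi <- g$b %/% wpr; wj <- g$b %% wpr
  pi <- g$n %/% P;  pj <- g$n %% P
  h <- wi * P + pi; w <- wj * P + pj
  list(idx = (h + 1L) + w * H + g$c * H * W, dim = c(B, N, C))
}

grid_index <- function(H, W, C, G) {
  # token (gi, gj) of block (a, b) sits at pixel (gi*H/G + a, gj*W/G + b):
  # the G x G grid positions are the interacting tokens (stride H/G, W/G),
  # batched over the HW/G^2 in-cell offsets, so the attention cost stays
  # linear in image area
  hpg <- H %/% G; wpg <- W %/% G
  B <- hpg * wpg; N <- G * G
  g <- expand.grid(b = 0:(B - 1), n = 0:(N - 1), c = 0:(C - 1))
  a <- g$b %/% wpg; bb <- g$b %% wpg
  gi <- g$n %/% G; gj <- g$n %% G
  h <- gi * hpg + a; w <- gj * wpg + bb
  list(idx = (h + 1L) + w * H + g$c * H * W, dim = c(B, N, C))
}

partition_cache <- new.env(parent = emptyenv())

cached_index <- function(kind, H, W, C, S) {
  key <- paste(kind, H, W, C, S, sep = "_")
  got <- partition_cache[[key]]
  if (!is.null(got)) return(got)
  v <- if (kind == "win") win_index(H, W, C, S) else grid_index(H, W, C, S)
  inv <- integer(length(v$idx))
  inv[v$idx] <- seq_along(v$idx)
  v$inv <- inv
  partition_cache[[key]] <- v
  v
}

#' Partition a feature map into non-overlapping P x P windows
#'
#' @param X (H, W, C) array (or autograd node); H and W divisible by P
#' @param P window size in pixels
#' @return (HW/P^2, P^2, C) array of window token blocks
#' @export
window_partition <- function(X, P) {
  if (P <= 0) stop("P must be positive")
  d <- dim(ag_data(X))
  if (d[1] %% P != 0L || d[2] %% P != 0L)
    stop("H and W must be divisible by P")
  v <- cached_index("win", d[1], d[2], d[3], P)
  out <- ag_gather(as_ag(X), v$idx, v$dim)
  if (ag_is_node(X)) out else out$data
}

#' Inverse of [window_partition()]
#' @param blocks (HW/P^2, P^2, C) array; @param H,W,P original geometry
#' @param H,W original spatial size
#' @param P window size
#' @return (H, W, C) array
#' @export
window_merge <- function(blocks, H, W, P) {
  d <- dim(ag_data(blocks))
  v <- cached_index("win", H, W, d[3], P)
  out <- ag_gather(as_ag(blocks), v$inv, c(H, W, d[3]))
  if (ag_is_node(blocks)) out else out$data
}

#' Partition a feature map into strided G x G grid token blocks
#'
#' Token (i, j) of block (a, b) is the pixel at (i*H/G + a, j*W/G + b): each
#' block gathers the G^2 grid positions strided by (H/G, W/G), so attention
#' within a block spans the whole map sparsely (global receptive field) while
#' its cost stays linear in image area.  There are HW/G^2 blocks of G^2
#' tokens.
#'
#' @param X (H, W, C) array (or autograd node); H and W divisible by G
#' @param G grid count
#' @return (HW/G^2, G^2, C) array of grid token blocks
#' @export
grid_partition <- function(X, G) {
  if (G <= 0) stop("G must be positive")
  d <- dim(ag_data(X))
  if (d[1] %% G != 0L || d[2] %% G != 0L)
    stop("H and W must be divisible by G")
  v <- cached_index("grid", d[1], d[2], d[3], G)
  out <- ag_gather(as_ag(X), v$idx, v$dim)
  if (ag_is_node(X)) out else out$data
}

#' Inverse of [grid_partition()]
#' @param blocks (G^2, HW/G^2, C) array
#' @param H,W original spatial size
#' @param G grid count
#' @return (H, W, C) array
#' @export
grid_merge <- function(blocks, H, W, G) {
  d <- dim(ag_data(blocks))
  v <- cached_index("grid", H, W, d[3], G)
  out <- ag_gather(as_ag(blocks), v$inv, c(H, W, d[3]))
  if (ag_is_node(blocks)) out else out$data
}

# ---- OSA attention ---------------------------------------------------------

# node-level core; X (B, N, C) node, proj nodes; returns list of nodes
osa_attention_ag <- function(X, Wq, Wk, Wv, d_k, act = "gelu",
                             mode = "additive") {
  d <- dim(ag_data(X))
  B <- d[1]; N <- d[2]; C <- d[3]
  flat <- ag_reshape(X, c(B * N, C))
  # (B*N, C) x (C, C), reshaped back: per-token shared projections
  Q <- ag_reshape(ag_matmul(flat, Wq), c(B, N, C))
  K <- ag_reshape(ag_matmul(flat, Wk), c(B, N, C))
  V <- ag_reshape(ag_matmul(flat, Wv), c(B, N, C))
  sc <- 1 / sqrt(d_k)
  As <- ag_softmax(ag_scale(ag_bmm(Q, K, tb = TRUE), sc))   # (B, N, N)
  Ac <- ag_softmax(ag_scale(ag_bmm(K, Q, ta = TRUE), sc))   # (B, C, C)
  spat <- ag_bmm(As, V)                                     # (B, N, C)
  if (mode == "additive") {
    chan <- ag_bmm(V, Ac, tb = TRUE)                        # tokens x Ac^T
    Y <- ag_activation(act)(ag_add(spat, chan))
  } else {
    Y <- ag_activation(act)(ag_bmm(spat, Ac, tb = TRUE))    # sequential
  }
  list(Y = Y, A_s = As, A_c = Ac, V = V)
}

#' Omnidirectional self-attention over a token block
#'
#' Projects tokens to Q, K, V, forms the row-stochastic spatial attention
#' `softmax(Q K' / sqrt(d_k))` and channel attention `softmax(K' Q / sqrt(d_k))`,
#' and combines the value matrix through both, closing with a nonlinearity.
#'
#' @param X token matrix (N, C) or batch of blocks (B, N, C)
#' @param proj list with `Wq`, `Wk`, `Wv` (C x C) and optionally `d_k`
#' @param act activation name (default `"gelu"`)
#' @param mode `"additive"` or `"sequential"` combination
#' @return list with `Y` (same shape as `X`), `A_s` (spatial attention,
#'   rows sum to 1) and `A_c` (channel attention, rows sum to 1); for matrix
#'   input the maps are matrices, for batched input arrays with leading B
#' @export
osa_attention <- function(X, proj, act = "gelu", mode = "additive") {
  if (!all(is.finite(ag_data(X)))) stop("non-finite values in attention input")
  single <- length(dim(X)) == 2L
  Xa <- if (single) array(X, dim = c(1L, nrow(X), ncol(X))) else X
  C <- dim(Xa)[3]
  for (nm in c("Wq", "Wk", "Wv"))
    if (!all(dim(proj[[nm]]) == c(C, C)))
      stop("projection ", nm, " must be ", C, "x", C)
  d_k <- proj$d_k %||% C
  out <- ag_no_grad(osa_attention_ag(ag_input(Xa), ag_input(proj$Wq),
                                     ag_input(proj$Wk), ag_input(proj$Wv),
                                     d_k, act, mode))
  Y <- ag_data(out$Y); As <- ag_data(out$A_s); Ac <- ag_data(out$A_c)
  if (single) {
    Y <- array(Y, dim = dim(Y)[2:3])
    As <- array(As, dim = dim(As)[2:3])
    Ac <- array(Ac, dim = dim(Ac)[2:3])
  }
  list(Y = Y, A_s = As, A_c = Ac)
}

# ---- DAFM ------------------------------------------------------------------

# node-level: X (B, N, C); As (B, N, N); Ac (B, C, C); prev NULL or node
dafm_forward_ag <- function(X, As, Ac, prev, Wf1, bf1, Wf2, bf2, beta,
                            act = "sigmoid") {
  d <- dim(ag_data(X))
  B <- d[1]; N <- d[2]; C <- d[3]
  # global average pool over blocks and tokens -> C vector
  pooled <- ag_gap(ag_reshape(X, c(B * N, 1L, C)))
  Wvec <- ag_softmax(ag_reshape(
    ag_dense(ag_relu(ag_dense(pooled, Wf1, bf1)), Wf2, bf2), c(1L, 2L)))
  W0 <- as.numeric(ag_data(Wvec))[1]
  W1 <- as.numeric(ag_data(Wvec))[2]
  spat <- ag_relu(ag_bmm(As, X))                 # A_s applied to X
  chan <- ag_relu(ag_bmm(X, Ac, tb = TRUE))      # A_c along channels
  # scale each stream by its predicted weight (kept on the tape via mul)
  w0n <- ag_reshape(Wvec, 2L)
  gate <- ag_relu(ag_add(ag_stream_scale(spat, w0n, 1L),
                         ag_stream_scale(chan, w0n, 2L)))
  core <- ag_mul(X, gate)
  if (!is.null(prev)) core <- ag_add(core, ag_scale(as_ag(prev), beta))
  list(out = ag_activation(act)(core), W = c(W0, W1))
}

# multiply a whole tensor by component `k` of a length-2 weight node
ag_stream_scale <- function(X, wvec, k) {
  X <- as_ag(X); wvec <- as_ag(wvec)
  wk <- as.numeric(wvec$data)[k]
  ag_node(X$data * wk, list(X, wvec), function(g) {
    gw <- numeric(2L)
    gw[k] <- sum(g * X$data)
    list(g * wk, gw)
  })
}

#' Dual-stream adaptive focus: fuse spatial and channel attention
#'
#' Predicts two softmax-normalised fusion weights from globally pooled
#' features through a two-layer network, gates the input with the rectified
#' weighted combination of the two attention streams, adds the optional
#' temporal feedback `beta * prev`, and closes with an activation.
#'
#' @param X token matrix (N, C) or batch (B, N, C)
#' @param A_s spatial attention (N, N) or (B, N, N)
#' @param A_c channel attention (C, C) or (B, C, C)
#' @param prev previous output `X'_(t-1)` or `NULL` at t = 0
#' @param params list with `Wf1`, `bf1`, `Wf2`, `bf2`, `beta`
#' @param act closing activation (default `"sigmoid"`)
#' @return list with `out` (same shape as `X`) and `W` (the two fusion
#'   weights, summing to 1)
#' @export
dafm_forward <- function(X, A_s, A_c, prev = NULL, params, act = "sigmoid") {
  single <- length(dim(X)) == 2L
  lift <- function(m) array(m, dim = c(1L, dim(m)))
  Xa <- if (single) lift(X) else X
  Asa <- if (single) lift(A_s) else A_s
  Aca <- if (single) lift(A_c) else A_c
  prev_a <- if (!is.null(prev)) { if (single) lift(prev) else prev }
  if (!is.null(prev_a) && !all(dim(prev_a) == dim(Xa)))
    stop("prev shape must match X")
  res <- ag_no_grad(dafm_forward_ag(
    ag_input(Xa), ag_input(Asa), ag_input(Aca),
    if (!is.null(prev_a)) ag_input(prev_a),
    ag_input(params$Wf1), ag_input(params$bf1),
    ag_input(params$Wf2), ag_input(params$bf2),
    params$beta %||% 0, act))
  out <- ag_data(res$out)
  if (single) out <- array(out, dim = dim(out)[2:3])
  list(out = out, W = res$W)
}

# ---- LCB -------------------------------------------------------------------

se_gate_ag <- function(X, w1, b1, w2, b2) {
  s <- ag_sigmoid(ag_dense(ag_relu(ag_dense(ag_gap(X), w1, b1)), w2, b2))
  ag_channel_scale(X, s)
}

lcb_forward_ag <- function(X, p) {
  h <- ag_conv2d(X, p$expand_w, p$expand_b)
  h <- ag_gelu(h)
  h <- ag_dwconv2d(h, p$dw_w, p$dw_b)
  h <- se_gate_ag(h, p$se_w1, p$se_b1, p$se_w2, p$se_b2)
  h <- ag_conv2d(h, p$proj_w, p$proj_b)
  ag_add(h, X)
}

#' Local convolution block: inverted bottleneck with squeeze-excitation
#'
#' 1x1 expansion, depthwise 3x3 convolution, squeeze-excitation channel
#' gating, 1x1 projection, plus the residual connection.
#'
#' @param X (H, W, C) feature map
#' @param params named list of the block weights (see [sr_model()] layout:
#'   `expand_w/b`, `dw_w/b`, `se_w1/b1/w2/b2`, `proj_w/b`)
#' @return (H, W, C) array
#' @export
lcb_forward <- function(X, params) {
  out <- ag_no_grad(lcb_forward_ag(ag_input(X),
                                   lapply(params, ag_input)))
  ag_data(out)
}

# ---- DEAF ------------------------------------------------------------------

deaf_forward_ag <- function(X, w, b) {
  E <- ag_dwconv2d(X, w, b)
  ag_add(X, E)
}

#' Dynamic edge adjustment: add a learned edge response to the features
#'
#' `E = W_e * X + b_e` as a channel-wise (depthwise) convolution with an odd
#' k x k kernel, then `X' = X + E`.
#'
#' @param X (H, W, C) feature map
#' @param params list with `w` (k, k, C) and `b` (length C)
#' @return (H, W, C) array
#' @export
deaf_forward <- function(X, params) {
  k <- dim(params$w)[1]
  if (k %% 2L == 0L) stop("edge kernel size must be odd")
  out <- ag_no_grad(deaf_forward_ag(ag_input(X), ag_input(params$w),
                                    ag_input(params$b)))
  ag_data(out)
}

# ---- OSAG ------------------------------------------------------------------

group_params <- function(params, g) {
  pre <- paste0("g", g, "_")
  nm <- names(params)[startsWith(names(params), pre)]
  out <- params[nm]
  names(out) <- substring(nm, nchar(pre) + 1L)
  out
}

attention_stage_ag <- function(X, H, W, part, merge, S, p, stage, config) {
  blocks <- part(X, S)
  osa <- osa_attention_ag(blocks, p[[paste0(stage, "_Wq")]],
                          p[[paste0(stage, "_Wk")]],
                          p[[paste0(stage, "_Wv")]],
                          config$d_k, config$act_attn, config$attn_mode)
  fused <- dafm_forward_ag(osa$Y, osa$A_s, osa$A_c, NULL,
                           p[[paste0(stage, "_dafm_Wf1")]],
                           p[[paste0(stage, "_dafm_bf1")]],
                           p[[paste0(stage, "_dafm_Wf2")]],
                           p[[paste0(stage, "_dafm_bf2")]],
                           config$beta, config$act_dafm)
  merge(fused$out, H, W, S)
}

osag_forward_ag <- function(X, config, p) {
  d <- dim(ag_data(X))
  H <- d[1]; W <- d[2]
  h <- lcb_forward_ag(X, list(expand_w = p$lcb_expand_w,
                              expand_b = p$lcb_expand_b,
                              dw_w = p$lcb_dw_w, dw_b = p$lcb_dw_b,
                              se_w1 = p$lcb_se_w1, se_b1 = p$lcb_se_b1,
                              se_w2 = p$lcb_se_w2, se_b2 = p$lcb_se_b2,
                              proj_w = p$lcb_proj_w, proj_b = p$lcb_proj_b))
  h <- attention_stage_ag(h, H, W, window_partition, window_merge,
                          config$window, p, "meso", config)
  h <- attention_stage_ag(h, H, W, grid_partition, grid_merge,
                          config$grid, p, "glob", config)
  agg <- ag_conv2d(ag_add(h, X), p$tail_w, p$tail_b)
  se_gate_ag(agg, p$se_w1, p$se_b1, p$se_w2, p$se_b2)
}

#' One omni-scale aggregation group (LCB, meso OSA, global OSA)
#'
#' `X_res = GlobalOSA(MesoOSA(LCB(X)))`, then the group output is
#' `SE(conv(X_res + X))`; shape preserved.
#'
#' @param X (H, W, C) feature map; H, W divisible by `lcm(window, grid)`
#' @param config an [sr_config()]
#' @param weights group parameter list (arrays), named as in [sr_model()]
#'   without the group prefix
#' @return (H, W, C) array
#' @export
osag_forward <- function(X, config, weights) {
  out <- ag_no_grad(osag_forward_ag(ag_input(X), config,
                                    lapply(weights, ag_input)))
  ag_data(out)
}

# ---- full network ----------------------------------------------------------

# reflect-pad (H, W, C) node up to multiples of m (no edge repeat)
reflect_pad_ag <- function(X, m) {
  d <- dim(ag_data(X))
  Hp <- ceiling(d[1] / m) * m
  Wp <- ceiling(d[2] / m) * m
  if (Hp == d[1] && Wp == d[2]) return(X)
  refl <- function(i, n) ifelse(i < n, i, 2L * n - 2L - i)
  hmap <- refl(0:(Hp - 1), d[1])
  wmap <- refl(0:(Wp - 1), d[2])
  g <- expand.grid(h = hmap, w = wmap, c = 0:(d[3] - 1))
  idx <- (g$h + 1L) + g$w * d[1] + g$c * d[1] * d[2]
  ag_gather(X, idx, c(Hp, Wp, d[3]))
}

crop_ag <- function(X, H, W) {
  d <- dim(ag_data(X))
  if (d[1] == H && d[2] == W) return(X)
  g <- expand.grid(h = 0:(H - 1), w = 0:(W - 1), c = 0:(d[3] - 1))
  idx <- (g$h + 1L) + g$w * d[1] + g$c * d[1] * d[2]
  ag_gather(X, idx, c(H, W, d[3]))
}

network_forward_ag <- function(Xin, model) {
  cf <- model$config
  p <- model$params
  d <- dim(ag_data(Xin))
  H <- d[1]; W <- d[2]
  x0 <- ag_conv2d(Xin, p$head_w, p$head_b)
  m <- lcm2(cf$window, cf$grid)
  x0p <- reflect_pad_ag(x0, m)
  h <- x0p
  for (g in seq_len(cf$n_groups)) {
    gp <- group_params(p, g)
    h <- osag_forward_ag(h, cf, gp)
  }
  h <- deaf_forward_ag(h, p$deaf_w, p$deaf_b)
  agg <- crop_ag(ag_add(x0p, h), H, W)
  r <- ag_conv2d(agg, p$rec_a_w, p$rec_a_b)
  r <- ag_conv2d(r, p$rec_up_w, p$rec_up_b)
  r <- ag_pixel_shuffle(r, cf$scale)
  ag_conv2d(r, p$rec_out_w, p$rec_out_b)
}

#' Super-resolve an image with the network
#'
#' Shallow convolution, `n_groups` OSAG blocks, the DEAF edge stage, shallow
#' plus deep feature aggregation, and a conv / sub-pixel-shuffle / conv
#' reconstruction tail.  Output spatial size is exactly `scale` times the
#' input; values are unclipped (clip with `clip = TRUE` for display).
#'
#' @param lr (H, W) matrix or (H, W, C) array, intensities in \[0, 1\]
#' @param model an [sr_model()]
#' @param clip clip output into \[0, 1\]
#' @return super-resolved image of size (H * scale, W * scale)
#' @export
network_forward <- function(lr, model, clip = TRUE) {
  d0 <- dim(lr)
  if (length(d0) == 2L) lr <- array(lr, dim = c(d0, 1L))
  if (dim(lr)[3] != model$config$in_channels)
    stop("model expects ", model$config$in_channels, " channel(s)")
  out <- ag_no_grad(network_forward_ag(ag_input(lr), model))
  y <- ag_data(out)
  if (!all(is.finite(y))) stop("non-finite values in network output")
  if (clip) y <- clip01(y)
  if (length(d0) == 2L) y <- y[, , 1]
  y
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint as a single JSON file
#'
#' The container holds a version tag, the full hyperparameter configuration
#' and every named weight array with its dimensions, so any language with a
#' JSON parser can reload it.
#'
#' @param model an [sr_model()]; @param path output file
#' @param path output file
#' @return `path`, invisibly
#' @export
save_model <- function(model, path) {
  obj <- list(version = "endosr-checkpoint-1",
              config = unclass(model$config),
              params = lapply(model$params, function(p)
                list(dim = dim(p$data) %||% length(p$data),
                     data = as.numeric(p$data))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint file
#' @return an `sr_model`
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "endosr-checkpoint-1"))
    stop("unrecognised checkpoint version: ", obj$version)
  cfg <- obj$config
  config <- sr_config(scale = cfg$scale, channels = cfg$channels,
                      n_groups = cfg$n_groups, window = cfg$window,
                      grid = cfg$grid, lcb_expansion = cfg$lcb_expansion,
                      dafm_hidden = cfg$dafm_hidden, beta = cfg$beta,
                      d_k = cfg$d_k, act_attn = cfg$act_attn,
                      act_dafm = cfg$act_dafm, attn_mode = cfg$attn_mode,
                      deaf_k = cfg$deaf_k, in_channels = cfg$in_channels)
  params <- lapply(obj$params, function(p)
    ag_param(array(p$data, dim = unlist(p$dim))))
  structure(list(config = config, params = params), class = "sr_model")
}
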