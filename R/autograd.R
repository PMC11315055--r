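# Minimal reverse-mode automatic differentiation over dense numeric arrays.
# Nodes are environments holding the value, the parents and a pullback
# closure; a global tape records creation order so backward() can sweep it in
# reverse.  Only what the SR network needs is implemented; every op keeps the
# array layout (H, W, C) for feature maps and (B, N, C) for token batches.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$enabled <- TRUE

ag_tape_start <- function() {
  .ag$tape <- vector("list", 0L)
  invisible(NULL)
}

ag_tape_clear <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
#' @noRd
ag_no_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  expr
}

ag_is_node <- function(x) inherits(x, "ag_node")

ag_node <- function(data, parents = list(), backfn = NULL, requires_grad = FALSE) {
  n <- new.env(parent = emptyenv())
  n$data <- data
  n$grad <- NULL
  n$requires_grad <- requires_grad || any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(n) <- "ag_node"
  if (.ag$enabled && n$requires_grad && !is.null(backfn)) {
    n$parents <- parents
    n$backfn <- backfn
    if (!is.null(.ag$tape)) .ag$tape[[length(.ag$tape) + 1L]] <- n
  } else {
    n$parents <- list()
    n$backfn <- NULL
  }
  n
}

#' @keywords internal
#' @noRd
ag_param <- function(data) ag_node(data, requires_grad = TRUE)

ag_input <- function(data) ag_node(data)

as_ag <- function(x) if (ag_is_node(x)) x else ag_input(x)

ag_data <- function(x) if (ag_is_node(x)) x$data else x

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Reverse sweep: populate `grad` on every node reachable from `loss`
#' @keywords internal
#' @noRd
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$data) == 1L)
  tape <- .ag$tape
  if (is.null(tape)) stop("no active tape; call ag_tape_start() before the forward pass")
  loss$grad <- array(1, dim = dim(loss$data) %||% 1L)
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (p$requires_grad && !is.null(gs[[j]])) ag_accum(p, gs[[j]])
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

keep_dim <- function(v, like) {
  d <- dim(like)
  if (is.null(d)) v else array(v, dim = d)
}

# ---- elementwise -----------------------------------------------------------

# add with limited broadcasting: identical shape, scalar, or bias over the
# last dimension of a 2-d/3-d array
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- a$data; db <- b$data
  if (identical(dim(da) %||% length(da), dim(db) %||% length(db))) {
    ag_node(da + db, list(a, b), function(g) list(g, keep_dim(g, db)))
  } else if (length(db) == 1L) {
    ag_node(da + as.numeric(db), list(a, b), function(g) list(g, sum(g)))
  } else {
    # bias over last dim
    d <- dim(da)
    stopifnot(!is.null(d), length(db) == d[length(d)])
    m <- matrix(da, ncol = d[length(d)])
    out <- array(sweep(m, 2L, as.numeric(db), "+"), dim = d)
    ag_node(out, list(a, b), function(g) {
      gm <- matrix(g, ncol = d[length(d)])
      list(keep_dim(g, da), colSums(gm))
    })
  }
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$data - b$data, list(a, b), function(g) list(g, -keep_dim(g, b$data)))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- a$data; db <- b$data
  if (length(db) == 1L) {
    ag_node(da * as.numeric(db), list(a, b),
            function(g) list(g * as.numeric(db), sum(g * da)))
  } else {
    stopifnot(identical(dim(da) %||% length(da), dim(db) %||% length(db)))
    ag_node(da * db, list(a, b),
            function(g) list(g * db, keep_dim(g * da, db)))
  }
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_node(a$data * s, list(a), function(g) list(g * s))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  m <- a$data > 0
  ag_node(a$data * m, list(a), function(g) list(g * m))
}

ag_gelu <- function(a) {
  a <- as_ag(a)
  x <- a$data
  ph <- stats::pnorm(x)
  ag_node(x * ph, list(a), function(g) list(g * (ph + x * stats::dnorm(x))))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  s <- 1 / (1 + exp(-a$data))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_identity_act <- function(a) as_ag(a)

ag_activation <- function(name) {
  switch(name,
         gelu = ag_gelu,
         relu = ag_relu,
         sigmoid = ag_sigmoid,
         identity = ag_identity_act,
         stop("unknown activation: ", name))
}

# ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$data %*% b$data, list(a, b), function(g)
    list(g %*% t(b$data), crossprod(a$data, g)))
}

# batched matmul: a is (B, N, K); b is (B, K, M) or a shared (K, M) matrix
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_ag(a); b <- as_ag(b)
  da <- a$data; db <- b$data
  B <- dim(da)[1]
  shared <- is.matrix(db)
  fa <- function(i) {
    m <- matrix(da[i, , ], dim(da)[2], dim(da)[3])
    if (ta) t(m) else m
  }
  fb <- function(i) {
    m <- if (shared) db else matrix(db[i, , ], dim(db)[2], dim(db)[3])
    if (tb) t(m) else m
  }
  o1 <- fa(1) %*% fb(1)
  out <- array(0, dim = c(B, nrow(o1), ncol(o1)))
  out[1, , ] <- o1
  if (B > 1) for (i in 2:B) out[i, , ] <- fa(i) %*% fb(i)
  ag_node(out, list(a, b), function(g) {
    ga <- array(0, dim = dim(da))
    gb <- if (shared) matrix(0, nrow(db), ncol(db)) else array(0, dim = dim(db))
    for (i in seq_len(B)) {
      gi <- matrix(g[i, , ], dim(g)[2], dim(g)[3])
      gA <- gi %*% t(fb(i))           # grad wrt fa(i)
      gB <- t(fa(i)) %*% gi           # grad wrt fb(i)
      ga[i, , ] <- if (ta) t(gA) else gA
      gBc <- if (tb) t(gB) else gB
      if (shared) gb <- gb + gBc else gb[i, , ] <- gBc
    }
    list(ga, gb)
  })
}

# softmax over the last dimension of a 2-d or 3-d array
ag_softmax <- function(a) {
  a <- as_ag(a)
  d <- dim(a$data)
  m <- matrix(a$data, ncol = d[length(d)])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  out <- array(s, dim = d)
  ag_node(out, list(a), function(g) {
    gm <- matrix(g, ncol = d[length(d)])
    dx <- s * (gm - rowSums(gm * s))
    list(array(dx, dim = d))
  })
}

# dense layer on a vector: W (out x in), x (in), b (out)
ag_dense <- function(x, W, b) {
  x <- as_ag(x); W <- as_ag(W); b <- as_ag(b)
  xv <- as.numeric(x$data)
  out <- as.numeric(W$data %*% xv) + as.numeric(b$data)
  ag_node(out, list(x, W, b), function(g) {
    gv <- as.numeric(g)
    list(as.numeric(crossprod(W$data, gv)), outer(gv, xv), gv)
  })
}

# ---- shape ops -------------------------------------------------------------

ag_reshape <- function(a, dims) {
  a <- as_ag(a)
  old <- dim(a$data) %||% length(a$data)
  ag_node(array(a$data, dim = dims), list(a),
          function(g) list(array(g, dim = old)))
}

# gather by a linear index permutation (bijection); out_dim gives the shape
ag_gather <- function(a, idx, out_dim) {
  a <- as_ag(a)
  old <- dim(a$data)
  out <- array(a$data[idx], dim = out_dim)
  ag_node(out, list(a), function(g) {
    gx <- numeric(length(a$data))
    gx[idx] <- as.numeric(g)
    list(array(gx, dim = old))
  })
}

# global average pool (H, W, C) -> length-C vector
ag_gap <- function(a) {
  a <- as_ag(a)
  d <- dim(a$data)
  out <- colMeans(matrix(a$data, ncol = d[3]))
  ag_node(out, list(a), function(g) {
    gv <- as.numeric(g) / (d[1] * d[2])
    list(array(rep(gv, each = d[1] * d[2]), dim = d))
  })
}

# per-channel scaling of (H, W, C) by a length-C vector (squeeze-excitation)
ag_channel_scale <- function(a, s) {
  a <- as_ag(a); s <- as_ag(s)
  d <- dim(a$data)
  sv <- as.numeric(s$data)
  sc <- rep(sv, each = d[1] * d[2])
  ag_node(array(a$data * sc, dim = d), list(a, s), function(g) {
    gm <- matrix(g * a$data, ncol = d[3])
    list(array(g * sc, dim = d), colSums(gm))
  })
}

# ---- convolutions ----------------------------------------------------------

pad_zero_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# dense 2-d convolution, stride 1, zero "same" padding
# x: (H, W, Cin); w: (k, k, Cin, Cout); b: length Cout
ag_conv2d <- function(x, w, b) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  dx <- dim(x$data); dw <- dim(w$data)
  H <- dx[1]; W <- dx[2]; Cin <- dx[3]; k <- dw[1]; Cout <- dw[4]
  p <- (k - 1L) %/% 2L
  xp <- pad_zero_hw(x$data, p)
  n <- H * W
  ymat <- matrix(rep(as.numeric(b$data), each = n), n, Cout)
  slices <- vector("list", k * k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xs <- matrix(xp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), ], n, Cin)
    slices[[(i - 1) * k + j]] <- xs
    ymat <- ymat + xs %*% matrix(w$data[i, j, , ], Cin, Cout)
  }
  ag_node(array(ymat, dim = c(H, W, Cout)), list(x, w, b), function(g) {
    gm <- matrix(g, n, Cout)
    gw <- array(0, dim = dw)
    gxp <- array(0, dim = dim(xp))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      xs <- slices[[(i - 1) * k + j]]
      gw[i, j, , ] <- crossprod(xs, gm)
      gs <- gm %*% t(matrix(w$data[i, j, , ], Cin, Cout))
      gxp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), ] <-
        gxp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), , drop = FALSE] +
        array(gs, c(H, W, Cin))
    }
    gx <- gxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
    list(array(gx, dim = dx), gw, colSums(gm))
  })
}

# depthwise 2-d convolution: w is (k, k, C), one kernel per channel
ag_dwconv2d <- function(x, w, b) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  dx <- dim(x$data); dw <- dim(w$data)
  H <- dx[1]; W <- dx[2]; C <- dx[3]; k <- dw[1]
  p <- (k - 1L) %/% 2L
  xp <- pad_zero_hw(x$data, p)
  out <- array(rep(as.numeric(b$data), each = H * W), dim = dx)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xs <- xp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), , drop = FALSE]
    wij <- rep(w$data[i, j, ], each = H * W)
    out <- out + xs * wij
  }
  ag_node(out, list(x, w, b), function(g) {
    gw <- array(0, dim = dw)
    gxp <- array(0, dim = dim(xp))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      xs <- xp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), , drop = FALSE]
      gw[i, j, ] <- colSums(matrix(g * xs, ncol = C))
      wij <- rep(w$data[i, j, ], each = H * W)
      gxp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), ] <-
        gxp[(i - 1) + seq_len(H), (j - 1) + seq_len(W), ] + g * wij
    }
    gx <- gxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
    list(array(gx, dim = dx), gw, colSums(matrix(g, ncol = C)))
  })
}

# pixel shuffle: (H, W, C*r^2) -> (H*r, W*r, C); channel c*r^2 block maps to
# an r x r sub-grid, row-major within the block
ag_pixel_shuffle <- function(x, r) {
  x <- as_ag(x)
  d <- dim(x$data)
  H <- d[1]; W <- d[2]; Cr2 <- d[3]
  stopifnot(Cr2 %% (r * r) == 0L)
  C <- Cr2 %/% (r * r)
  idx <- pixel_shuffle_index(H, W, C, r)
  out_dim <- c(H * r, W * r, C)
  ag_gather(x, idx, out_dim)
}

# linear indices into (H, W, C*r^2) such that out[hr, wr, c] = x[idx]
pixel_shuffle_index <- function(H, W, C, r) {
  Ho <- H * r; Wo <- W * r
  g <- expand.grid(ho = seq_len(Ho), wo = seq_len(Wo), c = seq_len(C))
  h <- (g$ho - 1L) %/% r + 1L
  w <- (g$wo - 1L) %/% r + 1L
  dy <- (g$ho - 1L) %% r
  dx <- (g$wo - 1L) %% r
  ch <- (g$c - 1L) * r * r + dy * r + dx + 1L
  h + (w - 1L) * H + (ch - 1L) * H * W
}

# ---- losses ----------------------------------------------------------------

ag_l1_loss <- function(pred, target) {
  pred <- as_ag(pred)
  t <- ag_data(target)
  d <- pred$data - t
  ag_node(mean(abs(d)), list(pred),
          function(g) list(keep_dim(as.numeric(g) * sign(d) / length(d), pred$data)))
}

ag_l2_loss <- function(pred, target) {
  pred <- as_ag(pred)
  t <- ag_data(target)
  d <- pred$data - t
  ag_node(mean(d^2), list(pred),
          function(g) list(keep_dim(as.numeric(g) * 2 * d / length(d), pred$data)))
}

# ---- optimiser -------------------------------------------------------------

#' Adam optimiser state over a flat named list of ag_param nodes
#' @keywords internal
#' @noRd
adam_init <- function(params, lr = 2e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p$data) %||% length(p$data))),
       v = lapply(params, function(p) array(0, dim = dim(p$data) %||% length(p$data))))
}

adam_step <- function(opt, params, lr = NULL) {
  opt$t <- opt$t + 1L
  lr <- lr %||% opt$lr
  b1 <- opt$beta1; b2 <- opt$beta2
  corr <- lr * sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- keep_dim(as.numeric(g), opt$m[[i]])
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    p$data <- p$data - keep_dim(corr * as.numeric(opt$m[[i]]) /
                                  (sqrt(as.numeric(opt$v[[i]])) + opt$eps), p$data)
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
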