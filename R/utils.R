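# Shared small helpers.

#' Evaluate an expression with a fixed RNG seed, restoring the caller's state
#' @param seed integer seed
#' @param expr expression
#' @return value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic fan-out of one global seed into per-stage seeds (kept < 2^31)
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483563) + 1L
}

clip01 <- function(x) {
  d <- dim(x)
  out <- pmin(1, pmax(0, x))
  if (!is.null(d)) dim(out) <- d
  out
}

is_image <- function(x) is.numeric(x) && (length(dim(x)) %in% c(2L, 3L))

image_channels <- function(x) if (length(dim(x)) == 3L) dim(x)[3] else 1L

#' Convert an RGB image to luminance (BT.601 weights); grayscale passes through
#' @param img image array, (H, W) or (H, W, 3), values in \[0, 1\]
#' @return (H, W) matrix
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  if (dim(img)[3] == 1L) return(img[, , 1])
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
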