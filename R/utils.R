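# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global stream.
#' A `NULL` seed runs `expr` against the current RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ITU-R 601 luminance of an 8-bit RGB array (h x w x 3), returned on the
# same 0..255 scale as a matrix.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

# Summed-area table (one leading row/col of zeros) for O(1) block sums.
integral_image <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s <- matrix(0, n1 + 1L, n2 + 1L)
  s[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  s
}

# Mean filter with half-width r and clipped (edge-shrinking) windows.
box_blur <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  s <- integral_image(m)
  lo1 <- pmax(seq_len(n1) - r, 1L); hi1 <- pmin(seq_len(n1) + r, n1)
  lo2 <- pmax(seq_len(n2) - r, 1L); hi2 <- pmin(seq_len(n2) + r, n2)
  tot <- s[hi1 + 1L, hi2 + 1L, drop = FALSE] - s[lo1, hi2 + 1L, drop = FALSE] -
    s[hi1 + 1L, lo2, drop = FALSE] + s[lo1, lo2, drop = FALSE]
  tot / outer(hi1 - lo1 + 1L, hi2 - lo2 + 1L)
}

# Non-overlapping block means of a matrix; trailing partial blocks are kept
# (their mean uses the actual pixel count).
block_mean <- function(m, block) {
  n1 <- nrow(m); n2 <- ncol(m)
  o1 <- ceiling(n1 / block); o2 <- ceiling(n2 / block)
  s <- integral_image(m)
  lo1 <- (seq_len(o1) - 1L) * block + 1L; hi1 <- pmin(seq_len(o1) * block, n1)
  lo2 <- (seq_len(o2) - 1L) * block + 1L; hi2 <- pmin(seq_len(o2) * block, n2)
  tot <- s[hi1 + 1L, hi2 + 1L, drop = FALSE] - s[lo1, hi2 + 1L, drop = FALSE] -
    s[hi1 + 1L, lo2, drop = FALSE] + s[lo1, lo2, drop = FALSE]
  tot / outer(hi1 - lo1 + 1L, hi2 - lo2 + 1L)
}

#' Write an 8-bit RGB image array to PNG
#'
#' @param img numeric array (h x w x 3) with values in 0..255.
#' @param path output file.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  png::writePNG(clamp8(img) / 255, target = path)
  invisible(path)
}

#' Read a PNG as an 8-bit RGB array
#'
#' Grayscale and alpha channels are expanded/dropped so the result is always
#' h x w x 3 on the 0..255 integer scale.
#' @param path PNG file.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) (x > 0) * x

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
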