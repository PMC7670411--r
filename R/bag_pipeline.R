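# Bag construction and the training-time augmentation stack.
#
# A bag is N tiles sampled from one slide, labeled with the slide label.
# At training time each tile passes through flip -> rotate -> color jitter
# -> cutout, then whole tiles are replaced by a constant dataset-mean-pixel
# image with probability `mean_pixel_prob` (mean-pixel regularization).
# Evaluation bags are never augmented or replaced.

#' Augmentation configuration
#'
#' Defaults follow the training protocol: left-right flip with probability
#' 0.5, a rotation drawn uniformly from \{0, 90, 180, 270\} degrees, color
#' jitter, one cutout square of side 100 filled with the dataset mean
#' pixel, and mean-pixel tile replacement with probability 0.75. Jitter
#' half-ranges are configurable (the protocol does not fix them):
#' brightness/contrast/saturation 0.25, hue 0.04.
#'
#' @param flip_prob probability of a left-right flip.
#' @param rotations allowed rotations in degrees, drawn equiprobably.
#' @param brightness,contrast,saturation,hue jitter half-ranges
#'   (multiplicative for the first three, additive in hue turns).
#' @param cutout_length side of the cutout square in pixels (0 disables);
#'   the square is clipped at tile borders.
#' @param mean_pixel_prob probability a bag tile is replaced by the
#'   constant mean-pixel image.
#' @param mean_pixel per-channel dataset mean color (8-bit scale); set from
#'   [dataset_mean_pixel()] on the training split.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(flip_prob = 0.5,
                           rotations = c(0, 90, 180, 270),
                           brightness = 0.25, contrast = 0.25,
                           saturation = 0.25, hue = 0.04,
                           cutout_length = 100,
                           mean_pixel_prob = 0.75,
                           mean_pixel = c(127.5, 127.5, 127.5)) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            mean_pixel_prob >= 0, mean_pixel_prob <= 1,
            cutout_length >= 0, length(mean_pixel) == 3L,
            all(rotations %% 90 == 0))
  structure(list(flip_prob = flip_prob, rotations = rotations,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue,
                 cutout_length = as.integer(cutout_length),
                 mean_pixel_prob = mean_pixel_prob,
                 mean_pixel = mean_pixel),
            class = "augment_config")
}

#' Per-channel dataset mean pixel over retained tiles
#'
#' Computed over all pixels of all retained tiles of the given slides.
#' Call it on the *training* split only: it is a training statistic and
#' must not see evaluation slides.
#'
#' @param slides named list of slide arrays (or `mil_cohort`).
#' @param tilesets named list of `TileSet`s aligned with `slides`.
#' @return 3-vector of channel means (8-bit scale).
#' @export
dataset_mean_pixel <- function(slides, tilesets) {
  if (inherits(slides, "mil_cohort")) slides <- slides$slides
  ids <- names(tilesets)
  stopifnot(length(ids) > 0, all(ids %in% names(slides)))
  tot <- c(0, 0, 0); npix <- 0
  for (id in ids) {
    ts <- tilesets[[id]]
    if (nrow(ts$tiles) == 0L) next
    img <- slides[[id]]
    for (i in seq_len(nrow(ts$tiles))) {
      tile <- get_tile(img, ts$tiles$row[i], ts$tiles$col[i], ts$tile_size)
      tot <- tot + c(sum(tile[, , 1]), sum(tile[, , 2]), sum(tile[, , 3]))
      npix <- npix + ts$tile_size^2
    }
  }
  if (npix == 0) stop("no retained tiles in the training split")
  tot / npix
}

#' Sample a bag of tiles from a slide
#'
#' Draws `n` retained tiles uniformly without replacement when the slide
#' has at least `n`; otherwise every retained tile is included once and the
#' remainder is filled by sampling with replacement (bag size is always
#' exactly `n`).
#'
#' @param tileset a `TileSet`.
#' @param n bag size.
#' @param label slide-level label attached to the bag.
#' @return list of class `mil_bag`: `slide_id`, `y`, `coords` (data.frame
#'   row/col/tile index into `tileset$tiles`), `augmented`.
#' @export
sample_bag <- function(tileset, n = 50, label = NA_integer_) {
  tl <- tileset$tiles
  if (nrow(tl) == 0L) stop("slide ", tileset$slide_id, " has no retained tiles")
  if (nrow(tl) >= n) {
    idx <- sample.int(nrow(tl), n)
  } else {
    extra <- sample.int(nrow(tl), n - nrow(tl), replace = TRUE)
    idx <- sample(c(seq_len(nrow(tl)), extra))
  }
  structure(list(slide_id = tileset$slide_id, y = label,
                 coords = data.frame(row = tl$row[idx], col = tl$col[idx],
                                     idx = idx),
                 augmented = FALSE),
            class = "mil_bag")
}

rotate90 <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) {
    # 90 degrees counter-clockwise per application
    img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

color_jitter <- function(img, b, cst, sat, hue) {
  x <- img / 255
  if (b != 0) x <- x * (1 + stats::runif(1, -b, b))
  if (cst != 0) {
    m <- mean(x)
    x <- (x - m) * (1 + stats::runif(1, -cst, cst)) + m
  }
  if (sat != 0) {
    lum <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    f <- 1 + stats::runif(1, -sat, sat)
    for (ch in 1:3) x[, , ch] <- lum + f * (x[, , ch] - lum)
  }
  x <- pmin(pmax(x, 0), 1)
  if (hue != 0) {
    hsv <- grDevices::rgb2hsv(rbind(as.vector(x[, , 1]), as.vector(x[, , 2]),
                                    as.vector(x[, , 3])), maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + stats::runif(1, -hue, hue)) %% 1
    rgb <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
    cr <- grDevices::col2rgb(rgb) / 255
    d <- dim(x)
    x <- array(c(cr[1, ], cr[2, ], cr[3, ]), d)
  }
  pmin(pmax(x, 0), 1) * 255
}

#' Augment one tile
#'
#' Applies, in order: left-right flip (probability `flip_prob`), one
#' rotation drawn from `rotations`, color jitter, and one cutout square of
#' side `cutout_length` (clipped at borders) filled with the mean pixel.
#' Output shape and 8-bit range are unchanged. The operations actually
#' drawn are recorded in attribute `"ops"`.
#'
#' @param tile 8-bit RGB tile array.
#' @param cfg an [augment_config()].
#' @return augmented tile.
#' @export
augment_tile <- function(tile, cfg = augment_config()) {
  ops <- list()
  ops$flip <- stats::runif(1) < cfg$flip_prob
  if (ops$flip) tile <- tile[, dim(tile)[2]:1, , drop = FALSE]
  ops$rotation <- cfg$rotations[sample.int(length(cfg$rotations), 1L)]
  tile <- rotate90(tile, ops$rotation %/% 90)
  if (cfg$brightness != 0 || cfg$contrast != 0 || cfg$saturation != 0 ||
      cfg$hue != 0) {
    tile <- color_jitter(tile, cfg$brightness, cfg$contrast,
                         cfg$saturation, cfg$hue)
  }
  if (cfg$cutout_length > 0) {
    h <- dim(tile)[1]; w <- dim(tile)[2]
    cy <- sample.int(h, 1L); cx <- sample.int(w, 1L)
    half <- cfg$cutout_length %/% 2L
    r0 <- max(1L, cy - half); r1 <- min(h, cy - half + cfg$cutout_length - 1L)
    c0 <- max(1L, cx - half); c1 <- min(w, cx - half + cfg$cutout_length - 1L)
    for (ch in 1:3) tile[r0:r1, c0:c1, ch] <- cfg$mean_pixel[ch]
    ops$cutout <- c(r0, r1, c0, c1)
  }
  tile <- clamp8(tile)
  attr(tile, "ops") <- ops
  tile
}

#' Mean-pixel tile replacement over a bag
#'
#' Independently replaces each tile image by the constant mean-pixel image
#' with probability `cfg$mean_pixel_prob`. The bag's size, coordinates and
#' label are untouched; which tiles were replaced is recorded in the
#' logical vector `bag$replaced`.
#'
#' @param tiles list of tile arrays (one bag).
#' @param cfg an [augment_config()].
#' @return list with `tiles` (possibly replaced) and `replaced` flags.
#' @export
mean_pixel_replace <- function(tiles, cfg = augment_config()) {
  n <- length(tiles)
  replaced <- stats::runif(n) < cfg$mean_pixel_prob
  if (any(replaced)) {
    d <- dim(tiles[[1]])
    const <- array(rep(cfg$mean_pixel, each = d[1] * d[2]), d)
    for (i in which(replaced)) tiles[[i]] <- const
  }
  list(tiles = tiles, replaced = replaced)
}

#' Balanced slide ordering for one epoch
#'
#' Every epoch presents an exact 50-50 class mix: each class contributes
#' `max(class counts)` draws; the majority class is a permutation of its
#' slides, the minority class is oversampled by cycling a shuffled copy
#' (so counts per slide differ by at most one), and the combined epoch is
#' shuffled.
#'
#' @param labels named 0/1 vector (names = slide ids).
#' @return character vector of slide ids of length `2 * max(class counts)`.
#' @export
balanced_epoch <- function(labels) {
  stopifnot(!is.null(names(labels)))
  pos <- names(labels)[labels == 1]
  neg <- names(labels)[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("balanced sampling needs both classes present")
  }
  m <- max(length(pos), length(neg))
  draw <- function(ids) {
    if (length(ids) == m) sample(ids) else rep(sample(ids), length.out = m)
  }
  sample(c(draw(pos), draw(neg)))
}
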