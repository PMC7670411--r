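# Tissue segmentation and non-overlapping tile enumeration.
#
# Slides are segmented on a downsampled thumbnail: grayscale conversion
# (ITU-R 601 luminance), a 256-bin histogram, Otsu's threshold, and the
# darker class taken as tissue (H&E tissue absorbs light; a polarity flag
# flips the rule for bright-tissue modalities). Tiles are enumerated on the
# non-overlapping grid anchored at (0,0); a tile is retained iff the
# fraction of its pixels marked tissue meets `min_foreground` (default 1%).

#' Otsu's threshold from a 256-bin grayscale histogram
#'
#' Returns the gray level `t` in 0..255 maximizing the between-class
#' variance of the split `{<= t}` vs `{> t}`; ties are broken by the
#' smallest maximizing level. A histogram with all mass in a single bin is
#' degenerate: that bin's level is returned with attribute
#' `"degenerate" = TRUE`.
#'
#' @param counts numeric vector of 256 bin counts (levels 0..255).
#' @return integer threshold with attribute `degenerate`.
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  if (sum(counts) <= 0) stop("histogram is empty")
  nz <- which(counts > 0)
  if (length(nz) == 1L) {
    return(structure(as.integer(nz - 1L), degenerate = TRUE))
  }
  lev <- 0:255
  w <- counts / sum(counts)
  w0 <- cumsum(w)                       # P(class <= t), t = 0..255
  mu_t <- cumsum(w * lev)
  mu <- mu_t[256L]
  w1 <- 1 - w0
  # between-class variance; undefined where a class is empty
  num <- (mu * w0 - mu_t)^2
  bcv <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), -Inf)
  t <- which.max(bcv) - 1L              # which.max takes the first maximum
  structure(as.integer(t), degenerate = FALSE)
}

# Downsampled luminance thumbnail (block means).
thumbnail_luminance <- function(img, downsample) {
  block_mean(luminance(img), as.integer(downsample))
}

#' Segment tissue from background on a slide thumbnail
#'
#' @param img 8-bit RGB slide array (h x w x 3).
#' @param downsample thumbnail downsampling factor (>= 1).
#' @param tissue_bright if `TRUE`, tissue is the brighter class (inverts
#'   the default darker-is-tissue rule).
#' @return object of class `tissue_mask`: list with the logical `mask`
#'   (thumbnail scale, `TRUE` = tissue), the Otsu `threshold`, `downsample`,
#'   and a `degenerate` flag. A uniform (blank) slide yields an
#'   all-background mask with a warning.
#' @export
segment_thumbnail <- function(img, downsample = 32, tissue_bright = FALSE) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L, downsample >= 1)
  thumb <- thumbnail_luminance(img, downsample)
  q <- pmin(pmax(round(thumb), 0), 255)
  counts <- tabulate(as.integer(q) + 1L, nbins = 256L)
  t <- otsu_threshold(counts)
  degenerate <- isTRUE(attr(t, "degenerate"))
  if (degenerate) {
    warning("uniform slide: no tissue/background contrast; returning ",
            "all-background mask")
    mask <- matrix(FALSE, nrow(thumb), ncol(thumb))
  } else if (tissue_bright) {
    mask <- q > t
  } else {
    mask <- q <= t
  }
  structure(list(mask = mask, threshold = as.integer(t),
                 downsample = as.integer(downsample),
                 degenerate = degenerate,
                 grayscale = "ITU-R 601 (0.299R + 0.587G + 0.114B)"),
            class = "tissue_mask")
}

#' Enumerate non-overlapping foreground tiles
#'
#' Tiles live on the grid anchored at pixel (0,0); partial tiles at the
#' right/bottom edges are dropped (tiles are exactly `tile_size` square,
#' never padded). Tile (row, col) is 0-based and covers the half-open pixel
#' square `[row*tile_size, (row+1)*tile_size) x [col*..., (col+1)*...)`.
#'
#' @param img 8-bit RGB slide array.
#' @param mask a `tissue_mask` from [segment_thumbnail()] (or `NULL` to
#'   segment with defaults).
#' @param tile_size tile edge in pixels.
#' @param min_foreground minimum tissue fraction for a tile to be retained.
#' @param slide_id identifier stored in the result.
#' @param resolution_tag free-text resolution metadata.
#' @return object of class `TileSet`: `tiles` data.frame (row, col,
#'   foreground_fraction) of retained tiles plus grid and segmentation
#'   metadata. `all_tiles` keeps the full grid so retained + dropped tiles
#'   always partition it.
#' @export
extract_tiles <- function(img, mask = NULL, tile_size = 256,
                          min_foreground = 0.01, slide_id = "slide",
                          resolution_tag = "synthetic") {
  stopifnot(length(dim(img)) == 3L, tile_size >= 1, min_foreground >= 0)
  if (is.null(mask)) mask <- segment_thumbnail(img)
  stopifnot(inherits(mask, "tissue_mask"))
  h <- dim(img)[1]; w <- dim(img)[2]
  gr <- h %/% tile_size; gc <- w %/% tile_size
  if (gr == 0L || gc == 0L) {
    warning("tile_size (", tile_size, ") exceeds slide dimensions (",
            h, "x", w, "); empty TileSet")
    empty <- data.frame(row = integer(), col = integer(),
                        foreground_fraction = numeric())
    return(structure(list(slide_id = slide_id, tile_size = as.integer(tile_size),
                          tiles = empty, all_tiles = empty,
                          grid_rows = 0L, grid_cols = 0L,
                          threshold = mask$threshold,
                          downsample = mask$downsample,
                          min_foreground = min_foreground,
                          resolution_tag = resolution_tag,
                          grayscale = mask$grayscale),
                     class = "TileSet"))
  }
  # nearest-neighbor upsample of the thumbnail mask to slide scale, then
  # exact per-tile block means of the resulting indicator
  ds <- mask$downsample
  ridx <- pmin((0:(h - 1L)) %/% ds + 1L, nrow(mask$mask))
  cidx <- pmin((0:(w - 1L)) %/% ds + 1L, ncol(mask$mask))
  fg <- matrix(as.numeric(mask$mask[ridx, cidx]), h, w)
  frac <- block_mean(fg[seq_len(gr * tile_size), seq_len(gc * tile_size), drop = FALSE],
                     as.integer(tile_size))
  all_tiles <- data.frame(
    row = rep(0:(gr - 1L), times = gc),
    col = rep(0:(gc - 1L), each = gr),
    foreground_fraction = as.vector(frac)
  )
  all_tiles <- all_tiles[order(all_tiles$row, all_tiles$col), , drop = FALSE]
  rownames(all_tiles) <- NULL
  keep <- all_tiles$foreground_fraction >= min_foreground
  structure(list(slide_id = slide_id, tile_size = as.integer(tile_size),
                 tiles = all_tiles[keep, , drop = FALSE],
                 all_tiles = all_tiles,
                 grid_rows = gr, grid_cols = gc,
                 threshold = mask$threshold, downsample = mask$downsample,
                 min_foreground = min_foreground,
                 resolution_tag = resolution_tag,
                 grayscale = mask$grayscale),
            class = "TileSet")
}

#' @export
print.TileSet <- function(x, ...) {
  cat("TileSet", x$slide_id, ":", nrow(x$tiles), "of",
      x$grid_rows * x$grid_cols, "tiles retained (tile",
      x$tile_size, "px, Otsu threshold", x$threshold, ")\n")
  invisible(x)
}

#' Crop one tile from a slide image
#'
#' @param img slide array; `row`, `col` 0-based tile coordinates.
#' @param tile_size tile edge in pixels.
#' @export
get_tile <- function(img, row, col, tile_size) {
  img[(row * tile_size + 1L):((row + 1L) * tile_size),
      (col * tile_size + 1L):((col + 1L) * tile_size), , drop = FALSE]
}

#' Tile all slides of a cohort
#'
#' Convenience wrapper running [segment_thumbnail()] + [extract_tiles()]
#' over every slide of a [generate_cohort()] result (or a named list of
#' arrays).
#'
#' @param slides `mil_cohort` or named list of slide arrays.
#' @param tile_size,min_foreground,downsample,tissue_bright see
#'   [extract_tiles()] and [segment_thumbnail()].
#' @return named list of `TileSet`s.
#' @export
tile_cohort <- function(slides, tile_size = NULL, min_foreground = 0.01,
                        downsample = 32, tissue_bright = FALSE) {
  if (inherits(slides, "mil_cohort")) {
    if (is.null(tile_size)) tile_size <- slides$spec$tile_size
    slides <- slides$slides
  }
  stopifnot(!is.null(tile_size), length(names(slides)) == length(slides))
  out <- lapply(names(slides), function(id) {
    m <- segment_thumbnail(slides[[id]], downsample, tissue_bright)
    extract_tiles(slides[[id]], m, tile_size, min_foreground, slide_id = id)
  })
  stats::setNames(out, names(slides))
}

#' Write TileSets as JSON
#'
#' One JSON object per slide with the threshold and retained tile list.
#' @param tilesets named list of `TileSet`s.
#' @param path output JSON file.
#' @export
write_tilesets <- function(tilesets, path) {
  obj <- lapply(tilesets, function(ts) {
    list(slide_id = ts$slide_id, tile_size = ts$tile_size,
         grid_rows = ts$grid_rows, grid_cols = ts$grid_cols,
         threshold = ts$threshold, downsample = ts$downsample,
         min_foreground = ts$min_foreground, grayscale = ts$grayscale,
         tiles = ts$tiles)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
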