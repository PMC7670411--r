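# Fixed multi-scale filter-bank tile encoder.
#
# The backbone maps a tile to a 256-dimensional descriptor built from a
# box-filter scale space of the luminance channel: band-pass (difference of
# box means) energies at four scales, local gradient energy, and color
# statistics, each pooled over a 4x4 spatial grid, plus global histogram /
# quantile / covariance summaries. It is deterministic and has no learned
# parameters; the two fully connected layers of the MIL network (trained
# with dropout) sit on top of it. Object size and density — the axis that
# separates the synthetic positive and negative morphologies — appear as
# the distribution of energy across scale bands.

#' Backbone configuration
#'
#' @param tile_size expected tile edge in pixels (enforced at feature
#'   extraction; mismatches are an error, not silently rescaled).
#' @param scales half-widths of the box-filter scale space.
#' @return list with class `backbone_config`; `d0` is the descriptor
#'   dimension (256).
#' @export
backbone_config <- function(tile_size = 256, scales = c(1L, 2L, 4L, 8L)) {
  structure(list(tile_size = as.integer(tile_size),
                 scales = as.integer(scales), d0 = 256L),
            class = "backbone_config")
}

# Exact 4x4 cell means via the summed-area table; always 16 values.
cell_means <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s <- integral_image(m)
  b1 <- floor((0:4) * n1 / 4); b2 <- floor((0:4) * n2 / 4)
  lo1 <- b1[1:4] + 1L; hi1 <- b1[2:5]
  lo2 <- b2[1:4] + 1L; hi2 <- b2[2:5]
  tot <- s[hi1 + 1L, hi2 + 1L, drop = FALSE] - s[lo1, hi2 + 1L, drop = FALSE] -
    s[hi1 + 1L, lo2, drop = FALSE] + s[lo1, lo2, drop = FALSE]
  as.vector(tot / outer(hi1 - lo1 + 1L, hi2 - lo2 + 1L))
}

safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx < 1e-12 || sy < 1e-12) return(0)
  stats::cor(x, y)
}

#' Extract the fixed backbone descriptor of one tile
#'
#' @param img 8-bit RGB tile array (`tile_size` square).
#' @param cfg a [backbone_config()].
#' @return numeric vector of length `cfg$d0` (256).
#' @export
backbone_features <- function(img, cfg = backbone_config()) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an RGB array tile")
  if (d[1] != cfg$tile_size || d[2] != cfg$tile_size) {
    stop("tile size mismatch: expected ", cfg$tile_size, "x", cfg$tile_size,
         ", got ", d[1], "x", d[2])
  }
  R <- img[, , 1] / 255; G <- img[, , 2] / 255; B <- img[, , 3] / 255
  L <- 0.299 * R + 0.587 * G + 0.114 * B
  n <- cfg$tile_size
  blurs <- lapply(cfg$scales, function(r) box_blur(L, r))
  bands <- vector("list", length(blurs))
  prev <- L
  for (i in seq_along(blurs)) {
    bands[[i]] <- prev - blurs[[i]]
    prev <- blurs[[i]]
  }
  dx <- cbind(abs(L[, -1] - L[, -n]), 0)
  dy <- rbind(abs(L[-1, ] - L[-n, ]), 0)
  gmag <- (dx + dy) / 2

  cells <- c(
    cell_means(L),
    sqrt(pmax(cell_means(L^2) - cell_means(L)^2, 0)),
    cell_means(R), cell_means(G), cell_means(B),
    unlist(lapply(bands, function(b) cell_means(abs(b)))),
    sqrt(pmax(cell_means(bands[[1]]^2), 0)),
    sqrt(pmax(cell_means(bands[[2]]^2), 0)),
    cell_means(gmag)
  )                                              # 12 x 16 = 192

  lv <- as.vector(L)
  hist_l <- tabulate(pmin(pmax(floor(lv * 24) + 1L, 1L), 24L), nbins = 24L) /
    length(lv)
  qs <- stats::quantile(lv, c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99),
                        names = FALSE, type = 7)
  band_stats <- unlist(lapply(bands, function(b) c(mean(abs(b)), stats::sd(b))))
  e <- vapply(bands, function(b) mean(b^2), numeric(1))
  eps <- 1e-8
  globals <- c(
    hist_l,                                      # 24
    qs,                                          # 9
    band_stats,                                  # 8
    mean(R), mean(G), mean(B),                   # 3
    stats::sd(R), stats::sd(G), stats::sd(B),    # 3
    mean(gmag), stats::sd(gmag),                 # 2
    mean(lv < 0.35), mean(lv < 0.5), mean(lv < 0.65),  # 3
    e[1] / (e[4] + eps), (e[1] + e[2]) / (e[3] + e[4] + eps),  # 2
    mean(lv), stats::sd(lv),                     # 2
    safe_cor(as.vector(R), as.vector(G)),
    safe_cor(as.vector(R), as.vector(B)),
    safe_cor(as.vector(G), as.vector(B)),        # 3
    mean(pmin(R, G, B)), mean(pmax(R, G, B)), mean(R - B),  # 3
    mean(pmax(R, G, B) - pmin(R, G, B)),
    stats::sd(pmax(R, G, B) - pmin(R, G, B))     # 2
  )                                              # 64
  out <- c(cells, globals)
  stopifnot(length(out) == cfg$d0)
  out
}

#' Backbone descriptors for a list of tiles
#'
#' @param tiles list of tile arrays.
#' @param cfg a [backbone_config()].
#' @return numeric matrix, one row per tile, `cfg$d0` columns.
#' @export
backbone_matrix <- function(tiles, cfg = backbone_config()) {
  t(vapply(tiles, backbone_features, numeric(cfg$d0), cfg = cfg))
}
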