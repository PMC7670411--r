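# Synthetic slide cohorts with known slide- and tile-level ground truth.
#
# The generator renders each slide as a mosaic of tiles of three kinds:
# near-white background, negative tissue (sparse, large, irregular
# nucleus-like objects) and positive tissue (dense, small, round objects).
# Both tissue kinds share the same base- and object-color distributions, so
# the positive/negative signal lives in local object statistics (size,
# density, shape), not in global color: background/tissue is separable by
# global intensity (Otsu-compatible) while positive/negative is not.

#' Default texture parameters for the synthetic tile renderers
#'
#' Radii are fractions of the tile edge so textures rescale with
#' `tile_size`. Both classes target the same expected object coverage
#' (`coverage`), which keeps their mean intensity matched and forces the
#' classifier to use object statistics rather than overall darkness.
#'
#' @param coverage expected fraction of a tissue tile covered by objects.
#' @param pos_radius,neg_radius object radius range (fraction of tile edge)
#'   for positive (small, round) and negative (large, irregular) morphology.
#' @param pos_irregularity,neg_irregularity radial wobble amplitude of the
#'   object boundary (0 = perfect ellipse).
#' @param base_color,base_jitter per-tile tissue base color (8-bit RGB) and
#'   the half-range of its uniform per-tile jitter.
#' @param object_color,object_jitter per-object color and jitter.
#' @param background_level gray-level range of background tiles (clamped to
#'   at least 230 so background stays near-white by construction).
#' @return a list of texture parameters for [render_tile()].
#' @export
texture_params <- function(coverage = 0.10,
                           pos_radius = c(0.030, 0.060),
                           neg_radius = c(0.100, 0.180),
                           pos_irregularity = 0.08,
                           neg_irregularity = 0.45,
                           base_color = c(208, 172, 196),
                           base_jitter = 10,
                           object_color = c(105, 80, 150),
                           object_jitter = 18,
                           background_level = c(238, 252)) {
  stopifnot(coverage > 0, coverage < 1,
            all(pos_radius > 0), all(neg_radius > 0),
            diff(pos_radius) >= 0, diff(neg_radius) >= 0)
  list(coverage = coverage,
       pos_radius = pos_radius, neg_radius = neg_radius,
       pos_irregularity = pos_irregularity, neg_irregularity = neg_irregularity,
       base_color = base_color, base_jitter = base_jitter,
       object_color = object_color, object_jitter = object_jitter,
       background_level = pmax(background_level, 230))
}

#' Specification of a synthetic slide cohort
#'
#' @param n_slides number of slides.
#' @param prevalence fraction of positive slides in `[0, 1]`.
#' @param witness_rate fraction of tissue tiles in a positive slide carrying
#'   positive morphology, in `(0, 1]`.
#' @param grid_rows,grid_cols tile-grid dimensions of each slide.
#' @param tile_size pixels per tile edge (>= 32).
#' @param background_fraction fraction of grid cells rendered as non-tissue
#'   background, in `[0, 1)`.
#' @param texture [texture_params()] list.
#' @param noise_sd additive Gaussian pixel noise standard deviation
#'   (8-bit scale), applied after rendering and then rounded, so the cohort
#'   is 8-bit exact and byte-identical across runs with the same seed.
#' @param seed integer RNG seed; the same spec and seed reproduce the cohort
#'   byte for byte.
#' @param slides_per_patient slides sharing one synthetic patient id
#'   (multi-slide patients exercise patient-grouped splitting).
#' @param contiguous_witness place witness tiles as one connected region
#'   instead of uniformly at random (useful for heatmap demos).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_slides,
                        prevalence = 0.5,
                        witness_rate = 0.2,
                        grid_rows = 8, grid_cols = 8,
                        tile_size = 64,
                        background_fraction = 0.25,
                        texture = texture_params(),
                        noise_sd = 3,
                        seed = 1,
                        slides_per_patient = 1,
                        contiguous_witness = FALSE) {
  stopifnot(n_slides >= 1,
            prevalence >= 0, prevalence <= 1,
            witness_rate > 0, witness_rate <= 1,
            grid_rows >= 1, grid_cols >= 1,
            tile_size >= 32,
            background_fraction >= 0, background_fraction < 1,
            noise_sd >= 0, slides_per_patient >= 1)
  structure(list(n_slides = as.integer(n_slides), prevalence = prevalence,
                 witness_rate = witness_rate,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 tile_size = as.integer(tile_size),
                 background_fraction = background_fraction,
                 texture = texture, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 slides_per_patient = as.integer(slides_per_patient),
                 contiguous_witness = contiguous_witness),
            class = "cohort_spec")
}

# Rasterize one irregular elliptical blob into a logical mask (in place).
# The boundary radius is modulated as r * (1 + irr * sin(k*theta + phase)).
draw_blob <- function(mask, cx, cy, r, ecc, angle, irr) {
  ts_r <- nrow(mask); ts_c <- ncol(mask)
  rmax <- r * (1 + abs(irr)) * ecc
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(ts_r, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(ts_c, ceiling(cx + rmax))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - cy; dx <- jj - cx
  # rotate into the ellipse frame
  ca <- cos(angle); sa <- sin(angle)
  X <- outer(dy, dx, function(y, x) x * ca + y * sa)
  Y <- outer(dy, dx, function(y, x) -x * sa + y * ca)
  rho <- sqrt((X / ecc)^2 + Y^2)
  theta <- atan2(Y, X / ecc)
  k <- sample(2:5, 1L)
  phase <- stats::runif(1L, 0, 2 * pi)
  rb <- r * (1 + irr * sin(k * theta + phase))
  mask[ii, jj] <- mask[ii, jj] | (rho <= rb)
  mask
}

#' Render one synthetic tile
#'
#' Draws a single tile of the requested kind using the current RNG state
#' (seed the RNG for reproducibility). Background tiles are near-white
#' (all pixels >= 230 before noise); tissue tiles are a stained base color
#' with at least one nucleus-like object. The logical object mask is
#' attached as attribute `"object_mask"` for ground-truth analyses.
#'
#' @param kind one of `"background"`, `"negative_tissue"`,
#'   `"positive_tissue"`.
#' @param tile_size pixels per tile edge.
#' @param params [texture_params()] list.
#' @param noise_sd additive Gaussian noise SD; the result is rounded and
#'   clamped to 0..255.
#' @return numeric array `tile_size x tile_size x 3` of 8-bit values.
#' @export
render_tile <- function(kind, tile_size = 64, params = texture_params(),
                        noise_sd = 0) {
  kinds <- c("background", "negative_tissue", "positive_tissue")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds)) {
    stop("unknown tile kind: ", deparse(kind),
         " (expected one of ", paste(kinds, collapse = ", "), ")")
  }
  ts <- as.integer(tile_size)
  img <- array(0, c(ts, ts, 3L))
  mask <- matrix(FALSE, ts, ts)
  if (kind == "background") {
    lvl <- stats::runif(1L, params$background_level[1], params$background_level[2])
    img[] <- lvl
  } else {
    base <- params$base_color + stats::runif(3L, -params$base_jitter, params$base_jitter)
    for (ch in 1:3) img[, , ch] <- base[ch]
    pos <- kind == "positive_tissue"
    rr <- (if (pos) params$pos_radius else params$neg_radius) * ts
    irr <- if (pos) params$pos_irregularity else params$neg_irregularity
    # expected n objects chosen so both classes hit the same coverage
    er2 <- (rr[1]^2 + rr[1] * rr[2] + rr[2]^2) / 3
    lambda <- params$coverage * ts^2 / (pi * er2)
    n_obj <- max(1L, stats::rpois(1L, lambda))
    for (k in seq_len(n_obj)) {
      cx <- stats::runif(1L, 1, ts); cy <- stats::runif(1L, 1, ts)
      r <- stats::runif(1L, rr[1], rr[2])
      ecc <- if (pos) stats::runif(1L, 1, 1.15) else stats::runif(1L, 1.2, 2.2)
      ang <- stats::runif(1L, 0, pi)
      mask <- draw_blob(mask, cx, cy, r, ecc, ang, irr)
    }
    col <- params$object_color + stats::runif(3L, -params$object_jitter, params$object_jitter)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  }
  img <- round(clamp8(img))
  attr(img, "object_mask") <- mask
  img
}

# Grow a connected region of n cells over the tissue grid via BFS from a
# random seed cell; falls back to random fill if the component is smaller.
grow_region <- function(tissue_cells, n) {
  if (n >= nrow(tissue_cells)) return(seq_len(nrow(tissue_cells)))
  key <- paste(tissue_cells$row, tissue_cells$col)
  start <- sample.int(nrow(tissue_cells), 1L)
  sel <- start
  frontier <- start
  while (length(sel) < n && length(frontier) > 0L) {
    cur <- frontier[1L]; frontier <- frontier[-1L]
    nb <- cbind(row = tissue_cells$row[cur] + c(-1L, 1L, 0L, 0L),
                col = tissue_cells$col[cur] + c(0L, 0L, -1L, 1L))
    idx <- match(paste(nb[, 1], nb[, 2]), key)
    idx <- idx[!is.na(idx) & !(idx %in% sel)]
    if (length(idx)) {
      idx <- idx[seq_len(min(length(idx), n - length(sel)))]
      sel <- c(sel, idx)
      frontier <- c(frontier, idx)
    }
  }
  if (length(sel) < n) {
    rest <- setdiff(seq_len(nrow(tissue_cells)), sel)
    sel <- c(sel, rest[sample.int(length(rest), n - length(sel))])
  }
  sel
}

#' Generate a synthetic slide cohort
#'
#' Renders `n_slides` slide mosaics with known slide labels and per-tile
#' ground truth. Negative slides contain only negative-morphology tissue;
#' positive slides embed `witness_rate` positive tiles among the tissue
#' cells (at least one — the defining MIL asymmetry: a positive bag holds
#' at least one positive instance, a negative bag none).
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, writes `slides/<id>.png`,
#'   `labels.csv` (columns slide_id, patient_id, label) and
#'   `ground_truth.json`.
#' @return an object of class `mil_cohort`: list with `spec`, `labels`
#'   (data.frame slide_id/patient_id/label), `tiles` (data.frame slide_id,
#'   row, col (0-based), kind), and `slides` (named list of 8-bit RGB
#'   arrays).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_slides
    n_pos <- round(spec$prevalence * n)
    if (spec$prevalence > 0 && n_pos == 0) {
      warning("prevalence rounds to 0 positive slides; witness-based checks ",
              "will be vacuous")
    }
    pos_ids <- sample.int(n, n_pos)
    ids <- sprintf("slide_%03d", seq_len(n))
    patients <- sprintf("patient_%03d", (seq_len(n) - 1L) %/% spec$slides_per_patient + 1L)
    labels <- data.frame(slide_id = ids, patient_id = patients,
                         label = as.integer(seq_len(n) %in% pos_ids),
                         stringsAsFactors = FALSE)
    gr <- spec$grid_rows; gc <- spec$grid_cols; ts <- spec$tile_size
    cells <- expand.grid(row = 0:(gr - 1L), col = 0:(gc - 1L))
    n_cells <- nrow(cells)
    n_bg <- round(spec$background_fraction * n_cells)
    slides <- vector("list", n); names(slides) <- ids
    tile_rows <- vector("list", n)
    for (s in seq_len(n)) {
      kind <- rep("negative_tissue", n_cells)
      if (n_bg > 0) kind[sample.int(n_cells, n_bg)] <- "background"
      tissue_idx <- which(kind != "background")
      if (labels$label[s] == 1L && length(tissue_idx) > 0L) {
        n_wit <- max(1L, round(spec$witness_rate * length(tissue_idx)))
        wit <- if (spec$contiguous_witness) {
          tissue_idx[grow_region(cells[tissue_idx, , drop = FALSE], n_wit)]
        } else {
          tissue_idx[sample.int(length(tissue_idx), n_wit)]
        }
        kind[wit] <- "positive_tissue"
      }
      img <- array(0, c(gr * ts, gc * ts, 3L))
      for (i in seq_len(n_cells)) {
        tile <- render_tile(kind[i], ts, spec$texture, spec$noise_sd)
        r0 <- cells$row[i] * ts; c0 <- cells$col[i] * ts
        img[(r0 + 1L):(r0 + ts), (c0 + 1L):(c0 + ts), ] <- tile
      }
      slides[[s]] <- img
      tile_rows[[s]] <- data.frame(slide_id = ids[s], row = cells$row,
                                   col = cells$col, kind = kind,
                                   stringsAsFactors = FALSE)
    }
    tiles <- do.call(rbind, tile_rows)
    cohort <- structure(list(spec = spec, labels = labels, tiles = tiles,
                             slides = slides, dir = out_dir),
                        class = "mil_cohort")
    if (!is.null(out_dir)) write_cohort(cohort, out_dir)
    cohort
  })
}

write_cohort <- function(cohort, out_dir) {
  slide_dir <- file.path(out_dir, "slides")
  dir.create(slide_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(slide_dir)) stop("cannot create output directory: ", out_dir)
  for (id in names(cohort$slides)) {
    write_image(cohort$slides[[id]], file.path(slide_dir, paste0(id, ".png")))
  }
  utils::write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- list(
    slide_labels = stats::setNames(as.list(cohort$labels$label),
                                   cohort$labels$slide_id),
    tile_labels = cohort$tiles
  )
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mil_cohort <- function(x, ...) {
  cat("Synthetic MIL cohort:", nrow(x$labels), "slides (",
      sum(x$labels$label), "positive ),",
      x$spec$grid_rows, "x", x$spec$grid_cols, "grid, tile",
      x$spec$tile_size, "px, witness rate", x$spec$witness_rate, "\n")
  invisible(x)
}
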