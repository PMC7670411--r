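# Attention-weight interpretability workflow: exhaustive slide embeddings,
# k-means with elbow-selected k over slides, cluster purity scoring by
# predicted label, top-attention tile selection, per-cluster tile panels,
# and attention heatmap overlays.

#' Exhaustive slide embedding
#'
#' Partitions all retained tiles of a slide into `ceiling(T / N)` bags of
#' size `N` (a seeded random partition; the last bag is padded by
#' resampling, with padding flagged), scores every bag, and combines the
#' per-bag aggregates into one slide embedding. Each bag's aggregate is
#' weighted by the attention mass its non-padded tiles carry after
#' renormalizing attention across the slide, so every tile contributes
#' exactly once.
#'
#' @param model trained `mil_model`.
#' @param entry feature-store entry for the slide.
#' @param bag_size N.
#' @param threshold probability threshold for the predicted label.
#' @param seed seed for the partition and padding draws.
#' @return list of class `slide_embedding`: `slide_id`, `z_agg`,
#'   `p_slide` (mean bag probability), `predicted_label`, and `attn` — a
#'   data.frame (row, col, idx, attention, bag) over all retained tiles
#'   with attention renormalized to sum to one over the slide.
#' @export
exhaustive_embed <- function(model, entry, bag_size = 50, threshold = 0.5,
                             seed = NULL) {
  tl <- entry$tileset$tiles
  n_tiles <- nrow(tl)
  if (n_tiles == 0L) stop("slide ", entry$slide_id, " has no retained tiles")
  with_seed(seed, {
    perm <- sample.int(n_tiles)
    n_bags <- ceiling(n_tiles / bag_size)
    pad <- n_bags * bag_size - n_tiles
    padded_idx <- if (pad > 0) perm[sample.int(n_tiles, pad, replace = TRUE)]
                  else integer(0)
    seqs <- split(c(perm, padded_idx),
                  rep(seq_len(n_bags), each = bag_size))
    is_pad <- split(c(rep(FALSE, n_tiles), rep(TRUE, pad)),
                    rep(seq_len(n_bags), each = bag_size))
    attn <- numeric(n_tiles)
    bag_of <- integer(n_tiles)
    zs <- matrix(0, n_bags, model$fc_dims[2])
    wts <- numeric(n_bags)
    probs <- numeric(n_bags)
    for (b in seq_len(n_bags)) {
      idx <- seqs[[b]]
      fw <- mil_forward(model, entry$X[idx, , drop = FALSE], train = FALSE)
      probs[b] <- if (model$pooling == "patch") mean(fw$p) else fw$p
      zs[b, ] <- fw$z
      real <- !is_pad[[b]]
      attn[idx[real]] <- fw$a[real] / n_bags
      bag_of[idx[real]] <- b
      wts[b] <- sum(fw$a[real]) / n_bags
    }
    attn <- attn / sum(attn)
    z_agg <- as.numeric(crossprod(zs, wts / sum(wts)))
    p_slide <- mean(probs)
    structure(list(slide_id = entry$slide_id, z_agg = z_agg,
                   p_slide = p_slide,
                   predicted_label = as.integer(p_slide >= threshold),
                   n_bags = n_bags,
                   attn = data.frame(row = tl$row, col = tl$col,
                                     idx = seq_len(n_tiles),
                                     attention = attn, bag = bag_of)),
              class = "slide_embedding")
  })
}

#' Exhaustively embed every slide of a store
#'
#' @param model trained model; `store` a feature store.
#' @param ids slide subset.
#' @param bag_size,threshold,seed see [exhaustive_embed()].
#' @return named list of `slide_embedding`s.
#' @export
embed_cohort <- function(model, store, ids = names(store), bag_size = 50,
                         threshold = 0.5, seed = NULL) {
  with_seed(seed, {
    out <- lapply(ids, function(id) {
      exhaustive_embed(model, store[[id]], bag_size, threshold)
    })
    stats::setNames(out, ids)
  })
}

# Inertia (total within-cluster sum of squares) curve for k = 1..k_max.
inertia_curve <- function(X, k_max, n_init) {
  tot <- sum(sweep(X, 2L, colMeans(X))^2)
  inert <- numeric(k_max)
  inert[1] <- tot
  for (k in 2:k_max) {
    km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 50)
    inert[k] <- km$tot.withinss
  }
  inert
}

# Kneedle-style elbow: the k whose normalized inertia lies farthest below
# the chord joining the curve's endpoints.
elbow_k <- function(inertia) {
  k_max <- length(inertia)
  if (k_max < 3L) return(k_max)
  x <- (seq_len(k_max) - 1) / (k_max - 1)
  rng <- max(inertia) - min(inertia)
  if (rng <= 0) return(1L)
  y <- (inertia - min(inertia)) / rng
  chord <- y[1] + (y[k_max] - y[1]) * x
  which.max(chord - y)
}

#' Cluster slide embeddings with elbow-selected k
#'
#' Runs multi-restart k-means for each k up to `k_max`, picks k at the
#' maximum-curvature (kneedle) point of the inertia curve, and scores each
#' cluster by the fraction of slides predicted positive. Clusters at least
#' 80% predicted-positive or 80% predicted-negative are flagged as highly
#' polarized.
#'
#' @param embeddings named list of `slide_embedding`s, or a numeric matrix
#'   (slides x d) with `predicted` supplied.
#' @param k_max largest k tried (>= 2, < number of slides).
#' @param predicted optional 0/1 predicted labels (taken from the
#'   embeddings by default).
#' @param purity flagging threshold (default 0.8).
#' @param n_init k-means restarts per k.
#' @param seed RNG seed.
#' @return list of class `cluster_report`: `k`, `assignments` (named),
#'   `positive_fraction`, `flagged`, `inertia`, `degenerate`.
#' @export
cluster_slides <- function(embeddings, k_max = 8, predicted = NULL,
                           purity = 0.8, n_init = 10, seed = NULL) {
  if (is.list(embeddings) && !is.matrix(embeddings)) {
    X <- do.call(rbind, lapply(embeddings, function(e) e$z_agg))
    rownames(X) <- names(embeddings)
    if (is.null(predicted)) {
      predicted <- vapply(embeddings, function(e) e$predicted_label,
                          integer(1))
    }
  } else {
    X <- embeddings
  }
  if (nrow(X) < 3L) stop("need at least 3 embeddings to cluster")
  if (k_max < 2L) stop("k_max must be at least 2")
  k_max <- min(k_max, nrow(X) - 1L)
  with_seed(seed, {
    if (all(apply(X, 2L, function(col) diff(range(col))) < 1e-12)) {
      assignments <- stats::setNames(rep(1L, nrow(X)), rownames(X))
      pf <- mean(predicted == 1)
      return(structure(list(k = 1L, assignments = assignments,
                            positive_fraction = c(`1` = pf),
                            flagged = (pf >= purity || pf <= 1 - purity),
                            inertia = NULL, degenerate = TRUE),
                       class = "cluster_report"))
    }
    inertia <- inertia_curve(X, k_max, n_init)
    k <- elbow_k(inertia)
    assignments <- if (k == 1L) rep(1L, nrow(X)) else {
      stats::kmeans(X, centers = k, nstart = n_init, iter.max = 50)$cluster
    }
    names(assignments) <- rownames(X)
    pf <- tapply(predicted == 1, assignments, mean)
    flagged <- pf >= purity | pf <= 1 - purity
    structure(list(k = as.integer(k), assignments = assignments,
                   positive_fraction = pf, flagged = flagged,
                   inertia = inertia, degenerate = FALSE),
              class = "cluster_report")
  })
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Slide clustering: k =", x$k,
      if (x$degenerate) "(degenerate: identical embeddings)" else "", "\n")
  cat("positive fraction per cluster:\n")
  print(round(x$positive_fraction, 3))
  invisible(x)
}

#' Top-attention tiles of each slide
#'
#' Selects, per slide, the `ceiling(fraction * T)` tiles with the highest
#' renormalized attention weight (ties broken by row, then column order).
#'
#' @param embeddings named list of `slide_embedding`s.
#' @param fraction top fraction (default 0.01 — the top 1%).
#' @return data.frame slide_id, row, col, idx, attention.
#' @export
top_attention_tiles <- function(embeddings, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  out <- lapply(embeddings, function(e) {
    at <- e$attn
    k <- ceiling(fraction * nrow(at))
    ord <- order(-at$attention, at$row, at$col)
    sel <- at[ord[seq_len(k)], , drop = FALSE]
    data.frame(slide_id = e$slide_id, sel, row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Tile panels for polarized slide clusters
#'
#' For each flagged slide cluster, k-means is run on the embeddings of the
#' member slides' top-attention tiles; from each tile cluster up to
#' `max_tiles` tiles are shown, each from a distinct slide, ordered by
#' ascending distance to the tile-cluster centroid.
#'
#' @param report a `cluster_report` (uses its flagged clusters).
#' @param top_tiles data.frame from [top_attention_tiles()].
#' @param store feature store (for tile embeddings).
#' @param model trained model (tile embeddings are the 512-d post-FC
#'   features the attention module scores).
#' @param k_tile tile clusters per slide cluster.
#' @param max_tiles tiles per panel (default 5).
#' @param seed RNG seed.
#' @return list of class `tile_panels`: one element per (slide cluster,
#'   tile cluster) with a provenance data.frame slide_id, row, col,
#'   attention, distance.
#' @export
build_panels <- function(report, top_tiles, store, model, k_tile = 2,
                         max_tiles = 5, seed = NULL) {
  flagged <- names(report$flagged)[report$flagged]
  if (length(flagged) == 0L) stop("no flagged clusters to build panels from")
  with_seed(seed, {
    panels <- list()
    for (cl in flagged) {
      members <- names(report$assignments)[report$assignments == as.integer(cl)]
      tt <- top_tiles[top_tiles$slide_id %in% members, , drop = FALSE]
      if (nrow(tt) == 0L) next
      H <- do.call(rbind, lapply(seq_len(nrow(tt)), function(i) {
        e <- store[[tt$slide_id[i]]]
        extract_features(e$X[tt$idx[i], , drop = FALSE], model)
      }))
      if (nrow(tt) < 2L) {
        warning("cluster ", cl, " has fewer than 2 top tiles; ",
                "single-tile panel")
        panels[[paste0("slide_cluster_", cl, "_tiles_1")]] <-
          data.frame(tt[, c("slide_id", "row", "col", "attention")],
                     distance = 0, row.names = NULL)
        next
      }
      kk <- min(k_tile, nrow(tt) - 1L)
      km <- stats::kmeans(H, centers = kk, nstart = 5, iter.max = 50)
      for (tc in seq_len(kk)) {
        in_tc <- which(km$cluster == tc)
        d <- sqrt(rowSums((H[in_tc, , drop = FALSE] -
                           matrix(km$centers[tc, ], length(in_tc),
                                  ncol(H), byrow = TRUE))^2))
        ord <- in_tc[order(d)]
        seen <- character(0); pick <- integer(0)
        for (j in seq_along(ord)) {
          sid <- tt$slide_id[ord[j]]
          if (sid %in% seen) next
          seen <- c(seen, sid); pick <- c(pick, ord[j])
          if (length(pick) == max_tiles) break
        }
        panels[[paste0("slide_cluster_", cl, "_tiles_", tc)]] <-
          data.frame(tt[pick, c("slide_id", "row", "col", "attention")],
                     distance = sqrt(rowSums((H[pick, , drop = FALSE] -
                       matrix(km$centers[tc, ], length(pick), ncol(H),
                              byrow = TRUE))^2)),
                     row.names = NULL)
      }
    }
    structure(panels, class = "tile_panels")
  })
}

#' Export tile panels as PNGs with a provenance table
#'
#' @param panels a `tile_panels`.
#' @param slides named list of slide arrays.
#' @param tile_size tile edge in pixels.
#' @param out_dir output directory (`panels/<name>_<i>.png` +
#'   `provenance.csv`).
#' @export
export_panels <- function(panels, slides, tile_size, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  for (nm in names(panels)) {
    pn <- panels[[nm]]
    for (i in seq_len(nrow(pn))) {
      tile <- get_tile(slides[[pn$slide_id[i]]], pn$row[i], pn$col[i],
                       tile_size)
      write_image(tile, file.path(out_dir, sprintf("%s_%d.png", nm, i)))
    }
    prov[[nm]] <- data.frame(panel = nm, rank = seq_len(nrow(pn)), pn,
                             row.names = NULL)
  }
  prov <- do.call(rbind, c(prov, list(make.row.names = FALSE)))
  utils::write.csv(prov, file.path(out_dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(prov)
}

#' Attention heatmap overlay
#'
#' Paints each tile footprint with an intensity proportional to its
#' min-max-normalized attention weight (red overlay), and outlines tiles
#' above the given attention quantile (the default 0.99 marks the top 1%).
#'
#' @param embedding a `slide_embedding`.
#' @param img the slide image.
#' @param tile_size tile edge in pixels.
#' @param quantile contour quantile on the normalized attention.
#' @param alpha maximum overlay opacity.
#' @return 8-bit RGB overlay image array; the normalized per-tile
#'   attention matrix is attached as attribute `"attention_grid"`.
#' @export
attention_heatmap <- function(embedding, img, tile_size, quantile = 0.99,
                              alpha = 0.5) {
  at <- embedding$attn
  rng <- range(at$attention)
  norm <- if (diff(rng) <= 0) rep(1, nrow(at)) else
    (at$attention - rng[1]) / diff(rng)
  out <- img
  grid <- matrix(NA_real_, max(at$row) + 1L, max(at$col) + 1L)
  cut <- stats::quantile(norm, quantile, names = FALSE, type = 7)
  overlay_col <- c(255, 40, 40)
  border_col <- c(40, 60, 255)
  for (i in seq_len(nrow(at))) {
    r0 <- at$row[i] * tile_size; c0 <- at$col[i] * tile_size
    rows <- (r0 + 1L):(r0 + tile_size); cols <- (c0 + 1L):(c0 + tile_size)
    wgt <- alpha * norm[i]
    for (ch in 1:3) {
      out[rows, cols, ch] <- (1 - wgt) * out[rows, cols, ch] +
        wgt * overlay_col[ch]
    }
    grid[at$row[i] + 1L, at$col[i] + 1L] <- norm[i]
    if (norm[i] >= cut) {
      edge <- c(rows[1:2], rows[(tile_size - 1):tile_size])
      for (ch in 1:3) {
        out[edge, cols, ch] <- border_col[ch]
        out[rows, c(cols[1:2], cols[(tile_size - 1):tile_size]), ch] <-
          border_col[ch]
      }
    }
  }
  attr(out, "attention_grid") <- grid
  out
}
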