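# Interpretability workflow: exhaustive embeddings, elbow clustering,
# top-attention tiles, panels and heatmaps.

fake_embedding <- function(slide_id, attention, grid = NULL) {
  n <- length(attention)
  if (is.null(grid)) grid <- ceiling(sqrt(n))
  structure(list(slide_id = slide_id, z_agg = rnorm(4), p_slide = 0.5,
                 predicted_label = 1L, n_bags = 1L,
                 attn = data.frame(row = (seq_len(n) - 1) %/% grid,
                                   col = (seq_len(n) - 1) %% grid,
                                   idx = seq_len(n),
                                   attention = attention, bag = 1L)),
            class = "slide_embedding")
}

test_that("exhaustive embedding partitions tiles exactly once", {
  fx <- small_cohort(n_slides = 6, grid = 8, tile_size = 32)
  m <- mil_model(backbone = backbone_config(32), seed = 1)
  m <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  entry <- fx$store[[1]]
  n_tiles <- nrow(entry$tileset$tiles)

  # slide with exactly N tiles: one bag, embedding equals the bag aggregate
  e1 <- exhaustive_embed(m, entry, bag_size = n_tiles, seed = 2)
  expect_equal(e1$n_bags, 1L)
  bp <- predict_bag(m, entry$X)
  expect_equal(e1$z_agg, bp$z, tolerance = 1e-12)
  expect_equal(e1$p_slide, bp$p, tolerance = 1e-12)

  # 2N tiles -> two bags, every tile exactly once
  e2 <- exhaustive_embed(m, entry, bag_size = ceiling(n_tiles / 2), seed = 3)
  expect_equal(e2$n_bags, 2L)
  expect_setequal(e2$attn$idx, seq_len(n_tiles))
  expect_false(any(duplicated(e2$attn$idx)))
  expect_equal(sum(e2$attn$attention), 1, tolerance = 1e-9)
})

test_that("embedding is stable under tile reordering", {
  fx <- small_cohort(n_slides = 6, grid = 8, tile_size = 32)
  m <- mil_model(backbone = backbone_config(32), seed = 4)
  m <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  entry <- fx$store[[1]]
  base <- exhaustive_embed(m, entry, bag_size = 12, seed = 5)
  shifts <- sapply(1:10, function(s) {
    perm <- exhaustive_embed(m, entry, bag_size = 12, seed = 100 + s)
    sqrt(sum((perm$z_agg - base$z_agg)^2)) / sqrt(sum(base$z_agg^2))
  })
  expect_lt(mean(shifts), 0.10)
})

test_that("elbow clustering finds three separated blobs", {
  set.seed(6)
  centers <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(40, sd = 0.1), 20, 2), 2, centers[k, ], "+")
  }))
  rownames(X) <- paste0("s", 1:60)
  rep <- cluster_slides(X, k_max = 8, predicted = rep(1, 60), seed = 7)
  expect_equal(rep$k, 3L)
  # inertia curve oracle: the chosen k is the kneedle point
  expect_equal(rep$k, wsimil:::elbow_k(rep$inertia))
  sizes <- sort(unname(table(rep$assignments)))
  expect_equal(as.integer(sizes), rep(20L, 3))
})

test_that("identical embeddings degenerate to a single cluster", {
  X <- matrix(1, 10, 4)
  rownames(X) <- paste0("s", 1:10)
  rep <- cluster_slides(X, k_max = 5, predicted = rep(c(1, 0), 5), seed = 1)
  expect_true(rep$degenerate)
  expect_equal(rep$k, 1L)
})

test_that("cluster purity is scored from predicted labels", {
  set.seed(8)
  X <- rbind(matrix(rnorm(10, sd = 0.05), 5, 2),
             matrix(rnorm(10, sd = 0.05) + 5, 5, 2))
  rownames(X) <- paste0("s", 1:10)
  predicted <- c(1, 1, 1, 1, 0,  0, 0, 0, 0, 0)
  rep <- cluster_slides(X, k_max = 5, predicted = predicted, seed = 9)
  expect_equal(rep$k, 2L)
  pf <- sort(as.numeric(rep$positive_fraction))
  expect_equal(pf, c(0, 0.8))
  expect_true(all(rep$flagged))               # 0.8-positive and 1.0-negative
  # self-consistency: fractions recompute exactly from the assignments
  for (cl in names(rep$positive_fraction)) {
    members <- names(rep$assignments)[rep$assignments == as.integer(cl)]
    expect_equal(unname(rep$positive_fraction[cl]),
                 mean(predicted[match(members, rownames(X))] == 1))
  }
})

test_that("top-attention selection uses the ceiling rule and tie order", {
  set.seed(10)
  e200 <- fake_embedding("a", runif(200))
  expect_equal(nrow(top_attention_tiles(list(a = e200), 0.01)), 2)
  e50 <- fake_embedding("b", runif(50))
  expect_equal(nrow(top_attention_tiles(list(b = e50), 0.01)), 1)

  # ties broken by (row, col) order
  etie <- fake_embedding("c", rep(0.25, 4), grid = 2)
  tt <- top_attention_tiles(list(c = etie), 0.5)
  expect_equal(tt$row, c(0, 0))
  expect_equal(tt$col, c(0, 1))

  top <- top_attention_tiles(list(a = e200), 0.05)
  expect_true(all(top$attention >= sort(e200$attn$attention,
                                        decreasing = TRUE)[10]))
})

test_that("panels pick up to five tiles from distinct slides by distance", {
  fx <- small_cohort(n_slides = 10, grid = 4, tile_size = 32,
                     background_fraction = 0)
  m <- mil_model(backbone = backbone_config(32), seed = 11)
  m <- fit_feature_scaling(m, do.call(rbind, lapply(fx$store, `[[`, "X")))
  emb <- embed_cohort(m, fx$store, bag_size = 16, seed = 12)
  ids <- names(emb)
  report <- structure(list(
    k = 1L,
    assignments = setNames(rep(1L, length(ids)), ids),
    positive_fraction = c(`1` = 1),
    flagged = c(`1` = TRUE), degenerate = FALSE),
    class = "cluster_report")
  tt <- top_attention_tiles(emb, fraction = 0.07)   # one tile per slide
  panels <- build_panels(report, tt, fx$store, m, k_tile = 1, seed = 13)
  pn <- panels[[1]]
  expect_lte(nrow(pn), 5)
  expect_false(any(duplicated(pn$slide_id)))
  expect_equal(pn$distance, sort(pn$distance))      # ascending centroid order
  # provenance maps back into each slide's TileSet
  for (i in seq_len(nrow(pn))) {
    tl <- fx$store[[pn$slide_id[i]]]$tileset$tiles
    expect_true(any(tl$row == pn$row[i] & tl$col == pn$col[i]))
  }
  # determinism
  panels2 <- build_panels(report, tt, fx$store, m, k_tile = 1, seed = 13)
  expect_identical(panels, panels2)

  # single-tile cluster warns and still produces a panel
  solo <- report
  solo$assignments <- setNames(1L, ids[1])
  expect_warning(p1 <- build_panels(solo, tt[tt$slide_id == ids[1], ],
                                    fx$store, m, seed = 1),
                 "fewer than 2")
  expect_equal(nrow(p1[[1]]), 1)
})

test_that("panel export writes tiles and provenance", {
  fx <- small_cohort(n_slides = 6, grid = 4, tile_size = 32,
                     background_fraction = 0)
  pn <- structure(list(panel_a = data.frame(
    slide_id = names(fx$store)[1:2], row = c(0, 1), col = c(0, 1),
    attention = c(0.3, 0.2), distance = c(0.1, 0.4))),
    class = "tile_panels")
  d <- withr::local_tempdir()
  prov <- export_panels(pn, fx$cohort$slides, 32, d)
  expect_true(file.exists(file.path(d, "panel_a_1.png")))
  expect_true(file.exists(file.path(d, "provenance.csv")))
  expect_equal(nrow(prov), 2)
})

test_that("heatmaps paint footprints and honor the contour quantile", {
  img <- array(200, c(64, 64, 3))
  flat <- fake_embedding("a", rep(0.25, 4), grid = 2)
  hm <- attention_heatmap(flat, img, 32, quantile = 0.99)
  grid <- attr(hm, "attention_grid")
  expect_true(all(grid == 1))                 # uniform -> flat (degenerate)

  onehot <- fake_embedding("b", c(1, 0, 0, 0) + 1e-6, grid = 2)
  hm2 <- attention_heatmap(onehot, img, 32, quantile = 0.75)
  g2 <- attr(hm2, "attention_grid")
  expect_equal(which(g2 >= 0.999), 1L)        # single highlighted footprint
  # the hot tile's red channel rises, its blue channel drops
  expect_gt(mean(hm2[3:30, 3:30, 1]), mean(img[3:30, 3:30, 1]) - 1)
  expect_lt(mean(hm2[3:30, 3:30, 3]), mean(img[3:30, 3:30, 3]))
})
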