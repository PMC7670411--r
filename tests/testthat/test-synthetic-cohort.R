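# Synthetic cohort generator: tile renderers, label contracts, ground-truth
# invariants, determinism and class separability.

test_that("tile renderers respect kind contracts", {
  expect_error(render_tile("tumor"), "unknown tile kind")

  set.seed(1)
  bg <- render_tile("background", 32)
  expect_true(all(bg >= 230))

  set.seed(2)
  for (kind in c("negative_tissue", "positive_tissue")) {
    tl <- render_tile(kind, 32)
    expect_equal(dim(tl), c(32, 32, 3))
    expect_true(any(attr(tl, "object_mask")))   # at least one object
    expect_true(all(tl >= 0 & tl <= 255))
  }
})

test_that("rendering is deterministic given the RNG state", {
  set.seed(42); a <- render_tile("positive_tissue", 32, noise_sd = 3)
  set.seed(42); b <- render_tile("positive_tissue", 32, noise_sd = 3)
  expect_identical(a, b)
})

test_that("positive objects are smaller than negative objects", {
  # independent oracle: connected-component labeling of the object masks
  set.seed(3)
  d_pos <- replicate(20, mean_object_diameter(
    attr(render_tile("positive_tissue", 64), "object_mask")))
  d_neg <- replicate(20, mean_object_diameter(
    attr(render_tile("negative_tissue", 64), "object_mask")))
  expect_lt(mean(d_pos), mean(d_neg))
})

test_that("object-size signal separates the classes (t-test)", {
  set.seed(4)
  d_pos <- replicate(50, mean_object_diameter(
    attr(render_tile("positive_tissue", 64), "object_mask")))
  d_neg <- replicate(50, mean_object_diameter(
    attr(render_tile("negative_tissue", 64), "object_mask")))
  expect_lt(t.test(d_pos, d_neg)$p.value, 0.001)
})

test_that("generate_cohort honors prevalence, witness rate and grid", {
  spec <- cohort_spec(n_slides = 10, prevalence = 0.5, witness_rate = 0.1,
                      grid_rows = 8, grid_cols = 8, tile_size = 32,
                      background_fraction = 0.25, seed = 7)
  co <- generate_cohort(spec)
  expect_equal(sum(co$labels$label), 5)
  for (id in co$labels$slide_id) {
    kinds <- co$tiles$kind[co$tiles$slide_id == id]
    n_tissue <- sum(kinds != "background")
    n_pos <- sum(kinds == "positive_tissue")
    if (co$labels$label[co$labels$slide_id == id] == 1) {
      expect_gte(n_pos, 1)
      expect_equal(n_pos, max(1, round(0.1 * n_tissue)))
    } else {
      expect_equal(n_pos, 0)
    }
    # mosaic dimensions
    expect_equal(dim(co$slides[[id]]), c(8 * 32, 8 * 32, 3))
  }
})

test_that("degenerate and saturated cohort settings behave as specified", {
  co0 <- generate_cohort(cohort_spec(n_slides = 4, prevalence = 0,
                                     grid_rows = 3, grid_cols = 3,
                                     tile_size = 32, seed = 1))
  expect_true(all(co0$labels$label == 0))
  expect_false(any(co0$tiles$kind == "positive_tissue"))

  co1 <- generate_cohort(cohort_spec(n_slides = 4, prevalence = 1,
                                     witness_rate = 1,
                                     background_fraction = 0,
                                     grid_rows = 3, grid_cols = 3,
                                     tile_size = 32, seed = 1))
  expect_true(all(co1$tiles$kind == "positive_tissue"))

  expect_warning(
    generate_cohort(cohort_spec(n_slides = 10, prevalence = 0.04,
                                grid_rows = 2, grid_cols = 2,
                                tile_size = 32, seed = 1)),
    "0 positive")
})

test_that("ground-truth invariants hold across random specs", {
  set.seed(99)
  for (i in 1:100) {
    spec <- cohort_spec(
      n_slides = sample(2:5, 1), prevalence = runif(1),
      witness_rate = runif(1, 0.05, 1),
      grid_rows = sample(2:4, 1), grid_cols = sample(2:4, 1),
      tile_size = 32, background_fraction = runif(1, 0, 0.6),
      noise_sd = runif(1, 0, 5), seed = sample.int(1e6, 1))
    co <- suppressWarnings(generate_cohort(spec))
    for (id in co$labels$slide_id) {
      n_pos <- sum(co$tiles$kind[co$tiles$slide_id == id] == "positive_tissue")
      if (co$labels$label[co$labels$slide_id == id] == 1) {
        expect_gte(n_pos, 1)
      } else {
        expect_equal(n_pos, 0)
      }
    }
  }
})

test_that("identical spec + seed reproduces the cohort byte for byte", {
  spec <- cohort_spec(n_slides = 3, grid_rows = 3, grid_cols = 3,
                      tile_size = 32, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$tiles, b$tiles)
  expect_identical(a$slides, b$slides)

  # on-disk artifacts too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(spec, out_dir = d1)
  generate_cohort(spec, out_dir = d2)
  expect_identical(readBin(file.path(d1, "labels.csv"), "raw", 1e6),
                   readBin(file.path(d2, "labels.csv"), "raw", 1e6))
  f1 <- file.path(d1, "slides", "slide_001.png")
  f2 <- file.path(d2, "slides", "slide_001.png")
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})

test_that("written cohort round-trips through PNG exactly", {
  spec <- cohort_spec(n_slides = 2, grid_rows = 2, grid_cols = 2,
                      tile_size = 32, seed = 5)
  d <- withr::local_tempdir()
  co <- generate_cohort(spec, out_dir = d)
  back <- read_image(file.path(d, "slides", "slide_001.png"))
  expect_equal(back, co$slides[["slide_001"]], ignore_attr = TRUE)
  lab <- read.csv(file.path(d, "labels.csv"))
  expect_equal(names(lab), c("slide_id", "patient_id", "label"))
})

test_that("contiguous witness placement yields a connected region", {
  spec <- cohort_spec(n_slides = 4, prevalence = 1, witness_rate = 0.3,
                      grid_rows = 5, grid_cols = 5, tile_size = 32,
                      background_fraction = 0, seed = 11,
                      contiguous_witness = TRUE)
  co <- generate_cohort(spec)
  for (id in co$labels$slide_id) {
    wt <- co$tiles[co$tiles$slide_id == id &
                   co$tiles$kind == "positive_tissue", ]
    # breadth-first search over 4-neighbor adjacency reaches every witness
    key <- paste(wt$row, wt$col)
    seen <- 1L; frontier <- 1L
    while (length(frontier)) {
      cur <- frontier[1]; frontier <- frontier[-1]
      nb <- match(paste(wt$row[cur] + c(-1, 1, 0, 0),
                        wt$col[cur] + c(0, 0, -1, 1)), key)
      nb <- nb[!is.na(nb) & !(nb %in% seen)]
      seen <- c(seen, nb); frontier <- c(frontier, nb)
    }
    expect_equal(sort(seen), seq_len(nrow(wt)))
  }
})
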