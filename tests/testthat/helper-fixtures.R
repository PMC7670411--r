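# Shared fixtures: small seeded cohorts, feature stores and score models.

# A small cohort + tilesets + feature store, memoised per parameter set so
# multiple test files can share the expensive backbone pass.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(n_slides = 10, witness_rate = 0.2, seed = 7,
                         grid = 4, tile_size = 32,
                         background_fraction = 0.25, prevalence = 0.5) {
  key <- paste(n_slides, witness_rate, seed, grid, tile_size,
               background_fraction, prevalence, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    spec <- cohort_spec(n_slides = n_slides, prevalence = prevalence,
                        witness_rate = witness_rate, grid_rows = grid,
                        grid_cols = grid, tile_size = tile_size,
                        background_fraction = background_fraction,
                        seed = seed)
    co <- generate_cohort(spec)
    ts <- tile_cohort(co)
    store <- build_feature_store(co, ts)
    .fixture_env[[key]] <- list(cohort = co, tilesets = ts, store = store)
  }
  .fixture_env[[key]]
}

# Binormal score model with a given true AUC: positives N(mu, 1),
# negatives N(0, 1), mu = sqrt(2) * qnorm(auc).
binormal_scores <- function(n1, n0, true_auc) {
  mu <- sqrt(2) * qnorm(true_auc)
  list(scores = c(rnorm(n1, mu), rnorm(n0)),
       labels = rep(c(1, 0), c(n1, n0)))
}

# Brute-force all-pairs AUC oracle (ties count one half).
auc_oracle <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# Exhaustive-scan Otsu oracle: maximize between-class variance over all
# 256 candidate thresholds directly from the definition.
otsu_oracle <- function(counts) {
  n <- sum(counts)
  lev <- 0:255
  best <- -Inf; best_t <- 0L
  for (t in 0:255) {
    in0 <- lev <= t
    w0 <- sum(counts[in0]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[in0] * lev[in0]) / sum(counts[in0])
    mu1 <- sum(counts[!in0] * lev[!in0]) / sum(counts[!in0])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# Mean equivalent diameter of connected components in a logical mask
# (EBImage labeling as the independent oracle).
mean_object_diameter <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(lab[lab > 0]))
  sizes <- sizes[sizes > 0]
  mean(sqrt(4 * sizes / pi))
}

# Ground-truth tile kind lookup for a cohort.
tile_kind <- function(cohort, slide_id, row, col) {
  gt <- cohort$tiles
  gt$kind[gt$slide_id == slide_id & gt$row == row & gt$col == col]
}
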