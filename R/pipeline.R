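# End-to-end pipeline orchestration: simulate -> tile -> train -> predict
# -> evaluate -> interpret, with every stage seeded so a rerun with the
# same seeds reproduces labels.csv, preds.csv and the evaluation JSON byte
# for byte.

#' Run the full synthetic pipeline
#'
#' Generates a cohort, tiles it, trains the MIL model on a patient-grouped
#' split, predicts the held-out slides by multi-bag aggregation, writes an
#' evaluation report, and (optionally) the interpretability outputs.
#' Deterministic given `spec$seed` and `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory; receives `labels.csv`, `preds.csv`,
#'   `eval.json` (and `embeddings.csv`, `clusters.json` when
#'   `interpret = TRUE`).
#' @param cfg a [train_config()] (default [desk_config()]).
#' @param holdout_fraction test fraction for the patient-grouped split.
#' @param n_bags bags per slide at test time.
#' @param threshold evaluation threshold.
#' @param interpret also run clustering/top-tile interpretability on the
#'   held-out slides.
#' @param seed master seed for split/predict/evaluate stages.
#' @return list with the fit, predictions, report and file paths.
#' @export
run_pipeline <- function(spec, out_dir, cfg = desk_config(),
                         holdout_fraction = 0.25, n_bags = 8,
                         threshold = 0.25, interpret = FALSE, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec, out_dir = out_dir)
  tilesets <- tile_cohort(cohort)
  store <- build_feature_store(cohort, tilesets)
  plan <- make_splits(cohort$labels, k = 5,
                      holdout_fraction = holdout_fraction, seed = seed)
  test_ids <- plan$slides$slide_id[plan$slides$fold == 0L]
  train_ids <- setdiff(names(store), test_ids)
  model <- mil_model(d0 = backbone_config()$d0,
                     backbone = backbone_config(tile_size = spec$tile_size),
                     seed = cfg$seed)
  fit <- train_mil(model, store, cfg, train_ids = train_ids,
                   slides = cohort$slides)
  preds <- predict_cohort(fit$model, store, ids = test_ids,
                          n_bags = n_bags, bag_size = cfg$bag_size,
                          seed = seed + 1L)
  utils::write.csv(preds, file.path(out_dir, "preds.csv"),
                   row.names = FALSE, quote = FALSE)
  y <- stats::setNames(cohort$labels$label, cohort$labels$slide_id)
  report <- evaluate_predictions(preds$p_slide, unname(y[preds$slide_id]),
                                 threshold = threshold, B = 200,
                                 seed = seed + 2L)
  write_eval_report(report, file.path(out_dir, "eval.json"))
  out <- list(cohort = cohort, store = store, plan = plan, fit = fit,
              preds = preds, report = report,
              paths = list(labels = file.path(out_dir, "labels.csv"),
                           preds = file.path(out_dir, "preds.csv"),
                           eval = file.path(out_dir, "eval.json")))
  if (interpret) {
    emb <- embed_cohort(fit$model, store, ids = test_ids,
                        bag_size = cfg$bag_size, seed = seed + 3L)
    cl <- cluster_slides(emb, k_max = min(8, length(emb) - 1L),
                         seed = seed + 4L)
    tt <- top_attention_tiles(emb, fraction = 0.01)
    embdf <- data.frame(slide_id = names(emb),
                        p_slide = vapply(emb, `[[`, numeric(1), "p_slide"),
                        predicted = vapply(emb, `[[`, integer(1),
                                           "predicted_label"))
    utils::write.csv(embdf, file.path(out_dir, "embeddings.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(k = cl$k,
           assignments = as.list(cl$assignments),
           positive_fraction = as.list(cl$positive_fraction),
           flagged = as.list(cl$flagged)),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    out$embeddings <- emb
    out$clusters <- cl
    out$top_tiles <- tt
  }
  out
}
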