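# Training protocol and slide-level inference.
#
# One epoch presents a balanced (50-50) sequence of slides; each slide
# contributes one freshly sampled bag. Bags are scored by the MIL network,
# the binary cross-entropy loss is backpropagated, and parameters are
# updated with Adam (L2 weight decay folded into the gradient). At the end
# of each epoch the highest-loss bags are revisited once more
# (hard-negative mining). At test time a slide's probability is the
# aggregate (mean by default) of several independently sampled bags.

#' Training configuration
#'
#' Defaults are the reference protocol: Adam with learning rate 1e-5 and
#' weight decay 5e-5 for 500 epochs, bag size 50, balanced sampling,
#' hard-negative mining, full augmentation with mean-pixel replacement at
#' probability 0.75. See [desk_config()] for the small-scale preset used
#' throughout the examples and tests.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient (added to gradients).
#' @param epochs training epochs.
#' @param bag_size tiles per bag (N).
#' @param balanced use exact 50-50 balanced sampling per epoch.
#' @param hard_negative_r retention fraction r for hard-negative mining:
#'   the top `ceiling(r * B)` highest-loss bags of each epoch get one extra
#'   update; 0 disables mining.
#' @param augment apply the augmentation stack to training tiles (requires
#'   slide images at train time).
#' @param aug augmentation settings, an [augment_config()].
#' @param val_bags bags per slide when scoring a validation split each
#'   epoch.
#' @param seed RNG seed for the whole run.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 5e-5,
                         epochs = 500, bag_size = 50, balanced = TRUE,
                         hard_negative_r = 0.25, augment = TRUE,
                         aug = augment_config(), val_bags = 4, seed = 1) {
  stopifnot(learning_rate >= 0, weight_decay >= 0, epochs >= 1,
            bag_size >= 1, hard_negative_r >= 0, hard_negative_r <= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), bag_size = as.integer(bag_size),
                 balanced = balanced, hard_negative_r = hard_negative_r,
                 augment = augment, aug = aug, val_bags = val_bags,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' A CPU-minutes configuration for synthetic cohorts: 40 epochs, bag size
#' 20, learning rate 1e-3 (the head trains from scratch for few epochs),
#' weight decay 5e-5, mining r = 0.25, augmentation off. The protocol
#' structure (balanced sampling, mining, Adam + BCE) is unchanged.
#'
#' @param ... overrides passed to [train_config()].
#' @export
desk_config <- function(...) {
  args <- list(learning_rate = 1e-3, epochs = 40L, bag_size = 20L,
               augment = FALSE,
               aug = augment_config(cutout_length = 0, mean_pixel_prob = 0))
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

#' Precompute backbone descriptors for a cohort
#'
#' Runs the fixed backbone over every retained tile of every slide once;
#' training and inference then operate on cached descriptor matrices.
#'
#' @param cohort `mil_cohort` (or named list of slide arrays).
#' @param tilesets named list of `TileSet`s.
#' @param backbone a [backbone_config()].
#' @param labels optional named 0/1 vector (defaults to cohort labels).
#' @return named list of entries: `slide_id`, `X` (tiles x d0), `tileset`,
#'   `label`.
#' @export
build_feature_store <- function(cohort, tilesets,
                                backbone = NULL, labels = NULL) {
  slides <- if (inherits(cohort, "mil_cohort")) cohort$slides else cohort
  if (is.null(labels) && inherits(cohort, "mil_cohort")) {
    labels <- stats::setNames(cohort$labels$label, cohort$labels$slide_id)
  }
  if (is.null(backbone)) {
    backbone <- backbone_config(tile_size = tilesets[[1]]$tile_size)
  }
  out <- lapply(names(tilesets), function(id) {
    ts <- tilesets[[id]]
    img <- slides[[id]]
    tiles <- lapply(seq_len(nrow(ts$tiles)), function(i) {
      get_tile(img, ts$tiles$row[i], ts$tiles$col[i], ts$tile_size)
    })
    X <- if (length(tiles)) backbone_matrix(tiles, backbone)
         else matrix(0, 0L, backbone$d0)
    list(slide_id = id, X = X, tileset = ts,
         label = if (!is.null(labels)) unname(labels[id]) else NA_integer_)
  })
  stats::setNames(out, names(tilesets))
}

# One Adam update; state holds first/second moments and the step counter.
adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' Select hard negatives from per-bag losses
#'
#' Returns the indices of the `ceiling(r * B)` highest-loss bags of an
#' epoch (ties resolved by earlier position), which are re-enqueued for one
#' extra update each at epoch end.
#'
#' @param losses per-bag losses seen this epoch.
#' @param r retention fraction in (0, 1].
#' @return integer indices into `losses`.
#' @export
hard_negative_step <- function(losses, r) {
  if (length(losses) == 0L) stop("no bags seen this epoch")
  if (r <= 0 || r > 1) stop("retention fraction r must be in (0, 1]")
  k <- ceiling(r * length(losses))
  order(losses, decreasing = TRUE)[seq_len(k)]
}

# Assemble the (possibly augmented) descriptor matrix for one bag.
bag_descriptors <- function(entry, bag, cfg, slides) {
  if (!cfg$augment && cfg$aug$mean_pixel_prob == 0) {
    return(entry$X[bag$coords$idx, , drop = FALSE])
  }
  img <- slides[[entry$slide_id]]
  ts <- entry$tileset$tile_size
  tiles <- lapply(seq_len(nrow(bag$coords)), function(i) {
    tl <- get_tile(img, bag$coords$row[i], bag$coords$col[i], ts)
    if (cfg$augment) tl <- augment_tile(tl, cfg$aug)
    tl
  })
  if (cfg$aug$mean_pixel_prob > 0) {
    tiles <- mean_pixel_replace(tiles, cfg$aug)$tiles
  }
  bb <- backbone_config(tile_size = ts)
  backbone_matrix(tiles, bb)
}

#' Train a MIL model
#'
#' Runs the training protocol: per epoch a balanced slide ordering, one
#' fresh bag per slide visit, BCE loss, Adam updates, then one extra
#' update for each of the epoch's hardest bags. Feature standardization is
#' fit from the training slides on the first call. Fully seeded: the same
#' store, config and seed reproduce the run exactly.
#'
#' @param model a `mil_model`.
#' @param store feature store from [build_feature_store()].
#' @param cfg a [train_config()].
#' @param train_ids slide ids to train on (default: all with a 0/1 label).
#' @param val_ids optional validation slide ids; when given, the returned
#'   model is the checkpoint with the best validation AUC.
#' @param slides named list of slide arrays; required when
#'   `cfg$augment` or mean-pixel replacement is on.
#' @return list of class `mil_fit`: `model` (trained), `history`
#'   (data.frame epoch/loss/train_auc/val_auc), `cfg`.
#' @export
train_mil <- function(model, store, cfg = train_config(),
                      train_ids = NULL, val_ids = NULL, slides = NULL) {
  if (is.null(train_ids)) {
    train_ids <- names(store)[vapply(store, function(e) !is.na(e$label),
                                     logical(1))]
  }
  labels <- vapply(store[train_ids], function(e) as.numeric(e$label),
                   numeric(1))
  if (length(unique(labels)) < 2L) {
    stop("training cohort must contain both classes")
  }
  needs_images <- cfg$augment || cfg$aug$mean_pixel_prob > 0
  if (needs_images && is.null(slides)) {
    stop("augmentation/mean-pixel replacement needs slide images; ",
         "pass `slides` or disable them")
  }
  with_seed(cfg$seed, {
    if (is.null(model$feat_center)) {
      Xall <- do.call(rbind, lapply(store[train_ids], function(e) e$X))
      model <- fit_feature_scaling(model, Xall)
    }
    state <- adam_init(model$params)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       train_auc = numeric(), val_auc = numeric())
    best <- list(auc = -Inf, params = model$params)
    for (ep in seq_len(cfg$epochs)) {
      order_ids <- if (cfg$balanced) balanced_epoch(labels)
                   else sample(names(labels))
      bag_losses <- numeric(0)
      bag_store <- list()
      probs <- numeric(0); ys <- numeric(0)
      for (sid in order_ids) {
        entry <- store[[sid]]
        bag <- sample_bag(entry$tileset, cfg$bag_size, entry$label)
        Xb <- bag_descriptors(entry, bag, cfg, slides)
        fw <- mil_forward(model, Xb, train = TRUE)
        loss <- bce_loss(fw, entry$label)
        if (!is.finite(loss)) {
          stop("non-finite loss at epoch ", ep, ", slide ", sid,
               "; aborting (check learning rate / inputs)")
        }
        gr <- mil_backward(model, fw, entry$label)
        upd <- adam_step(model$params, gr, state, cfg$learning_rate,
                         cfg$weight_decay)
        model$params <- upd$params; state <- upd$state
        bag_losses <- c(bag_losses, loss)
        bag_store[[length(bag_losses)]] <- list(X = Xb, y = entry$label)
        probs <- c(probs, if (model$pooling == "patch") mean(fw$p) else fw$p)
        ys <- c(ys, entry$label)
      }
      if (cfg$hard_negative_r > 0) {
        hard <- hard_negative_step(bag_losses, cfg$hard_negative_r)
        for (i in hard) {
          fw <- mil_forward(model, bag_store[[i]]$X, train = TRUE)
          gr <- mil_backward(model, fw, bag_store[[i]]$y)
          upd <- adam_step(model$params, gr, state, cfg$learning_rate,
                           cfg$weight_decay)
          model$params <- upd$params; state <- upd$state
        }
      }
      val_auc <- NA_real_
      if (!is.null(val_ids) && length(val_ids)) {
        vp <- vapply(val_ids, function(id) {
          predict_slide(model, store[[id]], n_bags = cfg$val_bags,
                        bag_size = cfg$bag_size)$p_slide
        }, numeric(1))
        vy <- vapply(store[val_ids], function(e) as.numeric(e$label),
                     numeric(1))
        val_auc <- if (length(unique(vy)) == 2L) auc(vp, vy) else NA_real_
        if (!is.na(val_auc) && val_auc > best$auc) {
          best <- list(auc = val_auc, params = model$params)
        }
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = mean(bag_losses),
        train_auc = if (length(unique(ys)) == 2L) auc(probs, ys) else NA_real_,
        val_auc = val_auc))
    }
    if (!is.null(val_ids) && is.finite(best$auc)) model$params <- best$params
    structure(list(model = model, history = hist, cfg = cfg),
              class = "mil_fit")
  })
}

#' Slide-level prediction by multi-bag aggregation
#'
#' Samples `n_bags` un-augmented bags from the slide, scores each, and
#' aggregates the bag probabilities (mean by default).
#'
#' @param model trained `mil_model`.
#' @param entry one feature-store entry (from [build_feature_store()]).
#' @param n_bags number of bags.
#' @param bag_size tiles per bag.
#' @param agg_rule `"mean"` or `"median"`.
#' @param seed optional seed for the bag draws.
#' @return list of class `slide_prediction`: `slide_id`, `p_slide`,
#'   `bag_probs`, `n_bags`, `agg_rule`.
#' @export
predict_slide <- function(model, entry, n_bags = 16, bag_size = 50,
                          agg_rule = c("mean", "median"), seed = NULL) {
  agg_rule <- match.arg(agg_rule)
  with_seed(seed, {
    bp <- vapply(seq_len(n_bags), function(i) {
      bag <- sample_bag(entry$tileset, bag_size, entry$label)
      if (model$pooling == "patch") {
        mean(mil_forward(model, entry$X[bag$coords$idx, , drop = FALSE])$p)
      } else {
        mil_forward(model, entry$X[bag$coords$idx, , drop = FALSE])$p
      }
    }, numeric(1))
    p <- if (agg_rule == "mean") mean(bp) else stats::median(bp)
    structure(list(slide_id = entry$slide_id, p_slide = p, bag_probs = bp,
                   n_bags = n_bags, agg_rule = agg_rule),
              class = "slide_prediction")
  })
}

#' Predict every slide of a store
#'
#' @param model trained model; `store` a feature store; `ids` slide subset.
#' @param n_bags,bag_size,agg_rule,seed see [predict_slide()]; each slide
#'   gets an independent but seed-derived bag stream.
#' @return data.frame with columns slide_id, p_slide, n_bags.
#' @export
predict_cohort <- function(model, store, ids = names(store), n_bags = 16,
                           bag_size = 50, agg_rule = "mean", seed = NULL) {
  with_seed(seed, {
    p <- vapply(ids, function(id) {
      predict_slide(model, store[[id]], n_bags, bag_size, agg_rule)$p_slide
    }, numeric(1))
    data.frame(slide_id = ids, p_slide = unname(p), n_bags = n_bags,
               stringsAsFactors = FALSE)
  })
}

#' Patient-grouped, label-stratified split plan
#'
#' Assigns patients (never individual slides) to `k` cross-validation
#' folds, optionally holding out a test fraction first. Folds are
#' stratified by patient-level label (positive if any slide is positive).
#'
#' @param labels data.frame with slide_id, patient_id, label.
#' @param k folds.
#' @param holdout_fraction fraction of patients held out as a test set.
#' @param seed RNG seed.
#' @return list of class `split_plan`: `assignment` (named patient -> fold,
#'   0 = holdout), `test_holdout` (patient ids), `slides` (data.frame with
#'   fold column), `k`.
#' @export
make_splits <- function(labels, k = 5, holdout_fraction = 0, seed = 1) {
  stopifnot(all(c("slide_id", "patient_id", "label") %in% names(labels)))
  pat <- tapply(labels$label, labels$patient_id, max)
  if (length(pat) < k) stop("fewer patients (", length(pat),
                            ") than folds (", k, ")")
  with_seed(seed, {
    assignment <- stats::setNames(integer(length(pat)), names(pat))
    holdout <- character(0)
    for (cls in unique(pat)) {
      ids <- sample(names(pat)[pat == cls])
      n_hold <- round(holdout_fraction * length(ids))
      if (n_hold > 0) {
        holdout <- c(holdout, ids[seq_len(n_hold)])
        ids <- ids[-seq_len(n_hold)]
      }
      if (length(ids)) {
        assignment[ids] <- rep_len(seq_len(k), length(ids))
      }
    }
    assignment[holdout] <- 0L
    slides <- labels
    slides$fold <- unname(assignment[slides$patient_id])
    structure(list(assignment = assignment, test_holdout = holdout,
                   slides = slides, k = as.integer(k)),
              class = "split_plan")
  })
}

#' Save / load a model checkpoint
#'
#' Single-file archive of the model configuration and parameters.
#' @param fit a `mil_fit` or `mil_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "mil_fit")) fit$model else fit
  saveRDS(list(version = model$version, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$version, "wsimil-1"))
  obj$model
}
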