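# The attention-MIL network and its pooling baselines.
#
# Architecture (from the tile descriptor onward): two fully connected
# layers with ReLU and dropout 0.5 map the backbone descriptor (D0) to a
# 512-d tile embedding; an attention module (linear 512 -> 128, tanh,
# linear 128 -> 1, softmax over the bag) produces one weight per tile; the
# attention-weighted sum of embeddings is the 512-d aggregate fed to a
# linear decision layer with a sigmoid. Meanpool/Maxpool baselines replace
# the attention weighting by the column mean/max of the embedding matrix;
# the single-patch baseline drops pooling entirely and scores tiles
# individually. Forward and backward passes are exact matrix algebra (no
# autodiff), verified against finite differences in the test suite.

#' Construct a MIL model
#'
#' Weights are He-initialized (`N(0, sqrt(2/fan_in))`) under the given
#' seed; biases start at zero. The default dimensions follow the reference
#' architecture: D0 -> 512 -> 512 tile embedding, 128-d attention hidden
#' layer, dropout 0.5 after each FC layer. Small dimensions are allowed
#' for toy/gradient tests.
#'
#' @param d0 backbone descriptor dimension.
#' @param fc_dims lengths of the two FC layers (embedding dim = last).
#' @param att_dim attention hidden dimension.
#' @param pooling one of `"attention"`, `"meanpool"`, `"maxpool"`,
#'   `"patch"`.
#' @param dropout dropout probability on both FC layers (train mode only).
#' @param backbone a [backbone_config()] describing the tile encoder.
#' @param seed RNG seed for initialization.
#' @return object of class `mil_model`.
#' @export
mil_model <- function(d0 = 256, fc_dims = c(512, 512), att_dim = 128,
                      pooling = c("attention", "meanpool", "maxpool", "patch"),
                      dropout = 0.5, backbone = backbone_config(),
                      seed = 1) {
  pooling <- match.arg(pooling)
  stopifnot(length(fc_dims) == 2L, dropout >= 0, dropout < 1)
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  with_seed(seed, {
    params <- list(
      W1 = he(d0, fc_dims[1]), b1 = numeric(fc_dims[1]),
      W2 = he(fc_dims[1], fc_dims[2]), b2 = numeric(fc_dims[2]),
      V = he(fc_dims[2], att_dim), cV = numeric(att_dim),
      w = as.numeric(he(att_dim, 1)),
      u = as.numeric(he(fc_dims[2], 1)), b = 0
    )
    structure(list(pooling = pooling, d0 = as.integer(d0),
                   fc_dims = as.integer(fc_dims),
                   att_dim = as.integer(att_dim), dropout = dropout,
                   backbone = backbone,
                   params = params,
                   feat_center = NULL, feat_scale = NULL,
                   version = "wsimil-1"),
              class = "mil_model")
  })
}

# Feature standardization (training-split statistics stored in the model).
standardize_features <- function(model, X) {
  if (is.null(model$feat_center)) return(X)
  sweep(sweep(X, 2L, model$feat_center), 2L, model$feat_scale, "/")
}

#' Fit per-feature standardization statistics
#'
#' Stores the mean and SD of each backbone feature over the given
#' (training-split) descriptor matrix in the model; they are applied in
#' every forward pass. Near-constant features get unit scale.
#'
#' @param model a `mil_model`.
#' @param X descriptor matrix (tiles x d0) from the training split only.
#' @return the updated model.
#' @export
fit_feature_scaling <- function(model, X) {
  model$feat_center <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  model$feat_scale <- ifelse(s < 1e-8, 1, s)
  model
}

# Coerce input (list of tile images or a descriptor matrix) to N x d0.
as_descriptor_matrix <- function(x, model) {
  if (is.list(x)) x <- backbone_matrix(x, model$backbone)
  stopifnot(is.matrix(x))
  if (ncol(x) != model$d0) {
    stop("descriptor dimension mismatch: expected ", model$d0,
         ", got ", ncol(x))
  }
  x
}

#' Forward pass through the MIL network
#'
#' @param model a `mil_model`.
#' @param X raw descriptor matrix (N x d0) or list of tile images.
#' @param train if `TRUE`, dropout masks are drawn from the current RNG;
#'   eval mode is deterministic.
#' @return list with `p` (bag probability; per-tile vector for the patch
#'   model), `a` (attention weights), `z` (aggregate embedding), `H`
#'   (N x 512 embedding matrix) and the caches needed by
#'   [mil_backward()].
#' @export
mil_forward <- function(model, X, train = FALSE) {
  X <- as_descriptor_matrix(X, model)
  n <- nrow(X)
  if (n == 0L) stop("empty bag: no tiles to score")
  pr <- model$params
  Xs <- standardize_features(model, X)
  A1 <- sweep(Xs %*% pr$W1, 2L, pr$b1, "+")
  R1 <- relu(A1)
  keep <- 1 - model$dropout
  M1 <- if (train && model$dropout > 0) {
    matrix(stats::runif(length(R1)) < keep, nrow(R1), ncol(R1)) / keep
  } else matrix(1, nrow(R1), ncol(R1))
  H1 <- R1 * M1
  A2 <- sweep(H1 %*% pr$W2, 2L, pr$b2, "+")
  R2 <- relu(A2)
  M2 <- if (train && model$dropout > 0) {
    matrix(stats::runif(length(R2)) < keep, nrow(R2), ncol(R2)) / keep
  } else matrix(1, nrow(R2), ncol(R2))
  H <- R2 * M2

  out <- list(Xs = Xs, A1 = A1, M1 = M1, H1 = H1, A2 = A2, M2 = M2, H = H,
              n = n)
  if (model$pooling == "attention") {
    Tn <- tanh(sweep(H %*% pr$V, 2L, pr$cV, "+"))
    s <- as.numeric(Tn %*% pr$w)
    a <- softmax(s)
    z <- as.numeric(crossprod(H, a))
    out$Tn <- Tn; out$a <- a; out$z <- z
  } else if (model$pooling == "meanpool") {
    a <- rep(1 / n, n)
    z <- colMeans(H)
    out$a <- a; out$z <- z
  } else if (model$pooling == "maxpool") {
    idx <- max.col(t(H), ties.method = "first")
    z <- H[cbind(idx, seq_len(ncol(H)))]
    out$maxidx <- idx; out$z <- z
    # share of feature dimensions each tile wins (ties split evenly, so the
    # summary is invariant to tile order)
    wins <- H == matrix(z, n, ncol(H), byrow = TRUE)
    out$a <- rowSums(wins / matrix(colSums(wins), n, ncol(H), byrow = TRUE)) /
      ncol(H)
  } else { # patch: score each tile independently
    logit <- as.numeric(H %*% pr$u) + pr$b
    out$p <- sigmoid(logit)
    out$logit <- logit
    out$a <- rep(1 / n, n)
    out$z <- colMeans(H)
    return(out)
  }
  out$logit <- sum(out$z * pr$u) + pr$b
  out$p <- sigmoid(out$logit)
  out
}

# Binary cross-entropy of a forward cache against label y (patch model:
# mean over tiles).
bce_loss <- function(fw, y) {
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' Backward pass: exact gradients of the BCE loss
#'
#' @param model a `mil_model`.
#' @param fw forward cache from [mil_forward()].
#' @param y bag label (0/1).
#' @return list of gradients with the same shapes as `model$params`.
#' @export
mil_backward <- function(model, fw, y) {
  pr <- model$params
  n <- fw$n
  H <- fw$H
  if (model$pooling == "patch") {
    dlog <- (fw$p - y) / n
    du <- as.numeric(crossprod(H, dlog))
    db <- sum(dlog)
    dH <- outer(dlog, pr$u)
    dV <- matrix(0, nrow(pr$V), ncol(pr$V)); dcV <- numeric(length(pr$cV))
    dw <- numeric(length(pr$w))
  } else {
    dlog <- fw$p - y
    du <- dlog * fw$z
    db <- dlog
    dz <- dlog * pr$u
    if (model$pooling == "attention") {
      da <- as.numeric(H %*% dz)
      dH <- outer(fw$a, dz)
      ds <- fw$a * (da - sum(fw$a * da))
      dw <- as.numeric(crossprod(fw$Tn, ds))
      dpre <- outer(ds, pr$w) * (1 - fw$Tn^2)
      dV <- crossprod(H, dpre)
      dcV <- colSums(dpre)
      dH <- dH + dpre %*% t(pr$V)
    } else if (model$pooling == "meanpool") {
      dH <- matrix(dz / n, n, length(dz), byrow = TRUE)
      dV <- matrix(0, nrow(pr$V), ncol(pr$V)); dcV <- numeric(length(pr$cV))
      dw <- numeric(length(pr$w))
    } else { # maxpool
      dH <- matrix(0, n, ncol(H))
      dH[cbind(fw$maxidx, seq_len(ncol(H)))] <- dz
      dV <- matrix(0, nrow(pr$V), ncol(pr$V)); dcV <- numeric(length(pr$cV))
      dw <- numeric(length(pr$w))
    }
  }
  dA2 <- (dH * fw$M2) * (fw$A2 > 0)
  dW2 <- crossprod(fw$H1, dA2)
  db2 <- colSums(dA2)
  dH1 <- tcrossprod(dA2, pr$W2)
  dA1 <- (dH1 * fw$M1) * (fw$A1 > 0)
  dW1 <- crossprod(fw$Xs, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       V = dV, cV = dcV, w = dw, u = du, b = db)
}

#' Tile embeddings (post-FC features)
#'
#' Runs the feature-extractor stack (backbone descriptor, standardization,
#' two FC layers) and returns the N x 512 embedding matrix. Eval mode is
#' deterministic (dropout off); train mode draws dropout masks from the
#' current RNG.
#'
#' @param x list of tile images or raw descriptor matrix (N x d0).
#' @param model a `mil_model`.
#' @param mode `"eval"` or `"train"`.
#' @return embedding matrix H (N x `fc_dims[2]`).
#' @export
extract_features <- function(x, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  mil_forward(model, x, train = mode == "train")$H
}

#' Attention weights over a bag
#'
#' `a = softmax_i(w' tanh(V h_i + c))`: each tile embedding is reduced to
#' `att_dim` dimensions, squashed by tanh, scored by a second linear map
#' and normalized over the bag by a softmax, so the weights are in `[0, 1]`
#' and sum to one.
#'
#' @param H embedding matrix (N x d).
#' @param params list with `V` (d x att_dim), `cV` (att_dim, optional),
#'   `w` (att_dim) — e.g. `model$params`.
#' @return attention vector of length N.
#' @export
attention_weights <- function(H, params) {
  if (!is.matrix(H) || nrow(H) == 0L) stop("empty bag: H has no rows")
  cV <- if (is.null(params$cV)) numeric(ncol(params$V)) else params$cV
  Tn <- tanh(sweep(H %*% params$V, 2L, cV, "+"))
  softmax(as.numeric(Tn %*% params$w))
}

#' Attention-weighted aggregate embedding
#'
#' @param H embedding matrix (N x d).
#' @param a attention weights of length N.
#' @return `z = sum_i a_i h_i` (length d).
#' @export
aggregate <- function(H, a) {
  if (length(a) != nrow(H)) {
    stop("length(a) (", length(a), ") != rows of H (", nrow(H), ")")
  }
  as.numeric(crossprod(H, a))
}

#' Decision layer
#'
#' @param z aggregate embedding.
#' @param params list with `u` (same length as `z`) and scalar `b`.
#' @return probability `sigmoid(u'z + b)`.
#' @export
decide <- function(z, params) {
  if (length(params$u) != length(z)) {
    stop("dimension mismatch: length(u) = ", length(params$u),
         ", length(z) = ", length(z))
  }
  sigmoid(sum(params$u * z) + params$b)
}

#' Mean/max pooling baselines
#'
#' @param H embedding matrix (N x d).
#' @param method `"meanpool"` (column means) or `"maxpool"` (column-wise
#'   maxima).
#' @return pooled embedding of length d.
#' @export
pool_baseline <- function(H, method = c("meanpool", "maxpool")) {
  method <- match.arg(method)
  stopifnot(is.matrix(H), nrow(H) > 0L)
  if (method == "meanpool") colMeans(H) else apply(H, 2L, max)
}

#' Score a bag
#'
#' @param model a `mil_model`.
#' @param x list of tile images or descriptor matrix.
#' @return list of class `bag_prediction`: `p`, `a` (length-N attention),
#'   `z` (aggregate embedding).
#' @export
predict_bag <- function(model, x) {
  fw <- mil_forward(model, x, train = FALSE)
  p <- if (model$pooling == "patch") mean(fw$p) else fw$p
  structure(list(p = p, a = fw$a, z = fw$z), class = "bag_prediction")
}

#' Single-patch baseline forward pass
#'
#' Scores tiles individually with the patch model (no pooling); the slide
#' score is the mean probability over `n_patches` sampled tiles.
#'
#' @param model a `mil_model` with `pooling = "patch"`.
#' @param x descriptor matrix or list of tiles (candidate patches).
#' @param n_patches patches sampled (with replacement if fewer available).
#' @return list with per-patch probabilities `p` and `slide_score`.
#' @export
patch_model_forward <- function(model, x, n_patches = 50) {
  X <- as_descriptor_matrix(x, model)
  idx <- if (nrow(X) >= n_patches) sample.int(nrow(X), n_patches)
         else sample.int(nrow(X), n_patches, replace = TRUE)
  fw <- mil_forward(model, X[idx, , drop = FALSE], train = FALSE)
  p <- if (model$pooling == "patch") fw$p else {
    # generic fallback: score each tile as its own bag
    vapply(seq_along(idx),
           function(i) mil_forward(model, X[idx[i], , drop = FALSE])$p,
           numeric(1))
  }
  list(p = p, slide_score = mean(p), idx = idx)
}

#' @export
print.mil_model <- function(x, ...) {
  cat("MIL model (", x$pooling, " pooling): ", x$d0, " -> ",
      paste(x$fc_dims, collapse = " -> "), " embedding, attention dim ",
      x$att_dim, ", dropout ", x$dropout, "\n", sep = "")
  invisible(x)
}
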