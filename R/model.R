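#' Boosted-tree model configuration
#'
#' Defaults follow the pipeline's reference configuration: learning rate
#' 0.08, maximum depth 6, 1000 estimators, deterministic CPU histogram tree
#' method, single thread, seed 42. No early stopping: the estimator count
#' is fixed, and any validation split is for monitoring only.
#'
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @param nrounds Number of boosting rounds (estimators).
#' @param tree_method xgboost tree construction algorithm (`"hist"`).
#' @param nthread Threads (1 keeps training bit-reproducible).
#' @param seed Seed passed to the learner.
#' @param use_pos_weight Apply per-label `scale_pos_weight`
#'   (`#neg / #pos`); disable to deliberately allow rare-class overfitting.
#' @return A `model_config` list.
#' @export
model_config <- function(eta = 0.08, max_depth = 6L, nrounds = 1000L,
                         tree_method = "hist", nthread = 1L, seed = 42L,
                         use_pos_weight = TRUE) {
  structure(list(eta = eta, max_depth = as.integer(max_depth),
                 nrounds = as.integer(nrounds), tree_method = tree_method,
                 nthread = as.integer(nthread), seed = as.integer(seed),
                 use_pos_weight = isTRUE(use_pos_weight)),
            class = "model_config")
}

# Columns with no nonzero entry in the training matrix can never host a
# split, so training on the active-column submatrix is statistically
# identical to training on the full 2^18-wide matrix while keeping the
# histogram scan proportional to the codes actually observed. The active
# set is stored on the fitted model and applied again at prediction.
active_columns <- function(X) {
  if (inherits(X, "dgCMatrix")) which(diff(X@p) > 0L) else which(colSums(X != 0) > 0L)
}

fit_xgb_binary <- function(X, y, config, spw = 1) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = config$nthread)
  params <- list(objective = "binary:logistic", eta = config$eta,
                 max_depth = config$max_depth, tree_method = config$tree_method,
                 nthread = config$nthread, scale_pos_weight = spw,
                 seed = config$seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = config$nrounds, verbose = 0)
}

check_label_classes <- function(Y) {
  npos <- colSums(Y == 1)
  nneg <- colSums(Y == 0)
  bad <- colnames(Y)[npos == 0 | nneg == 0]
  if (length(bad)) {
    stop("single-class label(s) in training data: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Fit a one-vs-rest multilabel model
#'
#' Three (or more) independent binary boosted-tree models, one per label,
#' each weighted by its own `scale_pos_weight` from the training labels.
#'
#' @param X Sparse feature matrix (patients x hashed features).
#' @param Y Binary label matrix aligned with `X`.
#' @param config A [model_config()].
#' @return An `ovr_model` object.
#' @export
fit_ovr <- function(X, Y, config = model_config()) {
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  check_label_classes(Y)
  active <- active_columns(X)
  Xa <- X[, active, drop = FALSE]
  spw <- if (config$use_pos_weight) pos_weight(Y) else
    setNames(rep(1, ncol(Y)), colnames(Y))
  models <- lapply(seq_len(ncol(Y)), function(j) {
    fit_xgb_binary(Xa, Y[, j], config, spw[j])
  })
  names(models) <- colnames(Y)
  structure(list(models = models, labels = colnames(Y), config = config,
                 pos_weights = spw, active = active, n_features = ncol(X)),
            class = "ovr_model")
}

# Rank labels by descending training prevalence; among the 6 permutations
# of 3 labels ordered lexicographically by their prevalence-rank vectors,
# keep the first 5 — dropping only the ordering that puts the sparsest
# label first and the anchors last-and-reversed.
default_chain_orderings <- function(Y, n_orderings = 5L) {
  labels <- colnames(Y)
  prev_rank <- rank(-colMeans(Y), ties.method = "first")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rank_vectors <- lapply(perms, function(p) prev_rank[p])
  ord <- do.call(order, as.data.frame(do.call(rbind, rank_vectors)))
  lapply(ord[seq_len(min(n_orderings, length(perms)))], function(i) labels[perms[[i]]])
}

#' Fit a classifier-chain ensemble
#'
#' An ensemble of binary boosted-tree chains over distinct label orderings
#' (default: the 5 orderings that best respect descending training
#' prevalence). Within a chain, the model for the j-th label consumes the
#' hashed features plus *predicted probabilities* for the earlier labels —
#' out-of-fold predictions during training (2-fold internal refits, to
#' avoid optimistically chaining on in-sample predictions) and the full
#' models' predictions at inference. Ensemble output is the unweighted mean
#' probability across chains.
#'
#' @param X Sparse feature matrix.
#' @param Y Binary label matrix aligned with `X`.
#' @param orderings List of label-name permutations; `NULL` for the default
#'   five prevalence-ranked orderings.
#' @param config A [model_config()].
#' @param oof_folds Internal folds for chain augmentation (default 2; set
#'   to 1 to chain on in-sample predictions).
#' @return A `cc_ensemble` object.
#' @export
fit_cc_ensemble <- function(X, Y, orderings = NULL, config = model_config(),
                            oof_folds = 2L) {
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  check_label_classes(Y)
  if (is.null(orderings)) orderings <- default_chain_orderings(Y)
  stopifnot(length(orderings) >= 1,
            !anyDuplicated(vapply(orderings, paste, character(1), collapse = ">")))
  for (o in orderings) stopifnot(setequal(o, colnames(Y)))
  spw <- if (config$use_pos_weight) pos_weight(Y) else
    setNames(rep(1, ncol(Y)), colnames(Y))
  n <- nrow(X)
  active <- active_columns(X)
  X <- X[, active, drop = FALSE]
  fold_id <- with_seed(config$seed, sample(rep_len(seq_len(max(oof_folds, 1L)), n)))

  chains <- lapply(orderings, function(ord) {
    aug_full <- NULL   # training-time augmentation (OOF predictions)
    models <- vector("list", length(ord))
    names(models) <- ord
    for (j in seq_along(ord)) {
      lab <- ord[j]
      Xj <- if (is.null(aug_full)) X else cbind(X, aug_full)
      models[[j]] <- fit_xgb_binary(Xj, Y[, lab], config, spw[lab])
      if (j < length(ord)) {
        oof <- numeric(n)
        if (oof_folds > 1L) {
          for (f in seq_len(oof_folds)) {
            hold <- fold_id == f
            m <- fit_xgb_binary(Xj[!hold, , drop = FALSE], Y[!hold, lab],
                                config, spw[lab])
            oof[hold] <- predict(m, Xj[hold, , drop = FALSE])
          }
        } else {
          oof <- predict(models[[j]], Xj)
        }
        aug_full <- cbind(aug_full, matrix(oof, ncol = 1,
                                           dimnames = list(NULL, paste0("chain_", lab))))
      }
    }
    list(ordering = ord, models = models)
  })
  structure(list(chains = chains, labels = colnames(Y), config = config,
                 pos_weights = spw, active = active),
            class = "cc_ensemble")
}

#' Predict per-label probabilities
#'
#' @param object A fitted `ovr_model` or `cc_ensemble`.
#' @param X Feature matrix with the same hashed-feature width as training.
#' @param ... Unused.
#' @return Numeric matrix of probabilities, columns in the training label
#'   order. For a chain ensemble this is the unweighted mean across chains.
#' @export
predict_proba <- function(object, X, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.ovr_model <- function(object, X, ...) {
  X <- X[, object$active, drop = FALSE]
  out <- vapply(object$models, function(m) predict(m, X), numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X), dimnames = list(rownames(X), object$labels))
  out
}

#' @rdname predict_proba
#' @export
predict_proba.cc_ensemble <- function(object, X, ...) {
  X <- X[, object$active, drop = FALSE]
  acc <- matrix(0, nrow(X), length(object$labels),
                dimnames = list(rownames(X), object$labels))
  for (chain in object$chains) {
    aug <- NULL
    preds <- matrix(NA_real_, nrow(X), length(chain$ordering),
                    dimnames = list(NULL, chain$ordering))
    for (j in seq_along(chain$ordering)) {
      Xj <- if (is.null(aug)) X else cbind(X, aug)
      p <- predict(chain$models[[j]], Xj)
      preds[, j] <- p
      if (j < length(chain$ordering)) aug <- cbind(aug, matrix(p, ncol = 1))
    }
    acc <- acc + preds[, object$labels, drop = FALSE]
  }
  acc / length(object$chains)
}
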