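#' Train a gradient-boosted tree classifier
#'
#' Thin, deterministic wrapper around xgboost (binary:logistic objective,
#' single-threaded, seeded). Default hyperparameters are a fixed small
#' configuration: 200 trees of depth 6 at learning rate 0.1.
#'
#' @param X numeric feature matrix (rows = records).
#' @param y integer 0/1 labels; both classes must be present.
#' @param params list overriding `nrounds`, `max_depth`, `eta`.
#' @param seed integer seed.
#' @return object of class `pcm_model`.
#' @export
train_classifier <- function(X, y, params = list(), seed = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    pcm_stop("training labels contain a single class",
             "pcm_degenerate_error")
  hp <- utils::modifyList(list(nrounds = 200, max_depth = 6, eta = 0.1), params)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%05d", seq_len(ncol(X)))
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = hp$nrounds, verbose = 0))
  structure(list(kind = "gbt_classifier", booster = booster,
                 feature_names = colnames(X), hyperparameters = hp,
                 seed = seed), class = "pcm_model")
}

#' Train a tree-ensemble regressor on pX values
#'
#' 100-tree ensembles with library-default depth settings: `engine = "rf"`
#' uses randomForest, `engine = "gbt"` uses xgboost with the squared-error
#' objective.
#'
#' @param X numeric feature matrix.
#' @param y numeric response (pX).
#' @param engine `"rf"` or `"gbt"`.
#' @param n_trees ensemble size (default 100).
#' @param seed integer seed.
#' @return object of class `pcm_model`.
#' @export
train_regressor <- function(X, y, engine = c("rf", "gbt"), n_trees = 100,
                            seed = 1) {
  engine <- match.arg(engine)
  stopifnot(length(y) == nrow(X), nrow(X) >= 10)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%05d", seq_len(ncol(X)))
  if (engine == "rf") {
    fit <- withr::with_seed(seed,
      randomForest::randomForest(x = X, y = as.numeric(y),
                                 ntree = n_trees))
    structure(list(kind = "rf_regressor", booster = fit,
                   feature_names = colnames(X),
                   hyperparameters = list(n_trees = n_trees), seed = seed),
              class = "pcm_model")
  } else {
    booster <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1),
      nrounds = n_trees, verbose = 0))
    structure(list(kind = "gbt_regressor", booster = booster,
                   feature_names = colnames(X),
                   hyperparameters = list(n_trees = n_trees), seed = seed),
              class = "pcm_model")
  }
}

#' @export
predict.pcm_model <- function(object, newdata, ...) {
  if (is.null(colnames(newdata))) colnames(newdata) <- object$feature_names
  if (object$kind == "rf_regressor")
    return(unname(stats::predict(object$booster, newdata)))
  stats::predict(object$booster,
                 xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' @export
print.pcm_model <- function(x, ...) {
  cat(sprintf("pcm_model: %s over %d features (seed %d)\n", x$kind,
              length(x$feature_names), x$seed))
  invisible(x)
}

#' Per-feature importance vector of a trained model
#'
#' Returns a non-negative importance for every feature column (zero for
#' features the ensemble never used). Gradient-boosted models report the
#' native gain-based importance; random forests report node-purity
#' improvement.
#'
#' @param model a `pcm_model`.
#' @return named non-negative numeric vector, one entry per feature column.
#' @export
feature_importances <- function(model) {
  out <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  if (model$kind == "rf_regressor") {
    imp <- randomForest::importance(model$booster)[, 1]
    out[names(imp)] <- pmax(imp, 0)
  } else {
    imp <- xgboost::xgb.importance(model = model$booster)
    if (nrow(imp) > 0) out[imp$Feature] <- imp$Gain
  }
  out
}

#' Protein feature importance (PFI)
#'
#' Fraction of the model's total feature importance carried by the protein
#' block of the joint representation. With zero total importance the PFI is
#' defined as 0; with uniform per-feature importance it reduces exactly to
#' `p / (p + q)`, i.e. the protein block's share of the feature space.
#'
#' @param model a `pcm_model`, or a precomputed importance vector.
#' @param blocks a [block_layout()] consistent with the feature columns.
#' @return PFI in `[0, 1]`.
#' @export
protein_feature_importance <- function(model, blocks) {
  imp <- if (inherits(model, "pcm_model")) feature_importances(model) else
    as.numeric(model)
  if (length(imp) != blocks$p + blocks$q)
    pcm_stop("importance length does not match the block layout",
             "pcm_bookkeeping_error")
  if (any(imp < 0))
    pcm_stop("feature importances must be non-negative",
             "pcm_bookkeeping_error")
  total <- sum(imp)
  if (total == 0) return(0)
  sum(imp[blocks$protein]) / total
}

#' Evaluate a trained model on a design
#'
#' Dispatches on the model kind: classification metrics (F1, AUROC, Recall,
#' MCC) plus PFI for classifiers; MAE and R^2 for regressors.
#'
#' @param model a `pcm_model`.
#' @param design a [build_design()] object (or a list with `X`, `y`,
#'   `blocks`).
#' @param threshold classification score cutoff.
#' @return named list of metrics.
#' @export
evaluate_model <- function(model, design, threshold = 0.5) {
  scores <- predict(model, design$X)
  if (model$kind == "gbt_classifier") {
    m <- classification_metrics(design$y, scores, threshold)
    m$pfi <- protein_feature_importance(model, design$blocks)
    m
  } else {
    regression_metrics(design$y, scores)
  }
}
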