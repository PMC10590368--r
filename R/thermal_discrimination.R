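#' Rank environmental variables by class-discriminating importance
#'
#' `boosted_trees` mode fits a multiclass gradient-boosted tree ensemble
#' (xgboost, softmax objective) on a stratified train split and reports the
#' split-frequency importance ("F score") per variable together with train
#' and test accuracy. `anova_f` mode is a deterministic alternative reporting
#' the one-way ANOVA F statistic per variable (no train/test split).
#'
#' @param env an [environmental_table()].
#' @param labels class per sample: named character vector or in row order.
#' @param model `"boosted_trees"` (default) or `"anova_f"`.
#' @param split_fraction fraction of each class assigned to the training set
#'   in boosted mode (default 2/3).
#' @param seed integer seed (mandatory for the stochastic boosted mode).
#' @param importance_measure `"frequency"` (split counts, default) or
#'   `"gain"`.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return Object of class `importance_report`: list with `ranking`
#'   (data.frame variable/importance, non-increasing), `train_accuracy` and
#'   `test_accuracy` (percentages; NA in anova_f mode), `split_spec`, `model`,
#'   `seed`.
#' @export
rank_variables <- function(env, labels,
                           model = c("boosted_trees", "anova_f"),
                           split_fraction = 2 / 3, seed = 1L,
                           importance_measure = c("frequency", "gain"),
                           nrounds = 50, max_depth = 3, eta = 0.3) {
  model <- match.arg(model)
  importance_measure <- match.arg(importance_measure)
  stopifnot(inherits(env, "environmental_table"),
            split_fraction > 0, split_fraction < 1)
  x <- env$values
  labels <- if (!is.null(names(labels))) labels[rownames(x)]
            else {
              stopifnot(length(labels) == nrow(x))
              labels
            }
  grp <- factor(as.character(labels))
  if (nlevels(grp) < 2) stop("need at least 2 classes")
  constant <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(constant))
    warning("constant variables get importance 0: ",
            paste(colnames(x)[constant], collapse = ", "))
  if (model == "anova_f") {
    fvals <- apply(x, 2, function(v) {
      if (stats::sd(v, na.rm = TRUE) == 0) return(0)
      sm <- summary(stats::aov(v ~ grp))[[1]]
      sm[["F value"]][1]
    })
    ranking <- data.frame(variable = colnames(x), importance = unname(fvals),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$importance, ranking$variable), ]
    rownames(ranking) <- NULL
    return(structure(list(ranking = ranking, train_accuracy = NA_real_,
                          test_accuracy = NA_real_,
                          split_spec = "none (deterministic mode)",
                          model = model, seed = as.integer(seed)),
                     class = "importance_report"))
  }
  if (min(table(grp)) < 8)
    stop("boosted mode needs >= 8 samples per class")
  set.seed(seed)
  train_idx <- unlist(lapply(levels(grp), function(lv) {
    idx <- which(grp == lv)
    sample(idx, size = max(1, round(split_fraction * length(idx))))
  }))
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  y <- as.integer(grp) - 1L
  dtrain <- xgboost::xgb.DMatrix(x[train_idx, , drop = FALSE],
                                 label = y[train_idx], nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = nlevels(grp),
                  max_depth = max_depth, eta = eta, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  col <- if (importance_measure == "frequency") "Frequency" else "Gain"
  scores <- stats::setNames(rep(0, ncol(x)), colnames(x))
  scores[imp$Feature] <- imp[[col]]
  ranking <- data.frame(variable = names(scores),
                        importance = unname(scores),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$importance, ranking$variable), ]
  rownames(ranking) <- NULL
  acc <- function(idx) {
    pred <- stats::predict(bst, xgboost::xgb.DMatrix(
      x[idx, , drop = FALSE], nthread = 1))
    100 * mean(pred == y[idx])
  }
  structure(list(ranking = ranking,
                 train_accuracy = acc(train_idx),
                 test_accuracy = acc(test_idx),
                 split_spec = sprintf(
                   "stratified %.0f%%/%.0f%% train/test (%d/%d samples)",
                   100 * split_fraction, 100 * (1 - split_fraction),
                   length(train_idx), length(test_idx)),
                 model = model, seed = as.integer(seed)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("importance_report (%s, seed %d)\n", x$model, x$seed))
  if (!is.na(x$train_accuracy))
    cat(sprintf("accuracy: train %.1f%%, test %.1f%% [%s]\n",
                x$train_accuracy, x$test_accuracy, x$split_spec))
  print(utils::head(x$ranking, 10))
  invisible(x)
}
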