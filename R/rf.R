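#' Train a random-forest classifier on a feature matrix
#'
#' Bootstrap-aggregated decision trees (probability forest via
#' \pkg{ranger}) with `sqrt(m)` candidate features per split by default.
#' The fit is deterministic for a fixed seed, keeps per-tree in-bag counts
#' (so out-of-bag sets are recoverable), and carries normalized Gini
#' (mean-decrease-impurity) feature importances.
#'
#' @param fm An `acp_features` object with both classes present.
#' @param num_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(m))`.
#' @param seed RNG seed for the forest.
#' @return Object of class `acp_rf`: the fitted ensemble, `feature_ids`,
#'   `params`, `gini_importance` (named, sums to 1), and per-tree in-bag
#'   counts.
#' @export
train_rf <- function(fm, num_trees = 500, mtry = NULL, seed = 42) {
  stopifnot(inherits(fm, "acp_features"))
  if (length(unique(fm$y)) < 2L) stop("training data must contain both classes")
  if (nrow(fm$x) < 4L) stop("need at least 4 samples to fit a forest")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(fm$x))))
  d <- data.frame(fm$x, .label = factor(fm$y, levels = c(0L, 1L)),
                  check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = d,
    num.trees = num_trees, mtry = mtry, probability = TRUE,
    min.node.size = 1, importance = "impurity", keep.inbag = TRUE,
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance[colnames(fm$x)]
  gini <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(
    fit = fit,
    feature_ids = colnames(fm$x),
    params = list(num_trees = num_trees, mtry = mtry, seed = seed),
    gini_importance = gini,
    inbag = fit$inbag.counts
  ), class = "acp_rf")
}

#' @export
print.acp_rf <- function(x, ...) {
  cat("acp_rf:", x$params$num_trees, "trees, mtry", x$params$mtry,
      ",", length(x$feature_ids), "features, seed", x$params$seed, "\n")
  invisible(x)
}

#' Predict positive-class scores
#'
#' @param object An `acp_rf` model.
#' @param newdata An `acp_features` object or numeric matrix with the
#'   model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of anticancer-class probabilities.
#' @export
predict.acp_rf <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "acp_features")) newdata$x else as.matrix(newdata)
  missing <- setdiff(object$feature_ids, colnames(x))
  if (length(missing)) {
    stop("feature mismatch: model feature(s) absent from data: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  x <- x[, object$feature_ids, drop = FALSE]
  p <- predict(object$fit, data = data.frame(x, check.names = FALSE),
               num.threads = 1)$predictions
  unname(p[, "1"])
}

#' Out-of-bag sample indices for one tree
#'
#' @param model An `acp_rf` model trained with in-bag bookkeeping.
#' @param tree Tree index in `1..num_trees`.
#' @return Integer vector of row indices never drawn into that tree's
#'   bootstrap sample.
#' @export
oob_samples <- function(model, tree) {
  stopifnot(inherits(model, "acp_rf"))
  which(model$inbag[[tree]] == 0L)
}

# per-tree hard predictions (n x num_trees matrix of 0/1) on a data matrix
per_tree_predictions <- function(model, x) {
  p <- predict(model$fit, data = data.frame(x, check.names = FALSE),
               predict.all = TRUE, num.threads = 1)$predictions
  # array n x 2 x num_trees; class order follows the factor levels c(0, 1)
  (p[, 2L, ] > 0.5) * 1L
}

#' Out-of-bag permutation feature importance
#'
#' For each tree, the baseline error `e1` is the misclassification rate on
#' the tree's out-of-bag samples; `e2` is the error on the same samples
#' after permuting feature `i`'s column. The reported importance of
#' feature `i` is `mean(e2 - e1)` over trees, positive for informative
#' features. The literal signed sum `sum(e1 - e2)/n_trees` is stored
#' alongside as `signed_mean` (it is the negated quantity). One seeded
#' permutation per feature is shared across trees.
#'
#' @param model An `acp_rf` fitted with [train_rf()].
#' @param fm The training `acp_features`.
#' @param seed Seed for the column permutations.
#' @return data.frame with columns `accession`, `importance`
#'   (`mean(e2 - e1)`) and `signed_mean` (`mean(e1 - e2)`), in model
#'   feature order.
#' @export
oob_importance <- function(model, fm, seed = 1) {
  stopifnot(inherits(model, "acp_rf"), inherits(fm, "acp_features"))
  x <- fm$x[, model$feature_ids, drop = FALSE]
  y <- fm$y
  n_trees <- model$params$num_trees
  oob <- lapply(seq_len(n_trees), function(t) oob_samples(model, t))
  if (any(lengths(oob) == 0L)) {
    stop("a tree has an empty out-of-bag set; use more samples or trees")
  }
  base <- per_tree_predictions(model, x)
  e1 <- vapply(seq_len(n_trees),
               function(t) mean(base[oob[[t]], t] != y[oob[[t]]]), numeric(1))
  m <- length(model$feature_ids)
  set.seed(seed)
  perms <- lapply(seq_len(m), function(j) sample.int(nrow(x)))
  delta <- numeric(m)
  for (j in seq_len(m)) {
    xp <- x
    xp[, j] <- x[perms[[j]], j]
    pred <- per_tree_predictions(model, xp)
    e2 <- vapply(seq_len(n_trees),
                 function(t) mean(pred[oob[[t]], t] != y[oob[[t]]]), numeric(1))
    delta[j] <- mean(e2 - e1)
  }
  data.frame(accession = model$feature_ids,
             importance = delta,
             signed_mean = -delta,
             stringsAsFactors = FALSE)
}

# stratified fold assignment; error if any training fold would miss a class
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < 2L) stop("class ", cls, " absent from some training fold")
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  for (f in seq_len(folds)) {
    train_y <- y[assign != f]
    if (length(unique(train_y)) < 2L) {
      stop("class absent from training fold ", f)
    }
  }
  assign
}

#' Stratified k-fold cross-validation of a random forest
#'
#' Folds are stratified by class under a fixed shuffling seed. Metrics are
#' computed on the pooled out-of-fold predictions (pooled confusion counts
#' and pooled scores for AUC), which keeps AUC well-defined even for small
#' folds.
#'
#' @inheritParams train_rf
#' @param folds Number of folds (default 5).
#' @return List: `metrics` (a `metric_set`), `per_fold` data.frame
#'   (`fold`, `n`, `acc`), `counts` (pooled `confusion_counts`), `scores`
#'   and `truth` (pooled, in input row order).
#' @export
cross_validate <- function(fm, folds = 5, num_trees = 500, mtry = NULL,
                           seed = 42) {
  stopifnot(inherits(fm, "acp_features"))
  assign <- stratified_folds(fm$y, folds, seed)
  n <- nrow(fm$x)
  scores <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    if (length(test) == 0L) next
    train <- which(assign != f)
    model <- train_rf(feature_matrix(fm$x[train, , drop = FALSE], fm$y[train]),
                      num_trees = num_trees, mtry = mtry, seed = seed + f)
    scores[test] <- predict(model, fm$x[test, , drop = FALSE])
  }
  pred <- as.integer(scores > 0.5)
  counts <- confusion(pred, fm$y)
  per_fold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    test <- which(assign == f)
    data.frame(fold = f, n = length(test),
               acc = if (length(test)) 100 * mean(pred[test] == fm$y[test])
                     else NA_real_)
  }))
  list(metrics = compute_metrics(counts, scores = scores, truth = fm$y),
       per_fold = per_fold, counts = counts, scores = scores, truth = fm$y)
}

#' Evaluate a trained model on an independent test set
#'
#' @param model An `acp_rf`.
#' @param test_fm An `acp_features` whose features match the model's
#'   (order is reconciled automatically; a differing feature set is an
#'   error).
#' @return A `metric_set` on the test set.
#' @export
evaluate_independent <- function(model, test_fm) {
  stopifnot(inherits(model, "acp_rf"), inherits(test_fm, "acp_features"))
  if (!setequal(colnames(test_fm$x), model$feature_ids)) {
    stop("feature mismatch between model and test set")
  }
  scores <- predict(model, test_fm)
  counts <- confusion(as.integer(scores > 0.5), test_fm$y)
  compute_metrics(counts, scores = scores, truth = test_fm$y)
}

#' Select random-forest hyperparameters by cross-validated accuracy
#'
#' Small grid search over tree count and per-split feature rule, scored by
#' [cross_validate()] ACC (ties: MCC, then fewer trees).
#'
#' @inheritParams cross_validate
#' @param trees_grid Candidate tree counts.
#' @param mtry_rules Candidate per-split feature rules: `"sqrt"` and/or
#'   `"log2"`.
#' @return List: `best` (list `num_trees`, `mtry`), `trace` data.frame.
#' @export
tune_rf <- function(fm, trees_grid = c(100, 500, 1000),
                    mtry_rules = c("sqrt", "log2"), folds = 5, seed = 42) {
  m <- ncol(fm$x)
  mtry_of <- c(sqrt = max(1L, floor(sqrt(m))), log2 = max(1L, floor(log2(m))))
  grid <- expand.grid(num_trees = trees_grid, rule = mtry_rules,
                      stringsAsFactors = FALSE)
  trace <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cv <- cross_validate(fm, folds = folds, num_trees = grid$num_trees[i],
                         mtry = mtry_of[[grid$rule[i]]], seed = seed)
    data.frame(num_trees = grid$num_trees[i], rule = grid$rule[i],
               mtry = mtry_of[[grid$rule[i]]],
               acc = cv$metrics$acc, mcc = cv$metrics$mcc)
  }))
  ord <- order(-trace$acc, -trace$mcc, trace$num_trees)
  best <- trace[ord[1L], ]
  list(best = list(num_trees = best$num_trees, mtry = best$mtry), trace = trace)
}

#' Persist a trained model (with the index entries it needs) to one file
#'
#' The saved object bundles the fitted forest, its parameters and seed,
#' and optionally the slice of the index table covering the model's
#' features, so [predict_acp()] can run from a FASTA file alone.
#'
#' @param model An `acp_rf`.
#' @param path Destination file.
#' @param table Optional [aaindex_table()] used at encoding time.
#' @param na_policy Encoding NA policy to replay at prediction time.
#' @return Invisibly, `path`.
#' @export
save_acp_model <- function(model, path, table = NULL,
                           na_policy = "drop_entry") {
  stopifnot(inherits(model, "acp_rf"))
  if (!is.null(table)) {
    keep <- match(model$feature_ids, table$accession)
    if (anyNA(keep)) stop("index table does not cover all model features")
    table <- aaindex_table(table$accession[keep], table$description[keep],
                           table$values[keep, , drop = FALSE],
                           table$extras[keep], table$source)
  }
  saveRDS(list(model = model, table = table, na_policy = na_policy,
               package_version = as.character(utils::packageVersion("acpforest"))),
          path)
  invisible(path)
}

#' @rdname save_acp_model
#' @export
load_acp_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj$model, "acp_rf")) stop("not an acpforest model file")
  obj
}

#' Predict anticancer activity for peptides
#'
#' Encodes the peptides with the model's index slice and applies the
#' forest: per-peptide positive-class score and hard label at 0.5.
#'
#' @param bundle A list as returned by [load_acp_model()] (model + index
#'   table + NA policy), or an `acp_rf` if `table` is given.
#' @param records data.frame with `id` and `sequence` columns, or a path
#'   to a FASTA file.
#' @param table Index table, required when `bundle` is a bare `acp_rf`.
#' @param policy Sequence validation policy (see [validate_sequence()]).
#' @return data.frame: `id`, `score`, `label` (1 = predicted ACP).
#' @export
predict_acp <- function(bundle, records, table = NULL, policy = "strict") {
  if (inherits(bundle, "acp_rf")) bundle <- list(model = bundle, table = table,
                                                 na_policy = "drop_entry")
  if (is.null(bundle$table)) stop("an index table is required for encoding")
  if (is.character(records)) records <- read_fasta(records)
  records$sequence <- vapply(records$sequence, validate_sequence, character(1),
                             policy = policy, USE.NAMES = FALSE)
  fm <- encode_dataset(records, rep(0L, nrow(records)), bundle$table,
                       na_policy = bundle$na_policy)
  scores <- predict(bundle$model, fm)
  data.frame(id = records$id, score = scores,
             label = as.integer(scores > 0.5), stringsAsFactors = FALSE)
}
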