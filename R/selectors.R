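# shared constructor: attach scores to accessions, rank descending,
# ties broken by accession lexicographic order (reproducible intersections)
feature_scores <- function(method, scores) {
  nm <- names(scores)
  ord <- order(-scores, nm, method = "radix")
  structure(list(method = method, scores = scores, ranking = nm[ord]),
            class = "feature_scores")
}

#' @export
print.feature_scores <- function(x, ...) {
  cat("feature_scores (", x$method, "): ", length(x$scores), " features; top: ",
      paste(utils::head(x$ranking, 5L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_two_classes <- function(fm) {
  if (length(unique(fm$y)) < 2L) stop("both classes must be present")
}

#' Rank features by one-way ANOVA F statistic
#'
#' Per feature, the F statistic of the positive-vs-negative group
#' comparison (between-group over within-group mean squares). Scale- and
#' location-invariant; a feature identical in both classes scores 0. Zero
#' within-group variance with non-zero between-group variance yields an
#' `Inf` sentinel ranked first.
#'
#' @param fm An `acp_features` object with both classes and `n >= 3`.
#' @return A `feature_scores` object (`method = "anova"`).
#' @export
score_anova <- function(fm) {
  stopifnot(inherits(fm, "acp_features"))
  check_two_classes(fm)
  n <- nrow(fm$x)
  if (n < 3L) stop("ANOVA needs at least 3 samples")
  pos <- fm$y == 1L
  n1 <- sum(pos); n0 <- n - n1
  m1 <- colMeans(fm$x[pos, , drop = FALSE])
  m0 <- colMeans(fm$x[!pos, , drop = FALSE])
  g <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - g)^2 + n0 * (m0 - g)^2
  ssw <- colSums((fm$x[pos, , drop = FALSE] -
                    matrix(m1, n1, ncol(fm$x), byrow = TRUE))^2) +
    colSums((fm$x[!pos, , drop = FALSE] -
               matrix(m0, n0, ncol(fm$x), byrow = TRUE))^2)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
              ifelse(ssb > 0, Inf, 0))
  names(f) <- colnames(fm$x)
  feature_scores("anova", f)
}

#' Rank features by the chi-squared statistic on class-wise sums
#'
#' Each feature is min-max scaled to \[0, 1\] on the given matrix (the
#' statistic requires non-negative inputs), then treated as a frequency:
#' observed `A_c` = sum of scaled values in class `c`, expected
#' `B_c` = class prior times the total sum, and
#' `chi2 = sum_c (A_c - B_c)^2 / B_c`. Constant features score 0.
#'
#' @inheritParams score_anova
#' @return A `feature_scores` object (`method = "chi2"`).
#' @export
score_chi2 <- function(fm) {
  stopifnot(inherits(fm, "acp_features"))
  check_two_classes(fm)
  x <- fm$x
  lo <- apply(x, 2L, min)
  rg <- apply(x, 2L, max) - lo
  scaled <- sweep(sweep(x, 2L, lo), 2L, ifelse(rg > 0, rg, 1), "/")
  scaled[, rg == 0] <- 0
  pos <- fm$y == 1L
  a1 <- colSums(scaled[pos, , drop = FALSE])
  a0 <- colSums(scaled[!pos, , drop = FALSE])
  tot <- a1 + a0
  p1 <- mean(pos)
  b1 <- tot * p1
  b0 <- tot * (1 - p1)
  chi2 <- ifelse(tot > 0, (a1 - b1)^2 / b1 + (a0 - b0)^2 / b0, 0)
  names(chi2) <- colnames(fm$x)
  feature_scores("chi2", chi2)
}

# plug-in discrete mutual information in nats
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# Ross-style kNN estimator for continuous feature vs discrete label, nats
knn_mi <- function(x, y, k) {
  n <- length(x)
  radius <- numeric(n)
  k_used <- integer(n)
  n_class <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    nc <- length(idx)
    n_class[idx] <- nc
    if (nc < 2L) next
    kc <- min(k, nc - 1L)
    k_used[idx] <- kc
    xc <- x[idx]
    for (ii in seq_along(idx)) {
      d <- abs(xc - xc[ii])
      radius[idx[ii]] <- sort(d, partial = kc + 1L)[kc + 1L]
    }
  }
  keep <- n_class > 1L
  xs <- x[keep]; rs <- radius[keep]
  m_all <- vapply(seq_along(xs),
                  function(i) sum(abs(xs - xs[i]) < rs[i]), numeric(1))
  mi <- digamma(sum(keep)) + mean(digamma(k_used[keep])) -
    mean(digamma(n_class[keep])) - mean(digamma(m_all))
  max(0, mi)
}

#' Rank features by mutual information with the class label
#'
#' Nonparametric estimate of `I(X, Y)` in nats between each feature and
#' the binary label. Continuous features use a k-nearest-neighbour
#' estimator (class-conditional k-th neighbour radius, neighbour counts in
#' the pooled sample); a tiny seeded jitter breaks ties, with one jitter
#' vector shared across features so duplicated columns score identically.
#' `discrete = TRUE` switches to the plug-in estimator on the empirical
#' joint distribution (e.g. a feature equal to a balanced binary label
#' then scores `ln 2`). Independent variables score approximately 0 (the
#' estimate is clipped at 0).
#'
#' @inheritParams score_anova
#' @param k Neighbour count for the continuous estimator (default 3).
#' @param seed Seed for the tie-breaking jitter.
#' @param discrete Logical, recycled over features: use the plug-in
#'   estimator for that feature.
#' @return A `feature_scores` object (`method = "mi"`).
#' @export
score_mi <- function(fm, k = 3, seed = 1, discrete = FALSE) {
  stopifnot(inherits(fm, "acp_features"))
  check_two_classes(fm)
  m <- ncol(fm$x)
  discrete <- rep_len(discrete, m)
  set.seed(seed)
  eps <- stats::rnorm(nrow(fm$x))
  mi <- vapply(seq_len(m), function(j) {
    col <- fm$x[, j]
    if (discrete[j]) return(discrete_mi(col, fm$y))
    scale <- 1e-10 * max(1, mean(abs(col)))
    knn_mi(col + scale * eps, fm$y, k)
  }, numeric(1))
  names(mi) <- colnames(fm$x)
  feature_scores("mi", mi)
}

#' Rank features by histogram gradient-boosting split gain
#'
#' Fits a histogram-based gradient-boosted tree ensemble (continuous
#' features are bucketed into discrete histogram bins before split
#' finding) on the labeled matrix and scores each feature by its total
#' split gain. Features never used in a split score 0. Deterministic for
#' a fixed seed with single-threaded training.
#'
#' @inheritParams score_anova
#' @param nrounds Boosting rounds (default 100).
#' @param num_leaves Maximum leaves per tree (default 31).
#' @param learning_rate Shrinkage (default 0.1).
#' @param seed Seed passed to the booster.
#' @return A `feature_scores` object (`method = "gbm"`).
#' @export
rank_gbm <- function(fm, nrounds = 100, num_leaves = 31,
                     learning_rate = 0.1, seed = 1) {
  stopifnot(inherits(fm, "acp_features"))
  if (length(unique(fm$y)) < 2L) stop("degenerate fit: all labels identical")
  dm <- xgboost::xgb.DMatrix(fm$x, label = fm$y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", tree_method = "hist",
                  grow_policy = "lossguide", max_depth = 0,
                  max_leaves = num_leaves, eta = learning_rate,
                  nthread = 1, seed = seed),
    data = dm, nrounds = nrounds, verbose = 0
  )
  # total split gain per feature, aggregated from the tree dump and
  # normalized to fractions (robust for models of any feature count)
  dt <- xgboost::xgb.model.dt.tree(model = bst)
  splits <- dt[dt$Feature != "Leaf", ]
  gain <- stats::setNames(rep(0, ncol(fm$x)), colnames(fm$x))
  if (nrow(splits) > 0L) {
    agg <- tapply(splits$Gain, splits$Feature, sum)
    gain[names(agg)] <- agg / sum(agg)
  }
  feature_scores("gbm", gain)
}

#' Default subset-size grid for the top-n sweep
#'
#' Multiples of 5 up to `min(100, m)`, plus the full dimensionality.
#'
#' @param m Number of available features.
#' @return Sorted integer vector of candidate subset sizes.
#' @export
default_sweep_grid <- function(m) {
  sort(unique(c(seq(5L, min(100L, m), by = 5L), m)))
}

#' Sweep top-n feature prefixes and keep the best-performing subset
#'
#' For each candidate size `n` in the grid, a random forest is evaluated
#' by stratified cross-validation on the first `n` features of the
#' ranking. The chosen `best_n` maximizes CV accuracy (ties: higher MCC,
#' then smaller `n`); the full sweep trace is returned for inspection.
#'
#' @param scores A `feature_scores` object (or bare ranking vector).
#' @param fm The `acp_features` the ranking refers to.
#' @param grid Candidate subset sizes; defaults to
#'   [default_sweep_grid()] clipped to the ranking length.
#' @param folds CV folds (default 5).
#' @param num_trees Trees per forest during the sweep (default 100; subset
#'   ranking is stable well below the final-model tree count).
#' @param seed CV fold seed.
#' @param dataset_id Optional label carried into the result.
#' @return Object of class `selection_result`: `dataset_id`, `method`,
#'   `best_n`, `selected` (the first `best_n` accessions) and `trace`
#'   (data.frame `n`, `acc`, `mcc`, `sn`, `sp`, `auc`).
#' @export
sweep_top_n <- function(scores, fm, grid = NULL, folds = 5, num_trees = 100,
                        seed = 42, dataset_id = NA_character_) {
  ranking <- if (inherits(scores, "feature_scores")) scores$ranking
             else as.character(scores)
  method <- if (inherits(scores, "feature_scores")) scores$method
            else "ranking"
  stopifnot(inherits(fm, "acp_features"))
  if (is.null(grid)) grid <- default_sweep_grid(length(ranking))
  grid <- sort(unique(as.integer(grid)))
  grid <- grid[grid >= 1L & grid <= length(ranking)]
  if (length(grid) == 0L) stop("empty sweep grid")
  trace <- do.call(rbind, lapply(grid, function(n) {
    cv <- cross_validate(restrict_features(fm, ranking[seq_len(n)]),
                         folds = folds, num_trees = num_trees, seed = seed)
    data.frame(n = n, acc = cv$metrics$acc, mcc = cv$metrics$mcc,
               sn = cv$metrics$sn, sp = cv$metrics$sp, auc = cv$metrics$auc)
  }))
  best <- trace[order(-trace$acc, -trace$mcc, trace$n)[1L], ]
  structure(list(dataset_id = dataset_id, method = method,
                 best_n = best$n,
                 selected = ranking[seq_len(best$n)],
                 trace = trace),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$method,
      if (!is.na(x$dataset_id)) paste0(", ", x$dataset_id), "): best_n = ",
      x$best_n, " of grid [", min(x$trace$n), "..", max(x$trace$n), "]\n",
      sep = "")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param result A `selection_result`.
#' @param path Optional output path.
#' @return The JSON string, invisibly if written to `path`.
#' @export
selection_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  j <- jsonlite::toJSON(list(
    dataset = result$dataset_id, method = result$method,
    best_n = result$best_n, selected = result$selected,
    sweep_trace = result$trace
  ), auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}
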