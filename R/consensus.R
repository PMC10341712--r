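#' Features selected in at least k datasets
#'
#' @param per_dataset_sets Named list of character vectors (one selected
#'   accession set per dataset).
#' @param k Minimum number of datasets a feature must appear in
#'   (default 3, the cross-dataset consensus rule).
#' @return Character vector (sorted) of accessions with membership count
#'   `>= k`.
#' @export
features_in_at_least_k <- function(per_dataset_sets, k = 3) {
  stopifnot(is.list(per_dataset_sets), k >= 1)
  if (k > length(per_dataset_sets)) {
    stop("k (", k, ") exceeds the number of datasets (",
         length(per_dataset_sets), ")")
  }
  counts <- table(unlist(lapply(per_dataset_sets, unique)))
  sort(names(counts)[counts >= k])
}

#' Per-method cross-dataset consensus
#'
#' Bundles one selector's per-dataset selected sets with their `>= k`
#' intersection (`common`).
#'
#' @param per_dataset_sets Named list of accession sets for one method.
#' @param method Selector name.
#' @inheritParams features_in_at_least_k
#' @return Object of class `method_consensus`.
#' @export
method_consensus <- function(per_dataset_sets, method, k = 3) {
  structure(list(method = method, per_dataset_sets = per_dataset_sets,
                 k = k, common = features_in_at_least_k(per_dataset_sets, k)),
            class = "method_consensus")
}

#' Merge per-method consensus sets into one candidate pool
#'
#' Set union of each method's `common` set (duplicates collapse); the
#' pool feeding the second selection round.
#'
#' @param consensus_list List of `method_consensus` objects (or bare
#'   character vectors).
#' @return Sorted character vector of merged accessions.
#' @export
merge_method_consensus <- function(consensus_list) {
  stopifnot(length(consensus_list) >= 1L)
  sets <- lapply(consensus_list, function(x) {
    if (inherits(x, "method_consensus")) x$common else as.character(x)
  })
  sort(unique(unlist(sets)))
}

#' Second-round per-dataset selection on the merged pool
#'
#' Restricts each dataset to the merged candidate pool, re-ranks with the
#' gradient-boosting selector, and sweeps top-n subsets per dataset.
#'
#' @param merged Character vector of candidate accessions (must exist in
#'   every dataset).
#' @param datasets Named list of `acp_features` objects.
#' @param seed Base seed; dataset `i` uses `seed + i`.
#' @param grid,folds,num_trees Passed to [sweep_top_n()].
#' @return Named list of `selection_result`, one per dataset.
#' @export
second_round_select <- function(merged, datasets, seed = 42, grid = NULL,
                                folds = 5, num_trees = 100) {
  stopifnot(length(merged) >= 1L, length(datasets) >= 1L)
  ids <- names(datasets)
  if (is.null(ids)) ids <- paste0("D", seq_along(datasets))
  out <- lapply(seq_along(datasets), function(i) {
    fm <- restrict_features(datasets[[i]], merged)
    scores <- rank_gbm(fm, seed = seed + i)
    sweep_top_n(scores, fm, grid = grid, folds = folds,
                num_trees = num_trees, seed = seed + i,
                dataset_id = ids[i])
  })
  stats::setNames(out, ids)
}

#' Intersect second-round sets under a per-dataset importance threshold
#'
#' The final consensus rule: keep the accessions present in every
#' dataset's second-round set whose importance exceeds `threshold` in
#' every dataset, ordered by mean importance (descending).
#'
#' @param second_round Named list of `selection_result` objects (or bare
#'   accession sets), one per dataset.
#' @param importances Named list (same datasets) of named importance
#'   vectors covering each second-round set.
#' @param threshold Minimum importance, exclusive (default 0.01).
#' @return Object of class `final_feature_set`: `accessions` (ordered),
#'   `per_dataset_importance`, `threshold`. Empty intersection yields a
#'   warning and an empty set.
#' @export
importance_filter_intersection <- function(second_round, importances,
                                           threshold = 0.01) {
  sets <- lapply(second_round, function(x) {
    if (inherits(x, "selection_result")) x$selected else as.character(x)
  })
  stopifnot(length(sets) >= 1L, length(importances) == length(sets))
  inter <- Reduce(intersect, sets)
  keep <- Filter(function(acc) {
    all(vapply(importances, function(imp) {
      !is.na(imp[acc]) && imp[acc] > threshold
    }, logical(1)))
  }, inter)
  keep <- as.character(keep)
  if (length(keep) == 0L) {
    warning("no features survive the intersection + importance filter")
    per <- lapply(importances, function(imp) stats::setNames(numeric(0), character(0)))
  } else {
    mean_imp <- vapply(keep, function(acc) {
      mean(vapply(importances, function(imp) imp[[acc]], numeric(1)))
    }, numeric(1))
    keep <- keep[order(-mean_imp, keep, method = "radix")]
    per <- lapply(importances, function(imp) imp[keep])
  }
  structure(list(accessions = keep, per_dataset_importance = per,
                 threshold = threshold),
            class = "final_feature_set")
}

#' @export
print.final_feature_set <- function(x, ...) {
  cat("final_feature_set:", length(x$accessions),
      "features (importance >", x$threshold, "in every dataset)\n")
  if (length(x$accessions)) {
    cat("  ", paste(utils::head(x$accessions, 10L), collapse = ", "),
        if (length(x$accessions) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Run the full two-round consensus feature-selection pipeline
#'
#' Round 1: each of the four selectors (ANOVA F, chi-squared, mutual
#' information, gradient boosting) ranks every dataset's features and a
#' top-n sweep picks each (dataset, method) subset; per method, features
#' selected in `>= k` datasets are retained and the per-method consensus
#' sets are merged by union. Round 2: each dataset is restricted to the
#' merged pool, re-ranked by gradient boosting and swept again; a random
#' forest per dataset then supplies Gini importances, and the final set is
#' the all-dataset intersection of second-round sets filtered at
#' `importance > threshold` in every dataset.
#'
#' @param datasets Named list of `acp_features` objects sharing a feature
#'   space.
#' @param k Consensus count for round 1 (default 3).
#' @param threshold Final importance threshold (default 0.01).
#' @param grid Sweep grid (default [default_sweep_grid()]).
#' @param folds CV folds inside sweeps (default 5).
#' @param sweep_trees Trees per forest inside sweeps (default 100).
#' @param final_trees Trees for the per-dataset importance forests
#'   (default 500).
#' @param seed Base seed.
#' @return Object of class `consensus_result` with components `round1`
#'   (method -> dataset -> `selection_result`), `method_consensus`,
#'   `merged`, `round2`, `importances` and `final`.
#' @export
run_consensus_pipeline <- function(datasets, k = 3, threshold = 0.01,
                                   grid = NULL, folds = 5, sweep_trees = 100,
                                   final_trees = 500, seed = 42) {
  stopifnot(length(datasets) >= 1L)
  ids <- names(datasets)
  if (is.null(ids)) {
    ids <- paste0("D", seq_along(datasets))
    names(datasets) <- ids
  }
  scorers <- list(
    anova = function(fm, s) score_anova(fm),
    chi2  = function(fm, s) score_chi2(fm),
    mi    = function(fm, s) score_mi(fm, seed = s),
    gbm   = function(fm, s) rank_gbm(fm, seed = s)
  )
  round1 <- lapply(names(scorers), function(meth) {
    res <- lapply(seq_along(datasets), function(i) {
      fm <- datasets[[i]]
      scores <- scorers[[meth]](fm, seed + i)
      sweep_top_n(scores, fm, grid = grid, folds = folds,
                  num_trees = sweep_trees, seed = seed + i,
                  dataset_id = ids[i])
    })
    stats::setNames(res, ids)
  })
  names(round1) <- names(scorers)
  cons <- lapply(names(scorers), function(meth) {
    method_consensus(lapply(round1[[meth]], function(r) r$selected),
                     method = meth, k = k)
  })
  names(cons) <- names(scorers)
  merged <- merge_method_consensus(cons)
  if (length(merged) == 0L) stop("round-1 consensus is empty; nothing to merge")
  round2 <- second_round_select(merged, datasets, seed = seed, grid = grid,
                                folds = folds, num_trees = sweep_trees)
  importances <- lapply(seq_along(datasets), function(i) {
    fm <- restrict_features(datasets[[i]], round2[[i]]$selected)
    train_rf(fm, num_trees = final_trees, seed = seed + i)$gini_importance
  })
  names(importances) <- ids
  final <- importance_filter_intersection(round2, importances,
                                          threshold = threshold)
  structure(list(round1 = round1, method_consensus = cons, merged = merged,
                 round2 = round2, importances = importances, final = final,
                 params = list(k = k, threshold = threshold, seed = seed)),
            class = "consensus_result")
}

#' Human-readable consensus report
#'
#' Textual summary of the pipeline: per-method per-dataset counts, the
#' `>= k` consensus sets, the merged pool, second-round sets and the final
#' set with per-dataset importances — a textual stand-in for the Venn
#' diagrams usually drawn for these intersections.
#'
#' @param result A `consensus_result`.
#' @return Character vector of report lines.
#' @export
consensus_report <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  lines <- c("== Two-round consensus feature selection ==", "")
  for (meth in names(result$method_consensus)) {
    mc <- result$method_consensus[[meth]]
    lines <- c(lines, sprintf("[%s] per-dataset best-n: %s", meth,
                              paste(sprintf("%s=%d", names(mc$per_dataset_sets),
                                            lengths(mc$per_dataset_sets)),
                                    collapse = ", ")),
               sprintf("[%s] >= %d-dataset consensus (%d): %s", meth, mc$k,
                       length(mc$common), paste(mc$common, collapse = " ")))
  }
  lines <- c(lines, "",
             sprintf("Merged pool (%d): %s", length(result$merged),
                     paste(result$merged, collapse = " ")), "")
  for (id in names(result$round2)) {
    r <- result$round2[[id]]
    lines <- c(lines, sprintf("Second round [%s]: best_n = %d", id, r$best_n))
  }
  fin <- result$final
  lines <- c(lines, "",
             sprintf("Final set (importance > %g in all datasets): %d features",
                     fin$threshold, length(fin$accessions)))
  for (acc in fin$accessions) {
    imps <- vapply(fin$per_dataset_importance, function(v) v[[acc]], numeric(1))
    lines <- c(lines, sprintf("  %-12s %s", acc,
                              paste(sprintf("%s=%.4f", names(imps), imps),
                                    collapse = " ")))
  }
  lines
}

#' Serialize a consensus result to JSON
#'
#' @param result A `consensus_result`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
consensus_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "consensus_result"))
  obj <- list(
    per_method_common = lapply(result$method_consensus, function(m) m$common),
    merged = result$merged,
    second_round = lapply(result$round2, function(r)
      list(best_n = r$best_n, selected = r$selected)),
    final = list(accessions = result$final$accessions,
                 threshold = result$final$threshold,
                 per_dataset_importance = lapply(
                   result$final$per_dataset_importance, as.list)),
    params = result$params
  )
  j <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(j, path); return(invisible(j)) }
  j
}
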