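test_that("at-least-k membership matches enumeration on the worked example", {
  sets <- list(D1 = c("a", "b", "c"), D2 = c("a", "b"),
               D3 = c("a", "c"), D4 = c("b", "d"))
  expect_identical(features_in_at_least_k(sets, 3), c("a", "b"))
  expect_identical(features_in_at_least_k(sets, 1),
                   sort(Reduce(union, sets)))
  expect_identical(features_in_at_least_k(sets, 4), character(0))
  expect_error(features_in_at_least_k(sets, 5), "exceeds")
})

test_that("consensus set algebra matches brute force on random set systems", {
  set.seed(101)
  universe <- sprintf("F%02d", 1:50)
  for (i in 1:250) {
    n_sets <- sample(2:6, 1)
    sets <- lapply(seq_len(n_sets),
                   function(j) sample(universe, sample(0:30, 1)))
    names(sets) <- paste0("D", seq_len(n_sets))
    k <- sample(seq_len(n_sets), 1)
    brute <- sort(Filter(function(f) {
      sum(vapply(sets, function(s) f %in% s, logical(1))) >= k
    }, universe))
    expect_identical(features_in_at_least_k(sets, k), brute)
    # monotonicity in k
    if (k < n_sets) {
      expect_true(all(features_in_at_least_k(sets, k + 1) %in%
                        features_in_at_least_k(sets, k)))
    }
    # union merge
    expect_identical(merge_method_consensus(sets), sort(Reduce(union, sets)))
  }
})

test_that("importance filter keeps only all-dataset members above threshold everywhere", {
  sets <- list(D1 = c("a", "b", "c"), D2 = c("a", "b"),
               D3 = c("a", "b"), D4 = c("a", "b", "d"))
  imp <- list(D1 = c(a = 0.02, b = 0.02, c = 0.5),
              D2 = c(a = 0.03, b = 0.009),
              D3 = c(a = 0.011, b = 0.04),
              D4 = c(a = 0.05, b = 0.03, d = 0.2))
  out <- importance_filter_intersection(sets, imp, threshold = 0.01)
  expect_identical(out$accessions, "a")   # b fails > 0.01 in D2
  # threshold 0 keeps the full intersection, ordered by mean importance
  out0 <- importance_filter_intersection(sets, imp, threshold = 0)
  expect_setequal(out0$accessions, c("a", "b"))
  # raising the threshold never adds features
  for (thr in c(0, 0.01, 0.02, 0.05)) {
    lo <- suppressWarnings(importance_filter_intersection(sets, imp, threshold = thr))
    hi <- suppressWarnings(importance_filter_intersection(sets, imp, threshold = thr + 0.01))
    expect_true(all(hi$accessions %in% lo$accessions))
  }
  expect_warning(empty <- importance_filter_intersection(sets, imp, threshold = 1),
                 "no features")
  expect_length(empty$accessions, 0L)
})

test_that("importance filter matches brute-force enumeration on random systems", {
  set.seed(77)
  universe <- sprintf("F%02d", 1:40)
  for (i in 1:120) {
    n_sets <- sample(2:6, 1)
    sets <- lapply(seq_len(n_sets), function(j) sample(universe, sample(5:30, 1)))
    names(sets) <- paste0("D", seq_len(n_sets))
    imp <- lapply(sets, function(s) stats::setNames(runif(length(s)), s))
    thr <- runif(1, 0, 0.8)
    got <- suppressWarnings(
      importance_filter_intersection(sets, imp, threshold = thr))
    brute <- Filter(function(f) {
      all(vapply(seq_along(sets), function(j) {
        f %in% sets[[j]] && imp[[j]][[f]] > thr
      }, logical(1)))
    }, universe)
    expect_setequal(got$accessions, brute)
    # ordering is by mean importance, descending
    if (length(got$accessions) > 1L) {
      means <- vapply(got$accessions, function(f) {
        mean(vapply(imp, function(v) v[[f]], numeric(1)))
      }, numeric(1))
      expect_true(all(diff(means) <= 1e-12))
    }
  }
})

test_that("second-round selection recovers an exactly-planted merged set", {
  suite <- make_benchmark_suite(n_datasets = 2, m = 15, n_planted = 2,
                                delta = 2.5, n_pos = 80, n_neg = 80, seed = 33)
  res <- second_round_select(suite$planted, suite$datasets, seed = 33,
                             grid = 1:2, num_trees = 50)
  expect_length(res, 2L)
  expect_named(res, names(suite$datasets))
  for (r in res) {
    expect_s3_class(r, "selection_result")
    expect_true(all(r$selected %in% suite$planted))
  }
  # merged of size 1 forces best_n = 1
  one <- second_round_select(suite$planted[1], suite$datasets[1], seed = 1,
                             grid = 1, num_trees = 50)
  expect_identical(one[[1]]$best_n, 1L)
})

test_that("pipeline nesting invariant: final set within merged within round-1 union", {
  suite <- make_benchmark_suite(n_datasets = 3, m = 15, n_planted = 2,
                                delta = 2, n_pos = 60, n_neg = 60, seed = 55)
  res <- run_consensus_pipeline(suite$datasets, k = 2, grid = c(3, 6, 10, 15),
                                sweep_trees = 50, final_trees = 100, seed = 55)
  round1_union <- sort(unique(unlist(lapply(res$round1, function(per_method) {
    unlist(lapply(per_method, function(r) r$selected))
  }))))
  expect_true(all(res$merged %in% round1_union))
  for (r in res$round2) expect_true(all(r$selected %in% res$merged))
  expect_true(all(res$final$accessions %in% res$merged))
  # every final feature clears the threshold in every dataset
  for (acc in res$final$accessions) {
    for (imp in res$importances) expect_gt(imp[[acc]], res$params$threshold)
  }
  # report renders and JSON round-trips
  rep <- consensus_report(res)
  expect_true(any(grepl("Merged pool", rep)))
  j <- jsonlite::fromJSON(consensus_to_json(res))
  expect_identical(sort(j$merged), res$merged)
  expect_identical(j$final$accessions, res$final$accessions)
})
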