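make_separable_fm <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(f1 = rnorm(n) + 6 * y, f2 = rnorm(n) - 4 * y)
  colnames(x) <- c("f1", "f2")
  feature_matrix(x, y)
}

test_that("forest training memorizes separable data and is seed-deterministic", {
  fm <- make_separable_fm()
  model <- train_rf(fm, num_trees = 100, seed = 5)
  expect_equal(sum(model$gini_importance), 1, tolerance = 1e-9)
  expect_true(all(model$gini_importance >= 0))
  train_acc <- mean((predict(model, fm) > 0.5) == (fm$y == 1L))
  expect_equal(train_acc, 1)
  # identical seed -> identical held-out predictions
  held <- make_separable_fm(n = 60, seed = 99)
  m2 <- train_rf(fm, num_trees = 100, seed = 5)
  expect_identical(predict(model, held), predict(m2, held))
  # different seed -> a different forest (sanity that the seed is wired)
  m3 <- train_rf(fm, num_trees = 100, seed = 6)
  expect_false(identical(predict(model, held), predict(m3, held)))
  expect_error(train_rf(feature_matrix(fm$x, rep(1L, nrow(fm$x)))),
               "both classes")
})

test_that("out-of-bag sets are exposed and per-tree bootstrap leaves samples out", {
  fm <- make_separable_fm(n = 100)
  model <- train_rf(fm, num_trees = 50, seed = 2)
  oob_sizes <- vapply(1:50, function(t) length(oob_samples(model, t)), numeric(1))
  expect_true(all(oob_sizes > 0))
  # bootstrap leaves ~ e^-1 of samples out per tree
  expect_gt(mean(oob_sizes) / 100, 0.25)
  expect_lt(mean(oob_sizes) / 100, 0.5)
})

test_that("permutation importance: signal feature on top, noise near zero, deterministic", {
  set.seed(4)
  n <- 400
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(sig = rnorm(n) + 2 * y,
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  fm <- feature_matrix(x, y)
  model <- train_rf(fm, num_trees = 200, seed = 9)
  imp <- oob_importance(model, fm, seed = 3)
  expect_identical(imp$accession[which.max(imp$importance)], "sig")
  expect_true(all(abs(imp$importance[imp$accession != "sig"]) < 0.02))
  # the literal signed form is the negated importance
  expect_equal(imp$signed_mean, -imp$importance)
  imp2 <- oob_importance(model, fm, seed = 3)
  expect_identical(imp, imp2)
})

test_that("duplicating an informative feature dilutes each copy's permutation importance", {
  set.seed(6)
  n <- 300
  y <- rep(c(1L, 0L), each = n / 2)
  sig <- rnorm(n) + 2 * y
  noise <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("n1", "n2")))
  fm1 <- feature_matrix(cbind(sig = sig, noise), y)
  fm2 <- feature_matrix(cbind(sig = sig, sig_copy = sig, noise), y)
  m1 <- train_rf(fm1, num_trees = 200, seed = 11)
  m2 <- train_rf(fm2, num_trees = 200, seed = 11)
  i1 <- oob_importance(m1, fm1, seed = 1)
  i2 <- oob_importance(m2, fm2, seed = 1)
  single <- i1$importance[i1$accession == "sig"]
  each_dup <- i2$importance[i2$accession %in% c("sig", "sig_copy")]
  expect_true(all(each_dup < single))
})

test_that("cross-validation pools counts that conserve the sample total", {
  fm <- make_separable_fm(n = 100, seed = 3)
  cv <- cross_validate(fm, folds = 5, num_trees = 100, seed = 7)
  expect_equal(cv$metrics$acc, 100)
  cc <- cv$counts
  expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 100L)
  expect_equal(sum(cv$per_fold$n), 100)
  # leave-one-out on 10 samples still accounts for every sample
  small <- feature_matrix(fm$x[c(1:15, 51:65), ], fm$y[c(1:15, 51:65)])
  tiny <- feature_matrix(small$x[c(1:5, 16:20), ], small$y[c(1:5, 16:20)])
  loo <- cross_validate(tiny, folds = 10, num_trees = 50, seed = 1)
  cc2 <- loo$counts
  expect_identical(cc2$tp + cc2$tn + cc2$fp + cc2$fn, 10L)
  # a singleton class cannot be stratified into every training fold
  lone <- feature_matrix(fm$x[c(1, 51:59), ], fm$y[c(1, 51:59)])
  expect_error(cross_validate(lone, folds = 5), "absent")
})

test_that("independent evaluation enforces feature agreement and scores a test split", {
  suite <- make_benchmark_suite(n_datasets = 1, m = 12, n_planted = 2,
                                delta = 2.5, n_pos = 150, n_neg = 150, seed = 20)
  fm <- suite$datasets[[1]]
  test_ds <- make_labeled_peptides(suite$table, planted = suite$planted,
                                   delta = 2.5, n_pos = 75, n_neg = 75,
                                   seed = 777)
  test_fm <- encode_dataset(test_ds$records, test_ds$labels, suite$table)
  model <- train_rf(fm, num_trees = 200, seed = 1)
  ms <- evaluate_independent(model, test_fm)
  expect_gt(ms$acc, 85)
  expect_gt(ms$auc, 0.9)
  # memorizing model on its own training data
  self_ms <- evaluate_independent(model, fm)
  expect_equal(self_ms$acc, 100)
  expect_error(evaluate_independent(model, restrict_features(test_fm,
                 colnames(test_fm$x)[1:3])), "feature mismatch")
  neg_only <- feature_matrix(test_fm$x[test_ds$labels == 0L, ],
                             rep(0L, sum(test_ds$labels == 0L)))
  expect_error(evaluate_independent(model, neg_only), "Sn undefined")
})

test_that("model persistence bundles the index slice needed for FASTA prediction", {
  suite <- make_benchmark_suite(n_datasets = 1, m = 10, n_planted = 2,
                                delta = 2.5, n_pos = 80, n_neg = 80, seed = 31)
  fm <- restrict_features(suite$datasets[[1]], suite$table$accession[1:6])
  model <- train_rf(fm, num_trees = 100, seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_acp_model(model, f, table = suite$table)
  bundle <- load_acp_model(f)
  expect_identical(bundle$model$feature_ids, colnames(fm$x))
  expect_length(bundle$table, 6L)
  fasta <- withr::local_tempfile(fileext = ".fasta")
  ds <- make_labeled_peptides(suite$table, planted = suite$planted,
                              delta = 2.5, n_pos = 10, n_neg = 10, seed = 5)
  write_fasta(ds$records$id, ds$records$sequence, fasta)
  pred <- predict_acp(bundle, fasta)
  expect_identical(nrow(pred), 20L)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_identical(pred$label, as.integer(pred$score > 0.5))
  # planted signal is strong enough that prediction beats chance comfortably
  expect_gt(mean(pred$label[1:10]), mean(pred$label[11:20]))
})
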