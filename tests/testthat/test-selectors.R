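test_that("ANOVA F matches hand arithmetic and stats::oneway.test", {
  x <- cbind(f1 = c(1, 2, 3, 4),      # pos [1,2] vs neg [3,4] -> F = 8
             f2 = c(5, 5, 5, 5),      # constant -> 0
             f3 = c(1, 1, 2, 2))      # zero within-group variance -> Inf
  fm <- tiny_fm(x, c(1, 1, 0, 0))
  sc <- score_anova(fm)
  expect_equal(unname(sc$scores["f1"]), 8)
  expect_equal(unname(sc$scores["f2"]), 0)
  expect_identical(unname(sc$scores["f3"]), Inf)
  expect_identical(sc$ranking[1], "f3")
  # affine transform leaves F unchanged
  fm2 <- tiny_fm(cbind(f1 = 3 * x[, "f1"] - 7), c(1, 1, 0, 0))
  expect_equal(unname(score_anova(fm2)$scores["f1"]), 8)
  # independent oracle on random data
  set.seed(5)
  xr <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  yr <- rep(c(1, 0), each = 10)
  sco <- score_anova(tiny_fm(xr, yr))
  for (j in c("a", "b")) {
    expect_equal(unname(sco$scores[j]),
                 unname(stats::oneway.test(xr[, j] ~ yr,
                                           var.equal = TRUE)$statistic))
  }
})

test_that("chi-squared statistic follows the class-sum formula after min-max scaling", {
  # scaled pos = [1,1], neg = [0,0], equal classes -> A=(2,0), B=(1,1) -> 2
  x <- cbind(f1 = c(9, 9, 3, 3), f2 = c(4, 4, 4, 4), f3 = c(1, 2, 2, 1))
  sc <- score_chi2(tiny_fm(x, c(1, 1, 0, 0)))
  expect_equal(unname(sc$scores["f1"]), 2)
  expect_equal(unname(sc$scores["f2"]), 0)   # constant feature
  expect_equal(unname(sc$scores["f3"]), 0)   # identical per-class sums
})

test_that("mutual information: discrete oracle, independence null, duplicate columns", {
  # feature identical to a balanced binary label -> plug-in MI = ln 2
  y <- rep(c(1L, 0L), each = 10)
  fm <- tiny_fm(cbind(f = as.numeric(y)), y)
  expect_equal(unname(score_mi(fm, discrete = TRUE)$scores["f"]), log(2))
  # independent continuous feature at n = 2000 scores near zero
  set.seed(21)
  yy <- rep(c(1L, 0L), each = 1000)
  xx <- cbind(noise = rnorm(2000))
  expect_lt(abs(score_mi(tiny_fm(xx, yy), seed = 1)$scores["noise"]), 0.05)
  # duplicated columns score identically (shared tie-break jitter)
  set.seed(8)
  z <- rnorm(60)
  fm2 <- tiny_fm(cbind(a = z, b = z), rep(c(1L, 0L), 30))
  s2 <- score_mi(fm2, seed = 3)
  expect_identical(unname(s2$scores["a"]), unname(s2$scores["b"]))
  # informative feature outranks noise
  set.seed(9)
  y3 <- rep(c(1L, 0L), each = 100)
  x3 <- cbind(sig = rnorm(200) + 1.5 * y3, n1 = rnorm(200), n2 = rnorm(200))
  expect_identical(score_mi(tiny_fm(x3, y3), seed = 2)$ranking[1], "sig")
})

test_that("gradient-boosting importance finds a planted separating feature", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    y <- rep(c(1L, 0L), each = 50)
    x <- matrix(rnorm(100 * 8), 100, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    x[, "f4"] <- y + 0.05 * rnorm(100)   # perfectly separating
    sc <- rank_gbm(tiny_fm(x, y), seed = s)
    hits <- hits + (sc$ranking[1] == "f4")
  }
  expect_gte(hits, 9L)
  expect_error(rank_gbm(tiny_fm(matrix(rnorm(40), 20, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                                rep(1L, 20))),
               "degenerate")
})

test_that("gbm split attribution over a duplicated signal pair is conserved", {
  set.seed(12)
  y <- rep(c(1L, 0L), each = 100)
  sig <- y + 0.3 * rnorm(200)
  noise <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("n", 1:5)))
  single <- rank_gbm(tiny_fm(cbind(sig = sig, noise), y), seed = 1)
  dup <- rank_gbm(tiny_fm(cbind(sig = sig, sig2 = sig, noise), y), seed = 1)
  pair_sum <- sum(dup$scores[c("sig", "sig2")])
  expect_gte(pair_sum, 0.5 * single$scores[["sig"]])
})

test_that("scorers are deterministic and invariant to feature column order", {
  set.seed(30)
  y <- rep(c(1L, 0L), each = 40)
  x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 2] <- x[, 2] + y
  fm <- tiny_fm(x, y)
  fm_perm <- tiny_fm(x[, c(4, 1, 6, 2, 3, 5)], y)
  for (scorer in list(score_anova, score_chi2,
                      function(z) score_mi(z, seed = 5))) {
    a <- scorer(fm); b <- scorer(fm_perm)
    expect_equal(a$scores[sort(names(a$scores))],
                 b$scores[sort(names(b$scores))])
    expect_identical(a$ranking, b$ranking)
  }
  # stochastic scorers reproduce under a fixed seed
  expect_identical(score_mi(fm, seed = 7)$scores, score_mi(fm, seed = 7)$scores)
  expect_identical(rank_gbm(fm, seed = 7)$scores, rank_gbm(fm, seed = 7)$scores)
  # the boosted ranker keeps the signal feature on top under permutation
  expect_identical(rank_gbm(fm, seed = 1)$ranking[1],
                   rank_gbm(fm_perm, seed = 1)$ranking[1])
})

test_that("top-n sweep picks the accuracy argmax with deterministic tie-breaks", {
  set.seed(14)
  suite <- make_benchmark_suite(n_datasets = 1, m = 12, n_planted = 2,
                                delta = 2, n_pos = 60, n_neg = 60, seed = 14)
  fm <- suite$datasets[[1]]
  sc <- score_anova(fm)
  # single-point grid is forced
  one <- sweep_top_n(sc, fm, grid = 4, num_trees = 50, seed = 2)
  expect_identical(one$best_n, 4L)
  expect_identical(one$selected, sc$ranking[1:4])
  res <- sweep_top_n(sc, fm, grid = c(2, 4, 8, 12), num_trees = 50, seed = 2)
  expect_identical(nrow(res$trace), 4L)
  expect_identical(res$selected, sc$ranking[seq_len(res$best_n)])
  best_rows <- res$trace[order(-res$trace$acc, -res$trace$mcc, res$trace$n), ]
  expect_identical(res$best_n, best_rows$n[1])
  expect_error(sweep_top_n(sc, fm, grid = integer(0)), "empty sweep grid")
  # ranking prefix is respected: selected always equals ranking[1:best_n]
  j <- selection_to_json(res)
  expect_identical(jsonlite::fromJSON(j)$best_n, res$best_n)
})
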