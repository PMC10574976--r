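test_that("the threshold grid is linear, inclusive and strictly increasing", {
  g <- thresholdGrid()
  expect_length(g, 1000)
  expect_equal(g[1], 0.005)
  expect_equal(g[1000], 0.500)
  expect_true(all(diff(g) > 0))
  expect_equal(unique(round(diff(g), 12)), round(0.495 / 999, 12))
})

test_that("balanced subsets keep every minority index and never repeat", {
  labels <- rep(c(1L, 0L), c(26, 10))
  subsets <- makeBalancedSubsets(labels, 10, 10, seed = 5)
  expect_length(subsets, 10)
  for (s in subsets) {
    expect_length(s, 20)
    expect_setequal(intersect(s, 27:36), 27:36)     # all ten zeros, once
    expect_equal(anyDuplicated(s), 0L)
    expect_equal(sum(labels[s] == 1), 10)
  }
  # draws differ across subsets but the whole construction is reproducible
  expect_false(all(vapply(subsets[-1], identical, TRUE, subsets[[1]])))
  expect_identical(makeBalancedSubsets(labels, 10, 10, seed = 5), subsets)

  # exactly 10 of each class: no sampling freedom, every subset is the set
  even <- makeBalancedSubsets(rep(c(0L, 1L), 10), 10, 10, seed = 1)
  expect_true(all(vapply(even, identical, TRUE, 1:20)))

  expect_error(makeBalancedSubsets(rep(c(1L, 0L), c(31, 5)), 10, 10, 1),
               "data error")
})

test_that("LOOCV accuracy is exact on separable, constant and granular data", {
  sep <- scoreRecords(c(rep(0.001, 10), rep(0.9, 10)),
                      rep(c(TRUE, FALSE), each = 10),
                      rep(c(1L, 0L), each = 10))
  r <- loocvAccuracy(sep)
  expect_equal(r$accuracy_pct, 100)
  expect_equal(r$fold_outcomes, rep(1L, 20))

  # identical records with balanced labels force a constant classifier; under
  # leave-one-out the held-out record always belongs to the training
  # minority, so every fold is classified wrong — the classic LOOCV artifact
  const <- scoreRecords(rep(0.2, 20), rep(TRUE, 20), rep(c(1L, 0L), 10))
  expect_equal(loocvAccuracy(const)$accuracy_pct, 0)

  # k = 20 folds quantise accuracy to multiples of 5
  set.seed(8)
  rnd <- scoreRecords(runif(20), sample(c(TRUE, FALSE), 20, TRUE),
                      sample(0:1, 20, TRUE))
  expect_equal(loocvAccuracy(rnd)$accuracy_pct %% 5, 0)
})

test_that("the smallest-maximizer tie-break is invariant to grid duplication", {
  set.seed(19)
  rec <- scoreRecords(runif(20, 0, 0.6), sample(c(TRUE, FALSE), 20, TRUE),
                      sample(0:1, 20, TRUE))
  g <- thresholdGrid(0.005, 0.5, 200)
  dup <- sort(c(g, g))                      # every value duplicated
  expect_equal(loocvAccuracy(rec, g), loocvAccuracy(rec, dup))
})

test_that("type-A uncertainty matches its closed form over all fold counts", {
  for (n in 2:50) for (k in 0:n) {
    outcomes <- rep(c(1L, 0L), c(k, n - k))
    phat <- k / n
    expect_equal(typeAUncertainty(outcomes),
                 100 * sqrt(phat * (1 - phat) / (n - 1)),
                 tolerance = 1e-12)
  }
  expect_equal(round(typeAUncertainty(rep(c(1, 0), c(14, 6))), 1), 10.5)
  expect_equal(round(typeAUncertainty(rep(c(1, 0), c(15, 5))), 1), 9.9)
  expect_equal(typeAUncertainty(rep(1, 20)), 0)
  expect_error(typeAUncertainty(1L), "at least 2")
})

test_that("uncertainty propagation and expansion follow their closed forms", {
  expect_equal(propagateMeanUncertainty(rep(2, 4)), 2 / sqrt(4))
  expect_equal(propagateMeanUncertainty(1.5), 1.5)
  expect_equal(expandedUncertainty(0), 0)
  expect_equal(expandedUncertainty(1.5, 3), 4.5)
})

test_that("system evaluation is exact in the separable limit and reproducible", {
  scores <- scoreRecords(
    c(rep(0.001, 26), rep(0.8, 10)),
    c(rep(TRUE, 26), rep(FALSE, 10)),
    rep(c(1L, 0L), c(26, 10)))
  rep1 <- evaluateSystem(scores, seed = 99)
  expect_equal(rep1@meanAccuracyPct, 100)
  expect_equal(rep1@uMeanPct, 0)
  expect_equal(rep1@expandedUPct, 0)

  rep2 <- evaluateSystem(scores, seed = 99)
  expect_identical(rep2@perSubset, rep1@perSubset)
})

test_that("score datasets and evaluation reports survive a disk round trip", {
  scores <- scoreRecords(c(0.01, 0.3, 0.9), c(TRUE, TRUE, FALSE),
                         c(1L, 0L, 0L))
  p <- withr::local_tempfile(fileext = ".csv")
  writeScores(scores, p)
  expect_equal(readScores(p), scores)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(readScores(bad), "format error")

  rep <- aggregateSubsets(c(70, 60), c(10.5, 9.9))
  out <- withr::local_tempfile(fileext = ".json")
  summ <- withr::local_tempfile(fileext = ".csv")
  writeEvalReport(rep, out, summ)
  back <- jsonlite::fromJSON(out)
  expect_equal(back$mean_accuracy_pct, 65)
  expect_equal(back$u_mean_pct, rep@uMeanPct)
  tab <- read.csv(summ)
  expect_equal(ncol(tab), 4)                       # row label, 2 sets, mean
  expect_equal(tab$mean[1], 65.0)
})
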