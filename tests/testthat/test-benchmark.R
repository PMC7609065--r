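test_that("stoichiometry bleach window mirrors probability-based detection", {
  # healthy stoichiometry never triggers
  expect_true(is.na(stoichiometry_bleach_index(rep(0.5, 100))))
  # S jumps to 1 at 0-based frame 20: 1-based window start 18 holds 4 hits
  s <- c(rep(0.5, 20), rep(1, 20))
  expect_equal(stoichiometry_bleach_index(s), 18L)
  # everything outside the window from the start
  expect_equal(stoichiometry_bleach_index(rep(0.9, 30)), 1L)
  # non-ALEX data is refused
  expect_error(stoichiometry_bleach_index(rep(NA_real_, 10)), "ALEX")
})

test_that("precision/recall arithmetic, including the printed contingency", {
  pr <- precision_recall(c(Tp = 80, Fp = 286, Fn = 120))
  expect_equal(pr$precision, 80 / 366)
  expect_equal(pr$precision, 0.2186, tolerance = 1e-4)
  expect_equal(pr$recall, 0.400)
  expect_equal(precision_recall(c(Tp = 10, Fp = 0, Fn = 0)),
               list(precision = 1, recall = 1))
  pr0 <- precision_recall(c(Tp = 0, Fp = 5, Fn = 5))
  expect_equal(pr0$precision, 0)
  expect_equal(pr0$recall, 0)
  # undefined ratios are NA markers, not zeros
  prna <- precision_recall(c(Tp = 0, Fp = 0, Fn = 0))
  expect_true(is.na(prna$precision))
  expect_true(is.na(prna$recall))
})

test_that("precision/recall agrees with direct counting on random sets", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    acc <- runif(n) < runif(1)
    truth <- runif(n) < runif(1)
    mine <- precision_recall(fretsort:::confusion_counts(acc, truth))
    oracle <- brute_precision_recall(acc, truth)
    expect_identical(mine, oracle)
  }
})

test_that("confusion matrix counts, fractions and binary collapse", {
  pred <- c("S", "D", "B", "A", "N", "X")
  cm <- confusion_matrix(pred, pred)
  expect_equal(sum(cm$counts), 6)
  expect_equal(sum(diag(cm$counts)), 6)
  expect_equal(cm$balanced_accuracy, 1)
  expect_error(confusion_matrix(pred, pred[-1]), "equal length")
  # balanced accuracy from a constructed 94/6 split
  pred2 <- c(rep("S", 94), rep("B", 6), rep("B", 94), rep("S", 6))
  truth2 <- c(rep("S", 100), rep("B", 100))
  cm2 <- confusion_matrix(pred2, truth2)
  expect_equal(cm2$tpr, 0.94)
  expect_equal(cm2$tnr, 0.94)
  expect_equal(cm2$balanced_accuracy, 0.94)
  # totals conserve the number of scored items
  expect_equal(sum(cm2$counts), 200)
})

test_that("precision-recall curve endpoints behave", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  cv <- precision_recall_curve(scores, truth, thresholds = c(0, 0.5, 0.95))
  expect_equal(cv$recall[1], 1)
  expect_equal(cv$n_accepted[1], 4)
  # perfectly separating scores reach precision 1 at recall 1
  expect_equal(cv$precision[2], 1)
  expect_equal(cv$recall[2], 1)
  # above the maximum score nothing is accepted and precision is undefined
  expect_equal(cv$n_accepted[3], 0)
  expect_true(is.na(cv$precision[3]))
})

test_that("threshold sorting accepts good smFRET and rejects artifacts", {
  set.seed(23)
  p <- clean_params(state_means = c(0.3, 0.7),
                    trans_prob_range = c(0.1, 0.1),
                    noise_sigma_range = c(0.05, 0.05))
  # a well-behaved molecule bleaching mid-trace
  good <- NULL
  for (i in 1:200) {
    lt <- simulate_trace(p, seed = i)
    if (lt$class == "D" && lt$first_dark > 100 && lt$first_dark <= 300) {
      good <- lt; break
    }
  }
  expect_false(is.null(good))
  # acceptor-only molecule: S near 1 throughout
  n <- 300
  acc_only <- fret_trace(dd = rnorm(n, 0, 0.02), da = rnorm(n, 0, 0.02),
                         aa = 1 + rnorm(n, 0, 0.02))
  res <- threshold_sort(list(good$trace, acc_only),
                        sort_thresholds(max_intensity_bounds = c(0.5, 2)),
                        truth = c(TRUE, FALSE))
  expect_equal(unname(res$accepted), c(TRUE, FALSE))
  expect_equal(res$counts[["Tp"]], 1)
  expect_equal(res$counts[["Tn"]], 1)
  # deterministic: same inputs, same decisions
  res2 <- threshold_sort(list(good$trace, acc_only),
                         sort_thresholds(max_intensity_bounds = c(0.5, 2)),
                         truth = c(TRUE, FALSE))
  expect_identical(res, res2)
  # empty input
  expect_length(threshold_sort(list(), sort_thresholds())$accepted, 0)
})

test_that("benchmark mixture has the stated composition", {
  mix <- simulate_benchmark_mix(n_true = 20, n_contaminant = 60, seed = 4)
  expect_length(mix$traces, 80)
  expect_equal(sum(mix$truth), 20)
  gt_cls <- vapply(mix$labeled[1:20], `[[`, character(1), "class")
  expect_true(all(gt_cls == "D"))
  # every ground-truth trace photobleaches within the observation window
  fd <- vapply(mix$labeled[1:20], `[[`, integer(1), "first_dark")
  expect_true(all(fd <= 300))
  bad_cls <- vapply(mix$labeled[21:80], `[[`, character(1), "class")
  expect_true(all(bad_cls %in% c("A", "N", "X")))
})
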