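test_that("confusion counting follows the strict score > threshold rule", {
  expect_error(confusion_at_threshold(numeric(0), character(0), 0.5), "empty")
  # all scores 1, all labels positive
  cm <- confusion_at_threshold(rep(1, 4), rep("HNSCC", 4), 0.5)
  expect_identical(unlist(cm[c("tp", "fp", "tn", "fn")]),
                   c(tp = 4L, fp = 0L, tn = 0L, fn = 0L))
  # threshold 1 predicts nothing positive, whatever the scores
  cm1 <- confusion_at_threshold(c(1, 1, 0.2), c("HNSCC", "LUNG", "LUNG"), 1)
  expect_identical(cm1$tp + cm1$fp, 0L)
  cm2 <- confusion_at_threshold(c(0.9, 0.6, 0.4, 0.1),
                                c("HNSCC", "HNSCC", "LUNG", "LUNG"), 0.5)
  expect_identical(unlist(cm2[c("tp", "fp", "tn", "fn")]),
                   c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
})

test_that("published diagnostic rates are reproduced from reconstructed counts", {
  # best-fit analysis: n = 52 HNSCC / 32 lung, printed sens 96 %, spec 88 %
  cm <- reconstruct_confusion(52, 32, 96, 88)
  expect_identical(unlist(cm[c("tp", "fp", "tn", "fn")]),
                   c(tp = 50L, fp = 4L, tn = 28L, fn = 2L))
  expect_identical(cm$fp + cm$fn, 6L) # six misclassified patients
  ssa <- sens_spec_acc(cm)
  expect_identical(round_half_up(100 * unname(ssa)), c(96, 88, 93))
  expect_equal(round(mcc(cm), 2), 0.85)

  # cross-validated analysis: printed sens 85 %, spec 84 %
  cm2 <- reconstruct_confusion(52, 32, 85, 84)
  expect_identical(unlist(cm2[c("tp", "fp", "tn", "fn")]),
                   c(tp = 44L, fp = 5L, tn = 27L, fn = 8L))
  expect_identical(cm2$fp + cm2$fn, 13L)
  expect_identical(round_half_up(100 * sens_spec_acc(cm2)[["accuracy"]]), 85)
  # the formula value for this matrix is 0.68 (2 dp)
  expect_equal(round(mcc(cm2), 2), 0.68)

  expect_identical(unlist(reconstruct_confusion(10, 10, 100, 100)
                          [c("tp", "fp", "tn", "fn")]),
                   c(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
})

test_that("MCC honours its extremes, symmetry and zero-marginal convention", {
  expect_equal(mcc(confusion_matrix(10, 0, 10, 0)), 1)
  expect_equal(mcc(confusion_matrix(0, 10, 0, 10)), -1)
  expect_equal(mcc(confusion_matrix(5, 5, 0, 0)), 0) # zero actual-negative margin
  for (seed in 1:20) {
    cnt <- withr::with_seed(seed, rpois(4, 8))
    if (sum(cnt) == 0) next
    cm <- confusion_matrix(cnt[1], cnt[2], cnt[3], cnt[4])
    sw <- confusion_matrix(cnt[3], cnt[4], cnt[1], cnt[2]) # tp<->tn, fp<->fn
    expect_equal(mcc(cm), mcc(sw))
    if (cnt[1] + cnt[4] >= 1 && cnt[2] + cnt[3] >= 1) {
      ssa <- sens_spec_acc(cm)
      npos <- cnt[1] + cnt[4]; nneg <- cnt[2] + cnt[3]
      expect_equal(ssa[["accuracy"]],
                   (ssa[["sensitivity"]] * npos + ssa[["specificity"]] * nneg) /
                     (npos + nneg))
    }
  }
})

test_that("threshold optimisation matches an exhaustive scan of all cuts", {
  th <- optimal_threshold(c(0.9, 0.6, 0.4, 0.1),
                          c("HNSCC", "HNSCC", "LUNG", "LUNG"), "accuracy")
  expect_equal(th, 0.5) # midpoint of the separating gap
  # all scores equal: an endpoint classifying the majority class correctly
  expect_equal(optimal_threshold(rep(0.7, 5), c(rep("HNSCC", 4), "LUNG")), 0)
  expect_equal(optimal_threshold(rep(0.7, 5), c("HNSCC", rep("LUNG", 4))), 1)
  brute_best <- function(scores, y, criterion) {
    cuts <- sort(unique(c(0, 1, scores, (sort(scores)[-1] +
                                           sort(scores)[-length(scores)]) / 2)))
    max(vapply(cuts, function(t) {
      pred <- scores > t
      if (criterion == "accuracy") mean(pred == (y == "HNSCC"))
      else mean(pred[y == "HNSCC"]) + mean(!pred[y == "LUNG"]) - 1
    }, numeric(1)))
  }
  for (seed in 1:8) {
    dat <- withr::with_seed(seed, list(s = round(runif(50), 2),
                                       y = sample(c("HNSCC", "LUNG"), 50,
                                                  replace = TRUE)))
    if (length(unique(dat$y)) < 2) next
    for (crit in c("accuracy", "youden")) {
      th <- optimal_threshold(dat$s, dat$y, crit)
      pred <- dat$s > th
      got <- if (crit == "accuracy") mean(pred == (dat$y == "HNSCC")) else
        mean(pred[dat$y == "HNSCC"]) + mean(!pred[dat$y == "LUNG"]) - 1
      expect_equal(got, brute_best(dat$s, dat$y, crit))
    }
    # the optimised accuracy can never fall below fixed clinical cuts
    th_acc <- optimal_threshold(dat$s, dat$y, "accuracy")
    acc_at <- function(t) mean((dat$s > t) == (dat$y == "HNSCC"))
    expect_gte(acc_at(th_acc), acc_at(0.55))
    expect_gte(acc_at(th_acc), acc_at(0.63))
  }
})

test_that("AUC equals the exhaustive pairwise win probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("HNSCC", "HNSCC", "LUNG", "LUNG"))$auc, 1)
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      n <- sample(6:30, 1)
      list(s = round(runif(n), 1),
           y = c("HNSCC", "LUNG", sample(c("HNSCC", "LUNG"), n - 2,
                                         replace = TRUE)))
    })
    pos <- dat$s[dat$y == "HNSCC"]; neg <- dat$s[dat$y == "LUNG"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(dat$s, dat$y)$auc, mean(pairs))
  }
})

test_that("labels independent of scores give chance-level AUC", {
  dat <- withr::with_seed(99, list(
    s = runif(84), y = rep(c("HNSCC", "LUNG"), c(52, 32))))
  auc <- roc_auc(dat$s, dat$y)$auc
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("ROC curve is monotone and the DeLong interval matches pROC", {
  dat <- withr::with_seed(7, list(
    s = c(rnorm(30, 0.7, 0.2), rnorm(25, 0.4, 0.2)),
    y = rep(c("HNSCC", "LUNG"), c(30, 25))))
  roc <- roc_auc(dat$s, dat$y)
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
  expect_true(roc$auc >= roc$ci95[1] && roc$auc <= roc$ci95[2])
  skip_if_not_installed("pROC")
  ref <- pROC::roc(dat$y, dat$s, levels = c("LUNG", "HNSCC"),
                   direction = "<", quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)))
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(roc$ci95, ci[c(1, 3)], tolerance = 1e-8)
})

test_that("baseline-table tests reproduce hand-computed statistics", {
  # tumor-stage distribution: lung (4,1,10,16) vs HNSCC (16,10,5,19)
  tab <- rbind(c(4, 1, 10, 16), c(16, 10, 5, 19))
  res <- chi_square_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$statistic, 12.7312, tolerance = 1e-4)
  expect_equal(res$df, 3)
  expect_equal(round(res$p, 3), 0.005) # prints as 0.005 at 3 dp
  # identical rows carry no association
  res0 <- chi_square_test(rbind(c(5, 10, 15), c(5, 10, 15)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # exact independence from products of margins
  ind <- outer(c(2, 3), c(4, 6))
  expect_equal(chi_square_test(ind)$statistic, 0)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("fisher_exact equals hypergeometric enumeration and is symmetric", {
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / 252)
  expect_equal(fisher_exact(rbind(c(2, 4), c(3, 6))), 1)
  for (seed in 1:6) {
    tab <- withr::with_seed(seed, matrix(rpois(4, 6) + 1, 2))
    # enumerate all tables with the observed margins
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    a <- max(0, k - n):min(k, m)
    pr <- dhyper(a, m, n, k)
    p_enum <- sum(pr[pr <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
    expect_equal(fisher_exact(tab), p_enum, tolerance = 1e-10)
    expect_equal(fisher_exact(tab), fisher_exact(tab[2:1, ]))
  }
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")
})

test_that("pooled t test agrees with a permutation oracle and handles degeneracy", {
  expect_equal(t_test_independent(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  expect_error(t_test_independent(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               "zero pooled variance")
  dat <- withr::with_seed(5, list(x = rnorm(30, 1), y = rnorm(30, 0)))
  res <- t_test_independent(dat$x, dat$y)
  expect_lt(res$p, 0.01)
  # permutation oracle on the mean difference
  obs <- mean(dat$x) - mean(dat$y)
  pooled <- c(dat$x, dat$y)
  perm <- withr::with_seed(6, vapply(1:4000, function(i) {
    idx <- sample(60, 30)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1)))
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(res$p - p_perm), 0.02)
})
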