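test_that("threshold metrics reproduce every published table row at 2 decimals", {
  dist <- noreflow_score_distribution()
  printed <- noreflow_threshold_table()
  for (i in seq_len(nrow(printed))) {
    m <- threshold_metrics(dist, printed$threshold[i])
    expect_equal(c(m$tp, m$fp, m$tn, m$fn),
                 c(printed$tp[i], printed$fp[i], printed$tn[i], printed$fn[i]))
    expect_equal(round_up(m$prevalence_positive), printed$prevalence[i])
    expect_equal(round_up(m$accuracy), printed$accuracy[i])
    expect_equal(round_up(m$sensitivity), printed$sensitivity[i])
    expect_equal(round_up(m$specificity), printed$specificity[i])
    expect_equal(round_up(m$ppv), printed$ppv[i])
    if (is.na(printed$npv[i])) expect_true(is.na(m$npv))
    else expect_equal(round_up(m$npv), printed$npv[i])
    expect_equal(round_up(m$f_score), printed$f_score[i])
  }
  # threshold 0 is forced: everyone positive
  m0 <- threshold_metrics(dist, 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
})

test_that("degenerate separations bound the ROC", {
  perfect <- score_distribution(cases = c(0, 10), controls = c(10, 0))
  expect_equal(roc_curve(perfect)$auc, 1)
  m <- threshold_metrics(perfect, 1)
  expect_equal(c(m$sensitivity, m$specificity, m$ppv, m$npv), c(1, 1, 1, 1))

  same <- score_distribution(cases = c(4, 3, 2), controls = c(8, 6, 4))
  expect_equal(roc_curve(same)$auc, 0.5)
  expect_error(roc_curve(score_distribution(c(0, 0), c(5, 0))), "non-empty")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  mw_auc <- function(dist) {
    x <- rep(as.integer(names(dist$cases)), dist$cases)
    y <- rep(as.integer(names(dist$controls)), dist$controls)
    cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
    mean(cmp)
  }
  set.seed(14)
  for (i in 1:10) {
    dist <- score_distribution(rpois(4, 6), rpois(4, 6))
    if (sum(dist$cases) == 0 || sum(dist$controls) == 0) next
    expect_equal(roc_curve(dist)$auc, mw_auc(dist), tolerance = 1e-12)
  }
  expect_equal(roc_curve(noreflow_score_distribution())$auc,
               mw_auc(noreflow_score_distribution()), tolerance = 1e-12)
})

test_that("AUC and its Hanley-McNeil interval match the published ROC analysis", {
  r <- roc_curve(noreflow_score_distribution())
  expect_equal(round(r$auc, 3), 0.724)
  expect_true(r$ci_low >= 0.60 && r$ci_low <= 0.62)
  expect_true(r$ci_high >= 0.83 && r$ci_high <= 0.85)
  expect_equal(round(r$ci_low, 3), 0.611)
  expect_equal(round(r$ci_high, 3), 0.838)
  # curve endpoints and monotonicity
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
})

test_that("AUC agrees with an independent ROC implementation", {
  dist <- noreflow_score_distribution()
  resp <- c(rep(1, sum(dist$cases)), rep(0, sum(dist$controls)))
  pred <- c(rep(as.integer(names(dist$cases)), dist$cases),
            rep(as.integer(names(dist$controls)), dist$controls))
  ref <- pROC::auc(pROC::roc(resp, pred, quiet = TRUE, direction = "<"))
  expect_equal(roc_curve(dist)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("sensitivity falls and specificity rises as the threshold increases", {
  set.seed(3)
  for (i in 1:5) {
    dist <- score_distribution(rpois(5, 5) + 1, rpois(5, 5) + 1)
    tt <- threshold_table(dist)
    tt <- tt[order(tt$threshold), ]
    expect_true(all(diff(tt$sensitivity) <= 0))
    expect_true(all(diff(tt$specificity) >= 0))
  }
})

test_that("per-score counts are recoverable from the cumulative confusion cells", {
  dist <- noreflow_score_distribution()
  expect_equal(unname(dist$cases + dist$controls), c(21L, 20L, 25L, 11L))
  back <- distribution_from_metrics(threshold_table(dist))
  expect_equal(back$cases, dist$cases)
  expect_equal(back$controls, dist$controls)
  expect_error(distribution_from_metrics(data.frame(threshold = c(0, 2),
                                                    tp = c(5, 1), fp = c(5, 1))),
               "every threshold")
})

test_that("the F-optimal threshold breaks ties upward", {
  tt <- threshold_table(noreflow_score_distribution())
  expect_equal(optimal_threshold(tt), 1)
  expect_equal(tt$f_score[tt$threshold == 1], 0.70, tolerance = 0.005)
  tied <- data.frame(threshold = c(1, 2), f_score = c(0.7, 0.7))
  expect_equal(optimal_threshold(tied), 2)
  expect_equal(optimal_threshold(data.frame(threshold = 3, f_score = 0.2)), 3)
})
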