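test_that("the published confusion matrix reproduces the full metric panel", {
  met <- classifier_metrics(table1_cm())
  pct1 <- function(v) round(100 * v, 1)
  expect_equal(pct1(met$accuracy), 63.9)
  expect_equal(pct1(met$sensitivity), 56.0)
  expect_equal(pct1(met$specificity), 74.7)
  expect_equal(pct1(met$ppv), 75.3)
  expect_equal(pct1(met$npv), 55.2)
  expect_equal(pct1(met$prevalence), 58.0)
  expect_equal(pct1(met$detection_rate), 32.5)
  expect_equal(pct1(met$detection_prevalence), 43.1)
  expect_equal(pct1(met$balanced_accuracy), 65.4)
  expect_equal(pct1(met$youden_j), 30.7)
  expect_equal(pct1(met$no_information_rate), 58.0)
  expect_equal(round(met$kappa, 4), 0.2931)
  expect_equal(met$total, 18440)
})

test_that("degenerate confusion matrices produce the expected extremes", {
  perfect <- classifier_metrics(confusion_matrix(100, 0, 0, 80))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$youden_j, 1)

  # marginally independent decisions: kappa exactly 0
  indep <- classifier_metrics(confusion_matrix(25, 25, 25, 25))
  expect_equal(indep$kappa, 0)
  expect_equal(indep$youden_j, 0)

  expect_error(confusion_matrix(0, 0, 0, 0), "positive total")
  # zero-denominator metrics surface as NA, not errors
  nocalls <- classifier_metrics(confusion_matrix(0, 0, 10, 10))
  expect_true(is.na(nocalls$ppv))
})

test_that("confusion construction is symmetric under decision/truth swap", {
  d <- random_labels(500, 0.45, seed = 3)
  t <- random_labels(500, 0.55, seed = 4)
  a <- confusion(d, t); b <- confusion(t, d)
  expect_equal(a$tp, b$tp); expect_equal(a$tn, b$tn)
  expect_equal(a$fp, b$fn); expect_equal(a$fn, b$fp)
  expect_error(confusion(d, t[-1]), "equal length")
})

test_that("metric identities hold on randomized confusion matrices", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      cm <- confusion_matrix(sample(1:500, 1), sample(1:500, 1),
                             sample(1:500, 1), sample(1:500, 1))
      m <- classifier_metrics(cm)
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
      expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)
      expect_equal(m$no_information_rate, max(m$prevalence, 1 - m$prevalence))
      expect_lte(m$detection_rate, m$detection_prevalence)
      expect_lte(m$detection_rate, m$prevalence)
      expect_gte(m$kappa, -1); expect_lte(m$kappa, 1)
      frs <- unlist(m[c("accuracy", "sensitivity", "specificity", "ppv",
                        "npv", "prevalence", "detection_rate",
                        "detection_prevalence", "balanced_accuracy",
                        "no_information_rate")])
      expect_true(all(frs >= 0 & frs <= 1))
    }
  })
})

test_that("PPV equals the hit rate achieved by firing on in-focus decisions", {
  d <- random_labels(2000, 0.4, seed = 7)
  t <- as.integer(random_labels(2000, 0.8, seed = 8) & d |
                    random_labels(2000, 0.5, seed = 9) & !d)
  m <- classifier_metrics(confusion(d, t))
  fired <- which(d == 1L)
  expect_equal(mean(t[fired]), m$ppv)
})

test_that("treatment-efficiency arithmetic matches the published estimates", {
  eff <- treatment_efficiency(table1_cm(), n_focus_annot = 11633,
                              n_out_annot = 23212 - 11633)
  expect_equal(round(eff$relative_treatment_time, 2), 1.94)
  expect_equal(round(100 * eff$mishit_ratio, 1), 32.9)
  expect_equal(round(100 * eff$mishit_reduction, 1), 67.1)
  expect_equal(round(eff$hits_per_minute_operator), 45)
  expect_equal(round(eff$hits_per_minute_ai), 23)

  # a perfect classifier on fully detected data: no extra time, no mishits
  t <- random_labels(1000, 0.5, seed = 5)
  cm <- confusion(t, t)
  effp <- treatment_efficiency(cm, sum(t), sum(1 - t))
  expect_equal(effp$relative_treatment_time, 1)
  expect_equal(effp$mishit_ratio, 0)
  expect_equal(effp$mishit_reduction, 1)
  expect_warning(treatment_efficiency(confusion_matrix(0, 5, 5, 5), 10, 10),
                 "tp = 0")
})

test_that("the alternative no-detection policy matches the marginal reconstruction", {
  # reconstruct the full 23 212-frame call/truth streams from the published
  # marginals: 11 633 annotated in focus; among detected frames the
  # confusion counts; 4 772 undetected split by subtraction
  nd_focus <- 11633 - (5987 + 4700)   # undetected but annotated in focus
  nd_out <- 4772 - nd_focus
  truth <- rep(c(1L, 0L, 1L, 0L, 1L, 0L),
               c(5987, 1961, 4700, 5792, nd_focus, nd_out))
  calls <- rep(c("in_focus", "in_focus", "out_of_focus", "out_of_focus",
                 "no_detection", "no_detection"),
               c(5987, 1961, 4700, 5792, nd_focus, nd_out))
  alt <- alternative_policy_report(calls, truth)
  expect_equal(round(100 * alt$sensitivity, 1), 51.5)
  expect_equal(round(100 * alt$specificity, 1), 83.1)
  expect_gt(alt$accuracy, classifier_metrics(table1_cm())$accuracy)

  # with no undetected frames the report equals the exclude-policy metrics
  clean_calls <- ifelse(random_labels(300, 0.5, seed = 12) == 1L,
                        "in_focus", "out_of_focus")
  clean_truth <- random_labels(300, 0.5, seed = 13)
  expect_equal(alternative_policy_report(clean_calls, clean_truth),
               classifier_metrics(confusion(
                 apply_no_detection_policy(clean_calls, "exclude")$decisions,
                 clean_truth)))

  # sensitivity under as_out_of_focus never exceeds the exclude policy
  withr::with_seed(14, {
    for (rep in 1:10) {
      n <- 400
      tr <- rbinom(n, 1, 0.5)
      cl <- sample(c("in_focus", "out_of_focus", "no_detection"), n, TRUE)
      if (!any(cl == "in_focus" & tr == 1L)) next
      excl <- apply_no_detection_policy(cl, "exclude")
      s_ex <- classifier_metrics(confusion(excl$decisions,
                                           tr[excl$kept]))$sensitivity
      s_alt <- alternative_policy_report(cl, tr)$sensitivity
      expect_lte(s_alt, s_ex)
    }
  })
})
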