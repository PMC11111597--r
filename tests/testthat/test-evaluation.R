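# Confusion metrics, exact tests, stratified reporting

test_that("confusion_counts partitions records with dementia positive", {
  truth <- c(rep("dementia", 3), rep("cognitively_normal", 2))
  cc <- confusion_counts(truth, truth)
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 3L, fn = 0L, fp = 0L, tn = 2L))
  fx <- table2_fixture()
  cc2 <- confusion_counts(fx$true_label, fx$predicted_label)
  expect_equal(unlist(cc2[c("tp", "fn", "fp", "tn")]),
               c(tp = 476L, fn = 13L, fp = 17L, tn = 1080L))
  expect_error(confusion_counts(c("dementia", "unknown"),
                                c("dementia", "dementia")),
               class = "vs_validation_error")
  expect_error(confusion_counts("dementia", character(0)),
               class = "vs_validation_error")
})

test_that("metrics carry fractions and percent at one half-up decimal", {
  m <- classification_metrics(
    structure(list(tp = 476L, fn = 13L, fp = 17L, tn = 1080L),
              class = "confusion_counts"))
  expect_equal(m$accuracy$percent, 98.1)
  expect_equal(m$accuracy$numerator, 1556L)
  expect_equal(m$sensitivity$percent, 97.3)
  expect_equal(m$specificity$percent, 98.5)

  mc <- classification_metrics(
    structure(list(tp = 15L, fn = 3L, fp = 1L, tn = 41L),
              class = "confusion_counts"))
  expect_equal(mc$accuracy$percent, 93.3)
  expect_equal(mc$sensitivity$percent, 83.3)
  expect_equal(mc$specificity$percent, 97.6)

  # empty positive stratum: sensitivity undefined, not an error
  m0 <- classification_metrics(
    structure(list(tp = 0L, fn = 0L, fp = 0L, tn = 10L),
              class = "confusion_counts"))
  expect_true(is.na(m0$sensitivity$percent))
  expect_equal(m0$specificity$percent, 100.0)

  # half-up at the .X5 tie, unlike round-half-even
  expect_equal(percent_1dp(93.35), 93.4)
  expect_equal(percent_1dp(100 * 1080 / 1097), 98.5)
})

test_that("accuracy identity holds for arbitrary prediction vectors", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    truth <- sample(c("dementia", "cognitively_normal"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
    pred <- ifelse(runif(n) < 0.8, truth,
                   ifelse(truth == "dementia", "cognitively_normal",
                          "dementia"))
    cc <- confusion_counts(truth, pred)
    m <- classification_metrics(cc)
    P <- cc$tp + cc$fn; N <- cc$fp + cc$tn
    if (P > 0 && N > 0) {
      acc <- (m$sensitivity$numerator + m$specificity$numerator) / (P + N)
      expect_equal(m$accuracy$numerator / m$accuracy$denominator, acc)
    }
  }
})

test_that("2x2 exact test matches exhaustive enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1.0)
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_equal(p, brute_fisher_2x2(tab), tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(tab)), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[, 2:1]), tolerance = 1e-12)
    # independent reference implementation
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2, 2)),
               class = "vs_validation_error")
})

test_that("r x c enumeration agrees with 2x2, brute force and fisher.test", {
  set.seed(17)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab), fisher_exact_2x2(tab),
                 tolerance = 1e-9)
  }
  for (i in 1:8) {
    tab <- matrix(rpois(6, 3), 3, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_rxc(tab)
    expect_equal(p, brute_fisher_rx2(tab), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
})

test_that("enumeration budget errors and Monte Carlo fallback works", {
  tab <- matrix(c(765, 17, 735, 9, 56, 4), 3, 2, byrow = TRUE)
  expect_error(fisher_exact_rxc(tab, budget = 10),
               class = "vs_budget_error")
  p_exact <- fisher_exact_rxc(tab)
  p_mc <- fisher_exact_rxc(tab, monte_carlo = TRUE, n_sim = 2e4, seed = 5)
  expect_lt(abs(p_mc - p_exact), 0.01)
  # MC is seeded-deterministic
  expect_identical(p_mc,
                   fisher_exact_rxc(tab, monte_carlo = TRUE, n_sim = 2e4,
                                    seed = 5))
})

test_that("age-decade report counts, percents and additivity are right", {
  fx <- table2_fixture()
  set.seed(31)
  # attach study-plausible ages; force 4 dementia records into the 40s,
  # exactly one of them misclassified
  fx$age <- round(runif(nrow(fx), 60, 95), 1)
  dem_correct <- which(fx$true_label == "dementia" &
                         fx$predicted_label == "dementia")[1:3]
  dem_wrong <- which(fx$true_label == "dementia" &
                       fx$predicted_label == "cognitively_normal")[1]
  fx$age[c(dem_correct, dem_wrong)] <- c(42, 44, 47, 45)
  rep40 <- accuracy_by_age_decade(fx)
  row <- rep40[rep40$group == "dementia" & rep40$decade == 40, ]
  expect_equal(row$n, 4L)
  expect_equal(row$n_correct, 3L)
  expect_equal(row$percent, 75.0)
  # empty bins stay with n = 0 and NA percent
  row20 <- rep40[rep40$group == "dementia" & rep40$decade == 20, ]
  expect_equal(row20$n, 0L)
  expect_true(is.na(row20$percent))
  # counts add up to the overall correct total
  expect_equal(sum(rep40$n_correct), 1556L)
  expect_equal(sum(rep40$n), 1586L)
  fx$age[1] <- 101
  expect_error(accuracy_by_age_decade(fx), class = "vs_exclusion_error")
})

test_that("evaluate_predictions assembles the stratified report", {
  fx <- table2_fixture()
  set.seed(41)
  fx$age <- round(runif(nrow(fx), 55, 95), 1)
  rep <- evaluate_predictions(fx)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$total$metrics$accuracy$percent, 98.1)
  expect_equal(rep$facility$B$metrics$accuracy$percent, 98.8)
  expect_lt(rep$total$fisher_p, 0.001)
  expect_equal(round(rep$facility_heterogeneity$accuracy, 3), 0.015)
  expect_equal(round(rep$facility_heterogeneity$sensitivity, 3), 0.010)
  expect_false(is.null(rep$by_age_decade))
  # JSON serialization round-trips the headline numbers
  j <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(j$total$metrics$accuracy$percent, 98.1)
  expect_error(evaluate_predictions(data.frame()),
               class = "vs_validation_error")
})
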