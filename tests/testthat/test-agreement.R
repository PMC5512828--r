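# expand a documented-by-calculated contingency table back into pairs
pairs_from_table <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  doc <- rep(rownames(tab)[idx[, 1]], tab[idx])
  calc <- rep(colnames(tab)[idx[, 2]], tab[idx])
  tibble::tibble(patient_id = sprintf("T%04d", seq_along(doc)),
                 documented = as_risk_category(doc),
                 calculated = as_risk_category(calc, extended = TRUE))
}

ref_tab <- reference_tables()$agreement

test_that("binary aggregation at the 20% threshold conserves counts", {
  bin <- aggregate_binary(ref_tab)
  expect_equal(unname(bin), matrix(c(19, 6, 130, 525), 2, byrow = TRUE))
  expect_equal(sum(bin), sum(ref_tab))
  # all-zero table maps to all-zero 2x2
  expect_equal(sum(aggregate_binary(ref_tab * 0)), 0)
  # a single CVD-calculated pair with documented <10 lands in (low, high)
  single <- ref_tab * 0
  single["<10", "history_of_cvd"] <- 1
  expect_equal(unname(aggregate_binary(single)),
               matrix(c(0, 0, 1, 0), 2, byrow = TRUE))
  # conservation on random tables
  set.seed(31)
  for (i in 1:15) {
    rnd <- ref_tab
    rnd[] <- sample(0:40, length(ref_tab), TRUE)
    expect_equal(sum(aggregate_binary(rnd)), sum(rnd))
  }
})

test_that("the CVD match rule rewrites only documented-high CVD pairs", {
  pairs <- pairs_from_table(ref_tab)
  matched <- apply_cvd_match_rule(pairs)
  hit <- pairs$calculated == "history_of_cvd" & is_high_risk(pairs$documented)
  expect_equal(as.character(matched$calculated[hit]),
               as.character(pairs$documented[hit]))
  expect_equal(matched$calculated[!hit], pairs$calculated[!hit])
  # documented <10 with calculated CVD is untouched
  low_cvd <- pairs$documented == "<10" & pairs$calculated == "history_of_cvd"
  expect_true(all(matched$calculated[low_cvd] == "history_of_cvd"))
  # diagonal mass never decreases
  set.seed(33)
  for (i in 1:10) {
    rnd <- ref_tab
    rnd[] <- sample(0:15, length(ref_tab), TRUE)
    rp <- pairs_from_table(rnd)
    before <- sum(diag(agreement_table(rp, square = TRUE)))
    after <- sum(diag(agreement_table(apply_cvd_match_rule(rp), square = TRUE)))
    expect_gte(after, before)
  }
})

test_that("Cohen's kappa satisfies its defining identities", {
  # perfect agreement
  expect_equal(cohen_kappa(diag(c(5, 9, 2))), 1)
  # independent margins (outer product) give zero
  outer_tab <- outer(c(20, 30, 50), c(10, 60, 30))
  expect_equal(cohen_kappa(outer_tab), 0, tolerance = 1e-12)
  # invariant under simultaneous permutation of rows and columns
  set.seed(19)
  for (i in 1:10) {
    m <- matrix(sample(0:20, 25, TRUE), 5)
    perm <- sample(5)
    expect_equal(cohen_kappa(m), cohen_kappa(m[perm, perm]))
  }
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
  expect_warning(k <- cohen_kappa(matrix(c(4, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(k))
})

test_that("kappa on the reference tables matches the hand-arithmetic oracle", {
  bin <- aggregate_binary(ref_tab)
  # oracle: p_o = 544/680, p_e = 351530/462400, worked by hand
  expect_equal(cohen_kappa(bin), (544 / 680 - 351530 / 462400) /
                 (1 - 351530 / 462400), tolerance = 1e-12)
  expect_equal(cohen_kappa(bin), 0.16587, tolerance = 1e-4)
  # six-level square table after the CVD match rule
  sq <- agreement_table(apply_cvd_match_rule(pairs_from_table(ref_tab)),
                        square = TRUE)
  expect_equal(sum(sq), 680)
  expect_equal(cohen_kappa(sq), 0.17784, tolerance = 1e-4)
})

test_that("kappa agrees with a pair-resampling chance-agreement estimate", {
  set.seed(101)
  for (i in 1:3) {
    m <- matrix(sample(5:40, 16, TRUE), 4)
    n <- sum(m)
    p_o <- sum(diag(m)) / n
    # Monte-Carlo chance agreement: resample the two raters independently
    # from their marginal distributions
    B <- 2e5
    r1 <- sample.int(4, B, TRUE, prob = rowSums(m))
    r2 <- sample.int(4, B, TRUE, prob = colSums(m))
    p_e_mc <- mean(r1 == r2)
    expect_equal(cohen_kappa(m), (p_o - p_e_mc) / (1 - p_e_mc),
                 tolerance = 0.02)
  }
})

test_that("proportion intervals bracket the estimate and hit known values", {
  ci <- proportion_ci(4, 11, "wilson_cc")
  expect_equal(round(100 * ci[["lower"]], 1), 12.4)
  expect_equal(round(100 * ci[["upper"]], 1), 68.4)
  # closed-form oracle for the lower bound, z = 1.96 quantile
  z <- qnorm(0.975); p <- 4 / 11; n <- 11
  lower <- (2 * n * p + z^2 - 1 -
              z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  expect_equal(ci[["lower"]], lower, tolerance = 1e-12)
  expect_equal(proportion_ci(0, 10)[["lower"]], 0)
  expect_equal(proportion_ci(10, 10)[["upper"]], 1)
  expect_equal(proportion_ci(0, 10, "exact")[["lower"]], 0)
  expect_equal(proportion_ci(10, 10, "exact")[["upper"]], 1)
  # exact = Clopper-Pearson; reproduces the printed (0.09, 0.45) for 6/25
  expect_equal(round(proportion_ci(6, 25, "exact"), 2),
               c(lower = 0.09, upper = 0.45))
  expect_error(proportion_ci(5, 0), "n >= 1")
  expect_error(proportion_ci(-1, 5), "0 <= x")
  # the interval always contains the point estimate
  set.seed(55)
  for (i in 1:40) {
    n <- sample(1:60, 1); x <- sample(0:n, 1)
    for (method in c("wilson_cc", "exact")) {
      ci <- proportion_ci(x, n, method)
      expect_lte(ci[["lower"]], x / n + 1e-12)
      expect_gte(ci[["upper"]], x / n - 1e-12)
      expect_gte(ci[["lower"]], 0)
      expect_lte(ci[["upper"]], 1)
    }
  }
})

test_that("documented-accuracy pairs use the first documented score", {
  chart <- synthetic_chart()
  model <- toy_tc_model()
  enrol <- as.Date("2015-01-01")
  p <- dplyr::bind_rows(
    make_patient("D1", age = 60),
    make_patient("D2", age = 60, conditions = list("stable_angina")),
    make_patient("D3", age = 60)  # never documented -> excluded
  )
  meas <- dplyr::bind_rows(
    make_measurements("D1", enrol + 1, "sbp", 150),
    make_measurements("D1", enrol + 1, "total_cholesterol", 5.2),
    make_measurements("D2", enrol + 1, "sbp", 120),
    make_measurements("D2", enrol + 1, "total_cholesterol", 4.1),
    make_measurements("D3", enrol + 1, "sbp", 120)
  )
  docs <- tibble::tibble(
    patient_id = c("D1", "D1", "D2"),
    date = c(enrol + 90, enrol + 30, enrol + 60),
    category = c(">=40", "10-<20", "<10"))
  cohort <- emr_cohort(p, meas, documented_scores = docs)
  pairs <- documented_accuracy_pairs(cohort, chart, model)
  expect_equal(nrow(pairs), 2)
  # first documented score by date, not file order
  expect_equal(as.character(pairs$documented[pairs$patient_id == "D1"]),
               "10-<20")
  # CVD patients land on the calculated history_of_cvd level
  expect_equal(as.character(pairs$calculated[pairs$patient_id == "D2"]),
               "history_of_cvd")
  # calculated side for D1 equals direct chart lookup on retrospective values
  direct <- calculate_risk(
    data.frame(sex = "female", age = 60, smoker = FALSE, diabetic = FALSE,
               sbp = 150, tc = 5.2), chart)
  expect_equal(as.character(pairs$calculated[pairs$patient_id == "D1"]),
               as.character(direct))
  # empty documented side -> empty pair list
  none <- emr_cohort(p, meas)
  expect_equal(nrow(documented_accuracy_pairs(none, chart, model)), 0)
})

test_that("diagonal agreement share matches direct arithmetic", {
  expect_equal(percent_correct(ref_tab), 444 / 680, tolerance = 1e-12)
  summ <- summarise_agreement(pairs_from_table(ref_tab))
  expect_equal(summ$n, 680)
  expect_equal(round(100 * summ$prop_correct), 65)
  expect_equal(summ$prop_doc_high_actually_low, 6 / 25)
  expect_equal(summ$prop_doc_low_actually_high, 130 / 655)
  expect_lte(summ$ci_doc_high_actually_low[["lower"]], 6 / 25)
  expect_gte(summ$ci_doc_high_actually_low[["upper"]], 6 / 25)
  expect_equal(round(summ$kappa_binary, 3), 0.166)
  expect_equal(round(summ$kappa_matched, 3), 0.178)
})
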