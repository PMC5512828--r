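index0 <- as.Date("2015-03-01")

test_that("prospective selection takes the earliest value on/after the index", {
  m <- make_measurements("P1", index0 + c(3, 10), "sbp", c(150, 140))
  expect_equal(first_prospective(m, index0, "sbp"), 150)
  expect_equal(first_prospective(m, index0 + 4, "sbp"), 140)
  expect_true(is.na(first_prospective(m, index0 + 11, "sbp")))
  # a missing (NA) record is skipped
  m2 <- make_measurements("P1", index0 + c(1, 5), "sbp", c(NA, 135))
  expect_equal(first_prospective(m2, index0, "sbp"), 135)
  # measurement on the index date itself counts
  expect_equal(first_prospective(
    make_measurements("P1", index0, "sbp", 128), index0, "sbp"), 128)
})

test_that("retrospective selection takes the latest value strictly before the index", {
  m <- make_measurements("P1", index0 - c(20, 2), "sbp", c(160, 145))
  expect_equal(first_retrospective(m, index0, "sbp"), 145)
  # only a same-day measurement: excluded under the strict rule
  same <- make_measurements("P1", index0, "sbp", 150)
  expect_true(is.na(first_retrospective(same, index0, "sbp")))
  expect_equal(first_retrospective(same, index0, "sbp", strict = FALSE), 150)
  expect_true(is.na(first_retrospective(m[0, ], index0, "sbp")))
})

test_that("same-date ties resolve to file order with a warning", {
  m <- make_measurements("P1", rep(index0 + 2, 2), "sbp", c(151, 149))
  expect_warning(v <- first_prospective(m, index0, "sbp"), "tie")
  expect_equal(v, 151)
  # brute-force oracle: scan rows in order, keep first with the best date
  best_date <- min(m$date[m$date >= index0])
  oracle <- m$value[m$date == best_date][1]
  expect_equal(v, oracle)
  # selection is invariant under permutation apart from documented ties
  m3 <- make_measurements("P1", index0 + c(5, 1, 9), "sbp", c(1, 2, 3))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(first_prospective(m3[perm, ], index0, "sbp"), 2)
    expect_equal(first_retrospective(m3[perm, ], index0 + 10, "sbp"), 3)
  }
})

test_that("vectorised selection matches the single-patient path", {
  set.seed(13)
  meas <- tibble::tibble(
    patient_id = sample(sprintf("P%d", 1:8), 60, TRUE),
    date = index0 + sample(-30:30, 60, TRUE),
    kind = sample(c("sbp", "total_cholesterol"), 60, TRUE),
    value = round(runif(60, 100, 180)))
  index <- tibble::tibble(patient_id = sprintf("P%d", 1:8), index_date = index0)
  for (dir in c("prospective", "retrospective")) {
    out <- suppressWarnings(select_measurement(meas, index, "sbp", dir))
    expect_equal(out$patient_id, index$patient_id)
    singles <- vapply(index$patient_id, function(id) {
      suppressWarnings(single <- penrisk:::single_patient_select(
        meas[meas$patient_id == id, ], index0, "sbp", dir))
      single
    }, numeric(1))
    expect_equal(out$value, unname(singles))
  }
})

test_that("SBP imputation fills only absences and is idempotent", {
  sel <- tibble::tibble(sbp = c(NA, 142, NA))
  out <- impute_sbp(sel)
  expect_equal(out$sbp, c(130, 142, 130))
  expect_equal(out$sbp_imputed, c(TRUE, FALSE, TRUE))
  expect_equal(impute_sbp(out), out)  # no-op on a fully imputed frame
  out2 <- impute_sbp(sel, fill = 120)
  expect_equal(out2$sbp[1], 120)
  clean <- tibble::tibble(sbp = c(110, 125))
  expect_equal(impute_sbp(clean)$sbp, clean$sbp)
  expect_false(any(impute_sbp(clean)$sbp_imputed))
})

test_that("the cholesterol model recovers a noiseless affine rule exactly", {
  set.seed(2)
  d <- tibble::tibble(
    age = sample(30:80, 50, TRUE),
    sex = sample(c("male", "female"), 50, TRUE),
    sbp = runif(50, 100, 200))
  d$tc <- 2 + 0.03 * d$age + 0.4 * (d$sex == "female") + 0.01 * d$sbp
  model <- fit_tc_model(d)
  expect_equal(unname(model$coefficients), c(2, 0.03, 0.4, 0.01),
               tolerance = 1e-10)
  expect_equal(model$fit_n, 50)
})

test_that("the cholesterol fit matches an independent normal-equations solve", {
  set.seed(42)
  n <- 5000
  d <- tibble::tibble(
    age = sample(30:80, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    sbp = runif(n, 100, 200))
  truth <- c(2, 0.03, 0.4, 0.01)
  d$tc <- truth[1] + truth[2] * d$age + truth[3] * (d$sex == "female") +
    truth[4] * d$sbp + rnorm(n, sd = 0.5)
  model <- fit_tc_model(d)
  # oracle: explicit least-squares solve, independent of lm
  X <- cbind(1, d$age, as.integer(d$sex == "female"), d$sbp)
  beta <- solve(t(X) %*% X, t(X) %*% d$tc)[, 1]
  expect_equal(unname(model$coefficients), unname(beta), tolerance = 1e-8)
  # coefficients lie within 3 standard errors of the truth
  se <- sqrt(diag(solve(t(X) %*% X)) * sum((d$tc - X %*% beta)^2) / (n - 4))
  expect_true(all(abs(model$coefficients - truth) < 3 * se))
})

test_that("degenerate cholesterol fits are rejected", {
  tiny <- tibble::tibble(age = c(40, 50, 60), sex = "male",
                         sbp = c(120, 130, 140), tc = c(5, 5.5, 6))
  expect_error(fit_tc_model(tiny), "at least 4")
  flat <- tibble::tibble(age = 50, sex = "male", sbp = 130, tc = runif(10))
  expect_error(fit_tc_model(flat), "rank-deficient")
})

test_that("TC imputation predicts from the affine model and flags fills", {
  d <- tibble::tibble(age = sample(30:80, 30, TRUE),
                      sex = sample(c("male", "female"), 30, TRUE),
                      sbp = runif(30, 100, 200))
  d$tc <- 2 + 0.03 * d$age + 0.4 * (d$sex == "female") + 0.01 * d$sbp
  model <- fit_tc_model(d)
  newd <- tibble::tibble(age = c(50, 60), sex = c("female", "male"),
                         sbp = c(130, 150), tc = c(NA, 6.5),
                         sbp_imputed = FALSE)
  out <- impute_tc(newd, model)
  expect_equal(out$tc, c(2 + 1.5 + 0.4 + 1.3, 6.5), tolerance = 1e-9)
  expect_equal(out$tc_imputed, c(TRUE, FALSE))
  # SBP must be resolved first
  expect_error(impute_tc(tibble::tibble(age = 50, sex = "male", sbp = NA,
                                        tc = NA), model),
               "SBP must be imputed")
  # an all-missing-TC frame becomes fully scoreable
  allna <- tibble::tibble(age = sample(40:70, 10, TRUE),
                          sex = "female", sbp = runif(10, 110, 170),
                          tc = NA_real_, smoker = FALSE, diabetic = FALSE)
  allna <- impute_tc(allna, model)
  expect_false(anyNA(allna$tc))
  expect_false(anyNA(calculate_risk(allna, synthetic_chart())))
})

test_that("imputation never alters observed values", {
  set.seed(8)
  d <- tibble::tibble(age = sample(30:80, 40, TRUE),
                      sex = sample(c("male", "female"), 40, TRUE),
                      sbp = ifelse(runif(40) < 0.3, NA, runif(40, 100, 200)),
                      tc = ifelse(runif(40) < 0.3, NA, runif(40, 3, 9)))
  model <- toy_tc_model()
  out <- impute_tc(impute_sbp(d), model)
  obs_sbp <- !is.na(d$sbp)
  obs_tc <- !is.na(d$tc)
  expect_equal(out$sbp[obs_sbp], d$sbp[obs_sbp])
  expect_equal(out$tc[obs_tc], d$tc[obs_tc])
  expect_equal(out$sbp_imputed, !obs_sbp)
  expect_equal(out$tc_imputed, !obs_tc)
})
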