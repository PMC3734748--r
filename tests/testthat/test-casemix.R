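# Shared medium cohort with no hospital effects: the banded logistic model
# is then exactly the data-generating model, so coefficient recovery and the
# score equation can be checked against the generator's truth.
cm_cfg <- cohort_config(n_hospitals = 80, sigma0_true = 0,
                        size_law = list(min = 100, median = 650, max = 1500,
                                        sdlog = 0.6),
                        seed = 20260902L)
cm <- generate_cohort(cm_cfg)
cm_edges <- derive_bands(cm$patients)
cm_model <- fit_risk_model(cm$patients, cm_edges)

test_that("range filters are closed intervals and remove violators", {
  base <- mk_patients(hospital_id = rep(1:2, each = 10),
                      died = rep(c(1, 0), 10))
  extra <- mk_patients(age = c(101, 17, 18, 100),
                       sbp = c(140, 140, 140, 140))
  extra2 <- mk_patients(sbp = c(48, 251, 49, 250))
  extra3 <- mk_patients(hr = c(19, 201, 20, 200))
  out <- apply_exclusions(rbind(base, extra, extra2, extra3),
                          exclusion_rules(min_admissions = 1,
                                          min_deaths = 0))
  # the two in-range rows of each probe survive, the two out-of-range do not
  expect_equal(nrow(out$patients), nrow(base) + 6)
  expect_true(all(out$patients$age <= 100 & out$patients$age >= 18))
  rep_counts <- setNames(out$report$removed, out$report$reason)
  expect_equal(unname(rep_counts["age_out_of_range"]), 2)
  expect_equal(unname(rep_counts["sbp_out_of_range"]), 2)
  expect_equal(unname(rep_counts["hr_out_of_range"]), 2)
})

test_that("sparse hospitals are removed whole", {
  p <- rbind(
    mk_patients(hospital_id = 1L),                          # one admission
    mk_patients(hospital_id = rep(2L, 30),
                died = rep(c(1, 0, 0), 10)),                # 10 deaths
    mk_patients(hospital_id = rep(3L, 30), died = 0L),      # no deaths
    mk_patients(hospital_id = rep(4L, 30),
                died = c(rep(1L, 6), rep(NA_integer_, 24))))# 80% missing
  out <- apply_exclusions(p, exclusion_rules())
  expect_equal(unique(out$patients$hospital_id), 2L)
  rep_counts <- setNames(out$report$removed, out$report$reason)
  expect_equal(unname(rep_counts["too_few_admissions"]), 1)
  expect_equal(unname(rep_counts["too_few_deaths"]), 1)
  expect_equal(unname(rep_counts["excess_missing"]), 1)
})

test_that("rules spanning all data leave the cohort untouched; empty result errors", {
  out <- apply_exclusions(cm$patients, exclusion_rules(min_admissions = 1,
                                                       min_deaths = 0))
  expect_identical(out$patients, cm$patients)
  expect_error(apply_exclusions(mk_patients(age = 101),
                                exclusion_rules()),
               "no patients survive")
})

test_that("age bands are fixed and SBP/HR bands are empirical fifths", {
  expect_equal(cm_edges$age, c(55, 65, 75, 85))
  banded <- band_patients(cm$patients, cm_edges)
  for (v in c("sbp_band", "hr_band")) {
    counts <- table(banded[[v]])
    expect_lt(diff(range(counts)), nrow(cm$patients) * 0.01)
  }
  # uniform grid: five bands with counts equal within one unit
  grid <- mk_patients(sbp = rep(seq(100, 199, by = 1), 2),
                      hr = rep(seq(40, 139, by = 1), 2))
  e <- derive_bands(grid)
  counts <- table(band_patients(grid, e)$sbp_band)
  expect_lte(diff(range(counts)), 2)
  expect_error(derive_bands(mk_patients(sbp = c(1, 2, 3, 4))),
               "at least 5 distinct")
})

test_that("age 64 and 65 fall in adjacent bands; banding drops nobody", {
  banded <- band_patients(mk_patients(age = c(54.9, 55, 64, 65, 74, 75,
                                              84, 85, 99)),
                          cm_edges)
  expect_equal(as.integer(banded$age_band),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  all_bands <- band_patients(cm$patients, cm_edges)
  expect_equal(sum(table(all_bands$age_band)), nrow(cm$patients))
})

test_that("risk model recovers the generator's coefficients within 3 SE", {
  expect_gt(cm_model$n_fit, 40000)
  truth <- cm_cfg$risk_coefficients
  true_vec <- c(truth$age[-1], truth$sbp[-1], truth$hr[-1],
                truth$diagnosis[-1])
  est <- cm_model$coefficients
  se <- cm_model$se[-1]
  expect_length(est, length(true_vec))
  expect_true(all(abs(est - true_vec) < 3 * se))
  # c-statistic in a plausible band for this case mix
  expect_gt(cm_model$c_statistic$estimate, 0.7)
  expect_lt(cm_model$c_statistic$estimate, 0.9)
})

test_that("null cohort yields near-zero effects", {
  zero <- list(age = rep(0, 5), sbp = rep(0, 5), hr = rep(0, 5),
               diagnosis = rep(0, 6))
  cfg <- cohort_config(n_hospitals = 20, sigma0_true = 0,
                       risk_coefficients = zero,
                       size_law = list(min = 1000, median = 1500,
                                       max = 2200, sdlog = 0.3),
                       seed = 7L)
  ch <- generate_cohort(cfg)
  m <- fit_risk_model(ch$patients, derive_bands(ch$patients))
  expect_true(all(abs(m$coefficients) < 4 * m$se[-1]))
  expect_lt(abs(m$c_statistic$estimate - 0.5), 0.02)
})

test_that("c-statistic matches the exhaustive pair-counting oracle", {
  set.seed(14)
  p <- runif(60)
  y <- rbinom(60, 1, p)
  oracle <- function(p, y) {
    deaths <- p[y == 1]; survivors <- p[y == 0]
    tot <- 0
    for (d in deaths) for (s in survivors)
      tot <- tot + (d > s) + 0.5 * (d == s)
    tot / (length(deaths) * length(survivors))
  }
  expect_equal(c_statistic(p, y)$estimate, oracle(p, y))
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5))$estimate, 0.5)
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2),
                           c(1, 1, 0, 0))$estimate, 1.0)
  expect_error(c_statistic(p, rep(1, 60)), "both outcome classes")
})

test_that("expected deaths sum predicted probabilities within hospitals", {
  six <- band_patients(cm$patients[1:6, ], cm_edges)
  pr <- predict(cm_model$fit, newdata = six, type = "response")
  es <- expected_deaths(cm$patients[1:6, ], cm_model)
  manual_E <- tapply(pr, six$hospital_id, sum)
  expect_equal(es$expected,
               as.vector(manual_E[as.character(es$hospital_id)]))
  expect_equal(es$observed,
               as.vector(tapply(six$died_30d, six$hospital_id, sum)))
})

test_that("refitting on training data balances the books (score equation)", {
  es <- expected_deaths(cm$patients, cm_model)
  expect_equal(sum(es$expected), sum(es$observed), tolerance = 1e-6)
  expect_true(all(es$observed <= es$n_admissions))
  expect_true(all(es$expected > 0))
})

test_that("E_i is invariant to patient and hospital ordering", {
  set.seed(8)
  perm <- sample(nrow(cm$patients))
  es1 <- expected_deaths(cm$patients, cm_model)
  es2 <- expected_deaths(cm$patients[perm, ], cm_model)
  expect_equal(es1, es2)
})

test_that("missing death status is complete-case everywhere", {
  p <- cm$patients[1:2000, ]
  p$died_30d[1:200] <- NA_integer_
  m <- fit_risk_model(p, cm_edges)
  expect_equal(m$n_fit, 1800)
  es <- expected_deaths(p, m)
  expect_equal(sum(es$n_admissions), 1800)
})
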