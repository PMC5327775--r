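test_that("Sokal score reduces to exactly 1 when every centered term vanishes", {
  v <- sokal_score(age = 43.4, spleen = 7.51, platelets = 700 * sqrt(0.563),
                   blasts = 2.10)
  expect_identical(v, 1.0)
  expect_equal(categorize("sokal", v), "intermediate")
})

test_that("score formulas match independently computed reference values", {
  # frozen from term-by-term hand evaluation of each published equation
  expect_equal(sokal_score(age = 60, spleen = 10, platelets = 300, blasts = 4),
               1.4559834926504842, tolerance = 1e-12)
  expect_equal(categorize("sokal", 1.4559834926504842), "high")

  expect_equal(hasford_score(age = 55, spleen = 10, blasts = 3, eosinophils = 2,
                             basophils = 4, platelets = 1600),
               2643.9, tolerance = 1e-9)
  expect_equal(categorize("hasford", 2643.9), "high")
  expect_identical(hasford_score(age = 30, spleen = 0, blasts = 0,
                                 eosinophils = 0, basophils = 0,
                                 platelets = 500), 0)
  expect_equal(categorize("hasford", 0), "low")

  expect_identical(eutos_score(basophils = 0, spleen = 0), 0)
  expect_equal(eutos_score(basophils = 3, spleen = 18.75), 96)
  expect_equal(categorize("eutos", 96), "high")

  expect_equal(elts_score(age = 40, spleen = 8, blasts = 1.5, platelets = 511),
               1.3839123668627387, tolerance = 1e-12)
  expect_equal(categorize("elts", 1.3839123668627387), "low")
  expect_identical(elts_score(age = 0, spleen = 0, blasts = 0, platelets = 1000),
                   0.4104)
})

test_that("threshold factors step by exactly their coefficient", {
  lo <- hasford_score(40, 5, 2, 1, 2.9, 400)
  hi <- hasford_score(40, 5, 2, 1, 3.0, 400)
  expect_equal(hi - lo, 203.9, tolerance = 1e-9)
  # age in completed years: fractional age does not move the ELTS score
  expect_identical(elts_score(40.9, 8, 1.5, 511), elts_score(40, 8, 1.5, 511))
  # but does move the Hasford age indicator only across 50
  expect_equal(hasford_score(49.9, 0, 0, 0, 0, 100), 0)
  expect_equal(hasford_score(50, 0, 0, 0, 0, 100), 666.6)
})

test_that("scores are monotone in their risk factors", {
  set.seed(11)
  for (i in 1:25) {
    age <- runif(1, 18, 75); spleen <- runif(1, 0, 20)
    platelets <- runif(1, 100, 1200); blasts <- runif(1, 0, 8)
    eos <- runif(1, 0, 5); baso <- runif(1, 0, 6)
    d <- runif(1, 0.5, 3)
    expect_gt(sokal_score(age, spleen + d, platelets, blasts),
              sokal_score(age, spleen, platelets, blasts))
    expect_gt(sokal_score(age, spleen, platelets, blasts + d),
              sokal_score(age, spleen, platelets, blasts))
    expect_gte(eutos_score(baso + d, spleen), eutos_score(baso, spleen))
    expect_gte(eutos_score(baso, spleen + d), eutos_score(baso, spleen))
    expect_lt(elts_score(age, spleen, blasts, platelets * (1 + d)),
              elts_score(age, spleen, blasts, platelets))
    # Hasford is linear in spleen/blasts/eosinophils, flat between thresholds
    expect_gt(hasford_score(age, spleen + d, blasts, eos, baso, platelets),
              hasford_score(age, spleen, blasts, eos, baso, platelets))
    expect_identical(
      hasford_score(30, spleen, blasts, eos, 1, 400),
      hasford_score(45, spleen, blasts, eos, 2.5, 800))
  }
})

test_that("category boundaries follow the published cut-off conventions", {
  eps <- 1e-9
  expect_equal(categorize("sokal", c(0.8 - eps, 0.8, 1.2, 1.2 + eps)),
               c("low", "intermediate", "intermediate", "high"))
  expect_equal(categorize("hasford", c(780, 780.5, 1480, 1480.5, 1481)),
               c("low", "intermediate", "intermediate", "high", "high"))
  expect_equal(categorize("eutos", c(86.999, 87)), c("low", "high"))
  expect_equal(categorize("elts", c(1.5680, 1.5680 + eps, 2.2185, 2.2185 + eps)),
               c("low", "intermediate", "intermediate", "high"))
  expect_error(categorize("sokal", Inf), "finite")
  expect_error(categorize("acute", 1), "arg")
})

test_that("validation rejects out-of-range inputs, naming the field", {
  p <- baseline_patient()
  expect_error(sokal_score(40, -1, 400, 2), "spleen")
  expect_error(elts_score(40, 5, 2, 0), "platelets")
  expect_error(hasford_score(40, 5, 2, 1, 120, 400), "basophils")
  expect_error(sokal_score(40, 5, NaN, 2), "platelets")
  expect_error(validate_baseline(transform(p, blasts = 101)), "blasts")
  expect_warning(validate_baseline(transform(p, blasts = 101), strict = FALSE),
                 "blasts")
  expect_error(validate_baseline(p[, setdiff(names(p), "age")]), "age")
})

test_that("score_cohort appends one value and one category per system", {
  cohort <- rbind(baseline_patient(),
                  baseline_patient(age = 60, spleen = 12, platelets = 1600,
                                   basophils = 4, patient_id = "P002"))
  scored <- score_cohort(cohort)
  for (sys in cml_systems) {
    vc <- paste0(sys, "_value"); cc <- paste0(sys, "_cat")
    expect_true(all(c(vc, cc) %in% names(scored)))
    expect_identical(scored[[cc]], categorize(sys, scored[[vc]]))
  }
  # deterministic pure functions: rescoring is bit-identical
  expect_identical(scored, score_cohort(cohort))
})

test_that("risk_profile returns all four systems once, consistent with categorize", {
  prof <- risk_profile(baseline_patient(age = 43.4, spleen = 7.51,
                                        platelets = 700 * sqrt(0.563),
                                        blasts = 2.10))
  expect_identical(prof$system, cml_systems)
  expect_identical(prof$value[prof$system == "sokal"], 1.0)
  expect_identical(prof$category[prof$system == "sokal"], "intermediate")
  expect_identical(prof$category,
                   mapply(categorize, prof$system, prof$value, USE.NAMES = FALSE))
  zero <- risk_profile(baseline_patient(spleen = 0, basophils = 0))
  expect_identical(zero$value[zero$system == "eutos"], 0)
  expect_identical(zero$category[zero$system == "eutos"], "low")
})

test_that("cohorts drawn from the default distributions populate all Sokal categories", {
  scored <- score_cohort(generate_cohort(cohort_config(n_patients = 400, seed = 3)))
  expect_setequal(unique(scored$sokal_cat), c("low", "intermediate", "high"))
})
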