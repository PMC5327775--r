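test_that("dichotomize merges the intermediate category per strategy", {
  expect_identical(dichotomize("intermediate", 1), "lowish")
  expect_identical(dichotomize("intermediate", 2), "high")
  expect_identical(dichotomize(c("low", "high"), 1), c("lowish", "high"))
  expect_identical(dichotomize(c("low", "high"), 2), c("lowish", "high"))
  expect_error(dichotomize("very-high", 1), "unknown")
  expect_error(dichotomize("low", 3), "strategy")
})

test_that("predicted MMR status is a bijection on the two labels", {
  expect_true(predicted_mmr("lowish"))
  expect_false(predicted_mmr("high"))
  expect_identical(predicted_mmr(c("lowish", "high")), c(TRUE, FALSE))
  expect_error(predicted_mmr("medium"), "unknown")
})

test_that("contingency tables count patients by label and outcome", {
  tab <- build_contingency(c("high", "lowish", "lowish"), c(0, 1, 0))
  expect_identical(tab$n_high_nommr, 1L)
  expect_identical(tab$n_high_mmr, 0L)
  expect_identical(tab$n_lowish_nommr, 1L)
  expect_identical(tab$n_lowish_mmr, 1L)
  expect_identical(tab$total, 3L)
  expect_error(build_contingency(c("high", "lowish"), c(1, NA)), "missing MMR")
  expect_error(build_contingency("high", c(1, 0)), "equal length")

  # conservation: cells always sum to cohort size
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    lab <- sample(c("lowish", "high"), n, replace = TRUE)
    mmr <- sample(0:1, n, replace = TRUE)
    t <- build_contingency(lab, mmr)
    expect_identical(t$n_high_nommr + t$n_high_mmr + t$n_lowish_nommr +
                       t$n_lowish_mmr, n)
  }
})

test_that("accuracy is agreements over total, rounded half-up to 2 dp", {
  expect_equal(accuracy(contingency_from_cells(11, 14, 22, 48)), 62.11)
  expect_equal(accuracy(contingency_from_cells(4, 2, 29, 60)), 67.37)
  expect_equal(accuracy(contingency_from_cells(7, 0, 0, 12)), 100)
  # 1/3 -> 33.333... rounds down, 2/3 -> 66.67 rounds up (half-up at 2 dp)
  expect_equal(accuracy(contingency_from_cells(1, 2, 0, 0)), 33.33)
  expect_equal(accuracy(contingency_from_cells(2, 1, 0, 0)), 66.67)
  expect_error(accuracy(contingency_from_cells(0, 0, 0, 0)), "empty")
  expect_error(contingency_from_cells(-1, 0, 0, 0), "nonnegative")
})

test_that("combination enumeration has N^S rows in deterministic order", {
  pats <- enumerate_combinations(4, 2)
  expect_identical(nrow(pats), 16L)
  expect_identical(names(pats), cml_systems)
  expect_identical(unlist(pats[1, ], use.names = FALSE), rep("lowish", 4))
  expect_identical(unlist(pats[16, ], use.names = FALSE), rep("high", 4))
  # first system most significant: rows 1-8 lowish Sokal, ELTS alternates
  expect_identical(pats$sokal, rep(c("lowish", "high"), each = 8))
  expect_identical(pats$elts, rep(c("lowish", "high"), 8))
  expect_identical(nrow(enumerate_combinations(1, 2)), 2L)
  expect_identical(nrow(enumerate_combinations(2, 3)), 9L)
  expect_error(enumerate_combinations(0, 2), "positive")
  expect_error(enumerate_combinations(2, 0), "positive")
})

test_that("partition separates consensus from conflict patients", {
  one <- function(s, h, e, l, mmr = 1) {
    tibble::tibble(patient_id = "p", sokal_cat = s, hasford_cat = h,
                   eutos_cat = e, elts_cat = l, mmr_achieved = mmr)
  }
  p1 <- consistency_partition(one("low", "intermediate", "low", "low"))
  expect_identical(p1$n_consensus, 1L)  # strategy 1: all four lowish
  p2 <- consistency_partition(one("high", "low", "low", "low"))
  expect_identical(p2$n_conflict, 1L)
  # the same patient is consensus under strategy 2 only if low everywhere
  p3 <- consistency_partition(one("low", "intermediate", "low", "low"), strategy = 2)
  expect_identical(p3$n_conflict, 1L)

  expect_error(consistency_partition(one(NA, "low", "low", "low")), "incomplete")
  expect_error(
    consistency_partition(one("low", "low", "low", "low", mmr = NA)),
    "missing MMR")
})

test_that("partition conserves the cohort across combination rows and groups", {
  for (seed in 1:10) {
    n <- 5L + seed * 7L
    coh <- random_label_cohort(n, seed)
    part <- consistency_partition(coh)
    expect_identical(sum(part$combination$n_mmr) + sum(part$combination$n_no_mmr),
                     n)
    expect_identical(part$n_consensus + part$n_conflict, n)
    expect_identical(sum(part$combination$consensus), 2L)
  }
})

test_that("aggregated-table accuracy equals patient-level accuracy", {
  # brute-force cross-check on 100 random cohorts
  for (seed in 1:100) {
    n <- sample(2:80, 1)
    coh <- random_label_cohort(n, seed + 1000)
    for (sys in cml_systems) {
      lab <- dichotomize(coh[[paste0(sys, "_cat")]], 1)
      patient_level <- mean(predicted_mmr(lab) == as.logical(coh$mmr_achieved))
      table_level <- accuracy(build_contingency(lab, coh$mmr_achieved))
      expect_equal(table_level, floor(100 * patient_level * 100 + 0.5) / 100)
    }
  }
})

test_that("EUTOS contingency tables are identical under both strategies", {
  coh <- random_label_cohort(60, 99)
  rep <- consistency_report(coh)
  expect_identical(rep$strategy_tables$strategy_1$eutos,
                   rep$strategy_tables$strategy_2$eutos)
})

test_that("whole-cohort agreements decompose into consensus plus conflict", {
  agreements <- function(tab) tab$n_high_nommr + tab$n_lowish_mmr
  for (seed in c(7, 21, 35)) {
    coh <- random_label_cohort(50, seed)
    part <- consistency_partition(coh)
    for (sys in cml_systems) {
      tabs <- lapply(c("all", "consensus", "conflict"), function(g) {
        attr(subgroup_accuracy(part, g, sys), "table")
      })
      expect_identical(agreements(tabs[[1]]),
                       agreements(tabs[[2]]) + agreements(tabs[[3]]))
    }
  }
})

test_that("subgroup accuracy handles degenerate subgroups", {
  one <- tibble::tibble(patient_id = "p", sokal_cat = "low",
                        hasford_cat = "low", eutos_cat = "low",
                        elts_cat = "low", mmr_achieved = 1)
  part <- consistency_partition(one)
  expect_equal(unclass(subgroup_accuracy(part, "consensus", "sokal"))[1], 100)
  expect_error(subgroup_accuracy(part, "conflict", "sokal"), "empty")

  rep <- consistency_report(one)
  expect_identical(rep$n, 1L)
  expect_identical(rep$partition$n_consensus, 1L)
  expect_true(all(sapply(rep$strategy_tables$strategy_1,
                         function(e) e$table$total) == 1L))
  expect_true(is.na(rep$subgroup_accuracies$conflict[1]))
})
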