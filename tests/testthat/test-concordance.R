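# Match scores, responder rates, and 2x2 tests.

test_that("match score is percent agreement, symmetric, 100 on identity", {
  expect_equal(match_score(c("a", "a", "b"), c("a", "b", "b")), 100 * 2 / 3)
  set.seed(31)
  for (i in 1:10) {
    x <- sample(c("responder", "non_responder"), 12, replace = TRUE)
    y <- sample(c("responder", "non_responder"), 12, replace = TRUE)
    expect_equal(match_score(x, x), 100)
    expect_equal(match_score(x, y), match_score(y, x))
  }
  expect_error(match_score(c("a", "b"), "a"), "equal length")
  expect_error(match_score(character(0), character(0)), "empty")
})

test_that("responder rate computes percent responders", {
  expect_equal(responder_rate(rep("responder", 4)), 100)
  expect_equal(responder_rate(c("responder", rep("non_responder", 12))),
               100 / 13)
  expect_error(responder_rate(character(0)), "empty")
})

test_that("Fisher test reproduces the published dataset comparison", {
  p <- fisher_exact_2x2(matrix(c(12, 1, 13, 3), 2, byrow = TRUE))$p_value
  expect_equal(round(p, 4), 0.6059)
})

test_that("Fisher test matches enumeration and stats::fisher.test", {
  # exhaustive over all small tables, then randomized larger margins
  for (n in c(2, 5, 8)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      m <- matrix(c(a, b, cc, n - a - b - cc), 2, byrow = TRUE)
      got <- fisher_exact_2x2(m)
      if (got$degenerate) {
        expect_equal(got$p_value, 1)
      } else {
        expect_equal(got$p_value, fisher_enum(m), tolerance = 1e-9)
        expect_equal(got$p_value, stats::fisher.test(m)$p.value,
                     tolerance = 1e-7)
      }
    }
  }
  set.seed(32)
  for (i in 1:200) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2)  # margins <= 30
    got <- fisher_exact_2x2(m)
    if (!got$degenerate) {
      expect_equal(got$p_value, fisher_enum(m), tolerance = 1e-9)
    }
  }
})

test_that("Fisher special cases: equiprobable and no-association tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(7, 7, 7, 7), 2))$p_value, 1)
  deg <- fisher_exact_2x2(matrix(c(0, 0, 5, 6), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("chi-square reproduces the published clinical-rate comparison", {
  res <- chi_square_2x2(matrix(c(5, 8, 6, 10), 2, byrow = TRUE))
  expect_equal(round(res$p_value, 4), 0.9577)
  expect_equal(res$method, "chi_square_no_correction")

  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  yates <- chi_square_2x2(matrix(c(4, 9, 9, 7), 2, byrow = TRUE),
                          correction = TRUE)
  expect_equal(yates$method, "chi_square_yates")
  expect_lt(chi_square_2x2(matrix(c(4, 9, 9, 7), 2, byrow = TRUE))$p_value,
            yates$p_value)

  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero expected")
})

test_that("p-values are invariant under simultaneous row/column swaps", {
  set.seed(33)
  for (i in 1:50) {
    m <- matrix(sample(1:12, 4, replace = TRUE), 2)
    sw <- m[2:1, 2:1]
    expect_equal(fisher_exact_2x2(m)$p_value,
                 fisher_exact_2x2(sw)$p_value, tolerance = 1e-12)
    expect_equal(chi_square_2x2(m)$p_value, chi_square_2x2(sw)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("automatic test choice switches on sparse expected counts", {
  expect_equal(compare_2x2(matrix(c(12, 1, 13, 3), 2, byrow = TRUE))$method,
               "fisher_exact_two_sided")
  expect_equal(compare_2x2(matrix(c(5, 8, 6, 10), 2, byrow = TRUE))$method,
               "chi_square_no_correction")
})

test_that("concordance report reproduces the published validation analysis", {
  cohort <- table1_cohort()
  rep <- concordance_report(cohort)
  expect_equal(rep$overall_correct, 25)
  expect_equal(rep$n, 29)
  expect_setequal(rep$mismatches, c("2FCOH7", "F3FK2W", "6QFSVV", "GI7AGZ"))
  expect_equal(round(rep$match_scores[["discovery"]], 2), 92.31)
  expect_equal(round(rep$match_scores[["validation"]], 2), 81.25)
  expect_equal(round_half_up(rep$responder_rates$clinical[["discovery"]]),
               38.5)
  expect_equal(round_half_up(rep$responder_rates$clinical[["validation"]]),
               37.5)
  expect_equal(round_half_up(rep$responder_rates$predicted[["discovery"]]),
               30.8)
  expect_equal(round_half_up(rep$responder_rates$predicted[["validation"]]),
               56.3)
  expect_equal(round(rep$tests$match_by_dataset$p_value, 4), 0.6059)
  expect_equal(round(rep$tests$clinical_responders_by_dataset$p_value, 4),
               0.9577)
  # per-dataset matches pool to the overall correct count
  m <- rep$tables$match_by_dataset
  expect_equal(sum(m[, "match"]), rep$overall_correct)
  expect_equal(unname(m[, "match"]), c(12, 13))
})

test_that("a perfectly predicted cohort reports full concordance", {
  set.seed(34)
  cohort <- pd_cohort(random_cohort(10))
  cls <- classify_cohort(cohort)
  cohort$clinical_response <- cls$traces$predicted
  rep <- concordance_report(cohort, classify_cohort(cohort))
  expect_equal(unname(rep$match_scores), rep(100, 3))
  expect_length(rep$mismatches, 0)
  expect_equal(rep$overall_correct, 10)
})
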