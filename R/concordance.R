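# Match scores, responder rates, and 2x2 contingency comparisons.

#' Match score between predicted and clinical labels
#'
#' The percentage of positions where two equal-length label vectors agree:
#' `100 * matches / length`. Symmetric in its arguments.
#'
#' @param predicted,clinical Character vectors of equal positive length.
#' @return Percent agreement (full precision; round for display).
#' @export
#' @examples
#' match_score(c("responder", "responder"), c("responder", "non_responder"))
match_score <- function(predicted, clinical) {
  if (length(predicted) != length(clinical)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("label vectors are empty", call. = FALSE)
  100 * mean(predicted == clinical)
}

#' Responder rate of a label vector
#'
#' @param labels Character vector of `"responder"` / `"non_responder"`.
#' @return Percent of responders (full precision).
#' @export
#' @examples
#' responder_rate(c("responder", "non_responder", "non_responder"))
responder_rate <- function(labels) {
  if (length(labels) == 0) stop("label vector is empty", call. = FALSE)
  100 * mean(labels == "responder")
}

.check_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("table entries must be nonnegative integers", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every admissible table whose point probability does not exceed that of
#' the observed table (within a relative tolerance of `1e-7`), the common
#' two-sided convention. Degenerate tables with a zero row or column margin
#' carry no information; they return `p = 1` with `degenerate = TRUE`.
#'
#' @param table 2x2 matrix (or object coercible to one) of counts; rows are
#'   groups, columns outcomes.
#' @return An object of class `pd_test`: list with `p_value`, `method`
#'   (`"fisher_exact_two_sided"`), `statistic` (`NA`; Fisher's test has no
#'   statistic here) and `degenerate`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(12, 1, 13, 3), 2, byrow = TRUE))  # p = 0.6059
fisher_exact_2x2 <- function(table) {
  m <- .check_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  degenerate <- r1 == 0 || r1 == n || c1 == 0 || c1 == n
  if (degenerate) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "fisher_exact_two_sided",
                          degenerate = TRUE), class = "pd_test"))
  }
  # Support of the [1,1] cell given fixed margins.
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  structure(list(statistic = NA_real_, p_value = min(1, p),
                 method = "fisher_exact_two_sided", degenerate = FALSE),
            class = "pd_test")
}

#' Pearson chi-square test for a 2x2 table
#'
#' The 1-degree-of-freedom Pearson test `sum((O - E)^2 / E)` with upper-tail
#' p-value, optionally with the Yates continuity correction. Delegates to
#' [stats::chisq.test()]. A zero expected cell (zero margin) is an error.
#'
#' @param table 2x2 matrix of counts.
#' @param correction Apply the Yates continuity correction? Default `FALSE`.
#' @return An object of class `pd_test` with `statistic`, `p_value` and
#'   `method` (`"chi_square_no_correction"` or `"chi_square_yates"`).
#' @export
#' @examples
#' chi_square_2x2(matrix(c(5, 8, 6, 10), 2, byrow = TRUE))  # p = 0.9577
chi_square_2x2 <- function(table, correction = FALSE) {
  m <- .check_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("chi-square undefined: zero expected cell (degenerate margin)",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correction))
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 method = if (correction) "chi_square_yates" else
                   "chi_square_no_correction",
                 degenerate = FALSE),
            class = "pd_test")
}

#' Choose a 2x2 test automatically
#'
#' Uses Fisher's exact test when the smallest expected count falls below 3
#' (sparse tables where the chi-square approximation is poorest) and the
#' uncorrected chi-square otherwise. Both tests remain available explicitly
#' via [fisher_exact_2x2()] and [chi_square_2x2()].
#'
#' @param table 2x2 matrix of counts.
#' @return A `pd_test` object.
#' @export
compare_2x2 <- function(table) {
  m <- .check_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 3)) fisher_exact_2x2(m) else chi_square_2x2(m)
}

#' @export
print.pd_test <- function(x, ...) {
  cat(x$method, ": p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.na(x$statistic)) {
    cat(" (statistic ", format(x$statistic, digits = 4), ")", sep = "")
  }
  if (isTRUE(x$degenerate)) cat(" [degenerate margins]")
  cat("\n")
  invisible(x)
}

#' Concordance report for a classified cohort
#'
#' Summarizes agreement between decision-tree predictions and recorded
#' clinical responses: per-dataset and overall match scores, responder rates
#' (clinical and predicted), the mismatching patient IDs, and three
#' discovery-vs-validation comparisons — match/mismatch counts by Fisher's
#' exact test, clinical responder counts and predicted responder counts by
#' uncorrected chi-square (the test assignments that the published p-values
#' correspond to).
#'
#' Match scores are rounded for display with standard (half-even) rounding
#' and responder rates with [round_half_up()]; full-precision values are
#' kept in the returned object.
#'
#' @param cohort A [pd_cohort].
#' @param classification Result of [classify_cohort()] on the same cohort;
#'   computed if `NULL`.
#' @return An object of class `pd_concordance`: list with `match_scores`,
#'   `responder_rates`, `mismatches`, `overall_correct`, `n`, `tables` and
#'   `tests`.
#' @export
#' @examples
#' rep <- concordance_report(table1_cohort())
#' rep$overall_correct
concordance_report <- function(cohort, classification = NULL) {
  validate_cohort(cohort)
  if (is.null(classification)) classification <- classify_cohort(cohort)
  traces <- classification$traces
  if (!identical(traces$study_id, cohort$study_id)) {
    stop("classification does not cover this cohort", call. = FALSE)
  }
  pred <- traces$predicted
  clin <- cohort$clinical_response
  sets <- list(discovery = cohort$dataset == "discovery",
               validation = cohort$dataset == "validation",
               overall = rep(TRUE, nrow(cohort)))

  match_scores <- vapply(sets, function(i) match_score(pred[i], clin[i]),
                         numeric(1))
  rates <- list(
    clinical = vapply(sets, function(i) responder_rate(clin[i]), numeric(1)),
    predicted = vapply(sets, function(i) responder_rate(pred[i]), numeric(1))
  )
  mism <- cohort$study_id[pred != clin]

  count2 <- function(x, i, positive) {
    c(sum(x[i] == positive), sum(x[i] != positive))
  }
  tables <- list(
    match_by_dataset = rbind(
      discovery = count2(pred == clin, sets$discovery, TRUE),
      validation = count2(pred == clin, sets$validation, TRUE)),
    clinical_responders_by_dataset = rbind(
      discovery = count2(clin, sets$discovery, "responder"),
      validation = count2(clin, sets$validation, "responder")),
    predicted_responders_by_dataset = rbind(
      discovery = count2(pred, sets$discovery, "responder"),
      validation = count2(pred, sets$validation, "responder"))
  )
  colnames(tables$match_by_dataset) <- c("match", "mismatch")
  colnames(tables$clinical_responders_by_dataset) <-
    c("responder", "non_responder")
  colnames(tables$predicted_responders_by_dataset) <-
    c("responder", "non_responder")

  # chi-square for the rate comparisons unless a margin is empty (a cohort
  # with only one label class), where only the exact test is defined
  rate_test <- function(m) {
    if (any(colSums(m) == 0) || any(rowSums(m) == 0)) fisher_exact_2x2(m)
    else chi_square_2x2(m)
  }
  tests <- list(
    match_by_dataset = fisher_exact_2x2(tables$match_by_dataset),
    clinical_responders_by_dataset =
      rate_test(tables$clinical_responders_by_dataset),
    predicted_responders_by_dataset =
      rate_test(tables$predicted_responders_by_dataset)
  )

  structure(list(match_scores = match_scores,
                 responder_rates = rates,
                 mismatches = mism,
                 overall_correct = sum(pred == clin),
                 n = nrow(cohort),
                 tables = tables,
                 tests = tests),
            class = "pd_concordance")
}

#' @export
print.pd_concordance <- function(x, ...) {
  cat("Concordance: ", x$overall_correct, " of ", x$n,
      " predictions match the clinical response\n", sep = "")
  cat(sprintf("Match scores: discovery %.1f%%, validation %.1f%%, overall %.1f%%\n",
              round(x$match_scores["discovery"], 1),
              round(x$match_scores["validation"], 1),
              round(x$match_scores["overall"], 1)))
  cat(sprintf("Responder rates (clinical):  discovery %.1f%%, validation %.1f%%\n",
              round_half_up(x$responder_rates$clinical["discovery"], 1),
              round_half_up(x$responder_rates$clinical["validation"], 1)))
  cat(sprintf("Responder rates (predicted): discovery %.1f%%, validation %.1f%%\n",
              round_half_up(x$responder_rates$predicted["discovery"], 1),
              round_half_up(x$responder_rates$predicted["validation"], 1)))
  if (length(x$mismatches) > 0) {
    cat("Mismatched patients:", paste(x$mismatches, collapse = ", "), "\n")
  }
  cat("Dataset comparisons:\n")
  for (nm in names(x$tests)) {
    cat("  ", nm, ": ", sep = ""); print(x$tests[[nm]])
  }
  invisible(x)
}
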