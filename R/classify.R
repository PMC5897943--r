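# The three-step decision tree assigning PD-1 responder status.

#' Decision-tree thresholds
#'
#' The four cutoffs of the three-step responder decision tree, in percent:
#' patients below `pdl1_cut` PD-L1 expression are non-responders (step 1);
#' of the rest, those with dendritic-cell infiltration index below `dc_low`
#' are non-responders (step 2a) and above `dc_high` responders (step 2b);
#' the remainder are non-responders if any immunosuppressive molecule
#' exceeds PD-L1 by more than `ism_margin` (step 3a), else responders
#' (step 3b).
#'
#' @param pdl1_cut PD-L1 percent-change cutoff (default 29.0).
#' @param dc_low Lower infiltration-index cutoff (default 20.0).
#' @param dc_high Upper infiltration-index cutoff (default 60.0).
#' @param ism_margin ISM-over-PD-L1 margin (default 5.0).
#' @return An object of class `pd_thresholds`.
#' @export
#' @examples
#' pd_thresholds()
#' pd_thresholds(pdl1_cut = 35)  # stricter step 1
pd_thresholds <- function(pdl1_cut = 29, dc_low = 20, dc_high = 60,
                          ism_margin = 5) {
  vals <- c(pdl1_cut = pdl1_cut, dc_low = dc_low, dc_high = dc_high,
            ism_margin = ism_margin)
  if (any(!is.finite(vals))) stop("thresholds must be finite", call. = FALSE)
  if (dc_low >= dc_high) stop("dc_low must be < dc_high", call. = FALSE)
  structure(as.list(vals), class = "pd_thresholds")
}

#' Read decision-tree thresholds from YAML or JSON
#'
#' @param path File with any of the keys `pdl1_cut`, `dc_low`, `dc_high`,
#'   `ism_margin`; omitted keys take their defaults.
#' @return A [pd_thresholds] object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c("pdl1_cut", "dc_low", "dc_high", "ism_margin")
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pd_thresholds, raw)
}

#' @export
print.pd_thresholds <- function(x, ...) {
  cat(sprintf(
    "Decision-tree thresholds: PD-L1 >= %.1f%%; DC index in [%.1f, %.1f]%%; ISM margin %.1f%%\n",
    x$pdl1_cut, x$dc_low, x$dc_high, x$ism_margin))
  invisible(x)
}

#' Classify one patient with the three-step decision tree
#'
#' Runs the decision tree on a single patient profile and returns the full
#' decision trace: the label, the terminal step, the molecules that
#' triggered a step-3a call, and every threshold comparison evaluated.
#'
#' Boundary semantics follow the published rule: PD-L1 exactly at the cutoff
#' proceeds to step 2 ("equal to or greater than"), and an infiltration
#' index exactly at either DC cutoff proceeds to step 3 (both DC tests are
#' strict).
#'
#' @param record A one-row [pd_cohort], or a list/one-row data frame with
#'   elements `PDL1`, `DC_index` and the 14 ISM columns.
#' @param thresholds A [pd_thresholds] object.
#' @return An object of class `pd_decision`: list with `label`
#'   (`"responder"`/`"non_responder"`), `terminal_step` (`"step1"`,
#'   `"step2a"`, `"step2b"`, `"step3a"`, `"step3b"`),
#'   `triggering_molecules` (character, non-empty only for step 3a), and
#'   `comparisons` (data frame of the tests evaluated).
#' @export
#' @examples
#' cohort <- table1_cohort()
#' classify_patient(cohort[cohort$study_id == "SA97V5", ])
classify_patient <- function(record, thresholds = pd_thresholds()) {
  if (!inherits(thresholds, "pd_thresholds")) {
    stop("thresholds must be a pd_thresholds object", call. = FALSE)
  }
  rec <- as.list(record)
  needed <- c("PDL1", "DC_index", ism_molecules())
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0) {
    stop("record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pdl1 <- as.numeric(rec$PDL1)
  dc <- as.numeric(rec$DC_index)
  ism <- vapply(rec[ism_molecules()], as.numeric, numeric(1))
  if (any(!is.finite(c(pdl1, dc, ism)))) {
    stop("record contains non-finite profile values", call. = FALSE)
  }

  cmp <- function(step, test, lhs, rhs, result) {
    data.frame(step = step, test = test, lhs = lhs, rhs = rhs,
               result = result, stringsAsFactors = FALSE)
  }
  comparisons <- cmp("step1", "PDL1 < pdl1_cut", pdl1, thresholds$pdl1_cut,
                     pdl1 < thresholds$pdl1_cut)
  trace <- function(label, step, trig = character(0)) {
    structure(list(label = label, terminal_step = step,
                   triggering_molecules = trig, comparisons = comparisons),
              class = "pd_decision")
  }

  if (pdl1 < thresholds$pdl1_cut) {
    return(trace("non_responder", "step1"))
  }
  comparisons <- rbind(
    cmp("step1", "PDL1 < pdl1_cut", pdl1, thresholds$pdl1_cut, FALSE),
    cmp("step2a", "DC_index < dc_low", dc, thresholds$dc_low,
        dc < thresholds$dc_low))
  if (dc < thresholds$dc_low) {
    return(trace("non_responder", "step2a"))
  }
  comparisons <- rbind(
    comparisons,
    cmp("step2b", "DC_index > dc_high", dc, thresholds$dc_high,
        dc > thresholds$dc_high))
  if (dc > thresholds$dc_high) {
    return(trace("responder", "step2b"))
  }
  exc <- ism_excess(ism, pdl1, margin = thresholds$ism_margin)
  comparisons <- rbind(
    comparisons,
    cmp("step3", "max(ISM - PDL1) > ism_margin", exc$max_excess,
        thresholds$ism_margin, exc$max_excess > thresholds$ism_margin))
  if (length(exc$molecules) > 0) {
    return(trace("non_responder", "step3a", exc$molecules))
  }
  trace("responder", "step3b")
}

#' @export
print.pd_decision <- function(x, ...) {
  cat("Decision:", x$label, "at", x$terminal_step)
  if (length(x$triggering_molecules) > 0) {
    cat(" (triggered by ", paste(x$triggering_molecules, collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Classify a whole cohort
#'
#' Applies [classify_patient()] to every record and tallies terminal steps.
#' The tally is reported two ways: over all patients, and over the subset
#' whose prediction matches the recorded clinical response (the convention
#' used in some published step counts, which drop mismatched patients).
#'
#' @param cohort A [pd_cohort].
#' @param thresholds A [pd_thresholds] object.
#' @return An object of class `pd_classification`: list with `traces` (data
#'   frame: `study_id`, `dataset`, `predicted`, `terminal_step`,
#'   `triggering_molecules` semicolon-joined), `step_counts` (named integer
#'   vector over the five terminal steps, all patients) and
#'   `matched_step_counts` (same, matched patients only), plus `thresholds`.
#' @export
#' @examples
#' cls <- classify_cohort(table1_cohort())
#' cls$step_counts
classify_cohort <- function(cohort, thresholds = pd_thresholds()) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  decisions <- lapply(seq_len(nrow(cohort)), function(i) {
    classify_patient(cohort[i, , drop = FALSE], thresholds)
  })
  traces <- data.frame(
    study_id = cohort$study_id,
    dataset = cohort$dataset,
    predicted = vapply(decisions, `[[`, character(1), "label"),
    terminal_step = vapply(decisions, `[[`, character(1), "terminal_step"),
    triggering_molecules = vapply(decisions, function(d) {
      paste(d$triggering_molecules, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  steps <- c("step1", "step2a", "step2b", "step3a", "step3b")
  tally <- function(idx) {
    vapply(steps, function(s) sum(traces$terminal_step[idx] == s),
           integer(1))
  }
  matched <- traces$predicted == cohort$clinical_response
  structure(list(traces = traces,
                 step_counts = tally(rep(TRUE, nrow(traces))),
                 matched_step_counts = tally(matched),
                 thresholds = thresholds),
            class = "pd_classification")
}

#' @export
print.pd_classification <- function(x, ...) {
  cat("Cohort classification (", nrow(x$traces), " patients)\n", sep = "")
  print(x$thresholds)
  cat("Terminal-step counts (all patients):\n")
  print(x$step_counts)
  cat("Predicted responders:", sum(x$traces$predicted == "responder"), "\n")
  invisible(x)
}
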