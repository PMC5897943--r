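# Expression metrics: percent change vs baseline, the weighted
# dendritic-cell infiltration index, and ISM-vs-PD-L1 excess.

#' Percent change of a disease-state value against its baseline
#'
#' Expression readouts are reported as percent change of the patient-specific
#' disease-state steady concentration `D` against the non-tumorigenic
#' baseline control `C` (both in uM): `((D / C) - 1) * 100`. The sign is
#' preserved and no clamping is applied.
#'
#' @param disease Numeric vector of disease-state values (`D`).
#' @param control Numeric vector (recycled) of baseline control values (`C`);
#'   must be strictly positive.
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(1.6703, 1)   # 67.03
#' percent_change(1, 2)        # -50
percent_change <- function(disease, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("baseline control values must be finite and > 0", call. = FALSE)
  }
  (disease / control - 1) * 100
}

#' Chemokine weights for the dendritic-cell infiltration index
#'
#' Validates (and by default constructs uniform) nonnegative weights over the
#' nine canonical chemokines. Weights must sum to 1; sums deviating by at
#' most `1e-6` are renormalized, larger deviations are an error.
#'
#' @param weights Named numeric vector over [dc_chemokines()]; defaults to
#'   uniform `1/9`.
#' @return Named numeric vector of validated weights summing to 1.
#' @export
#' @examples
#' dc_weights()  # uniform
dc_weights <- function(weights = NULL) {
  chems <- dc_chemokines()
  if (is.null(weights)) {
    return(stats::setNames(rep(1 / length(chems), length(chems)), chems))
  }
  missing <- setdiff(chems, names(weights))
  if (length(missing) > 0) {
    stop("weights missing chemokine(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- weights[chems]
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(w)
  if (abs(s - 1) > 1e-6) {
    stop("weights must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  w / s
}

#' Read chemokine weights from a YAML or JSON file
#'
#' The file must map each of the nine canonical chemokine names to a
#' nonnegative weight; the vector is validated by [dc_weights()].
#'
#' @param path Path to a YAML (or JSON, a YAML subset) mapping.
#' @return Named numeric vector of validated weights.
#' @export
read_dc_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  dc_weights(unlist(raw))
}

#' Dendritic-cell infiltration index
#'
#' The weighted sum of the percent-change expression of the nine
#' dendritic-cell-trafficking chemokines: `sum_i pct_i * w_i` with the
#' weights a convex combination (nonnegative, summing to 1). With uniform
#' weights this is the plain mean of the nine percent changes.
#'
#' @param chemokine_pct Named numeric vector with all nine canonical
#'   chemokine names.
#' @param weights Weights as accepted by [dc_weights()]; default uniform.
#' @return The index, in percent.
#' @export
#' @examples
#' dc_infiltration_index(sa97v5_chemokines())  # 24.3 under uniform weights
dc_infiltration_index <- function(chemokine_pct, weights = NULL) {
  w <- dc_weights(weights)
  missing <- setdiff(dc_chemokines(), names(chemokine_pct))
  if (length(missing) > 0) {
    stop("chemokine_pct missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pct <- chemokine_pct[dc_chemokines()]
  if (any(!is.finite(pct))) {
    stop("chemokine_pct must be finite", call. = FALSE)
  }
  sum(pct * w)
}

#' Immunosuppressive molecules exceeding PD-L1 by more than a margin
#'
#' Step 3 of the decision tree asks which of the 14 immunosuppressive
#' molecules (ISMs) exceed the patient's PD-L1 percent change by strictly
#' more than a margin (default 5 percentage points). Returns both the names
#' of those molecules and the maximum excess `ism - pdl1` over the whole
#' panel (which may be negative).
#'
#' @param ism_pct Named numeric vector with all 14 canonical ISM names.
#' @param pdl1_pct PD-L1 percent change of the same patient.
#' @param margin Threshold on the excess; strict inequality. Default `5`.
#' @return List with `molecules` (character, possibly empty) and
#'   `max_excess` (numeric).
#' @export
#' @examples
#' cohort <- table1_cohort()
#' pat <- cohort[cohort$study_id == "QIA43T", ]
#' ism_excess(unlist(pat[ism_molecules()]), pat$PDL1)$molecules
ism_excess <- function(ism_pct, pdl1_pct, margin = 5) {
  missing <- setdiff(ism_molecules(), names(ism_pct))
  if (length(missing) > 0) {
    stop("ism_pct missing molecule(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  exc <- ism_pct[ism_molecules()] - pdl1_pct
  list(molecules = names(exc)[exc > margin],
       max_excess = unname(max(exc)))
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up (away from zero), the convention
#' used for reporting responder rates at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(56.25, 1)  # 56.3 (base round() would give 56.2)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
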