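# Shared test helpers: an independent closed-form classifier oracle and a
# random patient-record generator.

# Closed-form restatement of the decision tree, written independently of
# classify_patient(): responder iff PD-L1 clears the cutoff, the DC index
# is not low, and either the DC index is high or no ISM exceeds PD-L1 by
# more than the margin.
oracle_label <- function(pdl1, dc, ism, th = pd_thresholds()) {
  responder <- (pdl1 >= th$pdl1_cut) && (dc >= th$dc_low) &&
    (dc > th$dc_high || max(ism - pdl1) <= th$ism_margin)
  if (responder) "responder" else "non_responder"
}

# Random profile spanning the thresholds (values straddle all cutoffs).
random_record <- function() {
  ism <- setNames(runif(14, -40, 120), ism_molecules())
  c(list(PDL1 = runif(1, -20, 150), DC_index = runif(1, 0, 90)),
    as.list(ism))
}

# Small valid cohort data frame for I/O round-trip tests.
random_cohort <- function(n = 6) {
  recs <- lapply(seq_len(n), function(i) as.data.frame(random_record()))
  df <- do.call(rbind, recs)
  cbind(data.frame(study_id = sprintf("PT%04d", seq_len(n)),
                   dataset = rep(c("discovery", "validation"),
                                 length.out = n),
                   clinical_response = sample(
                     c("responder", "non_responder"), n, replace = TRUE),
                   stringsAsFactors = FALSE),
        df)
}

# From-scratch two-sided Fisher enumeration over all tables with the
# observed margins, using log-binomial coefficients only (independent of
# dhyper and of the implementation under test).
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logs <- vapply(support, lp, numeric(1))
  obs <- lp(m[1, 1])
  sum(exp(logs)[logs <= obs + 1e-7])
}
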