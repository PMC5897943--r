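# Canonical molecule panels and name normalization.

#' Canonical immunosuppressive molecule names
#'
#' The 14 tumor-derived immunosuppressive molecules (ISMs) whose predicted
#' percent-change expression is compared against PD-L1 in step 3 of the
#' decision tree.
#'
#' @return Character vector of 14 molecule names.
#' @seealso [dc_chemokines()]
#' @export
#' @examples
#' ism_molecules()
ism_molecules <- function() {
  c("TGFB1", "IDO1", "IL6", "VEGFA", "TDO2", "PGE2", "IL10",
    "LGALS9", "FASLG", "CD47", "CTLA4", "PDCD1LG2", "GM3", "GD2")
}

#' Canonical dendritic-cell chemokine names
#'
#' The 9 chemokines capable of trafficking dendritic cells into the tumor
#' microenvironment. Their percent changes are combined by
#' [dc_infiltration_index()] into a single infiltration index.
#'
#' @return Character vector of 9 chemokine names.
#' @export
#' @examples
#' dc_chemokines()
dc_chemokines <- function() {
  c("CCL2", "CCL3", "CCL4", "CCL5", "CCL7", "CCL11", "CCL20",
    "CX3CL1", "CXCL14")
}

# Spellings seen in the source material and common variants mapped to the
# canonical column names used throughout the package.
.molecule_synonyms <- c(
  "CX3CL"    = "CX3CL1",
  "PD-L1"    = "PDL1",
  "PD_L1"    = "PDL1",
  "PDL-1"    = "PDL1",
  "TGFB"     = "TGFB1",
  "VEGF"     = "VEGFA",
  "DC Index" = "DC_index",
  "DC-index" = "DC_index",
  "DCIndex"  = "DC_index",
  "DC_Index" = "DC_index"
)

#' Normalize molecule names to canonical spelling
#'
#' Applies the synonym map (e.g. `CX3CL` -> `CX3CL1`, `PD-L1` -> `PDL1`)
#' and leaves already-canonical names untouched.
#'
#' @param x Character vector of molecule or column names.
#' @return Character vector of the same length with canonical spellings.
#' @export
#' @examples
#' canonical_molecule(c("CX3CL", "PDL1", "VEGF"))
canonical_molecule <- function(x) {
  hit <- match(x, names(.molecule_synonyms))
  x[!is.na(hit)] <- .molecule_synonyms[hit[!is.na(hit)]]
  x
}
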