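# Declarative reaction networks: schema, validation, loading, and
# mutation-profile perturbations.

#' Construct a reaction network
#'
#' A network couples species (each with a basal synthesis rate, first-order
#' degradation rate and initial concentration in uM) through reactions of
#' two kinds:
#'
#' * `michaelis_menten` — saturating enzyme-driven production of `product`
#'   at rate `Vmax * S / (Km + S)` where `S` is the effective concentration
#'   of the driving `substrate` (a signaling activation step; the driver is
#'   catalytic and not consumed);
#' * `mass_action` — conversion/turnover at rate `k * prod(substrates)`,
#'   consuming the substrates and producing the products.
#'
#' Either kind accepts `modifiers`: activators scale the rate by
#' `A / (Ka + A)` and inhibitors by `Ka / (Ka + A)`, with `A` the modifier's
#' effective concentration. Effective concentration is the species
#' concentration times its activity multiplier, the handle through which
#' activity-level mutations act (see [apply_perturbations()]).
#'
#' @param species Data frame with columns `name`, `synthesis`,
#'   `degradation`, `init`.
#' @param reactions List of reaction lists; see above for fields (`id`,
#'   `kind`, `substrate`/`substrates`, `product`/`products`, `Vmax`, `Km`,
#'   `k`, `modifiers`).
#' @param outputs Character vector of species reported by
#'   [predict_profile()]; must include `PDL1`.
#' @param name Optional network label.
#' @return An object of class `pd_network`.
#' @export
pd_network <- function(species, reactions = list(), outputs = NULL,
                       name = NULL) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(outputs)) outputs <- species$name
  for (col in c("activity", "synth_mult")) {
    if (is.null(species[[col]])) species[[col]] <- 1
  }
  net <- structure(list(name = name, species = species,
                        reactions = reactions, outputs = outputs),
                   class = "pd_network")
  validate_network(net)
  net
}

#' Validate a reaction network
#'
#' Checks all schema invariants: nonnegative rate parameters, strictly
#' positive `Km` for every Michaelis-Menten reaction, every referenced
#' species declared, and outputs a subset of species.
#'
#' @param net A [pd_network].
#' @return Invisibly `TRUE`; stops on the first violation.
#' @export
validate_network <- function(net) {
  sp <- net$species
  need <- c("name", "synthesis", "degradation", "init")
  missing <- setdiff(need, names(sp))
  if (length(missing) > 0) {
    stop("species table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp$name)) stop("duplicate species names", call. = FALSE)
  if (any(sp$synthesis < 0) || any(sp$degradation < 0) || any(sp$init < 0)) {
    stop("species rates and initial concentrations must be >= 0",
         call. = FALSE)
  }
  known <- sp$name
  for (r in net$reactions) {
    id <- if (is.null(r$id)) "<unnamed>" else r$id
    if (is.null(r$kind) ||
        !r$kind %in% c("michaelis_menten", "mass_action")) {
      stop("reaction ", id, ": kind must be michaelis_menten or mass_action",
           call. = FALSE)
    }
    subs <- unlist(c(r$substrate, r$substrates))
    prods <- unlist(c(r$product, r$products))
    mods <- vapply(r$modifiers, `[[`, character(1), "species")
    undeclared <- setdiff(c(subs, prods, mods), known)
    if (length(undeclared) > 0) {
      stop("reaction ", id, " references undeclared species: ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
    if (r$kind == "michaelis_menten") {
      if (length(subs) != 1) {
        stop("reaction ", id, ": michaelis_menten needs exactly one substrate",
             call. = FALSE)
      }
      if (is.null(r$Km) || r$Km <= 0) {
        stop("reaction ", id, ": Km must be > 0", call. = FALSE)
      }
      if (is.null(r$Vmax) || r$Vmax < 0) {
        stop("reaction ", id, ": Vmax must be >= 0", call. = FALSE)
      }
    } else {
      if (is.null(r$k) || r$k < 0) {
        stop("reaction ", id, ": k must be >= 0", call. = FALSE)
      }
    }
    for (m in r$modifiers) {
      if (is.null(m$role) || !m$role %in% c("activator", "inhibitor")) {
        stop("reaction ", id, ": modifier role must be activator or inhibitor",
             call. = FALSE)
      }
      if (is.null(m$Ka) || m$Ka <= 0) {
        stop("reaction ", id, ": modifier Ka must be > 0", call. = FALSE)
      }
    }
  }
  bad_out <- setdiff(net$outputs, known)
  if (length(bad_out) > 0) {
    stop("outputs not declared as species: ",
         paste(bad_out, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a reaction network from YAML
#'
#' The YAML mirrors the [pd_network()] schema: top-level `name`, `outputs`,
#' `species` (list of `{name, synthesis, degradation, init}`) and
#' `reactions`.
#'
#' @param path Path to the YAML file.
#' @return A validated [pd_network].
#' @export
#' @examples
#' net <- pdl1_network()
#' net
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$species)) stop("network file has no species", call. = FALSE)
  species <- do.call(rbind, lapply(raw$species, function(s) {
    data.frame(name = s$name, synthesis = s$synthesis,
               degradation = s$degradation, init = s$init,
               stringsAsFactors = FALSE)
  }))
  pd_network(species, reactions = raw$reactions %||% list(),
             outputs = unlist(raw$outputs), name = raw$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged reduced PD-L1 regulation network
#'
#' A ~45-species stand-in for a full cancer signaling network, encoding the
#' pathway arms that regulate PD-L1 transcription: the ERK arm
#' (EGFR-RAS-RAF-MEK-ERK-AP1), the PI3K arm (PIK3CA-AKT-MTOR-STAT3 with
#' KEAP1 support), the interferon-gamma arm (IFNG-IFNGR1-STAT1-IRF1), the
#' STK11-AMPK-MTOR energy-sensing input, wild-type TP53 inhibition of PD-L1
#' transcription with CDKN2A restraining TP53 turnover, and lumped
#' transcriptional readouts for the 9 chemokines and 14 immunosuppressive
#' molecules driven by the AP1/STAT1/STAT3/IRF1 activation factors.
#' Parameters are fixed so that characteristic KRAS co-mutation orderings of
#' predicted PD-L1 change hold (see the package vignette).
#'
#' @return A validated [pd_network].
#' @export
pdl1_network <- function() {
  read_network(system.file("extdata", "pdl1_network.yaml",
                           package = "pd1tree"))
}

#' @export
print.pd_network <- function(x, ...) {
  cat("<pd_network", if (!is.null(x$name)) paste0("'", x$name, "'"), ">",
      nrow(x$species), "species,", length(x$reactions), "reactions,",
      length(x$outputs), "outputs\n")
  invisible(x)
}

#' Michaelis-Menten rate law
#'
#' `Vmax * S / (Km + S)`: half its maximum at `S = Km`, zero at `S = 0`.
#'
#' @param substrate Substrate concentration (>= 0).
#' @param Vmax Maximum rate (>= 0).
#' @param Km Half-saturation constant (> 0).
#' @return Reaction rate.
#' @export
#' @examples
#' michaelis_menten_rate(1, Vmax = 2, Km = 1)  # Vmax / 2
michaelis_menten_rate <- function(substrate, Vmax, Km) {
  if (any(Km <= 0)) stop("Km must be > 0", call. = FALSE)
  if (any(substrate < 0)) stop("substrate must be >= 0", call. = FALSE)
  Vmax * substrate / (Km + substrate)
}

.effects <- c("oncogene_gof", "tsg_lof", "amplification", "deletion")

# Gene symbols commonly used in mutation calls mapped onto the packaged
# network's node names (isoform / family-member collapsing).
.gene_aliases <- c(KRAS = "RAS", NRAS = "RAS", HRAS = "RAS", BRAF = "RAF",
                   RAF1 = "RAF", MAP2K1 = "MEK", MAP2K2 = "MEK",
                   MAPK1 = "ERK", MAPK3 = "ERK", CDKN2B = "CDKN2A",
                   LKB1 = "STK11", AKT1 = "AKT")
.default_magnitude <- c(oncogene_gof = 5, tsg_lof = 10, amplification = 5,
                        deletion = 1)

#' Read a mutation profile from a TSV file
#'
#' Columns: `gene`, `effect` (one of `oncogene_gof`, `tsg_lof`,
#' `amplification`, `deletion`) and optionally `magnitude` (blank/NA takes
#' the per-effect default).
#'
#' @param path Path to the TSV file.
#' @return Data frame of mutations as accepted by [apply_perturbations()].
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$magnitude)) tab$magnitude <- NA_real_
  mutation_profile(tab$gene, tab$effect, tab$magnitude)
}

#' Build a mutation profile
#'
#' Mutation semantics at the network level: oncogene mutations are a gain of
#' function at the activity level (activity multiplied by `magnitude`,
#' default x5), tumor-suppressor mutations a loss of function at the
#' activity level (activity divided by `magnitude`, default /10), and copy
#' number events act at the expression level (synthesis multiplied by
#' `magnitude` for amplification, default x5; set to zero for deletion).
#'
#' @param gene Character vector of species names.
#' @param effect Character vector over
#'   `c("oncogene_gof", "tsg_lof", "amplification", "deletion")`.
#' @param magnitude Positive multiplier; `NA` takes the per-effect default.
#' @return Data frame with class `pd_mutations`.
#' @export
#' @examples
#' mutation_profile(c("RAS", "TP53"), c("oncogene_gof", "tsg_lof"))
mutation_profile <- function(gene, effect, magnitude = NA_real_) {
  if (!all(effect %in% .effects)) {
    stop("effect must be one of: ", paste(.effects, collapse = ", "),
         call. = FALSE)
  }
  magnitude <- rep_len(as.numeric(magnitude), length(gene))
  magnitude[is.na(magnitude)] <-
    .default_magnitude[effect[is.na(magnitude)]]
  if (any(magnitude <= 0)) stop("magnitude must be > 0", call. = FALSE)
  out <- data.frame(gene = gene, effect = effect, magnitude = magnitude,
                    stringsAsFactors = FALSE)
  class(out) <- c("pd_mutations", class(out))
  out
}

#' Apply mutation perturbations to a network
#'
#' Pure transformation: returns a modified copy, leaving the input network
#' untouched. `oncogene_gof` multiplies the gene's activity multiplier by
#' `magnitude` (its effective concentration rises wherever it drives or
#' modulates a reaction); `tsg_lof` divides the activity by `magnitude`;
#' `amplification` multiplies the species' synthesis rate by `magnitude`;
#' `deletion` sets synthesis to zero.
#'
#' @param net A [pd_network].
#' @param mutations A [mutation_profile()] data frame (or data frame with
#'   columns `gene`, `effect`, `magnitude`).
#' @return A new [pd_network] with perturbed activities/synthesis.
#' @export
#' @examples
#' net <- pdl1_network()
#' kras <- apply_perturbations(net, mutation_profile("RAS", "oncogene_gof"))
apply_perturbations <- function(net, mutations) {
  validate_network(net)
  if (nrow(mutations) == 0) return(net)
  if (!inherits(mutations, "pd_mutations")) {
    mutations <- mutation_profile(mutations$gene, mutations$effect,
                                  mutations$magnitude %||% NA_real_)
  }
  sp <- net$species
  alias <- match(mutations$gene, names(.gene_aliases))
  aliased <- !is.na(alias) & !(mutations$gene %in% sp$name)
  mutations$gene[aliased] <- .gene_aliases[alias[aliased]]
  unknown <- setdiff(mutations$gene, sp$name)
  if (length(unknown) > 0) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "),
         "; valid nodes: ", paste(sp$name, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(mutations))) {
    j <- match(mutations$gene[i], sp$name)
    m <- mutations$magnitude[i]
    switch(mutations$effect[i],
      oncogene_gof  = sp$activity[j] <- sp$activity[j] * m,
      tsg_lof       = sp$activity[j] <- sp$activity[j] / m,
      amplification = sp$synth_mult[j] <- sp$synth_mult[j] * m,
      deletion      = sp$synth_mult[j] <- 0
    )
  }
  net$species <- sp
  net
}
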