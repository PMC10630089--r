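#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' TraitProfile: species-by-trait presence/absence/unknown matrix
#'
#' Phylogenetic profile of a set of traits (ortholog presence and, for some
#' proteins, presence of a C-terminal CAAX prenylation motif) across species.
#' Each cell holds one of the three states \code{"1"} (present), \code{"0"}
#' (absent) or \code{"?"} (unknown, typically because only protein fragments
#' are available). A CAAX trait can never be present in a species where its
#' host protein is absent; the validity method enforces this.
#'
#' @slot species Character vector of species names (row order).
#' @slot traits Character vector of trait names (column order).
#' @slot states Character matrix over \code{c("1","0","?")}, dimension
#'   species x traits.
#' @slot caaxHost Named character vector mapping each CAAX trait to its host
#'   protein trait (e.g. \code{c("CENP-E-CAAX" = "CENP-E")}).
#' @exportClass TraitProfile
setClass("TraitProfile",
  representation(species = "character", traits = "character",
                 states = "matrix", caaxHost = "character"))

setValidity("TraitProfile", function(object) {
  msg <- character()
  st <- object@states
  if (!is.character(st)) msg <- c(msg, "states must be a character matrix")
  if (nrow(st) != length(object@species) || ncol(st) != length(object@traits))
    msg <- c(msg, "states dimensions must match species x traits")
  if (anyDuplicated(object@species))
    msg <- c(msg, "duplicated species names")
  if (anyDuplicated(object@traits))
    msg <- c(msg, "duplicated trait names")
  if (is.character(st) && !all(st %in% c("1", "0", "?")))
    msg <- c(msg, "states must be one of '1', '0', '?'")
  for (ct in names(object@caaxHost)) {
    host <- object@caaxHost[[ct]]
    if (!ct %in% object@traits || !host %in% object@traits) {
      msg <- c(msg, sprintf("caaxHost entry %s -> %s names unknown traits",
                            ct, host))
      next
    }
    bad <- st[, ct] == "1" & st[, host] == "0"
    if (any(bad))
      msg <- c(msg, sprintf(
        "CAAX trait '%s' present where host '%s' is absent (%s)",
        ct, host, paste(object@species[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' CooccurrenceReport: pairwise co-occurrence of two traits across species
#'
#' Counts of joint presence/absence for two traits, an agreement score and a
#' phi association coefficient, with species of unknown state excluded
#' pairwise. No independence test is attached: species are phylogenetically
#' non-independent, so phi is reported descriptively only.
#'
#' @slot traitA,traitB Character trait names.
#' @slot counts Named integer vector: both, aOnly, bOnly, neither, excluded.
#' @slot agreement Numeric in [0,1]: (both + neither) / included.
#' @slot phi Numeric phi coefficient; NA when undefined.
#' @slot nIncluded Integer number of species entering the 2x2 table.
#' @exportClass CooccurrenceReport
setClass("CooccurrenceReport",
  representation(traitA = "character", traitB = "character",
                 counts = "integer", agreement = "numeric", phi = "numeric",
                 nIncluded = "integer"))

setValidity("CooccurrenceReport", function(object) {
  need <- c("both", "aOnly", "bOnly", "neither", "excluded")
  if (!all(need %in% names(object@counts)))
    return("counts must be named both/aOnly/bOnly/neither/excluded")
  if (sum(object@counts[c("both", "aOnly", "bOnly", "neither")]) !=
      object@nIncluded)
    return("2x2 counts must sum to the number of included species")
  TRUE
})

#' ReconstructionResult: ancestral states and gain/loss events on a tree
#'
#' Result of a parsimony reconstruction (Dollo or general asymmetric-cost)
#' of a binary trait on a rooted species tree. Holds one optimal labeling of
#' every node, the list of gain/loss events that exactly explains all
#' parent-to-child state changes in that labeling, the minimum total cost,
#' and a flag marking whether co-optimal labelings disagree on the number of
#' gains.
#'
#' @slot mode "sankoff" or "dollo".
#' @slot nodeStates Named integer vector (0/1) over all tree nodes.
#' @slot events DataFrame with columns parent, child, type (gain/loss);
#'   a gain on the root stem edge has parent NA.
#' @slot totalCost Numeric minimum cost.
#' @slot nGains,nLosses Integer event counts in the reported labeling.
#' @slot costGain,costLoss Numeric per-event costs.
#' @slot ambiguous Logical; TRUE when co-optimal labelings differ in their
#'   number of gains (Sankoff mode), or when unknown leaves leave the single
#'   gain's placement undetermined between an earliest- and latest-possible
#'   node (Dollo mode).
#' @slot info List of mode-specific extras (for Dollo: earliest- and
#'   latest-possible gain nodes given unknown leaves).
#' @exportClass ReconstructionResult
setClass("ReconstructionResult",
  representation(mode = "character", nodeStates = "integer",
                 events = "DataFrame", totalCost = "numeric",
                 nGains = "integer", nLosses = "integer",
                 costGain = "numeric", costLoss = "numeric",
                 ambiguous = "logical", info = "list"))

setValidity("ReconstructionResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("sankoff", "dollo"))
    msg <- c(msg, "mode must be 'sankoff' or 'dollo'")
  if (!all(object@nodeStates %in% c(0L, 1L)))
    msg <- c(msg, "node states must be 0/1")
  expected <- object@nGains * object@costGain + object@nLosses * object@costLoss
  if (!isTRUE(all.equal(object@totalCost, expected)))
    msg <- c(msg, "totalCost must equal nGains*costGain + nLosses*costLoss")
  if (object@mode == "dollo" && object@nGains > 1L)
    msg <- c(msg, "Dollo reconstruction admits at most one gain")
  if (length(msg)) msg else TRUE
})

#' ConstructSpec: recipe for a truncation/substitution protein construct
#'
#' Describes an expression construct derived from a parent protein: a
#' residue range in 1-based parent coordinates, optional alanine-scan style
#' window substitutions, and an optional CAAX-box fusion appended to the
#' C-terminus (as in swapping in the KRAS4b motif).
#'
#' @slot name Construct name.
#' @slot start,end 1-based inclusive parent coordinates.
#' @slot substitutions List of lists with fields start, end, replacement
#'   (single residue), all in parent coordinates inside [start, end].
#' @slot caaxSwap Optional 4-residue motif fused to the C-terminus, or NULL.
#' @exportClass ConstructSpec
setClass("ConstructSpec",
  representation(name = "character", start = "integer", end = "integer",
                 substitutions = "list", caaxSwap = "characterOrNULL"))

setValidity("ConstructSpec", function(object) {
  msg <- character()
  if (object@start < 1L || object@end < object@start)
    msg <- c(msg, "require 1 <= start <= end")
  for (s in object@substitutions) {
    if (!all(c("start", "end", "replacement") %in% names(s))) {
      msg <- c(msg, "each substitution needs start, end, replacement")
      next
    }
    if (s$start < object@start || s$end > object@end || s$start > s$end)
      msg <- c(msg, "substitution window outside construct range")
    if (nchar(s$replacement) != 1L)
      msg <- c(msg, "replacement must be a single residue")
  }
  if (!is.null(object@caaxSwap) && nchar(object@caaxSwap) != 4L)
    msg <- c(msg, "caaxSwap must be a 4-residue motif")
  if (length(msg)) msg else TRUE
})

#' SimulatedHistory: a trait history simulated on a species tree
#'
#' True per-node presence/absence states and the gain/loss events generated
#' by the per-branch Bernoulli simulator, kept as ground truth for
#' reconstruction benchmarks.
#'
#' @slot nodeStates Named integer vector of 0/1 states over all nodes.
#' @slot leafStates Named integer vector restricted to the tips.
#' @slot events DataFrame with columns parent, child, type.
#' @slot seed Integer seed the history was drawn with.
#' @exportClass SimulatedHistory
setClass("SimulatedHistory",
  representation(nodeStates = "integer", leafStates = "integer",
                 events = "DataFrame", seed = "integer"))

#' EnrichmentResult: per-protein differential enrichment over two conditions
#'
#' Result table of the proximity-biotinylation enrichment test: per protein
#' a log2 fold change between two conditions, a p-value from a two-sample
#' test, and a hit flag from the volcano threshold rule. A
#' Benjamini-Hochberg adjusted p-value column is included for reference but
#' never used for the hit flag.
#'
#' @slot results DataFrame with columns protein, log2FC, pvalue, negLog10P,
#'   padj, hit.
#' @slot params List of run metadata: test used, thresholds, direction,
#'   condition labels.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(results = "DataFrame", params = "list"))

setValidity("EnrichmentResult", function(object) {
  r <- object@results
  need <- c("protein", "log2FC", "pvalue", "negLog10P", "hit")
  if (!all(need %in% colnames(r)))
    return(paste("results must contain", paste(need, collapse = ", ")))
  ok <- is.na(r$pvalue) | r$pvalue == 0 |
    abs(r$negLog10P + log10(r$pvalue)) < 1e-8
  if (!all(ok)) return("negLog10P inconsistent with pvalue")
  TRUE
})

#' TurboIDExperiment: protein x sample log-intensity container
#'
#' A \linkS4class{SummarizedExperiment} subclass for label-free
#' proximity-biotinylation data: one assay \code{"intensity"} of
#' log2 intensities (NA marks a missing value), \code{rowData} with a
#' \code{uniquePeptides} count per protein, and \code{colData} with a
#' \code{condition} label and a \code{replicate} index unique within each
#' condition.
#'
#' @exportClass TurboIDExperiment
setClass("TurboIDExperiment",
         contains = "SummarizedExperiment")

setValidity("TurboIDExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  } else {
    key <- paste(cd$condition, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "replicate indices must be unique within a condition")
  }
  if (!"uniquePeptides" %in%
      colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'uniquePeptides'")
  if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (!is.numeric(a)) msg <- c(msg, "intensities must be numeric")
    else if (any(is.infinite(a), na.rm = TRUE))
      msg <- c(msg, "intensities must be finite or NA")
  }
  if (length(msg)) msg else TRUE
})
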