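#' Accessors for coronaEvo classes
#'
#' Small accessor generics: \code{speciesNames} and \code{traitNames} return
#' the row/column identities of a \linkS4class{TraitProfile};
#' \code{traitStates} its state matrix. \code{nodeStates}, \code{events},
#' \code{totalCost}, \code{gainCount}, \code{lossCount} and
#' \code{isAmbiguous} expose the fields of a
#' \linkS4class{ReconstructionResult}; \code{enrichmentTable} and
#' \code{enrichmentParams} those of an \linkS4class{EnrichmentResult}.
#'
#' @param x An object of the documented class.
#' @return The corresponding slot, unchanged.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @rdname accessors
#' @export
setGeneric("traitStates", function(x) standardGeneric("traitStates"))
#' @rdname accessors
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
#' @rdname accessors
#' @export
setGeneric("gainCount", function(x) standardGeneric("gainCount"))
#' @rdname accessors
#' @export
setGeneric("lossCount", function(x) standardGeneric("lossCount"))
#' @rdname accessors
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))
#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))
#' @rdname accessors
#' @export
setGeneric("enrichmentParams", function(x) standardGeneric("enrichmentParams"))

#' @rdname accessors
#' @export
setMethod("speciesNames", "TraitProfile", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("traitNames", "TraitProfile", function(x) x@traits)
#' @rdname accessors
#' @export
setMethod("traitStates", "TraitProfile", function(x) {
  m <- x@states
  dimnames(m) <- list(x@species, x@traits)
  m
})
#' @rdname accessors
#' @export
setMethod("nodeStates", "ReconstructionResult", function(x) x@nodeStates)
#' @rdname accessors
#' @export
setMethod("nodeStates", "SimulatedHistory", function(x) x@nodeStates)
#' @rdname accessors
#' @export
setMethod("events", "ReconstructionResult", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("events", "SimulatedHistory", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("totalCost", "ReconstructionResult", function(x) x@totalCost)
#' @rdname accessors
#' @export
setMethod("gainCount", "ReconstructionResult", function(x) x@nGains)
#' @rdname accessors
#' @export
setMethod("lossCount", "ReconstructionResult", function(x) x@nLosses)
#' @rdname accessors
#' @export
setMethod("isAmbiguous", "ReconstructionResult", function(x) x@ambiguous)
#' @rdname accessors
#' @export
setMethod("enrichmentTable", "EnrichmentResult", function(x) x@results)
#' @rdname accessors
#' @export
setMethod("enrichmentParams", "EnrichmentResult", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("gainCount", "SimulatedHistory", function(x)
  sum(x@events$type == "gain"))
#' @rdname accessors
#' @export
setMethod("lossCount", "SimulatedHistory", function(x)
  sum(x@events$type == "loss"))

setMethod("show", "TraitProfile", function(object) {
  cat(sprintf("TraitProfile: %d species x %d traits\n",
              length(object@species), length(object@traits)))
  cat("traits:", paste(object@traits, collapse = ", "), "\n")
  tab <- table(factor(object@states, levels = c("1", "0", "?")))
  cat(sprintf("states: %d present, %d absent, %d unknown\n",
              tab[["1"]], tab[["0"]], tab[["?"]]))
})

setMethod("show", "CooccurrenceReport", function(object) {
  cat(sprintf("CooccurrenceReport: %s vs %s\n", object@traitA, object@traitB))
  print(object@counts)
  cat(sprintf("agreement = %.3f over %d species; phi = %s\n",
              object@agreement, object@nIncluded,
              ifelse(is.na(object@phi), "undefined",
                     sprintf("%.3f", object@phi))))
})

setMethod("show", "ReconstructionResult", function(object) {
  cat(sprintf("ReconstructionResult (%s parsimony)\n", object@mode))
  cat(sprintf("  cost %g (gain=%g, loss=%g): %d gain(s), %d loss(es)%s\n",
              object@totalCost, object@costGain, object@costLoss,
              object@nGains, object@nLosses,
              if (object@ambiguous) " [count ambiguous]" else ""))
  if (nrow(object@events)) {
    cat("  events:\n")
    ev <- as.data.frame(object@events)
    for (i in seq_len(nrow(ev)))
      cat(sprintf("    %s: %s -> %s\n", ev$type[i],
                  ifelse(is.na(ev$parent[i]), "<stem>", ev$parent[i]),
                  ev$child[i]))
  }
})

setMethod("show", "SimulatedHistory", function(object) {
  cat(sprintf("SimulatedHistory: %d leaves, %d gain(s), %d loss(es), seed %d\n",
              length(object@leafStates), sum(object@events$type == "gain"),
              sum(object@events$type == "loss"), object@seed))
})

setMethod("show", "EnrichmentResult", function(object) {
  r <- object@results
  cat(sprintf("EnrichmentResult: %d proteins, %d hit(s) (%s test, |log2FC| > %g, -log10 p > %g)\n",
              nrow(r), sum(r$hit), object@params$test,
              object@params$lfcThreshold, object@params$nlpThreshold))
})
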