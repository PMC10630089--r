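#' Construct a TraitProfile
#'
#' Low-level constructor; most users will build profiles from per-protein
#' calls with \code{\link{buildProfile}} or load one with
#' \code{\link{readTraitProfile}}.
#'
#' @param states Character matrix over \code{c("1","0","?")} with species as
#'   rows and traits as columns (dimnames used when \code{species}/
#'   \code{traits} are missing).
#' @param species,traits Character vectors naming rows and columns.
#' @param caaxHost Named character vector mapping CAAX traits to host
#'   traits; by default inferred from the \code{"-CAAX"} suffix.
#' @return A \linkS4class{TraitProfile}.
#' @export
TraitProfile <- function(states, species = rownames(states),
                         traits = colnames(states), caaxHost = NULL) {
  states <- as.matrix(states)
  mode(states) <- "character"
  if (is.null(caaxHost)) {
    ct <- grep("-CAAX$", traits, value = TRUE)
    host <- sub("-CAAX$", "", ct)
    caaxHost <- setNames(host, ct)[host %in% traits]
    if (length(caaxHost) == 0L) caaxHost <- setNames(character(), character())
  }
  dimnames(states) <- list(species, traits)
  methods::new("TraitProfile", species = as.character(species),
               traits = as.character(traits), states = states,
               caaxHost = caaxHost)
}

#' Build a species-by-trait profile from per-protein CAAX calls
#'
#' Collapses per-protein, per-species calls (as returned by
#' \code{\link{detectCaax}}) into a phylogenetic profile. For each ortholog
#' family the protein trait is \code{"1"} when at least one ortholog was
#' detected in the species and \code{"0"} otherwise (paralogs are not
#' distinguished). For families carrying a CAAX trait, that trait is
#' \code{"1"} when at least one complete ortholog is CAAX-positive,
#' \code{"0"} when complete orthologs exist and all are CAAX-negative, and
#' \code{"?"} when the family is present but only fragments (or sequences
#' with \code{X} at -4) are available. A CAAX trait is \code{"0"} wherever
#' the host protein is absent.
#'
#' @param calls DataFrame/data.frame with columns \code{species},
#'   \code{family} and \code{state} (present/absent/unknown), one row per
#'   detected ortholog. Species with no orthologs of a family simply have no
#'   rows for it.
#' @param speciesOrder Character vector fixing the row order; species with
#'   no calls at all get an all-absent row.
#' @param families Character vector fixing the trait (column) order; by
#'   default the families observed in \code{calls}, sorted.
#' @param caaxFamilies Families for which a \code{<family>-CAAX} trait
#'   column is emitted (default: all of \code{families}).
#' @param backgroundFamilies Families to ignore entirely (decoy proteins);
#'   default \code{"background"}.
#' @return A \linkS4class{TraitProfile}.
#' @export
buildProfile <- function(calls, speciesOrder,
                         families = sort(unique(calls$family)),
                         caaxFamilies = families,
                         backgroundFamilies = "background") {
  if (anyDuplicated(speciesOrder))
    stop("species listed twice in 'speciesOrder': ",
         paste(unique(speciesOrder[duplicated(speciesOrder)]), collapse = ", "))
  calls <- as.data.frame(calls)
  calls <- calls[!(calls$family %in% backgroundFamilies), , drop = FALSE]
  families <- setdiff(families, backgroundFamilies)
  extra <- setdiff(calls$species, speciesOrder)
  if (length(extra))
    stop("calls contain species not in 'speciesOrder': ",
         paste(extra, collapse = ", "))

  traits <- unlist(lapply(families, function(f)
    c(f, if (f %in% caaxFamilies) paste0(f, "-CAAX"))))
  st <- matrix("0", nrow = length(speciesOrder), ncol = length(traits),
               dimnames = list(speciesOrder, traits))
  for (f in families) {
    for (sp in speciesOrder) {
      rows <- calls$species == sp & calls$family == f
      if (!any(rows)) next
      st[sp, f] <- "1"
      if (f %in% caaxFamilies) {
        states <- calls$state[rows]
        caax <- if (any(states == "present")) "1"
                else if (any(states == "absent")) "0"
                else "?"
        st[sp, paste0(f, "-CAAX")] <- caax
      }
    }
  }
  TraitProfile(st, species = speciesOrder, traits = traits)
}

phiCoefficient <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; r0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  den <- sqrt(r1) * sqrt(r0) * sqrt(c1) * sqrt(c0)
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

#' Co-occurrence of two traits across species
#'
#' Cross-tabulates two profile columns over the species where both states
#' are known; species with \code{"?"} in either trait are excluded pairwise
#' rather than imputed. Agreement is the fraction of included species where
#' the two traits co-occur (both present or both absent). The association
#' statistic is the phi coefficient of the 2x2 table, reported as NA
#' (undefined) when any margin is empty or fewer than 2 species are
#' included; no p-value is attached because species are phylogenetically
#' non-independent.
#'
#' @param profile A \linkS4class{TraitProfile}.
#' @param traitA,traitB Trait names present in the profile.
#' @return A \linkS4class{CooccurrenceReport}.
#' @export
cooccurrence <- function(profile, traitA, traitB) {
  st <- traitStates(profile)
  for (tr in c(traitA, traitB))
    if (!tr %in% colnames(st)) stop("trait not in profile: ", tr)
  a <- st[, traitA]; b <- st[, traitB]
  keep <- a != "?" & b != "?"
  n11 <- sum(a == "1" & b == "1" & keep)
  n10 <- sum(a == "1" & b == "0" & keep)
  n01 <- sum(a == "0" & b == "1" & keep)
  n00 <- sum(a == "0" & b == "0" & keep)
  nInc <- sum(keep)
  phi <- if (nInc < 2L) NA_real_ else phiCoefficient(n11, n10, n01, n00)
  if (nInc < 2L)
    warning("fewer than 2 species with known states for both traits; ",
            "association statistic undefined")
  methods::new("CooccurrenceReport", traitA = traitA, traitB = traitB,
               counts = c(both = n11, aOnly = n10, bOnly = n01,
                          neither = n00,
                          excluded = as.integer(sum(!keep))),
               agreement = if (nInc) (n11 + n00) / nInc else NA_real_,
               phi = phi, nIncluded = as.integer(nInc))
}

#' Coherence of a trait module across species
#'
#' Fraction of species that are all-present or all-absent across a subset of
#' traits, the signature of an evolutionarily coherent module (such as
#' ROD/ZWILCH/SPINDLY). Species with any unknown state among the subset are
#' excluded.
#'
#' @param profile A \linkS4class{TraitProfile}.
#' @param traits Character vector of at least two trait names.
#' @return List with \code{coherence} (numeric in [0,1]) and
#'   \code{incoherentSpecies} (character vector).
#' @export
moduleCoherence <- function(profile, traits) {
  if (length(traits) < 2L)
    stop("module coherence requires at least two traits")
  st <- traitStates(profile)
  missing <- setdiff(traits, colnames(st))
  if (length(missing)) stop("trait not in profile: ",
                            paste(missing, collapse = ", "))
  sub <- st[, traits, drop = FALSE]
  known <- rowSums(sub == "?") == 0L
  coherent <- known & (rowSums(sub == "1") == length(traits) |
                       rowSums(sub == "0") == length(traits))
  inc <- rownames(sub)[known & !coherent]
  list(coherence = if (sum(known)) sum(coherent) / sum(known) else NA_real_,
       incoherentSpecies = inc)
}

#' Restrict a profile to a subset of species and/or traits
#'
#' @param profile A \linkS4class{TraitProfile}.
#' @param species,traits Optional character vectors to keep, in order.
#' @return A \linkS4class{TraitProfile}.
#' @export
subsetProfile <- function(profile, species = speciesNames(profile),
                          traits = traitNames(profile)) {
  st <- traitStates(profile)[species, traits, drop = FALSE]
  TraitProfile(st, species = species, traits = traits)
}
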