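#' Packaged eukaryote fixture tree
#'
#' A small rooted species tree over ten major eukaryotic lineages
#' (Opisthokonta, Apusozoa, Breviata, Amoebozoa, Archaeplastida, Discoba,
#' Metamonada, Stramenopila, Alveolata, Rhizaria), with labeled internal
#' nodes for Obazoa (Opisthokonta + Apusozoa + Breviata, with Opisthokonta
#' sister to Apusozoa), Amorphea, SAR (Stramenopila + Alveolata + Rhizaria,
#' with Stramenopila sister to Alveolata as Halvaria) and Diaphoretickes.
#' The root is the Last Eukaryotic Common Ancestor (LECA), left as a
#' polytomy because the placement of the eukaryote root is unresolved.
#'
#' @return An \code{ape} \code{phylo} tree with 10 tips.
#' @examples
#' tr <- coronaFixtureTree()
#' tr$tip.label
#' @export
coronaFixtureTree <- function() {
  path <- system.file("extdata", "eukaryote_fixture.nwk",
                      package = "coronaEvo", mustWork = TRUE)
  readNewickTree(path)
}

#' Packaged fixture trait profile of fibrous-corona genes
#'
#' A species-by-trait profile over the ten fixture lineages and the seven
#' traits CENP-E, CENP-E-CAAX, SPINDLY, SPINDLY-CAAX, ROD, ZWILCH and ZW10,
#' encoding the qualitative eukaryote-wide pattern of the corona machinery:
#' CENP-E and ZW10 orthologs are found in all major lineages; the
#' ROD/ZWILCH/SPINDLY module is restricted to Opisthokonta and Apusozoa
#' (unknown in Breviata, where only sequence fragments are available); the
#' CENP-E CAAX box occurs in Opisthokonta/Apusozoa and, independently, in
#' Stramenopila/Alveolata; the SPINDLY CAAX box is confirmed in Opisthokonta
#' with unknown status in Apusozoa and Breviata.
#'
#' @return A \linkS4class{TraitProfile} (10 species x 7 traits).
#' @examples
#' traitStates(coronaFixtureProfile())
#' @export
coronaFixtureProfile <- function() {
  species <- c("Opisthokonta", "Apusozoa", "Breviata", "Amoebozoa",
               "Archaeplastida", "Discoba", "Metamonada", "Stramenopila",
               "Alveolata", "Rhizaria")
  traits <- c("CENP-E", "CENP-E-CAAX", "SPINDLY", "SPINDLY-CAAX",
              "ROD", "ZWILCH", "ZW10")
  st <- matrix("0", nrow = length(species), ncol = length(traits),
               dimnames = list(species, traits))
  st[, "CENP-E"] <- "1"
  st[, "ZW10"] <- "1"
  st[c("Opisthokonta", "Apusozoa", "Stramenopila", "Alveolata"),
     "CENP-E-CAAX"] <- "1"
  st["Breviata", "CENP-E-CAAX"] <- "?"
  for (tr in c("SPINDLY", "ROD", "ZWILCH")) {
    st[c("Opisthokonta", "Apusozoa"), tr] <- "1"
    st["Breviata", tr] <- "?"
  }
  st["Opisthokonta", "SPINDLY-CAAX"] <- "1"
  st[c("Apusozoa", "Breviata"), "SPINDLY-CAAX"] <- "?"
  TraitProfile(st, species = species, traits = traits)
}
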