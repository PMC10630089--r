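#' Simulate presence/absence evolution of a trait on a species tree
#'
#' Evolves a binary trait down a rooted tree by a per-edge Bernoulli
#' process: along every edge the trait is gained with probability
#' \code{gainRate} when the parent lacks it, and lost with probability
#' \code{lossRate} when the parent carries it. This discrete per-lineage
#' process matches the granularity at which gene-family presence/absence is
#' usually reasoned about (one verdict per lineage), and it keeps the truth
#' bookkeeping exact: the returned event list explains every parent-to-child
#' state change. With \code{dolloMode = TRUE} at most one gain occurs in the
#' whole history (after the first gain, further gains are suppressed),
#' emulating a Dollo character such as the birth of a gene or of a CAAX
#' motif.
#'
#' @param tree Rooted \code{phylo} tree (polytomies allowed).
#' @param gainRate,lossRate Per-edge probabilities in [0, 1].
#' @param rootState 0 or 1, the state at the root.
#' @param dolloMode Logical; allow at most one gain in the history.
#' @param seed Integer seed; identical seeds give identical histories.
#' @return A \linkS4class{SimulatedHistory}.
#' @examples
#' tr <- coronaFixtureTree()
#' h <- simulateTraitHistory(tr, gainRate = 0, lossRate = 0.1,
#'                           rootState = 1, seed = 7)
#' nodeStates(h)[tr$tip.label]
#' @export
simulateTraitHistory <- function(tree, gainRate, lossRate, rootState,
                                 dolloMode = FALSE, seed) {
  assertRootedTree(tree)
  if (gainRate < 0 || gainRate > 1 || lossRate < 0 || lossRate > 1)
    stop("gainRate and lossRate must lie in [0, 1]")
  if (!rootState %in% c(0L, 1L)) stop("rootState must be 0 or 1")
  set.seed(as.integer(seed))

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  labels <- nodeLabels(tree)
  states <- integer(nnode)
  states[root] <- as.integer(rootState)
  gainUsed <- FALSE
  ev <- list()

  edgesPre <- reorder(tree, "cladewise")$edge
  for (i in seq_len(nrow(edgesPre))) {
    p <- edgesPre[i, 1L]; ch <- edgesPre[i, 2L]
    u <- runif(1)   # one draw per edge keeps histories seed-stable
    s <- states[p]
    if (s == 0L) {
      if (!(dolloMode && gainUsed) && u < gainRate) {
        s <- 1L; gainUsed <- TRUE
        ev[[length(ev) + 1L]] <- list(parent = labels[p], child = labels[ch],
                                      type = "gain")
      }
    } else if (u < lossRate) {
      s <- 0L
      ev[[length(ev) + 1L]] <- list(parent = labels[p], child = labels[ch],
                                    type = "loss")
    }
    states[ch] <- s
  }
  events <- if (length(ev)) {
    DataFrame(parent = vapply(ev, `[[`, "", "parent"),
              child = vapply(ev, `[[`, "", "child"),
              type = vapply(ev, `[[`, "", "type"))
  } else {
    DataFrame(parent = character(), child = character(), type = character())
  }
  methods::new("SimulatedHistory",
               nodeStates = setNames(states, labels),
               leafStates = setNames(states[seq_len(ntip)],
                                     labels[seq_len(ntip)]),
               events = events, seed = as.integer(seed))
}

#' Emit synthetic proteomes consistent with a trait profile
#'
#' Generates one predicted proteome per species such that scanning it
#' reproduces the given profile: for every species where a family is present
#' an ortholog sequence is emitted whose C-terminus carries (CAAX state
#' \code{"1"}) or lacks (\code{"0"}) a cysteine at -4; CAAX state \code{"?"}
#' yields a C-terminally truncated fragment flagged \code{partial=true} in
#' the FASTA description. Decoy background proteins (family
#' \code{"background"}) are added to every species, drawn uniformly over the
#' 20 amino acids with the -4 position kept non-cysteine so decoys never
#' score as CAAX-positive. An extra \code{fragmentFraction} of the definite
#' orthologs can be truncated to exercise fragment handling.
#'
#' @param profile A \linkS4class{TraitProfile}; every host-protein cell must
#'   be \code{"1"} or \code{"0"} (an unknown presence state cannot be
#'   emitted and raises an error).
#' @param familySpecs Named list, one entry per host family:
#'   \code{list(caaxMotif = "CKTQ", lengthRange = c(300, 600))}. The motif's
#'   first residue must be \code{C}.
#' @param fragmentFraction Proportion of definite orthologs additionally
#'   emitted as C-terminal fragments (default 0).
#' @param nDecoys Background proteins per species (default 5).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param dir Optional directory; when given, one FASTA per species is
#'   written there (named \code{<species>.fasta}).
#' @return List with \code{proteomes} (named list of
#'   \code{Biostrings::AAStringSet}, with \code{mcols} columns species,
#'   family, protein_id, partial), \code{truth} (DataFrame of the emitted
#'   states) and \code{files} (paths, when \code{dir} was given).
#' @export
emitProteomes <- function(profile, familySpecs, fragmentFraction = 0,
                          nDecoys = 5L, seed, dir = NULL) {
  stopifnot(methods::is(profile, "TraitProfile"))
  if (fragmentFraction < 0 || fragmentFraction > 1)
    stop("fragmentFraction must lie in [0, 1]")
  st <- traitStates(profile)
  families <- names(familySpecs)
  missing <- setdiff(families, colnames(st))
  if (length(missing))
    stop("familySpecs name traits absent from the profile: ",
         paste(missing, collapse = ", "))
  for (f in families) {
    if (any(st[, f] == "?"))
      stop("cannot emit a proteome for unknown presence state of family '",
           f, "'")
    if (substr(familySpecs[[f]]$caaxMotif, 1L, 1L) != "C")
      stop("caaxMotif for family '", f, "' must start with C")
  }
  set.seed(as.integer(seed))

  proteomes <- list()
  truth <- list()
  for (sp in speciesNames(profile)) {
    seqs <- character(); ids <- character(); fams <- character()
    partials <- logical()
    for (f in families) {
      spec <- familySpecs[[f]]
      present <- st[sp, f] == "1"
      caaxTrait <- paste0(f, "-CAAX")
      caax <- if (caaxTrait %in% colnames(st)) st[sp, caaxTrait] else "0"
      truth[[length(truth) + 1L]] <- list(species = sp, family = f,
                                          present = present, caax = caax)
      if (!present) next
      L <- sample(seq(spec$lengthRange[1], spec$lengthRange[2]), 1L)
      s <- randomProtein(L, forbidCaax = TRUE)
      isFrag <- FALSE
      if (caax == "1") {
        substr(s, L - 3L, L) <- spec$caaxMotif
      } else if (caax == "?") {
        isFrag <- TRUE
      }
      if (!isFrag && fragmentFraction > 0 && runif(1) < fragmentFraction)
        isFrag <- TRUE
      if (isFrag) {
        # truncate before the terminal motif so no CAAX call is possible
        s <- substr(s, 1L, max(4L, ceiling(L * 0.4)))
      }
      seqs <- c(seqs, s)
      ids <- c(ids, sprintf("%s_%s_1", gsub("[^A-Za-z0-9]", "", sp),
                            gsub("[^A-Za-z0-9]", "", f)))
      fams <- c(fams, f)
      partials <- c(partials, isFrag)
    }
    for (d in seq_len(nDecoys)) {
      seqs <- c(seqs, randomProtein(sample(100:400, 1L), forbidCaax = TRUE))
      ids <- c(ids, sprintf("%s_bg_%d", gsub("[^A-Za-z0-9]", "", sp), d))
      fams <- c(fams, "background")
      partials <- c(partials, FALSE)
    }
    aa <- Biostrings::AAStringSet(seqs)
    S4Vectors::mcols(aa) <- DataFrame(species = rep(sp, length(seqs)),
                                      family = fams, protein_id = ids,
                                      partial = partials,
                                      extra = rep("", length(seqs)))
    names(aa) <- proteinFastaHeaders(aa)
    proteomes[[sp]] <- aa
  }
  truth <- DataFrame(
    species = vapply(truth, `[[`, "", "species"),
    family = vapply(truth, `[[`, "", "family"),
    present = vapply(truth, `[[`, TRUE, "present"),
    caax = vapply(truth, `[[`, "", "caax"))

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(names(proteomes), function(sp) {
      path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", sp), ".fasta"))
      writeProteinFasta(proteomes[[sp]], path)
      path
    }, "")
  }
  list(proteomes = proteomes, truth = truth, files = files)
}

#' Simulate a TurboID-style log-intensity table with planted enrichment
#'
#' Draws a protein-by-sample table of log2 intensities emulating a
#' label-free proximity-biotinylation experiment: protein baselines are
#' Gaussian across the proteome, replicate noise is Gaussian, a chosen set
#' of proteins is shifted by \code{effectLog2} in the bait condition, and
#' missingness is missing-not-at-random -- the probability that a value
#' drops out follows a decreasing logistic curve in the true log2 intensity,
#' with parameters \code{midpoint} (intensity of 50\% dropout) and
#' \code{steepness}.
#'
#' @param nProteins Number of proteins (> 0).
#' @param nEnriched Number of planted enriched proteins (<= nProteins).
#' @param effectLog2 Planted log2 fold change, bait minus control.
#' @param nReps Replicates per condition (>= 2; the study used 3).
#' @param dropout NULL to disable dropout, or
#'   \code{list(midpoint =, steepness =)} for the logistic MNAR model.
#' @param conditions Length-2 character: bait condition first, control
#'   second (default \code{c("WT", "emp")}: wild-type bait vs. empty tag).
#' @param baselineMean,baselineSd,repSd Gaussian parameters of the proteome
#'   baseline and replicate noise, on the log2 scale.
#' @param seed Integer seed.
#' @return List with \code{experiment} (a \linkS4class{TurboIDExperiment})
#'   and \code{truth} (DataFrame: protein, enriched, trueEffect).
#' @examples
#' sim <- simulateIntensityTable(50, 5, effectLog2 = 4, nReps = 3,
#'                               dropout = NULL, seed = 1)
#' sim$experiment
#' @export
simulateIntensityTable <- function(nProteins, nEnriched, effectLog2 = 4,
                                   nReps = 3L,
                                   dropout = list(midpoint = 22,
                                                  steepness = 1),
                                   conditions = c("WT", "emp"),
                                   baselineMean = 25, baselineSd = 2,
                                   repSd = 0.4, seed) {
  if (nProteins <= 0L || nReps <= 0L || nEnriched < 0L)
    stop("counts must be positive")
  if (nEnriched > nProteins) stop("nEnriched must not exceed nProteins")
  if (nReps < 2L) stop("at least 2 replicates per condition are required")
  stopifnot(length(conditions) == 2L)
  set.seed(as.integer(seed))

  proteins <- sprintf("P%04d", seq_len(nProteins))
  enriched <- logical(nProteins)
  enriched[sample.int(nProteins, nEnriched)] <- TRUE
  base <- rnorm(nProteins, baselineMean, baselineSd)

  nSamp <- 2L * nReps
  condition <- rep(conditions, each = nReps)
  replicate <- rep(seq_len(nReps), times = 2L)
  trueMean <- outer(base, rep(1, nSamp)) +
    outer(ifelse(enriched, effectLog2, 0), as.numeric(condition == conditions[1]))
  x <- trueMean + matrix(rnorm(nProteins * nSamp, 0, repSd),
                         nrow = nProteins)
  if (!is.null(dropout)) {
    pMiss <- stats::plogis(-(x - dropout$midpoint) * dropout$steepness)
    x[matrix(runif(length(x)), nrow = nProteins) < pMiss] <- NA_real_
  }
  colnames(x) <- paste(condition, replicate, sep = "_")
  rownames(x) <- proteins
  expt <- TurboIDExperiment(x, condition = condition, replicate = replicate,
                            uniquePeptides = 1L + rpois(nProteins, 3),
                            logScale = TRUE)
  list(experiment = expt,
       truth = DataFrame(protein = proteins, enriched = enriched,
                         trueEffect = ifelse(enriched, effectLog2, 0)))
}
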