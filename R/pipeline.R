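defaultEvolutionConfig <- function() {
  list(
    seed = 1L,
    tree = NULL,                      # NULL = packaged eukaryote fixture
    families = list(
      "CENP-E" = list(caaxMotif = "CKTQ", lengthRange = c(400L, 600L)),
      "SPINDLY" = list(caaxMotif = "CLIS", lengthRange = c(300L, 500L))),
    gainRate = 0.15, lossRate = 0.1, rootState = 0L, dolloMode = TRUE,
    caaxGainRate = 0.2, caaxLossRate = 0.05,
    fragmentFraction = 0, nDecoys = 5L,
    mode = "dollo", costGain = 1, costLoss = 1)
}

defaultProteomicsConfig <- function() {
  list(
    seed = 1L,
    table = NULL, design = NULL,      # NULL = simulate
    nProteins = 300L, nEnriched = 10L, effectLog2 = 4, nReps = 3L,
    dropout = list(midpoint = 22, steepness = 1),
    conditions = c("WT", "emp"),
    minUniquePeptides = 1L, minReps = 2L,
    shiftSd = 1.8, widthSd = 0.3,
    test = "welch", lfcThreshold = 2, nlpThreshold = 2, direction = "both")
}

manifestEntry <- function(files) {
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             row.names = NULL)
}

#' Run an end-to-end pipeline arm
#'
#' Executes one of the two study pipelines on a configuration list and
#' writes every artifact plus a JSON manifest (file names and MD5 hashes)
#' into \code{outDir}. The \code{"evolution"} arm simulates trait histories
#' on the species tree, emits proteomes consistent with them, scans the
#' proteomes for CAAX motifs, rebuilds the trait profile and reconstructs
#' gains/losses per trait. The \code{"proteomics"} arm simulates (or loads)
#' an intensity table and runs filter, normalization, imputation, testing
#' and volcano ranking. All stage seeds are fanned out from
#' \code{config$seed} with \code{\link{stageSeed}}, so a fixed master seed
#' reproduces every artifact byte for byte. Outputs are staged in a
#' temporary directory and moved into place only on success, so a failing
#' run leaves no partial outputs behind.
#'
#' @param config List of parameters; omitted entries fall back to the
#'   defaults documented in the vignette. Pass \code{list()} for an
#'   all-default run.
#' @param arm \code{"evolution"} or \code{"proteomics"}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = list(), arm = c("evolution", "proteomics"),
                        outDir) {
  arm <- match.arg(arm)
  defaults <- if (arm == "evolution") defaultEvolutionConfig()
              else defaultProteomicsConfig()
  cfg <- utils::modifyList(defaults, config)
  staging <- file.path(tempfile("coronaEvo_stage"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if (arm == "evolution") {
    tree <- runStage("ingest", {
      if (is.null(cfg$tree)) coronaFixtureTree() else readNewickTree(cfg$tree)
    })
    truthProfile <- runStage("simulate", {
      families <- names(cfg$families)
      cols <- list()
      for (f in families) {
        h <- simulateTraitHistory(tree, cfg$gainRate, cfg$lossRate,
                                  cfg$rootState, dolloMode = cfg$dolloMode,
                                  seed = stageSeed(cfg$seed,
                                                   paste0("history:", f)))
        hc <- simulateTraitHistory(tree, cfg$caaxGainRate, cfg$caaxLossRate,
                                   0L, dolloMode = cfg$dolloMode,
                                   seed = stageSeed(cfg$seed,
                                                    paste0("caax:", f)))
        present <- h@leafStates
        # a CAAX motif only exists where its host protein does
        caax <- as.integer(present == 1L & hc@leafStates == 1L)
        cols[[f]] <- as.character(present)
        cols[[paste0(f, "-CAAX")]] <- as.character(caax)
      }
      st <- do.call(cbind, cols)
      rownames(st) <- tree$tip.label
      TraitProfile(st, species = tree$tip.label, traits = names(cols))
    })
    emitted <- runStage("emit", {
      emitProteomes(truthProfile, cfg$families,
                    fragmentFraction = cfg$fragmentFraction,
                    nDecoys = cfg$nDecoys,
                    seed = stageSeed(cfg$seed, "emit"),
                    dir = file.path(staging, "proteomes"))
    })
    calls <- runStage("scan", {
      do.call(rbind, lapply(emitted$files, function(f)
        detectCaax(readProteinFasta(f))))
    })
    profile <- runStage("profile", {
      p <- buildProfile(calls, speciesOrder = tree$tip.label,
                        families = names(cfg$families))
      writeTraitProfile(p, file.path(staging, "profile.tsv"))
      p
    })
    runStage("reconstruct", {
      for (tr in traitNames(profile)) {
        states <- setNames(traitStates(profile)[, tr],
                           speciesNames(profile))
        rec <- if (cfg$mode == "dollo") dolloReconstruct(tree, states)
               else sankoffReconstruct(tree, states, cfg$costGain,
                                       cfg$costLoss)
        ann <- annotateTree(tree, rec)
        safe <- gsub("[^A-Za-z0-9_-]", "_", tr)
        writeLines(ann$newick,
                   file.path(staging, paste0("reconstruction_", safe, ".nwk")))
        writeEventTable(ann$events,
                        file.path(staging, paste0("events_", safe, ".tsv")))
      }
    })
    writeTraitProfile(truthProfile, file.path(staging, "truth_profile.tsv"))
  } else {
    expt <- runStage("ingest", {
      if (!is.null(cfg$table)) {
        readIntensityTable(cfg$table, cfg$design)
      } else {
        sim <- simulateIntensityTable(
          cfg$nProteins, cfg$nEnriched, cfg$effectLog2, cfg$nReps,
          dropout = cfg$dropout, conditions = cfg$conditions,
          seed = stageSeed(cfg$seed, "simulate"))
        writeIntensityTable(sim$experiment,
                            file.path(staging, "intensities.tsv"),
                            file.path(staging, "design.tsv"))
        write.table(as.data.frame(sim$truth),
                    file.path(staging, "truth.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        sim$experiment
      }
    })
    result <- runStage("enrich", {
      x <- filterProteins(expt, cfg$minUniquePeptides, cfg$minReps)
      x <- normalizeVST(x)
      x <- imputeMNAR(x, cfg$shiftSd, cfg$widthSd,
                      seed = stageSeed(cfg$seed, "impute"))
      testEnrichment(x, cfg$conditions[1], cfg$conditions[2],
                     test = cfg$test, lfcThreshold = cfg$lfcThreshold,
                     nlpThreshold = cfg$nlpThreshold,
                     direction = cfg$direction)
    })
    runStage("volcano", {
      write.table(as.data.frame(volcanoTable(result)),
                  file.path(staging, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
  }

  files <- list.files(staging, recursive = TRUE, full.names = TRUE)
  manifest <- manifestEntry(files)
  manifest$file <- list.files(staging, recursive = TRUE)
  jsonlite::write_json(manifest,
                       file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (rel in c(list.files(staging, recursive = TRUE))) {
    dest <- file.path(outDir, rel)
    if (!dir.exists(dirname(dest))) dir.create(dirname(dest), recursive = TRUE)
    file.copy(file.path(staging, rel), dest, overwrite = TRUE)
  }
  invisible(manifest)
}
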