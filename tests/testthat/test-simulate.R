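test_that("trait history limits: no change and forced loss", {
  tr <- coronaFixtureTree()
  h <- simulateTraitHistory(tr, gainRate = 0, lossRate = 0, rootState = 1,
                            seed = 1)
  expect_true(all(h@leafStates == 1L))
  expect_equal(nrow(events(h)), 0L)

  h2 <- simulateTraitHistory(tr, gainRate = 0, lossRate = 1, rootState = 1,
                             seed = 1)
  expect_true(all(h2@leafStates == 0L))
  # every root-child edge carries a loss
  rootKids <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1, 2]
  expect_equal(sum(events(h2)$parent == "LECA"), length(rootKids))
  expect_true(all(events(h2)$type == "loss"))
})

test_that("trait histories are seed-deterministic and validated", {
  tr <- coronaFixtureTree()
  h1 <- simulateTraitHistory(tr, 0.3, 0.2, 0, seed = 42)
  h2 <- simulateTraitHistory(tr, 0.3, 0.2, 0, seed = 42)
  expect_identical(nodeStates(h1), nodeStates(h2))
  expect_identical(as.data.frame(events(h1)), as.data.frame(events(h2)))
  h3 <- simulateTraitHistory(tr, 0.3, 0.2, 0, seed = 43)
  expect_false(identical(nodeStates(h1), nodeStates(h3)))

  expect_error(simulateTraitHistory(tr, -0.1, 0.2, 0, seed = 1), "\\[0, 1\\]")
  expect_error(simulateTraitHistory(tr, 0.1, 1.2, 0, seed = 1), "\\[0, 1\\]")
})

test_that("events exactly explain state changes; dollo mode caps gains at one", {
  tr <- coronaFixtureTree()
  labels <- names(nodeStates(simulateTraitHistory(tr, 0, 0, 0, seed = 1)))
  for (s in 1:30) {
    h <- simulateTraitHistory(tr, 0.4, 0.3, 0, dolloMode = (s %% 2 == 0),
                              seed = s)
    ns <- nodeStates(h)
    changed <- sum(ns[labels[tr$edge[, 1]]] != ns[labels[tr$edge[, 2]]])
    expect_equal(nrow(events(h)), changed)
    if (s %% 2 == 0) expect_lte(sum(events(h)$type == "gain"), 1L)
  }
})

test_that("loss events occur at the per-edge Bernoulli rate", {
  tr <- coronaFixtureTree()
  lossRate <- 0.1
  losses <- 0
  exposed <- 0   # edges descending from state-1 parents
  labels <- names(nodeStates(simulateTraitHistory(tr, 0, 0, 1, seed = 1)))
  for (s in 1:1000) {
    h <- simulateTraitHistory(tr, 0, lossRate, 1, seed = s)
    ns <- nodeStates(h)
    losses <- losses + sum(events(h)$type == "loss")
    exposed <- exposed + sum(ns[labels[tr$edge[, 1]]] == 1L)
  }
  expected <- lossRate * exposed
  se <- sqrt(exposed * lossRate * (1 - lossRate))
  expect_lt(abs(losses - expected), 3 * se)
})

test_that("emitted proteomes honor the profile and carry truth labels", {
  st <- cbind("CENP-E" = c("1", "1", "0", "1"),
              "CENP-E-CAAX" = c("1", "0", "0", "?"))
  rownames(st) <- paste0("sp", 1:4)
  profile <- TraitProfile(st)
  specs <- list("CENP-E" = list(caaxMotif = "CKTQ",
                                lengthRange = c(60L, 90L)))
  em <- emitProteomes(profile, specs, fragmentFraction = 0, nDecoys = 3,
                      seed = 8)
  orth <- lapply(em$proteomes, function(p)
    p[S4Vectors::mcols(p)$family == "CENP-E"])
  # present + CAAX: terminal 4-mer C-x-x-x (here the CENP-E motif itself)
  s1 <- as.character(orth$sp1[[1]])
  expect_equal(substr(s1, nchar(s1) - 3, nchar(s1)), "CKTQ")
  # present - CAAX: no cysteine at -4
  s2 <- as.character(orth$sp2[[1]])
  expect_false(substr(s2, nchar(s2) - 3, nchar(s2) - 3) == "C")
  # absent: no ortholog at all (decoys only)
  expect_equal(length(orth$sp3), 0L)
  expect_equal(length(em$proteomes$sp3), 3L)
  # unknown CAAX: fragment, flagged partial
  expect_true(S4Vectors::mcols(orth$sp4)$partial)
  # truth table matches the profile
  tr <- em$truth
  expect_equal(tr$present, st[, "CENP-E"] == "1", ignore_attr = TRUE)
  expect_equal(tr$caax, unname(st[, "CENP-E-CAAX"]))
  # conservation: present cells equal emitted ortholog count
  expect_equal(sum(tr$present),
               sum(vapply(orth, length, 0L)))
})

test_that("unknown presence states cannot be emitted", {
  st <- cbind("CENP-E" = c("1", "?"))
  rownames(st) <- c("sp1", "sp2")
  expect_error(emitProteomes(TraitProfile(st),
                             list("CENP-E" = list(caaxMotif = "CKTQ",
                                                  lengthRange = c(50L, 60L))),
                             seed = 1),
               "unknown presence state")
})

test_that("forced fragments are truncated before the terminal motif", {
  st <- cbind("CENP-E" = rep("1", 3), "CENP-E-CAAX" = rep("1", 3))
  rownames(st) <- paste0("sp", 1:3)
  specs <- list("CENP-E" = list(caaxMotif = "CKTQ", lengthRange = c(80L, 80L)))
  em <- emitProteomes(TraitProfile(st), specs, fragmentFraction = 1,
                      nDecoys = 0, seed = 2)
  for (p in em$proteomes) {
    expect_true(all(S4Vectors::mcols(p)$partial))
    expect_true(all(Biostrings::width(p) < 80L))
  }
  # and the scanner consequently reports unknown
  calls <- do.call(rbind, lapply(em$proteomes, detectCaax))
  expect_true(all(calls$state == "unknown"))
})

test_that("proteome emission is byte-deterministic under a fixed seed", {
  profile <- coronaFixtureProfile()
  profile <- subsetProfile(profile, traits = c("CENP-E", "CENP-E-CAAX"))
  specs <- list("CENP-E" = list(caaxMotif = "CKTQ", lengthRange = c(50L, 70L)))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  emitProteomes(profile, specs, seed = 99, dir = d1)
  emitProteomes(profile, specs, seed = 99, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("scan over emitted proteomes reproduces the generating profile", {
  tr <- coronaFixtureTree()
  for (s in 1:5) {
    h <- simulateTraitHistory(tr, 0.3, 0.2, 1, seed = s)
    hc <- simulateTraitHistory(tr, 0.3, 0.2, 1, seed = s + 100)
    st <- cbind("CENP-E" = as.character(h@leafStates),
                "CENP-E-CAAX" = as.character(
                  as.integer(h@leafStates == 1L & hc@leafStates == 1L)))
    rownames(st) <- tr$tip.label
    profile <- TraitProfile(st)
    em <- emitProteomes(profile,
                        list("CENP-E" = list(caaxMotif = "CKTQ",
                                             lengthRange = c(50L, 80L))),
                        fragmentFraction = 0, seed = s)
    calls <- do.call(rbind, lapply(em$proteomes, detectCaax))
    rebuilt <- buildProfile(calls, speciesOrder = tr$tip.label,
                            families = "CENP-E")
    expect_identical(traitStates(rebuilt), traitStates(profile))
  }
})

test_that("intensity simulation plants effects and validates arguments", {
  sim <- simulateIntensityTable(100, 10, effectLog2 = 3, nReps = 3,
                                dropout = NULL, seed = 4)
  a <- SummarizedExperiment::assay(sim$experiment)
  expect_false(anyNA(a))
  cond <- SummarizedExperiment::colData(sim$experiment)$condition
  planted <- sim$truth$enriched
  gap <- rowMeans(a[, cond == "WT"]) - rowMeans(a[, cond == "emp"])
  expect_gt(mean(gap[planted]), 2.5)
  expect_lt(abs(mean(gap[!planted])), 0.3)

  expect_error(simulateIntensityTable(0, 0, seed = 1), "positive")
  expect_error(simulateIntensityTable(10, 20, seed = 1), "exceed")
  expect_error(simulateIntensityTable(10, 2, nReps = 1, seed = 1),
               "2 replicates")
})

test_that("null simulation without dropout balances conditions", {
  gaps <- vapply(1:50, function(s) {
    sim <- simulateIntensityTable(60, 0, effectLog2 = 0, dropout = NULL,
                                  seed = s)
    a <- SummarizedExperiment::assay(sim$experiment)
    cond <- SummarizedExperiment::colData(sim$experiment)$condition
    mean(rowMeans(a[, cond == "WT"]) - rowMeans(a[, cond == "emp"]))
  }, 0)
  expect_lt(abs(mean(gaps)), 0.02)
})

test_that("hard-threshold dropout removes everything below the midpoint", {
  sim <- simulateIntensityTable(300, 0, effectLog2 = 0,
                                dropout = list(midpoint = 25,
                                               steepness = 1e6),
                                seed = 9)
  a <- SummarizedExperiment::assay(sim$experiment)
  expect_true(all(a[!is.na(a)] >= 25))
})

test_that("missingness rate decreases with intensity decile", {
  pooledRates <- matrix(NA_real_, nrow = 100, ncol = 10)
  for (s in 1:100) {
    sim <- simulateIntensityTable(150, 0, effectLog2 = 0, seed = s)
    a <- SummarizedExperiment::assay(sim$experiment)
    base <- rowMeans(a, na.rm = TRUE)
    dec <- cut(base, quantile(base, probs = 0:10 / 10, na.rm = TRUE),
               include.lowest = TRUE, labels = FALSE)
    pooledRates[s, ] <- vapply(1:10, function(d)
      mean(is.na(a[dec == d, , drop = FALSE])), 0)
  }
  avg <- colMeans(pooledRates, na.rm = TRUE)
  expect_true(all(diff(avg) <= 0.02))   # monotone non-increasing (MC noise)
  expect_gt(avg[1], avg[10])
})
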