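# Independent oracles used across the suite. Everything here is deliberately
# brute-force and shares no code with the package implementation.

# Minimum parsimony cost by exhaustive enumeration over all internal-node
# labelings (and both resolutions of every '?' leaf).
exhaustiveParsimonyCost <- function(tree, leafStates, costGain = 1,
                                    costLoss = 1,
                                    rootPrior = c("forced0", "free")) {
  rootPrior <- match.arg(rootPrior)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ls <- as.character(leafStates[tree$tip.label])

  fixed <- rep(NA_integer_, nnode)
  fixed[seq_len(ntip)][ls == "0"] <- 0L
  fixed[seq_len(ntip)][ls == "1"] <- 1L
  free <- which(is.na(fixed))
  if (rootPrior == "forced0") {
    fixed[root] <- 0L
    free <- setdiff(free, root)
  }

  combos <- if (length(free)) {
    t(as.matrix(expand.grid(rep(list(0:1), length(free)))))
  } else {
    matrix(0L, nrow = 0L, ncol = 1L)
  }
  nLab <- ncol(combos)
  S <- matrix(fixed, nrow = nnode, ncol = nLab)
  if (length(free)) S[free, ] <- combos
  cost <- numeric(nLab)
  for (i in seq_len(nrow(tree$edge))) {
    p <- S[tree$edge[i, 1L], ]; ch <- S[tree$edge[i, 2L], ]
    cost <- cost + costGain * (p == 0L & ch == 1L) +
      costLoss * (p == 1L & ch == 0L)
  }
  min(cost)
}

# Number of maximal all-absent subtrees inside the clade rooted at the MRCA
# of the definitely-present leaves ('?' resolved to presence when a subtree
# holds no definite absence). Simple independent recursion over children.
maximalAbsentSubtrees <- function(tree, leafStates) {
  ntip <- ape::Ntip(tree)
  ls <- as.character(leafStates[tree$tip.label])
  present <- which(ls == "1")
  if (!length(present)) return(0L)
  kids <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  hasP <- function(v) {
    if (v <= ntip) return(ls[v] == "1")
    any(vapply(kids[[v]], hasP, TRUE))
  }
  hasA <- function(v) {
    if (v <= ntip) return(ls[v] == "0")
    any(vapply(kids[[v]], hasA, TRUE))
  }
  mrca <- if (length(present) == 1L) present else ape::getMRCA(tree, present)
  count <- function(v, parentAlive) {
    alive <- hasP(v) || !hasA(v)
    n <- 0L
    if (parentAlive && !alive) return(1L)  # top of a lost subtree
    if (v > ntip) for (ch in kids[[v]]) n <- n + count(ch, alive)
    n
  }
  n <- 0L
  if (mrca > ntip) for (ch in kids[[mrca]]) n <- n + count(ch, TRUE)
  n
}

randomLeafStates <- function(tree, pUnknown = 0.15) {
  states <- sample(c("0", "1"), ape::Ntip(tree), replace = TRUE)
  states[runif(length(states)) < pUnknown] <- "?"
  setNames(states, tree$tip.label)
}

# Add a stem edge above the root (singleton root node). The Dollo model's
# single gain may sit on the edge above the original root; a Sankoff DP with
# a forced-0 root can only express that with an explicit stem edge.
addStemEdge <- function(tree) {
  ape::read.tree(text = paste0("(", sub(";\\s*$", "", ape::write.tree(tree)),
                               ")stem;"))
}

randomRootedTree <- function(nTips) {
  tr <- ape::rtree(nTips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(nTips))
  tr
}

# One full proteomics pass: filter -> normalize -> impute -> test.
runEnrichmentPipeline <- function(sim, seedOffset = 0L, ...) {
  x <- filterProteins(sim$experiment)
  x <- normalizeVST(x)
  x <- imputeMNAR(x, seed = 90000L + seedOffset)
  testEnrichment(x, "WT", "emp", ...)
}
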