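#' @import methods
#' @importFrom stats mad median pt p.adjust reorder rnorm rpois runif sd setNames
#' @importFrom utils read.delim write.table modifyList
NULL

utils::globalVariables(c("log2FC", "negLog10P", "hit"))

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Derive a per-stage seed from a master seed
#'
#' Deterministically fans a single master seed out into independent per-stage
#' seeds, so that each stochastic stage of a pipeline is reproducible on its
#' own regardless of stage ordering.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' stageSeed(1L, "simulate")
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps results inside R's integer range
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# unique root = exactly one node that never appears as a child.
# ape::is.rooted() calls basal polytomies unrooted; a polytomous root is a
# legitimate statement of uncertainty for a species tree, so we only require
# a unique in-degree-0 node.
assertRootedTree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be an ape 'phylo' object")
  }
  nodes <- unique(as.vector(tree$edge))
  roots <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(unique(roots)) != 1L) {
    stop("tree is not rooted: expected exactly one node without a parent")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(nodes)
}

# children of every node, as a list indexed by node id
treeChildren <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# human-readable label for every node id (tips first, ape convention)
nodeLabels <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- c(tree$tip.label,
           if (!is.null(tree$node.label)) tree$node.label
           else rep("", tree$Nnode))
  idx <- which(is.na(lab) | lab == "")
  lab[idx] <- paste0("N", idx)
  lab
}

randomProtein <- function(length, forbidCaax = TRUE) {
  s <- sample(AA20, length, replace = TRUE)
  if (forbidCaax && length >= 4L && s[length - 3L] == "C") {
    s[length - 3L] <- sample(setdiff(AA20, "C"), 1L)
  }
  paste(s, collapse = "")
}
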