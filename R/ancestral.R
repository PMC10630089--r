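checkLeafStates <- function(tree, leafStates) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(leafStates))
  if (length(missing))
    stop("no state for leaf/leaves: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(leafStates), tips)
  if (length(extra))
    stop("states given for names not in the tree: ",
         paste(extra, collapse = ", "))
  ls <- as.character(leafStates[tips])
  if (!all(ls %in% c("0", "1", "?")))
    stop("leaf states must be '0', '1' or '?'")
  ls
}

eventsFromLabeling <- function(tree, states, labels) {
  ev <- list()
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    if (states[p] != states[c]) {
      ev[[length(ev) + 1L]] <- list(
        parent = labels[p], child = labels[c],
        type = if (states[p] == 0L) "gain" else "loss")
    }
  }
  if (!length(ev))
    return(DataFrame(parent = character(), child = character(),
                     type = character()))
  DataFrame(parent = vapply(ev, `[[`, "", "parent"),
            child = vapply(ev, `[[`, "", "child"),
            type = vapply(ev, `[[`, "", "type"))
}

#' Minimum-cost (Sankoff) ancestral reconstruction of a binary trait
#'
#' Dynamic programming over states \{0, 1\} on a rooted tree (polytomies are
#' handled exactly by summing child cost vectors). A gain (0 -> 1 along an
#' edge) costs \code{costGain} and a loss (1 -> 0) costs \code{costLoss}.
#' Leaves with state \code{"?"} are zero-cost wildcards in the DP rather
#' than being imputed beforehand, so the reported optimum is exact. The root
#' prior is either \code{"forced0"} (the trait is absent before its origin;
#' appropriate for gene- or motif-birth characters) or \code{"free"}.
#'
#' Among co-optimal labelings the reported one follows a canonical
#' tie-break: prefer state 0 toward the root, delaying gains toward the tips
#' (DELTRAN-like). In addition, a second pass computes the minimum and
#' maximum number of gains over \emph{all} co-optimal labelings; when they
#' disagree the result is flagged ambiguous rather than silently resolved.
#'
#' @param tree Rooted \code{phylo} tree (polytomies allowed).
#' @param leafStates Named character vector over the tips with values
#'   \code{"0"}, \code{"1"} or \code{"?"}.
#' @param costGain,costLoss Non-negative per-event costs (not both zero).
#' @param rootPrior \code{"forced0"} (default) or \code{"free"}.
#' @return A \linkS4class{ReconstructionResult}.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' sankoffReconstruct(tr, c(A = "1", B = "0", C = "1", D = "0"))
#' @export
sankoffReconstruct <- function(tree, leafStates, costGain = 1, costLoss = 1,
                               rootPrior = c("forced0", "free")) {
  rootPrior <- match.arg(rootPrior)
  assertRootedTree(tree)
  if (costGain < 0 || costLoss < 0) stop("costs must be non-negative")
  if (costGain == 0 && costLoss == 0) stop("costs must not both be zero")
  ls <- checkLeafStates(tree, leafStates)

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  labels <- nodeLabels(tree)
  # trans[from + 1, to + 1]
  trans <- matrix(c(0, costLoss, costGain, 0), nrow = 2L)

  cost <- matrix(Inf, nrow = nnode, ncol = 2L)
  gmin <- matrix(0, nrow = nnode, ncol = 2L)   # min gains among co-optima
  gmax <- matrix(0, nrow = nnode, ncol = 2L)   # max gains among co-optima
  for (i in seq_len(ntip)) {
    cost[i, ] <- switch(ls[i], "0" = c(0, Inf), "1" = c(Inf, 0), "?" = c(0, 0))
  }

  edgesPost <- reorder(tree, "postorder")$edge
  internal <- unique(edgesPost[, 1L])
  kids <- treeChildren(tree)
  for (v in internal) {
    for (s in 0:1) {
      tot <- 0; gmn <- 0; gmx <- 0
      for (ch in kids[[v]]) {
        opt <- trans[s + 1L, ] + cost[ch, ]
        m <- min(opt)
        best <- which(opt == m) - 1L   # child states achieving the optimum
        tot <- tot + m
        gAdd <- vapply(best, function(t)
          gmin[ch, t + 1L] + as.numeric(s == 0L && t == 1L), 0)
        gAddMax <- vapply(best, function(t)
          gmax[ch, t + 1L] + as.numeric(s == 0L && t == 1L), 0)
        gmn <- gmn + min(gAdd)
        gmx <- gmx + max(gAddMax)
      }
      cost[v, s + 1L] <- tot
      gmin[v, s + 1L] <- gmn
      gmax[v, s + 1L] <- gmx
    }
  }

  rootStates <- if (rootPrior == "forced0") 0L else {
    m <- min(cost[root, ])
    which(cost[root, ] == m) - 1L
  }
  totalCost <- min(cost[root, rootStates + 1L])
  coopt <- rootStates[cost[root, rootStates + 1L] == totalCost]
  allGmin <- min(gmin[root, coopt + 1L])
  allGmax <- max(gmax[root, coopt + 1L])
  ambiguous <- allGmin != allGmax

  # traceback: prefer 0 on ties (root and children alike) to delay gains
  states <- integer(nnode)
  states[root] <- if (0L %in% coopt) 0L else coopt[1L]
  edgesPre <- reorder(tree, "cladewise")$edge
  for (i in seq_len(nrow(edgesPre))) {
    p <- edgesPre[i, 1L]; ch <- edgesPre[i, 2L]
    opt <- trans[states[p] + 1L, ] + cost[ch, ]
    best <- which(opt == min(opt)) - 1L
    states[ch] <- if (0L %in% best) 0L else 1L
  }

  ev <- eventsFromLabeling(tree, states, labels)
  nG <- sum(ev$type == "gain"); nL <- sum(ev$type == "loss")
  methods::new("ReconstructionResult", mode = "sankoff",
               nodeStates = setNames(states, labels), events = ev,
               totalCost = nG * costGain + nL * costLoss,
               nGains = as.integer(nG), nLosses = as.integer(nL),
               costGain = costGain, costLoss = costLoss,
               ambiguous = ambiguous,
               info = list(rootPrior = rootPrior, minGains = allGmin,
                           maxGains = allGmax, dpCost = totalCost))
}

# node ids on the path from 'node' up to the root
ancestorPath <- function(tree, node) {
  parent <- setNames(tree$edge[, 1L], tree$edge[, 2L])
  path <- integer()
  v <- node
  while (!is.na(parent[as.character(v)])) {
    v <- parent[[as.character(v)]]
    path <- c(path, v)
  }
  path
}

subtreeTips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- treeChildren(tree)
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}

#' Dollo parsimony reconstruction of a binary trait
#'
#' Under the Dollo model a character is gained at most once and afterwards
#' only lost. The single gain is placed on the edge above the most recent
#' common ancestor (MRCA) of all leaves where the trait is definitely
#' present; leaves with state \code{"?"} are resolved so as to minimize
#' losses (a subtree containing only unknowns inside the gain clade is
#' resolved to present at zero cost). Each loss is charged once, at the top
#' of a maximal subtree inside the gain clade that contains a definite
#' absence and no presence.
#'
#' Because unknown leaves leave the gain placement partially undetermined,
#' the result's \code{info} also reports the \emph{latest}-possible gain
#' node (the MRCA of definite presences, used for the reported labeling,
#' consistent with the delay-gains tie-break) and the \emph{earliest}-
#' possible gain node (the highest ancestor reachable from it through
#' subtrees containing only unknowns).
#'
#' @param tree Rooted \code{phylo} tree (polytomies allowed).
#' @param leafStates Named character vector over the tips with values
#'   \code{"0"}, \code{"1"} or \code{"?"}.
#' @return A \linkS4class{ReconstructionResult} with unit event costs; its
#'   \code{info} holds \code{gainNodeLatest} and \code{gainNodeEarliest}.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dolloReconstruct(tr, c(A = "1", B = "0", C = "1", D = "0"))
#' @export
dolloReconstruct <- function(tree, leafStates) {
  assertRootedTree(tree)
  ls <- checkLeafStates(tree, leafStates)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  labels <- nodeLabels(tree)

  presentTips <- which(ls == "1")
  if (!length(presentTips)) {
    states <- setNames(integer(nnode), labels)
    return(methods::new("ReconstructionResult", mode = "dollo",
                        nodeStates = states,
                        events = DataFrame(parent = character(),
                                           child = character(),
                                           type = character()),
                        totalCost = 0, nGains = 0L, nLosses = 0L,
                        costGain = 1, costLoss = 1, ambiguous = FALSE,
                        info = list(gainNodeLatest = NA_character_,
                                    gainNodeEarliest = NA_character_)))
  }

  gainNode <- if (length(presentTips) == 1L) presentTips else
    ape::getMRCA(tree, presentTips)

  # earliest-possible gain: climb while every definite leaf added by the
  # step is unknown (all-? sister subtrees can be resolved present for free)
  earliest <- gainNode
  for (anc in ancestorPath(tree, gainNode)) {
    added <- setdiff(subtreeTips(tree, anc), subtreeTips(tree, earliest))
    if (all(ls[added] == "?")) earliest <- anc else break
  }

  # definite presence/absence anywhere in each subtree
  hasP <- logical(nnode); hasA <- logical(nnode)
  hasP[seq_len(ntip)] <- ls == "1"
  hasA[seq_len(ntip)] <- ls == "0"
  edgesPost <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edgesPost))) {
    p <- edgesPost[i, 1L]; ch <- edgesPost[i, 2L]
    hasP[p] <- hasP[p] || hasP[ch]
    hasA[p] <- hasA[p] || hasA[ch]
  }

  inClade <- logical(nnode)
  inClade[subtreeTips(tree, gainNode)] <- TRUE
  if (gainNode > ntip) {
    stack <- gainNode
    kids <- treeChildren(tree)
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      inClade[v] <- TRUE
      if (v > ntip) stack <- c(stack, kids[[v]])
    }
  }

  # inside the gain clade a node stays present unless its subtree holds a
  # definite absence and no presence; unknown-only subtrees resolve present
  states <- integer(nnode)
  edgesPre <- reorder(tree, "cladewise")$edge
  states[gainNode] <- 1L
  for (i in seq_len(nrow(edgesPre))) {
    p <- edgesPre[i, 1L]; ch <- edgesPre[i, 2L]
    if (!inClade[ch] || !inClade[p] && ch != gainNode) next
    if (ch == gainNode) next
    states[ch] <- if (states[p] == 1L && (hasP[ch] || !hasA[ch])) 1L else 0L
  }

  ev <- eventsFromLabeling(tree, states, labels)
  if (gainNode == root) {
    # the gain sits on the stem edge above the root and has no parent node
    ev <- rbind(DataFrame(parent = NA_character_, child = labels[gainNode],
                          type = "gain"), ev)
  }
  nG <- sum(ev$type == "gain"); nL <- sum(ev$type == "loss")
  stopifnot(nG == 1L)
  methods::new("ReconstructionResult", mode = "dollo",
               nodeStates = setNames(states, labels), events = ev,
               totalCost = nG + nL, nGains = as.integer(nG),
               nLosses = as.integer(nL), costGain = 1, costLoss = 1,
               ambiguous = labels[earliest] != labels[gainNode],
               info = list(gainNodeLatest = labels[gainNode],
                           gainNodeEarliest = labels[earliest]))
}

#' Annotate a tree with reconstructed states
#'
#' Serializes the tree to Newick with an NHX-style comment
#' \code{[&&NHX:state=0|1]} after every node, together with a gain/loss
#' event table. The annotation is lossless: \code{\link{parseAnnotatedNewick}}
#' recovers every node state.
#'
#' @param tree The \code{phylo} tree the result was computed on.
#' @param result A \linkS4class{ReconstructionResult} for that tree.
#' @return List with \code{newick} (character scalar) and \code{events}
#'   (DataFrame, identical to \code{events(result)}).
#' @export
annotateTree <- function(tree, result) {
  assertRootedTree(tree)
  labels <- nodeLabels(tree)
  if (!identical(sort(labels), sort(names(nodeStates(result)))))
    stop("tree and reconstruction result do not match (node labels differ)")
  st <- nodeStates(result)
  kids <- treeChildren(tree)
  ntip <- ape::Ntip(tree)
  quoteLabel <- function(x) {
    if (grepl("[][ ():;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  recurse <- function(v) {
    tag <- sprintf("[&&NHX:state=%d]", st[[labels[v]]])
    if (v <= ntip) return(paste0(quoteLabel(labels[v]), tag))
    inner <- paste(vapply(kids[[v]], recurse, ""), collapse = ",")
    paste0("(", inner, ")", quoteLabel(labels[v]), tag)
  }
  root <- ntip + 1L
  list(newick = paste0(recurse(root), ";"), events = events(result))
}

#' Parse an annotated Newick string back into tree + node states
#'
#' Inverse of \code{\link{annotateTree}}: strips the NHX state comments,
#' parses the topology with \code{ape}, and returns the per-node states
#' keyed by node label.
#'
#' @param text Annotated Newick string.
#' @return List with \code{tree} (phylo) and \code{states} (named integer).
#' @export
parseAnnotatedNewick <- function(text) {
  m <- gregexpr("('[^']*'|[^\\s(),;\\[]+)?\\[&&NHX:state=([01])\\]", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L) stop("no NHX state annotations found")
  pieces <- regmatches(text, gregexpr(
    "('[^']*'|[^\\s(),;\\[\\]]+)\\[&&NHX:state=[01]\\]", text, perl = TRUE))[[1]]
  lab <- sub("\\[&&NHX:state=[01]\\]$", "", pieces)
  lab <- ifelse(grepl("^'.*'$", lab),
                gsub("''", "'", substr(lab, 2L, nchar(lab) - 1L)), lab)
  st <- as.integer(sub("^.*state=([01])\\]$", "\\1", pieces))
  clean <- gsub("\\[&&NHX:state=[01]\\]", "", text)
  tree <- ape::read.tree(text = clean)
  tree$tip.label <- stripNewickQuotes(tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- stripNewickQuotes(tree$node.label)
  list(tree = tree, states = setNames(st, lab))
}
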