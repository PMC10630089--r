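proteinFastaHeaders <- function(x) {
  mc <- S4Vectors::mcols(x)
  h <- paste(mc$species, mc$family, mc$protein_id, sep = "|")
  flag <- !is.na(mc$partial)
  h[flag] <- paste0(h[flag], " partial=", tolower(as.character(mc$partial[flag])))
  if ("extra" %in% colnames(mc)) {
    keep <- !is.na(mc$extra) & nzchar(mc$extra)
    h[keep] <- paste(h[keep], mc$extra[keep])
  }
  h
}

#' Read protein records from FASTA
#'
#' Parses FASTA with the header grammar
#' \code{>\{species\}|\{family\}|\{protein_id\} key=value ...}. The
#' \code{partial} key becomes a logical flag (NA when unstated); any other
#' keys are preserved verbatim in the \code{extra} metadata column and
#' written back unchanged. CRLF line endings are accepted.
#'
#' @param path FASTA file path.
#' @return A \code{Biostrings::AAStringSet} with \code{mcols} columns
#'   \code{species}, \code{family}, \code{protein_id}, \code{partial},
#'   \code{extra}.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    aa <- Biostrings::AAStringSet()
    S4Vectors::mcols(aa) <- DataFrame(species = character(),
                                      family = character(),
                                      protein_id = character(),
                                      partial = logical(),
                                      extra = character())
    return(aa)
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  first <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  parts <- strsplit(first, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed FASTA header at record ", bad[1L], ": '",
         headers[bad[1L]], "' (expected species|family|id)")
  partial <- rep(NA, length(aa))
  extra <- character(length(aa))
  for (i in seq_along(aa)) {
    if (!nzchar(rest[i])) next
    kv <- strsplit(rest[i], "\\s+")[[1]]
    isPartial <- grepl("^partial=", kv)
    if (any(isPartial)) {
      val <- sub("^partial=", "", kv[isPartial][1L])
      if (!val %in% c("true", "false"))
        stop("malformed partial flag at record ", i, ": ", kv[isPartial][1L])
      partial[i] <- val == "true"
    }
    extra[i] <- paste(kv[!isPartial], collapse = " ")
  }
  S4Vectors::mcols(aa) <- DataFrame(
    species = vapply(parts, `[`, "", 1L),
    family = vapply(parts, `[`, "", 2L),
    protein_id = vapply(parts, `[`, "", 3L),
    partial = as.logical(partial), extra = extra)
  names(aa) <- proteinFastaHeaders(aa)
  aa
}

#' Write protein records to FASTA
#'
#' Inverse of \code{\link{readProteinFasta}}; writing then reading is the
#' identity, and re-writing a read file is byte-identical (LF line endings,
#' 80-column wrapping).
#'
#' @param x An \code{AAStringSet} with the \code{mcols} documented in
#'   \code{\link{readProteinFasta}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  names(x) <- proteinFastaHeaders(x)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

stripNewickQuotes <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L))
  x
}

quoteNewickLabel <- function(x) {
  # ']' leads the class: POSIX bracket expressions take '\' literally
  need <- grepl("[][ ():;,']", x)
  x[need] <- paste0("'", gsub("'", "''", x[need]), "'")
  x
}

#' Read a rooted tree from a Newick file
#'
#' Wraps \code{ape::read.tree} with stricter diagnostics: unbalanced
#' parentheses are reported with their character position, duplicate leaf
#' names are an error, and single quotes around labels (used for names with
#' spaces) are stripped after parsing. Polytomies, including at the root,
#' are preserved.
#'
#' @param path Newick file path (or use \code{text =} for a literal string).
#' @param text Optional Newick string instead of a file.
#' @return An \code{ape} \code{phylo} tree.
#' @export
readNewickTree <- function(path, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  inQuote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") inQuote <- !inQuote
    if (inQuote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses: unexpected ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' left open")
  if (!grepl("\\(", text)) text <- sub("^\\s*([^;]+);?\\s*$", "(\\1);", text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse Newick input")
  tree$tip.label <- stripNewickQuotes(tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- stripNewickQuotes(tree$node.label)
  assertRootedTree(tree)
  tree
}

#' Write a tree to Newick
#'
#' Canonical writer used throughout the package: internal labels are kept,
#' labels containing spaces or Newick metacharacters are single-quoted, and
#' branch lengths are written when present. Reading the output back with
#' \code{\link{readNewickTree}} reproduces the tree.
#'
#' @param tree A \code{phylo} tree.
#' @param path Output path; when NULL the Newick string is returned instead.
#' @return The path (invisibly) or the Newick string.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  assertRootedTree(tree)
  ntip <- ape::Ntip(tree)
  kids <- treeChildren(tree)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep("", tree$Nnode))
  labels[is.na(labels)] <- ""
  bl <- tree$edge.length
  blOf <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(bl)) blOf[tree$edge[, 2L]] <- bl
  recurse <- function(v) {
    out <- if (v <= ntip) quoteNewickLabel(labels[v]) else
      paste0("(", paste(vapply(kids[[v]], recurse, ""), collapse = ","), ")",
             quoteNewickLabel(labels[v]))
    if (!is.na(blOf[v])) out <- paste0(out, ":", format(blOf[v], digits = 10))
    out
  }
  nwk <- paste0(recurse(ntip + 1L), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Read / write a species-by-trait profile as TSV
#'
#' The matrix layout matches conventional profile figures: one row per
#' species, one column per trait, cells in \code{1/0/?}.
#'
#' @param path TSV path.
#' @return A \linkS4class{TraitProfile}.
#' @export
readTraitProfile <- function(path) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  rn <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rn
  TraitProfile(m, species = rn, traits = colnames(m))
}

#' @rdname readTraitProfile
#' @param profile A \linkS4class{TraitProfile} to write.
#' @export
writeTraitProfile <- function(profile, path) {
  m <- traitStates(profile)
  d <- data.frame(species = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a protein intensity table as TSV + design sidecar
#'
#' The wide table holds one row per protein with columns \code{protein},
#' \code{uniquePeptides} and one column per sample; missing values are empty
#' cells (never 0, which is a valid log intensity). The design sidecar maps
#' each sample column to its condition and replicate index.
#'
#' @param path Wide TSV path.
#' @param designPath Design TSV path with columns sample, condition,
#'   replicate.
#' @param logScale Whether the stored values are log2 (default TRUE).
#' @return A \linkS4class{TurboIDExperiment}.
#' @export
readIntensityTable <- function(path, designPath, logScale = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(designPath)) stop("no such file: ", designPath)
  d <- read.delim(path, check.names = FALSE)
  design <- read.delim(designPath, check.names = FALSE)
  stopifnot(all(c("sample", "condition", "replicate") %in% colnames(design)))
  samples <- as.character(design$sample)
  missingCols <- setdiff(samples, colnames(d))
  if (length(missingCols))
    stop("design names sample column(s) absent from the table: ",
         paste(missingCols, collapse = ", "))
  m <- as.matrix(d[, samples, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$protein
  TurboIDExperiment(m, condition = design$condition,
                    replicate = design$replicate,
                    uniquePeptides = d$uniquePeptides, logScale = logScale)
}

#' @rdname readIntensityTable
#' @param x A \linkS4class{TurboIDExperiment} to write.
#' @export
writeIntensityTable <- function(x, path, designPath) {
  a <- intensityAssay(x)
  cd <- SummarizedExperiment::colData(x)
  d <- data.frame(protein = rownames(a),
                  uniquePeptides =
                    SummarizedExperiment::rowData(x)$uniquePeptides,
                  a, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  design <- data.frame(sample = colnames(a), condition = cd$condition,
                       replicate = cd$replicate)
  write.table(design, designPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a gain/loss event table as TSV
#'
#' @param events DataFrame with columns parent, child, type (as stored in a
#'   \linkS4class{ReconstructionResult}).
#' @param path Output path.
#' @export
writeEventTable <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
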