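#' Assess whether protein records are complete or fragmentary
#'
#' A CAAX prenylation motif can only be scored on a sequence whose true
#' C-terminus is present. An explicit \code{partial} flag (as written by the
#' proteome simulator and parsed from FASTA headers) is always trusted.
#' When the flag is unstated, a configurable heuristic stands in: a record is
#' judged a fragment when its length falls below \code{minFraction} of the
#' family's median length, or when the sequence ends in the ambiguity
#' character \code{X} (a common signature of a truncated gene model). With no
#' evidence of fragmentation the verdict fails open to \code{"complete"}.
#'
#' @param sequences Character vector of residue sequences.
#' @param partial Logical vector (TRUE/FALSE/NA) of explicit partiality
#'   flags; NA means unstated. Recycled if length 1.
#' @param family Character vector of family assignments (used to look up
#'   \code{familyStats}); may be NULL when no stats are supplied.
#' @param familyStats Optional data.frame with columns \code{family} and
#'   \code{medianLength}.
#' @param minFraction Fraction of the family median length below which an
#'   unflagged record is called a fragment (default 0.5).
#' @return Character vector, \code{"complete"} or \code{"fragment"}.
#' @examples
#' assessCompleteness(c("MKTA", "MK"), partial = c(NA, NA),
#'   family = c("f", "f"),
#'   familyStats = data.frame(family = "f", medianLength = 4))
#' @export
assessCompleteness <- function(sequences, partial = NA, family = NULL,
                               familyStats = NULL, minFraction = 0.5) {
  n <- length(sequences)
  partial <- rep_len(as.logical(partial), n)
  verdict <- rep("complete", n)
  verdict[!is.na(partial) & partial] <- "fragment"
  unstated <- is.na(partial)
  if (any(unstated)) {
    seqs <- sub("\\*+$", "", sequences[unstated])
    frag <- grepl("X$", seqs)
    if (!is.null(familyStats) && !is.null(family)) {
      med <- setNames(familyStats$medianLength, familyStats$family)
      m <- med[family[unstated]]
      frag <- frag | (!is.na(m) & nchar(seqs) < minFraction * m)
    }
    verdict[unstated][frag] <- "fragment"
  }
  verdict
}

#' Detect C-terminal CAAX prenylation motifs, fragment-aware
#'
#' Scans protein sequences for a CAAX box using the operational rule of a
#' cysteine at offset -4 from the C-terminus (the terminal residue counts as
#' -1). The "AAX" residues are deliberately unconstrained: the farnesyl
#' acceptor cysteine position is the only requirement enforced. Calls are
#' three-state: \code{present}, \code{absent}, or \code{unknown} when the
#' record is judged fragmentary (its true C-terminus may be missing) or when
#' the residue at -4 is the ambiguity character \code{X}. Trailing stop
#' characters (\code{*}) are stripped before scanning.
#'
#' @param sequences Character vector of residue sequences, or a
#'   \code{Biostrings::AAStringSet} as returned by
#'   \code{\link{readProteinFasta}} (its \code{mcols} supply ids, species,
#'   family and partial flags).
#' @param ids,species,family Optional per-record annotation (recycled).
#' @param partial Logical TRUE/FALSE/NA flags passed to
#'   \code{\link{assessCompleteness}}.
#' @param familyStats,minFraction Passed to \code{\link{assessCompleteness}}.
#' @return A \code{DataFrame} with one row per record: \code{protein_id},
#'   \code{species}, \code{family}, \code{state}
#'   (present/absent/unknown), \code{acceptor_position} (1-based, the
#'   sequence position of the acceptor cysteine; NA unless present),
#'   \code{acceptor_offset} (-4 for every present call) and \code{motif}
#'   (the terminal 4-mer; NA unless present).
#' @examples
#' detectCaax("MAEEGAVAPLCKTQ")         # present, motif CKTQ
#' detectCaax("MAEEGAVAPLAKTQ")         # absent: no Cys at -4
#' detectCaax("MAEEGAVAPL", partial = TRUE)  # unknown: fragment
#' @export
detectCaax <- function(sequences, ids = NULL, species = NA_character_,
                       family = NA_character_, partial = NA,
                       familyStats = NULL, minFraction = 0.5) {
  if (methods::is(sequences, "AAStringSet")) {
    mc <- S4Vectors::mcols(sequences)
    if (!is.null(mc) && "partial" %in% colnames(mc)) partial <- mc$partial
    if (!is.null(mc) && "species" %in% colnames(mc)) species <- mc$species
    if (!is.null(mc) && "family" %in% colnames(mc)) family <- mc$family
    if (!is.null(mc) && "protein_id" %in% colnames(mc)) ids <- mc$protein_id
    sequences <- as.character(sequences)
  }
  n <- length(sequences)
  if (n == 0L) {
    return(DataFrame(protein_id = character(), species = character(),
                     family = character(), state = character(),
                     acceptor_position = integer(),
                     acceptor_offset = integer(), motif = character()))
  }
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  species <- rep_len(species, n)
  family <- rep_len(family, n)
  partial <- rep_len(as.logical(partial), n)

  seqs <- sub("\\*+$", "", sequences)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))

  completeness <- assessCompleteness(sequences, partial, family,
                                     familyStats, minFraction)
  L <- nchar(seqs)
  state <- character(n)
  acceptorPos <- rep(NA_integer_, n)
  acceptorOff <- rep(NA_integer_, n)
  motif <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (completeness[i] == "fragment") {
      state[i] <- "unknown"
      next
    }
    if (L[i] < 4L) {
      warning("complete record '", ids[i],
              "' shorter than 4 residues: calling absent")
      state[i] <- "absent"
      next
    }
    m <- substr(seqs[i], L[i] - 3L, L[i])
    r4 <- substr(m, 1L, 1L)
    if (r4 == "X") {
      state[i] <- "unknown"
    } else if (r4 == "C") {
      state[i] <- "present"
      acceptorPos[i] <- L[i] - 3L
      acceptorOff[i] <- -4L
      motif[i] <- m
    } else {
      state[i] <- "absent"
    }
  }
  DataFrame(protein_id = as.character(ids), species = as.character(species),
            family = as.character(family), state = state,
            acceptor_position = acceptorPos, acceptor_offset = acceptorOff,
            motif = motif)
}

#' Create a construct specification
#'
#' @param name Construct name.
#' @param start,end 1-based inclusive residue range in parent coordinates.
#' @param substitutions List of window substitutions, each a list with
#'   \code{start}, \code{end} (parent coordinates inside \code{[start, end]})
#'   and \code{replacement} (a single residue, e.g. \code{"A"} for an
#'   alanine scan).
#' @param caaxSwap Optional 4-residue CAAX motif fused after the construct's
#'   C-terminus, or NULL.
#' @return A \linkS4class{ConstructSpec}.
#' @examples
#' ConstructSpec("2111-C", start = 2111, end = 2701)
#' @export
ConstructSpec <- function(name, start, end, substitutions = list(),
                          caaxSwap = NULL) {
  methods::new("ConstructSpec", name = name, start = as.integer(start),
               end = as.integer(end), substitutions = substitutions,
               caaxSwap = caaxSwap)
}

#' Build a truncation/substitution construct from a parent protein
#'
#' Applies a \linkS4class{ConstructSpec} to a parent sequence: extracts the
#' residue range, substitutes each specified window with the replacement
#' residue, and optionally fuses a 4-residue CAAX motif to the C-terminus.
#' The report quantifies the construct against the parent: its length, the
#' number of substituted positions that actually changed, and the number of
#' residues removed from each terminus relative to parent coordinates.
#'
#' @param parent Parent residue sequence (character scalar).
#' @param spec A \linkS4class{ConstructSpec}.
#' @return List with \code{sequence} (character), \code{name}, and
#'   \code{report}: a list with \code{length}, \code{nSubstituted},
#'   \code{removedN}, \code{removedC}.
#' @examples
#' parent <- strrep("Q", 2697)
#' parent <- paste0(substr(parent, 1, 2697), "CKTQ")  # 2701 aa, ends CKTQ
#' cons <- buildConstruct(parent, ConstructSpec("2111-C", 2111, 2701))
#' cons$report$length  # 591
#' @export
buildConstruct <- function(parent, spec) {
  stopifnot(is.character(parent), length(parent) == 1L)
  methods::validObject(spec)
  L <- nchar(parent)
  if (spec@end > L)
    stop(sprintf("construct window [%d, %d] outside parent of length %d",
                 spec@start, spec@end, L))
  seq <- substr(parent, spec@start, spec@end)
  for (s in spec@substitutions) {
    # window is given in parent coordinates; shift into the construct
    a <- s$start - spec@start + 1L
    b <- s$end - spec@start + 1L
    substr(seq, a, b) <- strrep(s$replacement, b - a + 1L)
  }
  nSub <- sum(strsplit(seq, "")[[1]] !=
              strsplit(substr(parent, spec@start, spec@end), "")[[1]])
  if (!is.null(spec@caaxSwap)) {
    if (nchar(seq) < 4L)
      stop("cannot fuse a CAAX box onto a construct shorter than 4 residues")
    seq <- paste0(seq, spec@caaxSwap)
  }
  list(sequence = seq, name = spec@name,
       report = list(length = nchar(seq), nSubstituted = nSub,
                     removedN = spec@start - 1L, removedC = L - spec@end))
}
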