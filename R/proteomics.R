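#' Construct a TurboIDExperiment
#'
#' @param intensity Numeric protein x sample matrix (log2 scale unless
#'   \code{logScale = FALSE}); NA marks a missing value.
#' @param condition Character condition label per sample column.
#' @param replicate Integer replicate index per sample, unique within each
#'   condition.
#' @param uniquePeptides Integer unique-peptide count per protein.
#' @param logScale Logical; FALSE when \code{intensity} holds raw
#'   intensities that still need the log2 variance-stabilizing transform.
#' @return A \linkS4class{TurboIDExperiment}.
#' @export
TurboIDExperiment <- function(intensity, condition, replicate,
                              uniquePeptides, logScale = TRUE) {
  intensity <- as.matrix(intensity)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(uniquePeptides = as.integer(uniquePeptides)),
    colData = DataFrame(condition = as.character(condition),
                        replicate = as.integer(replicate)))
  obj <- methods::new("TurboIDExperiment", se)
  metadata(obj)$logScale <- isTRUE(logScale)
  methods::validObject(obj)
  obj
}

intensityAssay <- function(x) SummarizedExperiment::assay(x, "intensity")

conditionOf <- function(x) SummarizedExperiment::colData(x)$condition

#' Filter proteins on identification evidence
#'
#' Applies the study's pre-test filter to a protein-group table: a protein
#' is kept only if it has at least \code{minUniquePeptides} unique peptides
#' and was identified (non-missing) in at least \code{minReps} replicates of
#' at least one condition. Row order is preserved and the operation is
#' idempotent.
#'
#' @param x A \linkS4class{TurboIDExperiment}.
#' @param minUniquePeptides Minimum unique peptides (default 1, the rule as
#'   stated; configurable because stricter thresholds are common).
#' @param minReps Minimum replicates with an identification in some
#'   condition (default 2, i.e. two out of three).
#' @return The filtered \linkS4class{TurboIDExperiment}.
#' @export
filterProteins <- function(x, minUniquePeptides = 1L, minReps = 2L) {
  stopifnot(methods::is(x, "TurboIDExperiment"))
  cond <- conditionOf(x)
  nPer <- table(cond)
  if (any(nPer < minReps))
    stop("condition(s) with fewer samples than minReps: ",
         paste(names(nPer)[nPer < minReps], collapse = ", "))
  a <- intensityAssay(x)
  obsPerCond <- vapply(unique(cond), function(cc)
    rowSums(!is.na(a[, cond == cc, drop = FALSE])), numeric(nrow(a)))
  if (nrow(a) == 1L) obsPerCond <- matrix(obsPerCond, nrow = 1L)
  keep <- SummarizedExperiment::rowData(x)$uniquePeptides >=
    minUniquePeptides &
    (if (nrow(a)) apply(obsPerCond, 1L, max) >= minReps else logical(0))
  x[keep, ]
}

#' Variance-stabilizing normalization of a log-intensity table
#'
#' Background-corrects and normalizes protein intensities: raw intensities
#' are first variance-stabilized with a log2 transform (skipped when the
#' table is already on the log scale), then each sample group (condition) is
#' affinely shifted and scaled -- the group's pooled median to the common
#' median, its pooled MAD to the common MAD over all observed values -- so
#' that group medians align and spreads match. The transform is estimated
#' per group rather than per sample: pooling the group's replicates makes
#' the shift/scale estimates stable and avoids re-scaling genuine
#' between-condition differences within a group. Missing values stay
#' missing and the operation is deterministic.
#'
#' @param x A \linkS4class{TurboIDExperiment}.
#' @return A normalized \linkS4class{TurboIDExperiment} (metadata flag
#'   \code{normalized} set).
#' @export
normalizeVST <- function(x) {
  stopifnot(methods::is(x, "TurboIDExperiment"))
  a <- intensityAssay(x)
  if (!isTRUE(metadata(x)$logScale)) {
    if (any(a <= 0, na.rm = TRUE))
      stop("raw intensities must be positive for the log2 transform")
    a <- log2(a)
  }
  cond <- conditionOf(x)
  for (g in unique(cond)) {
    if (all(is.na(a[, cond == g])))
      stop("sample group with all values missing: ", g)
    if (sum(!is.na(a[, cond == g])) < 2L)
      stop("sample group with fewer than 2 observed values: ", g)
  }
  medG <- median(a, na.rm = TRUE)
  madG <- mad(a, na.rm = TRUE)
  for (g in unique(cond)) {
    cols <- cond == g
    mg <- median(a[, cols], na.rm = TRUE)
    sg <- mad(a[, cols], na.rm = TRUE)
    scale <- if (sg > 0 && madG > 0) madG / sg else 1
    a[, cols] <- (a[, cols] - mg) * scale + medG
  }
  SummarizedExperiment::assay(x, "intensity") <- a
  metadata(x)$logScale <- TRUE
  metadata(x)$normalized <- TRUE
  x
}

#' Left-shifted Gaussian imputation of missing-not-at-random values
#'
#' Proximity-biotinylation tables drop low-intensity proteins
#' preferentially, so missing values are imputed from a Gaussian that is
#' deliberately shifted into the left tail of each sample's observed
#' distribution: a missing cell in sample j is drawn from
#' \code{Normal(mean_j - shiftSd * sd_j, (widthSd * sd_j)^2)}, where mean_j
#' and sd_j are computed from the observed values of that sample. Observed
#' values are never touched and a fixed seed reproduces the imputation
#' exactly.
#'
#' @param x A normalized \linkS4class{TurboIDExperiment}.
#' @param shiftSd Left shift in sample standard deviations (default 1.8).
#' @param widthSd Width of the imputation Gaussian in sample standard
#'   deviations (default 0.3).
#' @param seed Integer seed.
#' @return A complete \linkS4class{TurboIDExperiment} (metadata flag
#'   \code{imputed} set).
#' @export
imputeMNAR <- function(x, shiftSd = 1.8, widthSd = 0.3, seed) {
  stopifnot(methods::is(x, "TurboIDExperiment"))
  a <- intensityAssay(x)
  nObs <- colSums(!is.na(a))
  if (any(nObs < 2L))
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(a)[nObs < 2L], collapse = ", "))
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(a))) {
    miss <- which(is.na(a[, j]))
    if (!length(miss)) next
    m <- mean(a[, j], na.rm = TRUE)
    s <- sd(a[, j], na.rm = TRUE)
    a[miss, j] <- rnorm(length(miss), m - shiftSd * s, widthSd * s)
  }
  SummarizedExperiment::assay(x, "intensity") <- a
  metadata(x)$imputed <- TRUE
  metadata(x)$imputeParams <- list(shiftSd = shiftSd, widthSd = widthSd,
                                   seed = as.integer(seed))
  x
}

rowVarsNA <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
}

#' Per-protein differential enrichment between two conditions
#'
#' Two-sample test per protein on (normalized, imputed) log2 intensities.
#' The effect size is \code{log2FC = mean(A) - mean(B)} on the log2 scale;
#' the p-value comes from Welch's t-test by default (a pooled-variance
#' option is provided). A protein is flagged a hit by the volcano rule:
#' \code{-log10 p} above \code{nlpThreshold} and a log2 fold change beyond
#' \code{lfcThreshold} (two-sided by default; set \code{direction = "up"}
#' to require enrichment in A). Raw p-values drive the hit flag -- this
#' volcano convention applies no multiplicity adjustment -- and a
#' Benjamini-Hochberg column is included for reference only.
#'
#' @param x A \linkS4class{TurboIDExperiment} with no remaining missing
#'   values in the tested conditions.
#' @param conditionA,conditionB Condition labels (A is the bait/numerator).
#' @param test \code{"welch"} (default) or \code{"pooled"}.
#' @param lfcThreshold,nlpThreshold Volcano thresholds (defaults 2 and 2).
#' @param direction \code{"both"} (|log2FC|) or \code{"up"} (log2FC only).
#' @return An \linkS4class{EnrichmentResult}.
#' @export
testEnrichment <- function(x, conditionA, conditionB,
                           test = c("welch", "pooled"),
                           lfcThreshold = 2, nlpThreshold = 2,
                           direction = c("both", "up")) {
  test <- match.arg(test)
  direction <- match.arg(direction)
  stopifnot(methods::is(x, "TurboIDExperiment"))
  cond <- conditionOf(x)
  for (cc in c(conditionA, conditionB))
    if (!cc %in% cond) stop("unknown condition label: ", cc)
  A <- intensityAssay(x)[, cond == conditionA, drop = FALSE]
  B <- intensityAssay(x)[, cond == conditionB, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  if (any(nA < 2L) || any(nB < 2L))
    stop("every protein needs >= 2 observed replicates per condition; ",
         "impute or filter first")
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- rowVarsNA(A); vB <- rowVarsNA(B)
  lfc <- mA - mB
  if (test == "welch") {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  } else {
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- nA + nB - 2L
  }
  tstat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  # degenerate rows: zero variance on both sides
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  nlp <- -log10(p)
  effectOK <- if (direction == "both") abs(lfc) > lfcThreshold
              else lfc > lfcThreshold
  hit <- effectOK & nlp > nlpThreshold
  proteins <- rownames(intensityAssay(x))
  if (is.null(proteins)) proteins <- sprintf("P%04d", seq_along(lfc))
  res <- DataFrame(protein = proteins, log2FC = unname(lfc),
                   pvalue = unname(p), negLog10P = unname(nlp),
                   padj = unname(p.adjust(p, "BH")), hit = unname(hit))
  methods::new("EnrichmentResult", results = res,
               params = list(test = test, lfcThreshold = lfcThreshold,
                             nlpThreshold = nlpThreshold,
                             direction = direction,
                             conditionA = conditionA,
                             conditionB = conditionB))
}

#' Rank an enrichment result for volcano-style reporting
#'
#' Sorts the result table with hits first, then by decreasing
#' \code{-log10 p}; ties in p are broken by larger |log2FC|, then by
#' protein identifier (lexicographic).
#'
#' @param result An \linkS4class{EnrichmentResult}.
#' @return The ranked \code{DataFrame}.
#' @export
volcanoTable <- function(result) {
  stopifnot(methods::is(result, "EnrichmentResult"))
  r <- enrichmentTable(result)
  ord <- order(-r$hit, -r$negLog10P, -abs(r$log2FC), r$protein)
  r[ord, ]
}

#' Volcano plot of an enrichment result
#'
#' @param result An \linkS4class{EnrichmentResult}.
#' @return A ggplot object: log2 fold change against -log10 p with dashed
#'   guides at the configured thresholds and hits highlighted.
#' @export
plotVolcano <- function(result) {
  stopifnot(methods::is(result, "EnrichmentResult"))
  d <- as.data.frame(enrichmentTable(result))
  p <- enrichmentParams(result)
  ggplot2::ggplot(d, ggplot2::aes(x = log2FC, y = negLog10P, colour = hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = p$nlpThreshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * p$lfcThreshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey50",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "hit") +
    ggplot2::theme_classic()
}
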