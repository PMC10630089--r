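toyExperiment <- function() {
  # six proteins chosen to exercise every clause of the identification filter
  m <- rbind(
    allObs     = c(25, 26, 25.5, 20, 20.5, 21),   # kept
    oneCondOk  = c(24, 24.5, NA,  NA, NA, NA),    # 2/3 in WT -> kept
    sparse     = c(24, NA, NA,    23, NA, NA),    # 1/3 everywhere -> removed
    lowPeptide = c(25, 25, 25,    25, 25, 25),    # 0 unique peptides -> removed
    bOnly      = c(NA, NA, NA,    22, 22.5, 23),  # 3/3 in emp -> kept
    borderline = c(25, NA, 24,    NA, 21, NA))    # 2/3 in WT -> kept
  TurboIDExperiment(m, condition = rep(c("WT", "emp"), each = 3),
                    replicate = rep(1:3, 2),
                    uniquePeptides = c(2L, 3L, 4L, 0L, 1L, 2L))
}

test_that("filterProteins keeps exactly the hand-enumerated survivors", {
  kept <- rownames(filterProteins(toyExperiment()))
  expect_equal(kept, c("allObs", "oneCondOk", "bOnly", "borderline"))
  # idempotence
  once <- filterProteins(toyExperiment())
  expect_identical(rownames(filterProteins(once)), rownames(once))
  # empty table stays empty
  empty <- toyExperiment()[integer(0), ]
  expect_equal(nrow(filterProteins(empty)), 0L)
  # a condition smaller than minReps is a design error
  bad <- TurboIDExperiment(matrix(c(1, 2, 3), nrow = 1),
                          condition = c("WT", "WT", "emp"),
                          replicate = c(1, 2, 1), uniquePeptides = 1L)
  expect_error(filterProteins(bad), "fewer samples")
})

test_that("TurboIDExperiment validity catches malformed containers", {
  expect_error(TurboIDExperiment(matrix(1:4, 2),
                                 condition = c("WT", "WT"),
                                 replicate = c(1, 1),
                                 uniquePeptides = c(1L, 1L)),
               "unique within")
  expect_error(TurboIDExperiment(matrix(c(1, Inf, 2, 3), 2),
                                 condition = c("WT", "emp"),
                                 replicate = c(1, 1),
                                 uniquePeptides = c(1L, 1L)),
               "finite")
})

test_that("normalizeVST aligns sample medians and spreads", {
  set.seed(1)
  base <- rnorm(120, 25, 2)
  m <- cbind(a = base + rnorm(120, 0, .1), b = base + rnorm(120, 0, .1))
  x <- TurboIDExperiment(m, condition = c("WT", "emp"), replicate = c(1, 1),
                         uniquePeptides = rep(1L, 120))
  # identical samples stay identical
  xx <- TurboIDExperiment(cbind(a = base, b = base),
                          condition = c("WT", "emp"), replicate = c(1, 1),
                          uniquePeptides = rep(1L, 120))
  n <- SummarizedExperiment::assay(normalizeVST(xx))
  expect_equal(n[, "a"], n[, "b"])
  # an additive shift between samples is removed
  xs <- TurboIDExperiment(cbind(a = base, b = base + 3),
                          condition = c("WT", "emp"), replicate = c(1, 1),
                          uniquePeptides = rep(1L, 120))
  ns <- SummarizedExperiment::assay(normalizeVST(xs))
  expect_equal(ns[, "a"], ns[, "b"], tolerance = 1e-12)
  # missing cells stay missing
  m2 <- m; m2[5, 1] <- NA
  x2 <- TurboIDExperiment(m2, condition = c("WT", "emp"),
                          replicate = c(1, 1),
                          uniquePeptides = rep(1L, 120))
  expect_true(is.na(SummarizedExperiment::assay(normalizeVST(x2))[5, 1]))
  # all-missing sample is an error
  m3 <- m; m3[, 2] <- NA
  x3 <- TurboIDExperiment(m3, condition = c("WT", "emp"),
                          replicate = c(1, 1),
                          uniquePeptides = rep(1L, 120))
  expect_error(normalizeVST(x3), "all values missing")
})

test_that("the log2 transform stabilizes variance across intensity tertiles", {
  set.seed(2)
  ratios <- replicate(100, {
    mu <- runif(90, 20, 30)                       # per-protein log2 abundance
    raw <- 2^(mu + matrix(rnorm(90 * 6, 0, 0.3), 90, 6))
    v <- apply(raw, 1, var)
    tert <- cut(mu, quantile(mu, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                labels = FALSE)
    rawRatio <- mean(v[tert == 3]) / mean(v[tert == 1])
    x <- TurboIDExperiment(raw, condition = rep(c("WT", "emp"), each = 3),
                           replicate = rep(1:3, 2),
                           uniquePeptides = rep(1L, 90), logScale = FALSE)
    a <- SummarizedExperiment::assay(normalizeVST(x))
    vt <- apply(a, 1, var)
    c(raw = rawRatio, vst = mean(vt[tert == 3]) / mean(vt[tert == 1]))
  })
  expect_gt(mean(ratios["raw", ]), 3)             # > 200% difference before
  expect_lt(abs(mean(ratios["vst", ]) - 1), 0.2)  # < 20% difference after
})

test_that("imputeMNAR draws from the left-shifted Gaussian and is a no-op without NAs", {
  set.seed(3)
  m <- matrix(rnorm(400, 25, 2), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  x <- TurboIDExperiment(m, condition = rep(c("WT", "emp"), each = 2),
                         replicate = rep(1:2, 2),
                         uniquePeptides = rep(1L, 100))
  expect_identical(SummarizedExperiment::assay(imputeMNAR(x, seed = 1)),
                   m)
  # degenerate Gaussian: shift 0, width ~0 -> imputed values equal the mean
  m2 <- m; m2[1:10, 1] <- NA
  x2 <- TurboIDExperiment(m2, condition = rep(c("WT", "emp"), each = 2),
                          replicate = rep(1:2, 2),
                          uniquePeptides = rep(1L, 100))
  a <- SummarizedExperiment::assay(imputeMNAR(x2, shiftSd = 0,
                                              widthSd = 1e-12, seed = 1))
  expect_equal(unname(a[1:10, 1]),
               rep(mean(m2[, 1], na.rm = TRUE), 10), tolerance = 1e-6)
  # observed cells are untouched; fixed seed reproduces the imputation
  a1 <- SummarizedExperiment::assay(imputeMNAR(x2, seed = 7))
  a2 <- SummarizedExperiment::assay(imputeMNAR(x2, seed = 7))
  expect_identical(a1, a2)
  expect_equal(a1[-(1:10), 1], m2[-(1:10), 1])
  expect_error(imputeMNAR(TurboIDExperiment(
    matrix(c(1, NA, NA, 2, 3, 4), ncol = 2), condition = c("WT", "emp"),
    replicate = c(1, 1), uniquePeptides = rep(1L, 3)), seed = 1),
    "fewer than 2 observed")
})

test_that("imputed values sit in the left tail below the sample median", {
  set.seed(4)
  below <- replicate(50, {
    m <- matrix(rnorm(600, 25, 2), ncol = 6)
    m[sample(length(m), 120)] <- NA
    x <- TurboIDExperiment(m, condition = rep(c("WT", "emp"), each = 3),
                           replicate = rep(1:3, 2),
                           uniquePeptides = rep(1L, 100))
    a <- SummarizedExperiment::assay(imputeMNAR(x, seed = sample.int(1e6, 1)))
    ok <- vapply(seq_len(ncol(m)), function(j) {
      idx <- is.na(m[, j])
      if (!any(idx)) return(1)
      mean(a[idx, j] < median(m[, j], na.rm = TRUE))
    }, 0)
    mean(ok)
  })
  expect_gte(mean(below), 0.99)
})

test_that("testEnrichment computes Welch and pooled statistics correctly", {
  set.seed(5)
  m <- matrix(rnorm(60, 25, 1), ncol = 6)
  m[1, ] <- c(29, 29.5, 28.5, 24, 24.5, 25)
  m[2, ] <- rep(25, 6)                      # identical values -> null
  rownames(m) <- paste0("P", 1:10)
  x <- TurboIDExperiment(m, condition = rep(c("WT", "emp"), each = 3),
                         replicate = rep(1:3, 2),
                         uniquePeptides = rep(2L, 10))
  for (method in c("welch", "pooled")) {
    res <- enrichmentTable(testEnrichment(x, "WT", "emp", test = method))
    # cross-check every non-degenerate row against stats::t.test
    for (i in 1:10) {
      if (var(m[i, 1:3]) + var(m[i, 4:6]) == 0) next
      tt <- t.test(m[i, 1:3], m[i, 4:6], var.equal = (method == "pooled"))
      expect_equal(res$pvalue[i], tt$p.value, tolerance = 1e-12)
      expect_equal(res$log2FC[i],
                   unname(tt$estimate[1] - tt$estimate[2]),
                   tolerance = 1e-12)
    }
    expect_equal(res$log2FC[2], 0)
    expect_false(res$hit[2])
    expect_true(res$hit[1])   # log2FC ~4.5, p well below 0.01
  }
  expect_error(testEnrichment(x, "WT", "mock"), "unknown condition")
})

test_that("the hit rule is exactly the double-threshold volcano rule", {
  # synthetic result rows on both sides of each threshold
  m <- rbind(c(28.2, 28.1, 28.3, 26, 26.05, 25.95),  # lfc ~2.2, tiny p -> hit
             c(26.4, 26.5, 26.6, 25, 24.9, 25.1),    # lfc 1.5 -> no
             c(30, 25, 28, 25.1, 24.8, 25.2))        # big lfc, big p -> no
  rownames(m) <- c("a", "b", "c")
  x <- TurboIDExperiment(m, condition = rep(c("WT", "emp"), each = 3),
                         replicate = rep(1:3, 2),
                         uniquePeptides = rep(2L, 3))
  res <- enrichmentTable(testEnrichment(x, "WT", "emp"))
  expect_equal(res$hit, c(TRUE, FALSE, FALSE))
  expect_equal(res$hit,
               abs(res$log2FC) > 2 & res$negLog10P > 2)
  # a 2.5-fold-change, p = 1e-3 protein is a hit by definition of the rule
  expect_true(2.5 > 2 && -log10(1e-3) > 2)
})

test_that("volcanoTable ranks hits first with documented tie-breaks", {
  res <- methods::new("EnrichmentResult",
    results = S4Vectors::DataFrame(
      protein = c("b", "a", "c", "d"),
      log2FC = c(3, -4, 3, 1),
      pvalue = c(1e-3, 1e-3, 1e-4, 0.5),
      negLog10P = c(3, 3, 4, -log10(0.5)),
      padj = c(1, 1, 1, 1),
      hit = c(TRUE, TRUE, TRUE, FALSE)),
    params = list(test = "welch", lfcThreshold = 2, nlpThreshold = 2,
                  direction = "both", conditionA = "WT", conditionB = "emp"))
  ranked <- volcanoTable(res)
  expect_equal(ranked$protein, c("c", "a", "b", "d"))
  single <- res
  single@results <- res@results[1, ]
  expect_equal(nrow(volcanoTable(single)), 1L)
})

test_that("MNAR dropout never increases the pipeline's power", {
  recover <- function(useDropout) {
    hits <- 0; planted <- 0
    for (s in 1:40) {
      sim <- simulateIntensityTable(
        80, 5, effectLog2 = 4, nReps = 3,
        dropout = if (useDropout) list(midpoint = 22, steepness = 1) else NULL,
        seed = s)
      tab <- enrichmentTable(runEnrichmentPipeline(sim, seedOffset = s))
      truth <- sim$truth[match(tab$protein, sim$truth$protein), ]
      hits <- hits + sum(tab$hit & truth$enriched)
      planted <- planted + sum(sim$truth$enriched)
    }
    hits / planted
  }
  expect_lte(recover(TRUE), recover(FALSE))
  expect_gt(recover(TRUE), 0.5)
})

test_that("the full proteomics chain is deterministic end to end", {
  run <- function() {
    sim <- simulateIntensityTable(60, 4, seed = 13)
    as.data.frame(enrichmentTable(runEnrichmentPipeline(sim)))
  }
  expect_identical(run(), run())
})
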