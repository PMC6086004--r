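test_that("median-of-ratios size factors: identity, scale, and oracle agreement", {
  set.seed(1)
  a <- matrix(rpois(100, 60), 50, 2)
  ident <- cbind(a[, 1], a[, 1])
  expect_equal(unname(medianRatioSizeFactors(ident)), c(1, 1))

  doubled <- cbind(a[, 1], 2L * a[, 1])
  sf <- medianRatioSizeFactors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)
  nrm <- normalizeCounts(doubled, sf)$normalized
  expect_equal(nrm[, 1], nrm[, 2])

  ## odd gene count so the median is a single order statistic and the naive
  ## ratio-scale oracle coincides with the log-scale median exactly
  m <- matrix(rnbinom(51 * 6, mu = 80, size = 10) + 1L, 51, 6)
  m <- sweep(m, 2, c(1, 2, 1, 3, 1, 1), "*")
  expect_equal(unname(medianRatioSizeFactors(m)), morOracle(m),
               tolerance = 1e-12)
})

test_that("size factors agree with an established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(80 * 5, mu = 120, size = 8), 80, 5)
  expect_equal(unname(medianRatioSizeFactors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("degenerate count matrices are rejected with informative errors", {
  expect_error(medianRatioSizeFactors(matrix(0L, 5, 3)), "all zero")
  m <- matrix(5L, 4, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  m[, 2] <- 0L
  expect_error(medianRatioSizeFactors(m), "s2")
  expect_error(medianRatioSizeFactors(matrix(1L, 3, 1)), "2 samples")
})

.tinyDesign <- function() simulateDesign(3)

.tinyCounts <- function(design, ctrl, kds) {
  ## one gene per row of ctrl/kds: constant within each condition
  n <- length(ctrl)
  m <- matrix(0L, n, nrow(design),
              dimnames = list(sprintf("g%02d", seq_len(n)), design$sample))
  for (j in seq_len(nrow(design))) {
    cond <- design$condition[j]
    m[, j] <- if (design$is_control[j]) ctrl else kds[[cond]]
  }
  m
}

test_that("fold change and repression hit the null and boundary cases exactly", {
  design <- .tinyDesign()
  kdConds <- unique(design$condition[!design$is_control])
  ## all conditions identical: FC = 1, r = 0
  kds <- setNames(rep(list(rep(100L, 8)), 4), kdConds)
  rp <- repressionProfiles(.tinyCounts(design, rep(100L, 8), kds),
                           design, pseudocount = 0, test = "welch")
  for (ck in c("A1", "A2", "B1", "B2")) {
    expect_equal(unname(rp[[paste0("fc_", ck)]]), rep(1, 8))
    expect_equal(unname(rp[[paste0("r_", ck)]]), rep(0, 8))
  }
  ## knockdown at exactly 0.7x control with pseudocount 0: r = 0.30.
  ## genes 2-8 are unchanged ballast so every size factor is exactly 1.
  ctrl <- c(100L, 40L, 60L, 80L, 120L, 160L, 240L, 500L)
  kd <- ctrl; kd[1] <- 70L
  kds <- setNames(rep(list(kd), 4), kdConds)
  rp <- repressionProfiles(.tinyCounts(design, ctrl, kds),
                           design, pseudocount = 0, test = "welch")
  for (ck in c("A1", "A2", "B1", "B2"))
    expect_equal(unname(rp[[paste0("r_", ck)]][1]), 0.3)
  expect_equal(unname(rp$r_A1[-1]), rep(0, 7))
})

test_that("estimated repression tracks planted truth on simulated data", {
  se <- simulateKnockdown(simParams(nGenes = 800, seed = 4))
  rp <- repressionProfiles(se)
  tt <- truthTable(se)
  co <- tt$class == "co_repressed"
  for (ck in c("A1", "A2", "B1", "B2"))
    expect_lt(abs(median(rp[[paste0("r_", ck)]][co]) - 0.6), 0.1)
  expect_identical(rownames(rp), rownames(se))
})

test_that("fold changes are invariant to rescaling one sample's counts", {
  se <- simulateKnockdown(simParams(nGenes = 200, seed = 7))
  counts <- SummarizedExperiment::assay(se)
  design <- as.data.frame(SummarizedExperiment::colData(se))
  ## pseudocount 0: the rescaling cancels exactly through the size factors
  rp1 <- repressionProfiles(counts, design, pseudocount = 0, test = "welch")
  scaled <- counts
  scaled[, 4] <- scaled[, 4] * 3L
  rp2 <- repressionProfiles(scaled, design, pseudocount = 0, test = "welch")
  for (ck in c("A1", "A2", "B1", "B2"))
    expect_equal(rp1[[paste0("fc_", ck)]], rp2[[paste0("fc_", ck)]],
                 tolerance = 1e-9)
})

test_that("swapping knockdown and control inverts the fold change", {
  design <- .tinyDesign()
  kdConds <- unique(design$condition[!design$is_control])
  ## three regulated genes plus unchanged ballast keeping size factors at 1
  ctrl <- c(100L, 50L, 200L, 80L, 90L, 110L, 130L, 150L, 170L)
  kd <- c(40L, 100L, 150L, 80L, 90L, 110L, 130L, 150L, 170L)
  kds <- setNames(rep(list(kd), 4), kdConds)
  rp <- repressionProfiles(.tinyCounts(design, ctrl, kds), design,
                           pseudocount = 0, test = "welch")
  kdsSwap <- setNames(rep(list(ctrl), 4), kdConds)
  rpSwap <- repressionProfiles(.tinyCounts(design, kd, kdsSwap), design,
                               pseudocount = 0, test = "welch")
  ## r -> 1 - 1/(1 - r): enhancement is the reciprocal on the FC scale
  expect_equal(unname(rpSwap$r_A1), 1 - 1 / (1 - rp$r_A1), tolerance = 1e-9)
})

test_that("the welch option reproduces stats::t.test per gene", {
  se <- simulateKnockdown(simParams(nGenes = 40, seed = 9))
  counts <- SummarizedExperiment::assay(se)
  design <- as.data.frame(SummarizedExperiment::colData(se))
  rp <- repressionProfiles(counts, design, test = "welch")
  nrm <- normalizeCounts(counts)$normalized
  lg <- log2(nrm + 0.5)
  kd <- design$condition == "shMYC.1"
  ctrl <- design$is_control
  pRef <- apply(lg, 1, function(x) t.test(x[kd], x[ctrl])$p.value)
  expect_equal(unname(rp$p_A1), unname(pRef), tolerance = 1e-12)
})

test_that("low-expression genes are flagged but kept", {
  se <- simulateKnockdown(simParams(nGenes = 300, seed = 10,
                                    baselineMeanLog = log(8), baselineSdLog = 2))
  rp <- repressionProfiles(se, expressionFloor = 5)
  expect_gt(sum(rp$low_expression), 0)
  expect_equal(nrow(rp), nrow(se))
})

test_that("designs without a clone condition or replicates are rejected", {
  se <- simulateKnockdown(simParams(nGenes = 50, seed = 1))
  counts <- SummarizedExperiment::assay(se)
  design <- as.data.frame(SummarizedExperiment::colData(se))
  drop <- design$condition != "shTip60.2"
  expect_error(repressionProfiles(counts[, drop], design[drop, ]),
               "B2.*absent|absent.*B2")
  one <- design$condition != "shGFP" | design$sample == "shGFP_r1"
  expect_error(repressionProfiles(counts[, one], design[one, ]), "control")
})

test_that("BH adjustment matches hand step-up computations and the oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.123), 0.123)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(100, 1))
    expect_equal(bhAdjust(p), bhStepUpOracle(p), tolerance = 1e-12)
  }
})
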