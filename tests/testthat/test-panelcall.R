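.profileOf <- function(tab) RepressionProfile(tab)

## a handful of archetypal expression responses: co-repressed with high
## significance, enhanced-by-A1, weakly repressed, co-activated
.archetypes <- function() {
  rows <- list(
    FEN1  = c(A1 = 0.60, A2 = 0.55, B1 = 0.50, B2 = 0.45),  # co-repressed
    CCNE2 = c(A1 = 0.45, A2 = 0.40, B1 = 0.62, B2 = 0.30),  # co-repressed
    CDC7  = c(A1 = -0.35, A2 = 0.50, B1 = 0.40, B2 = 0.35), # enhanced by A1
    CDK1  = c(A1 = -0.20, A2 = 0.45, B1 = 0.35, B2 = 0.20), # enhanced by A1
    CCNB1 = c(A1 = 0.10, A2 = 0.05, B1 = 0.08, B2 = 0.02),  # weak
    UPREG = c(A1 = -0.80, A2 = -0.70, B1 = -0.90, B2 = -0.60)) # co-activated
  tab <- data.frame(gene = names(rows))
  for (ck in c("A1", "A2", "B1", "B2")) {
    r <- vapply(rows, `[[`, numeric(1), ck)
    tab[[paste0("fc_", ck)]] <- 1 - r
    tab[[paste0("r_", ck)]] <- r
    tab[[paste0("p_", ck)]] <- 0.001
    tab[[paste0("q_", ck)]] <- 0.01
  }
  tab$low_expression <- FALSE
  tab
}

test_that("genes repressed by all clones enter the consensus panel; clone-1-enhanced genes do not", {
  rp <- .profileOf(.archetypes())
  panel <- callConsensusPanel(rp)
  expect_true(all(c("FEN1", "CCNE2") %in% panel$gene))
  expect_false(any(c("CDC7", "CDK1", "CCNB1", "UPREG") %in% panel$gene))
})

test_that("an empty profile yields an empty panel", {
  rp <- .profileOf(.archetypes()[0, ])
  expect_equal(nrow(callConsensusPanel(rp)), 0)
  expect_equal(nrow(callCoactivatedPanel(rp)), 0)
})

test_that("the consensus call agrees with a row-by-row predicate oracle", {
  tab <- randomProfileTable(500, seed = 21, lowFrac = 0.1)
  ## shrink r into a range where all three criteria are exercised
  for (ck in c("A1", "A2", "B1", "B2")) {
    tab[[paste0("r_", ck)]] <- tab[[paste0("r_", ck)]] * 0.6
    tab[[paste0("fc_", ck)]] <- 1 - tab[[paste0("r_", ck)]]
  }
  panel <- callConsensusPanel(.profileOf(tab))
  expect_setequal(panel$gene, consensusOracle(tab))
})

test_that("the co-repression score is the min of the two clone-averaged repressions", {
  tab <- .archetypes()
  rp <- .profileOf(tab)
  allHalf <- tab
  for (ck in c("A1", "A2", "B1", "B2")) {
    allHalf[[paste0("r_", ck)]] <- 0.5
    allHalf[[paste0("fc_", ck)]] <- 0.5
  }
  expect_equal(unname(corepressionScore(.profileOf(allHalf))["FEN1"]), 0.5)
  ## A-average 0.6, B-average 0.4 -> 0.4
  mixed <- allHalf[1, ]
  mixed$r_A1 <- 0.7; mixed$r_A2 <- 0.5; mixed$r_B1 <- 0.45; mixed$r_B2 <- 0.35
  for (ck in c("A1", "A2", "B1", "B2"))
    mixed[[paste0("fc_", ck)]] <- 1 - mixed[[paste0("r_", ck)]]
  expect_equal(unname(corepressionScore(.profileOf(mixed))), 0.4)
  expect_error(corepressionScore(rp, "NOSUCH"), "absent")
})

test_that("consensus ranking equals a brute-force sort by (score desc, gene asc)", {
  tab <- randomProfileTable(200, seed = 5)
  ## quantize scores to force ties
  for (ck in c("A1", "A2", "B1", "B2")) {
    tab[[paste0("r_", ck)]] <- round(tab[[paste0("r_", ck)]], 1)
    tab[[paste0("fc_", ck)]] <- 1 - tab[[paste0("r_", ck)]]
    tab[[paste0("p_", ck)]] <- 0.001
    tab[[paste0("q_", ck)]] <- 0.01
  }
  panel <- callConsensusPanel(.profileOf(tab))
  sc <- (pmin(tab$r_A1 + tab$r_A2, tab$r_B1 + tab$r_B2)) / 2
  keep <- tab$r_A1 >= 0.3 & tab$r_B1 >= 0.3 & tab$r_A2 >= 0 & tab$r_B2 >= 0
  ref <- data.frame(gene = tab$gene[keep], score = sc[keep])
  ref <- ref[order(-ref$score, ref$gene), ]
  expect_equal(panel$gene, ref$gene)
  expect_equal(panel$score, ref$score)
  expect_true(all(diff(panel$score) <= 0))
})

test_that("topPanel truncates deterministically and warns when short", {
  tab <- randomProfileTable(3000, seed = 8)
  for (ck in c("A1", "B1")) {
    tab[[paste0("p_", ck)]] <- 0.0005
    tab[[paste0("q_", ck)]] <- 0.001
  }
  gp <- callPanels(.profileOf(tab))
  n <- nrow(consensusPanel(gp))
  expect_gt(n, 50)
  top <- topPanel(gp)
  expect_equal(nrow(top), 50)
  expect_true(all(diff(top$score) <= 0))
  expect_identical(top$gene, topPanel(gp)$gene)
  expect_warning(short <- topPanel(gp, topK = n + 10), "only")
  expect_equal(nrow(short), n)
})

test_that("exclusive panels respect the gap between excl_min and excl_other_max", {
  tab <- .archetypes()[1, ]
  set1 <- function(rA, rB) {
    t2 <- tab
    t2$r_A1 <- rA; t2$r_A2 <- rA; t2$r_B1 <- rB; t2$r_B2 <- rB
    for (ck in c("A1", "A2", "B1", "B2"))
      t2[[paste0("fc_", ck)]] <- 1 - t2[[paste0("r_", ck)]]
    callExclusivePanels(.profileOf(t2))
  }
  clear <- set1(0.5, 0.05)
  expect_equal(clear$a_only$gene, "FEN1")
  expect_equal(nrow(clear$b_only), 0)
  gap <- set1(0.5, 0.15)          # other-factor repression in (0.10, 0.30)
  expect_equal(nrow(gap$a_only), 0)
  expect_equal(nrow(gap$b_only), 0)
})

test_that("exclusive and co-activated calls match brute-force predicates", {
  tab <- randomProfileTable(400, seed = 13)
  rp <- .profileOf(tab)
  ex <- callExclusivePanels(rp)
  rA <- (tab$r_A1 + tab$r_A2) / 2
  rB <- (tab$r_B1 + tab$r_B2) / 2
  expect_setequal(ex$a_only$gene, tab$gene[rA >= 0.30 & rB <= 0.10])
  expect_setequal(ex$b_only$gene, tab$gene[rB >= 0.30 & rA <= 0.10])
  co <- callCoactivatedPanel(rp)
  expect_setequal(co$gene, tab$gene[pmin(-rA, -rB) >= 0.47])
})

test_that("co-activation uses the weaker factor's clone-averaged activation", {
  tab <- .archetypes()
  co <- callCoactivatedPanel(.profileOf(tab))
  expect_equal(co$gene, "UPREG")
  expect_equal(co$score, min((0.8 + 0.7) / 2, (0.9 + 0.6) / 2))
  ## a_A = 0.6, a_B = 0.3: below the 0.47 floor on the weaker side
  t2 <- tab[1, ]
  t2$r_A1 <- -0.6; t2$r_A2 <- -0.6; t2$r_B1 <- -0.3; t2$r_B2 <- -0.3
  for (ck in c("A1", "A2", "B1", "B2"))
    t2[[paste0("fc_", ck)]] <- 1 - t2[[paste0("r_", ck)]]
  expect_equal(nrow(callCoactivatedPanel(.profileOf(t2))), 0)
})

test_that("low-expression genes are ineligible for every panel", {
  tab <- .archetypes()
  tab$low_expression <- TRUE
  gp <- callPanels(.profileOf(tab))
  expect_equal(nrow(consensusPanel(gp)), 0)
  expect_equal(nrow(aOnlyPanel(gp)), 0)
  expect_equal(nrow(coactivatedPanel(gp)), 0)
})

test_that("raising any minimum threshold never grows a panel", {
  for (s in 1:5) {
    tab <- randomProfileTable(250, seed = 100 + s)
    rp <- .profileOf(tab)
    base <- callConsensusPanel(rp, panelThresholds())
    for (arg in c("r1Min", "r2Min")) {
      for (delta in c(0.05, 0.2)) {
        args <- list(); args[[arg]] <- formals(panelThresholds)[[arg]] + delta
        tighter <- callConsensusPanel(rp, do.call(panelThresholds, args))
        expect_true(all(tighter$gene %in% base$gene))
      }
    }
    looseQ <- callConsensusPanel(rp, panelThresholds(qMax = 0.01))
    expect_true(all(looseQ$gene %in% base$gene))
    coBase <- callCoactivatedPanel(rp)
    coTight <- callCoactivatedPanel(rp, panelThresholds(coactMin = 0.6))
    expect_true(all(coTight$gene %in% coBase$gene))
  }
})

test_that("score bounds hold: per-factor max above, 0.15 floor for default consensus", {
  tab <- randomProfileTable(300, seed = 31)
  rp <- .profileOf(tab)
  sc <- corepressionScore(rp)
  expect_true(all(sc <= pmax(tab$r_A1, tab$r_A2) + 1e-12))
  expect_true(all(sc <= pmax(tab$r_B1, tab$r_B2) + 1e-12))
  panel <- callConsensusPanel(rp)
  if (nrow(panel)) expect_true(all(panel$score >= 0.15))
})

test_that("consensus and exclusive panels are disjoint under default thresholds", {
  for (s in 1:3) {
    gp <- callPanels(.profileOf(randomProfileTable(300, seed = 200 + s)))
    expect_length(intersect(consensusPanel(gp)$gene, aOnlyPanel(gp)$gene), 0)
    expect_length(intersect(consensusPanel(gp)$gene, bOnlyPanel(gp)$gene), 0)
  }
})

test_that("profiles missing a clone column are rejected", {
  tab <- .archetypes()
  tab$r_B2 <- NULL
  expect_error(callConsensusPanel(RepressionProfile(tab)), "missing columns")
})
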