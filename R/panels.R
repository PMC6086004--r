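#' Construct panel-calling thresholds
#'
#' Defaults are the study's published cuts; see
#' \linkS4class{PanelThresholds}.
#'
#' @param r1Min,qMax,r2Min consensus criteria (stringent clone-1 repression
#'   floor, adjusted-P ceiling, confirmatory clone-2 floor).
#' @param exclMin,exclOtherMax exclusive-panel bounds on clone-averaged
#'   repression.
#' @param coactMin co-activation floor.
#' @param topK ranked top-panel size.
#' @return a validated [PanelThresholds].
#' @examples
#' panelThresholds()
#' panelThresholds(r1Min = 0.5, topK = 20)
#' @export
panelThresholds <- function(r1Min = 0.30, qMax = 0.05, r2Min = 0.0,
                            exclMin = 0.30, exclOtherMax = 0.10,
                            coactMin = 0.47, topK = 50) {
  new("PanelThresholds", r1Min = r1Min, qMax = qMax, r2Min = r2Min,
      exclMin = exclMin, exclOtherMax = exclOtherMax, coactMin = coactMin,
      topK = as.integer(topK))
}

.profCol <- function(profiles, name) {
  if (!name %in% colnames(profiles))
    stop(sprintf("profile table lacks column '%s'", name))
  profiles[[name]]
}

## eligible = passed the expression floor
.eligible <- function(profiles) !profiles$low_expression

.panelFrame <- function(profiles, idx, score = NULL) {
  keep <- c(paste0("r_", CLONE_KEYS), paste0("q_", CLONE_KEYS))
  out <- S4Vectors::DataFrame(gene = rownames(profiles)[idx])
  if (!is.null(score)) out$score <- score
  for (cn in keep) out[[cn]] <- profiles[[cn]][idx]
  rownames(out) <- out$gene
  out
}

#' Co-repression score
#'
#' The efficiency of co-repression by the two factors, read as the common
#' part ("extent of overlap") of the two clone-averaged repression
#' efficiencies: \code{min((r_A1 + r_A2)/2, (r_B1 + r_B2)/2)}.
#'
#' @param profiles a [RepressionProfile].
#' @param genes genes to score (default: all); any missing repression value
#'   is an error.
#' @return named numeric scores.
#' @examples
#' tab <- data.frame(gene = "x",
#'   fc_A1 = 0.5, r_A1 = 0.5, p_A1 = 0.01, q_A1 = 0.02,
#'   fc_A2 = 0.5, r_A2 = 0.5, p_A2 = 0.01, q_A2 = 0.02,
#'   fc_B1 = 0.5, r_B1 = 0.5, p_B1 = 0.01, q_B1 = 0.02,
#'   fc_B2 = 0.5, r_B2 = 0.5, p_B2 = 0.01, q_B2 = 0.02)
#' corepressionScore(RepressionProfile(tab))
#' @export
corepressionScore <- function(profiles, genes = NULL) {
  if (is.null(genes)) genes <- rownames(profiles)
  miss <- setdiff(genes, rownames(profiles))
  if (length(miss))
    stop(sprintf("gene(s) absent from profiles: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  idx <- match(genes, rownames(profiles))
  rA <- (.profCol(profiles, "r_A1")[idx] + .profCol(profiles, "r_A2")[idx]) / 2
  rB <- (.profCol(profiles, "r_B1")[idx] + .profCol(profiles, "r_B2")[idx]) / 2
  if (anyNA(rA) || anyNA(rB))
    stop("missing repression values for scored genes")
  stats::setNames(pmin(rA, rB), genes)
}

## ordering used everywhere: score descending, gene id ascending on ties
.rankOrder <- function(score, gene) order(-score, gene, method = "radix")

#' Call the consensus (co-repressed) panel
#'
#' A gene enters the consensus panel iff (i) both stringent clone-1
#' repressions reach \code{r1Min}, (ii) both clone-1 adjusted P values are
#' at most \code{qMax}, and (iii) both confirmatory clone-2 repressions are
#' at least \code{r2Min}. Low-expression genes are ineligible. The panel is
#' returned ordered by decreasing [corepressionScore()] (ties by gene id).
#'
#' @param profiles a [RepressionProfile].
#' @param thresholds a [PanelThresholds].
#' @return \linkS4class{DFrame} of panel genes with \code{score} and
#'   per-clone \code{r}/\code{q} columns.
#' @export
callConsensusPanel <- function(profiles, thresholds = panelThresholds()) {
  validObject(thresholds)
  r <- lapply(CLONE_KEYS, function(ck) .profCol(profiles, paste0("r_", ck)))
  names(r) <- CLONE_KEYS
  q <- lapply(c("A1", "B1"), function(ck) .profCol(profiles, paste0("q_", ck)))
  names(q) <- c("A1", "B1")
  pass <- .eligible(profiles) &
    !is.na(r$A1) & !is.na(r$B1) & !is.na(r$A2) & !is.na(r$B2) &
    !is.na(q$A1) & !is.na(q$B1) &
    r$A1 >= thresholds@r1Min & r$B1 >= thresholds@r1Min &
    q$A1 <= thresholds@qMax & q$B1 <= thresholds@qMax &
    r$A2 >= thresholds@r2Min & r$B2 >= thresholds@r2Min
  idx <- which(pass)
  score <- if (length(idx)) corepressionScore(profiles, rownames(profiles)[idx])
           else numeric()
  ord <- .rankOrder(score, rownames(profiles)[idx])
  .panelFrame(profiles, idx[ord], score = unname(score[ord]))
}

#' Top of the ranked consensus panel
#'
#' @param panels a [GenePanels] (or the consensus \linkS4class{DFrame}
#'   itself).
#' @param topK panel size; defaults to the thresholds stored in
#'   \code{panels}. If fewer consensus genes exist, all are returned with a
#'   warning.
#' @return the first \code{topK} rows of the consensus panel.
#' @export
topPanel <- function(panels, topK = NULL) {
  cons <- if (is(panels, "GenePanels")) consensusPanel(panels) else panels
  if (is.null(topK))
    topK <- if (is(panels, "GenePanels")) panels@thresholds@topK else 50L
  if (nrow(cons) < topK) {
    warning(sprintf("consensus panel has only %d genes (< topK = %d); returning all",
                    nrow(cons), topK))
    return(cons)
  }
  cons[seq_len(topK), , drop = FALSE]
}

#' Call the factor-exclusive panels
#'
#' A gene is A-only when its clone-averaged repression by factor A is at
#' least \code{exclMin} while its clone-averaged repression by factor B is
#' at most \code{exclOtherMax}; B-only symmetrically. Genes in the gap
#' belong to neither.
#'
#' @inheritParams callConsensusPanel
#' @return list with elements \code{a_only} and \code{b_only}, each ordered
#'   by decreasing own-factor average repression.
#' @export
callExclusivePanels <- function(profiles, thresholds = panelThresholds()) {
  validObject(thresholds)
  rA <- (.profCol(profiles, "r_A1") + .profCol(profiles, "r_A2")) / 2
  rB <- (.profCol(profiles, "r_B1") + .profCol(profiles, "r_B2")) / 2
  elig <- .eligible(profiles) & !is.na(rA) & !is.na(rB)
  aIdx <- which(elig & rA >= thresholds@exclMin & rB <= thresholds@exclOtherMax)
  bIdx <- which(elig & rB >= thresholds@exclMin & rA <= thresholds@exclOtherMax)
  aOrd <- .rankOrder(rA[aIdx], rownames(profiles)[aIdx])
  bOrd <- .rankOrder(rB[bIdx], rownames(profiles)[bIdx])
  list(a_only = .panelFrame(profiles, aIdx[aOrd], score = unname(rA[aIdx][aOrd])),
       b_only = .panelFrame(profiles, bIdx[bOrd], score = unname(rB[bIdx][bOrd])))
}

#' Call the co-activated panel
#'
#' Activation is negative repression, \code{a = -r}. A gene is co-activated
#' when the smaller of its two clone-averaged activations reaches
#' \code{coactMin}; the panel is ordered by that minimum, descending.
#'
#' @inheritParams callConsensusPanel
#' @return ordered \linkS4class{DFrame} of co-activated genes with their
#'   min-activation \code{score}.
#' @export
callCoactivatedPanel <- function(profiles, thresholds = panelThresholds()) {
  validObject(thresholds)
  aA <- -(.profCol(profiles, "r_A1") + .profCol(profiles, "r_A2")) / 2
  aB <- -(.profCol(profiles, "r_B1") + .profCol(profiles, "r_B2")) / 2
  act <- pmin(aA, aB)
  idx <- which(.eligible(profiles) & !is.na(act) & act >= thresholds@coactMin)
  ord <- .rankOrder(act[idx], rownames(profiles)[idx])
  .panelFrame(profiles, idx[ord], score = unname(act[idx][ord]))
}

#' Call all panels
#'
#' Runs the consensus, exclusive, and co-activated calls with one set of
#' thresholds and bundles the results with their provenance.
#'
#' @inheritParams callConsensusPanel
#' @return a [GenePanels].
#' @examples
#' se <- simulateKnockdown(simParams(nGenes = 500, seed = 3))
#' gp <- callPanels(repressionProfiles(se))
#' gp
#' head(consensusPanel(gp))
#' @export
callPanels <- function(profiles, thresholds = panelThresholds()) {
  excl <- callExclusivePanels(profiles, thresholds)
  new("GenePanels",
      consensus = callConsensusPanel(profiles, thresholds),
      aOnly = excl$a_only, bOnly = excl$b_only,
      coactivated = callCoactivatedPanel(profiles, thresholds),
      thresholds = thresholds,
      scoreConvention = "min_of_clone_averages")
}
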