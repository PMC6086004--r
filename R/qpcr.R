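## Comparative-Ct relative quantification for RT-qPCR validation tables.
## Two normalization modes: ddct (internal reference gene, e.g. GAPDH) and
## equal-input (no reference; samples standardized by equal input RNA, for
## cases where the reference gene itself responds to the perturbation).
## Amplification efficiency is taken as perfect doubling (2 per cycle).

.checkCt <- function(ct) {
  need <- c("sample", "condition", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% colnames(ct)))
    stop(sprintf("Ct table must have columns: %s", paste(need, collapse = ", ")))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive finite cycle numbers")
  if (anyDuplicated(ct[, c("sample", "gene")]))
    stop("each (sample, gene) pair may appear at most once")
  ct
}

.summarizeRel <- function(condition, rel) {
  conds <- unique(condition)
  out <- data.frame(
    condition = conds,
    relative_expression = vapply(conds, function(cc)
      2^mean(log2(rel[condition == cc])), numeric(1)),
    min = vapply(conds, function(cc) min(rel[condition == cc]), numeric(1)),
    max = vapply(conds, function(cc) max(rel[condition == cc]), numeric(1)),
    n = vapply(conds, function(cc) sum(condition == cc), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative expression by the comparative-Ct method
#'
#' Standard ddCt quantification with an internal reference gene: per
#' replicate sample, \code{dCt = Ct(gene) - Ct(reference)}; \code{ddCt =
#' dCt - mean dCt(calibrator condition)}; relative expression =
#' \code{2^-ddCt}. Replicates are aggregated on the dCt scale (geometric
#' mean of relative expressions), with the per-condition range reported.
#'
#' @param ct data.frame with columns \code{sample}, \code{condition},
#'   \code{gene}, \code{ct} (cycles).
#' @param gene target gene.
#' @param referenceGene internal control gene, measured in every sample of
#'   the target gene (error naming the sample otherwise).
#' @param calibrator condition against which expression is 1 by definition.
#' @return data.frame per condition: \code{relative_expression} (geometric
#'   mean), \code{min}, \code{max}, \code{n}.
#' @examples
#' ct <- data.frame(sample = rep(c("s1", "s2"), each = 2),
#'                  condition = rep(c("shGFP", "shMYC.1"), each = 2),
#'                  gene = rep(c("FEN1", "GAPDH"), 2),
#'                  ct = c(20, 15, 21, 15))
#' relativeExpressionDdct(ct, "FEN1", "GAPDH", "shGFP")
#' @export
relativeExpressionDdct <- function(ct, gene, referenceGene, calibrator) {
  ct <- .checkCt(ct)
  tg <- ct[ct$gene == gene, , drop = FALSE]
  if (nrow(tg) == 0L) stop(sprintf("gene '%s' not in the Ct table", gene))
  if (!calibrator %in% ct$condition)
    stop(sprintf("calibrator condition '%s' not present", calibrator))
  rf <- ct[ct$gene == referenceGene, , drop = FALSE]
  refIdx <- match(tg$sample, rf$sample)
  if (anyNA(refIdx))
    stop(sprintf("reference gene '%s' not measured in sample(s): %s",
                 referenceGene,
                 paste(tg$sample[is.na(refIdx)], collapse = ", ")))
  dct <- tg$ct - rf$ct[refIdx]
  calMean <- mean(dct[tg$condition == calibrator])
  if (is.nan(calMean))
    stop(sprintf("gene '%s' not measured in the calibrator condition", gene))
  rel <- 2^(-(dct - calMean))
  .summarizeRel(tg$condition, rel)
}

#' Relative expression from equal input RNA
#'
#' As [relativeExpressionDdct()] but without a reference gene: samples are
#' assumed standardized by equal quantities of input RNA, so \code{dCt =
#' Ct(gene)} and relative expression = \code{2^-(Ct - mean Ct(calibrator))}.
#' Used when the internal control itself responds to the perturbation.
#'
#' @inheritParams relativeExpressionDdct
#' @return data.frame per condition as in [relativeExpressionDdct()].
#' @export
relativeExpressionEqualInput <- function(ct, gene, calibrator) {
  ct <- .checkCt(ct)
  tg <- ct[ct$gene == gene, , drop = FALSE]
  if (nrow(tg) == 0L) stop(sprintf("gene '%s' not in the Ct table", gene))
  if (!calibrator %in% tg$condition)
    stop(sprintf("calibrator condition '%s' not present for gene '%s'",
                 calibrator, gene))
  calMean <- mean(tg$ct[tg$condition == calibrator])
  rel <- 2^(-(tg$ct - calMean))
  .summarizeRel(tg$condition, rel)
}
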