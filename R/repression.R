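#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with sorted P values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and
#' mapped back to input order. Thin validating wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues numeric vector of P values in [0, 1].
#' @return adjusted values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("pvalues must be numeric")
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("pvalues must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

## Row-wise Welch two-sample t test (two-sided) on matrices x, y.
## Degenerate rows (both group variances zero) get p = 1 when the means
## agree and p = 0 when they differ: the data admit no other reading.
.rowWelch <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
  p
}

## Moderated t (limma-trend) per contrast: ordinary linear fit on the
## log-expression of the two groups, residual variances shrunk toward a
## mean-variance trend fitted across genes. The trend needs a reasonable
## number of genes; below that, a constant prior is used.
.rowModerated <- function(x, y) {
  mat <- cbind(x, y)
  design <- cbind(Intercept = 1, kd = c(rep(1, ncol(x)), rep(0, ncol(y))))
  fit <- limma::lmFit(mat, design)
  fit <- limma::eBayes(fit, trend = nrow(mat) >= 100)
  fit$p.value[, "kd"]
}

#' Per-gene, per-clone repression profiles
#'
#' Normalizes counts by median-of-ratios, then for each hairpin clone
#' estimates the fold change as the ratio of mean normalized expression
#' (knockdown/control, both means offset by \code{pseudocount}), the
#' repression efficiency \code{r = 1 - fold change}, a two-sided P value
#' from a test on \code{log2(normalized + pseudocount)}, and a BH-adjusted
#' P within each clone's contrast. Genes whose mean normalized control
#' expression falls below \code{expressionFloor} are flagged
#' \code{low_expression} (and later excluded from panels), never dropped.
#'
#' The default test is a moderated t (limma-trend): per-gene variances are
#' shrunk toward a global mean-variance trend, which restores power at the
#' small replicate numbers typical of knockdown designs. \code{"welch"}
#' gives the unmoderated Welch t on the same log values.
#'
#' @param x a \linkS4class{SummarizedExperiment} with a \code{counts} assay
#'   and design columns (\code{condition}, \code{factor},
#'   \code{clone_index}, \code{is_control}) in \code{colData}, or a count
#'   matrix (then \code{design} is required).
#' @param design data.frame as from [simulateDesign()]; ignored when
#'   \code{x} is a SummarizedExperiment.
#' @param pseudocount offset for fold changes and log transformation.
#' @param expressionFloor minimum mean normalized control count.
#' @param test \code{"moderated"} (default) or \code{"welch"}.
#' @return a [RepressionProfile].
#' @examples
#' se <- simulateKnockdown(simParams(nGenes = 300, seed = 2))
#' rp <- repressionProfiles(se)
#' head(rp)
#' @export
repressionProfiles <- function(x, design = NULL, pseudocount = 0.5,
                               expressionFloor = 5,
                               test = c("moderated", "welch")) {
  test <- match.arg(test)
  if (is(x, "SummarizedExperiment")) {
    design <- as.data.frame(SummarizedExperiment::colData(x))
    counts <- SummarizedExperiment::assay(x, "counts")
  } else {
    if (is.null(design)) stop("a design table is required with a count matrix")
    counts <- x
  }
  need <- c("condition", "factor", "clone_index", "is_control")
  if (!all(need %in% colnames(design)))
    stop(sprintf("design must have columns: %s", paste(need, collapse = ", ")))
  if (!is.null(design$sample) &&
      !is.null(colnames(counts)) &&
      !identical(as.character(design$sample), colnames(counts)))
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]

  factors <- unique(design$factor[!design$is_control])
  factors <- factors[!is.na(factors)]
  if (length(factors) != 2L)
    stop("design must contain exactly two knockdown factors")
  cloneKey <- .cloneKeyOf(design, factors)

  ctrlIdx <- which(design$is_control)
  if (length(ctrlIdx) < 2L) stop("the control condition needs >= 2 replicates")
  cloneIdx <- lapply(CLONE_KEYS, function(ck) which(cloneKey == ck))
  names(cloneIdx) <- CLONE_KEYS
  for (ck in CLONE_KEYS)
    if (length(cloneIdx[[ck]]) < 2L)
      stop(sprintf("clone condition %s (%s) is absent or has < 2 replicates",
                   ck, c(A = factors[1], B = factors[2])[substr(ck, 1, 1)]))

  nrm <- normalizeCounts(counts)
  norm <- nrm$normalized
  logNorm <- log2(norm + pseudocount)
  ctrlMean <- rowMeans(norm[, ctrlIdx, drop = FALSE])
  lowExpr <- ctrlMean < expressionFloor

  cols <- list()
  cloneMap <- character()
  for (ck in CLONE_KEYS) {
    idx <- cloneIdx[[ck]]
    kdMean <- rowMeans(norm[, idx, drop = FALSE])
    fc <- (kdMean + pseudocount) / (ctrlMean + pseudocount)
    p <- switch(test,
                welch = .rowWelch(logNorm[, idx, drop = FALSE],
                                  logNorm[, ctrlIdx, drop = FALSE]),
                moderated = .rowModerated(logNorm[, idx, drop = FALSE],
                                          logNorm[, ctrlIdx, drop = FALSE]))
    q <- stats::p.adjust(p, method = "BH")
    cols[[paste0("fc_", ck)]] <- unname(fc)
    cols[[paste0("r_", ck)]] <- unname(1 - fc)
    cols[[paste0("p_", ck)]] <- unname(p)
    cols[[paste0("q_", ck)]] <- unname(q)
    cloneMap[ck] <- design$condition[idx[1]]
  }
  cols$low_expression <- unname(lowExpr)

  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("g%0*d", nchar(nrow(counts)), seq_len(nrow(counts)))
  tab <- do.call(S4Vectors::DataFrame, c(cols, list(row.names = ids)))
  new("RepressionProfile", tab,
      pseudocount = pseudocount, expressionFloor = expressionFloor,
      test = test, sizeFactors = nrm$sizeFactors, cloneMap = cloneMap)
}

#' Construct a RepressionProfile from a plain table
#'
#' For profiles computed elsewhere (or read back from disk with
#' [readProfileTsv()]): the table must carry, for each clone A1, A2, B1, B2,
#' the \code{fc_}, \code{r_}, \code{p_}, \code{q_} columns; a missing
#' \code{low_expression} column is taken as all-FALSE.
#'
#' @param table data.frame or DataFrame with gene rownames (or a
#'   \code{gene} column).
#' @param pseudocount,expressionFloor,test,sizeFactors,cloneMap provenance;
#'   defaults mark the profile as externally computed.
#' @return a validated [RepressionProfile].
#' @export
RepressionProfile <- function(table, pseudocount = NA_real_,
                              expressionFloor = NA_real_,
                              test = "external", sizeFactors = numeric(),
                              cloneMap = character()) {
  tab <- S4Vectors::DataFrame(table)
  if (is.null(rownames(tab)) && "gene" %in% colnames(tab)) {
    rownames(tab) <- tab$gene
    tab$gene <- NULL
  }
  if (!"low_expression" %in% colnames(tab))
    tab$low_expression <- FALSE
  new("RepressionProfile", tab,
      pseudocount = pseudocount, expressionFloor = expressionFloor,
      test = test, sizeFactors = sizeFactors, cloneMap = cloneMap)
}
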