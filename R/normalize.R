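#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over genes with all-positive
#' counts, of the ratio of the sample's count to the gene's geometric mean
#' across samples. This centers each sample on the majority of genes, so
#' size factors are insensitive to a minority of strongly regulated genes
#' (unlike total-count scaling).
#'
#' @param counts nonnegative integer gene x sample matrix with >= 2 columns.
#' @return named numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(rpois(200, 50), 50, 4)
#' medianRatioSizeFactors(m)
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- .checkCounts(counts)
  logGeo <- rowMeans(log(counts))            # -Inf where any count is 0
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene has all-positive counts; size factors are undefined")
  sf <- apply(counts, 2, function(col)
    exp(stats::median(log(col[use]) - logGeo[use])))
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by median-of-ratios size factors
#'
#' @param counts nonnegative integer gene x sample matrix.
#' @param sizeFactors optional precomputed size factors; estimated with
#'   [medianRatioSizeFactors()] when missing.
#' @return list with \code{normalized} (counts divided column-wise by the
#'   size factor) and \code{sizeFactors}.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  counts <- .checkCounts(counts)
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
  if (length(sizeFactors) != ncol(counts))
    stop("need one size factor per sample")
  list(normalized = sweep(counts, 2, sizeFactors, "/"),
       sizeFactors = sizeFactors)
}

.checkCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (all(counts == 0)) stop("count matrix is all zero")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(bad, collapse = ", ")))
  }
  counts
}
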