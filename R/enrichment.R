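#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene symbols (case-folded
#'   to upper case, deduplicated within a set).
#' @param name collection label.
#' @param backgroundSize background universe size N; the default 21000
#'   approximates a genome-wide functional-annotation database.
#' @return a validated [GeneSetCollection].
#' @examples
#' gsc <- GeneSetCollection(list(s1 = c("FEN1", "CCNE2")), backgroundSize = 100)
#' @export
GeneSetCollection <- function(sets, name = "collection",
                              backgroundSize = 21000) {
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  new("GeneSetCollection", name = name, backgroundSize = backgroundSize,
      sets = sets)
}

## half-up rounding to integer (R's round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Percentage composition, rounded half-up
#'
#' The style used for reported panel compositions: \code{100 * flagged /
#' total}, rounded half-up to an integer percent.
#'
#' @param flagged count of members carrying the annotation.
#' @param total total members; when 0 the composition is undefined and
#'   \code{NA} is returned.
#' @return integer percentage (or \code{NA}).
#' @examples
#' compositionPercent(39, 54)   # 72
#' compositionPercent(164, 424) # 39
#' @export
compositionPercent <- function(flagged, total) {
  if (length(total) != 1L || length(flagged) != 1L)
    stop("flagged and total must be scalars")
  if (total == 0) return(NA_real_)
  if (flagged < 0 || flagged > total)
    stop("need 0 <= flagged <= total")
  .roundHalfUp(100 * flagged / total)
}

#' Overlap report between two gene panels
#'
#' Intersects two panels after case-folding and, for each supplied
#' annotation flag, reports the percentage of the overlap carrying it
#' (rounded half-up, as panel compositions are conventionally quoted).
#' Empty panels give a defined empty report.
#'
#' @param panelA,panelB character vectors of gene symbols.
#' @param flags optional named list of character vectors: annotation name ->
#'   flagged gene symbols.
#' @return list of class \code{overlapReport}: \code{overlap} (sorted
#'   symbols), \code{nA}, \code{nB}, \code{nOverlap}, and per-flag
#'   \code{composition} percentages (\code{NA} when the overlap is empty).
#' @examples
#' overlapPanels(c("FEN1", "CCNE2", "PLK1"), c("CCNE2", "PLK1", "TYMS"),
#'               flags = list(cell_cycle = c("CCNE2", "PLK1")))
#' @export
overlapPanels <- function(panelA, panelB, flags = NULL) {
  a <- unique(toupper(as.character(panelA)))
  b <- unique(toupper(as.character(panelB)))
  ov <- sort(intersect(a, b))
  comp <- NULL
  if (!is.null(flags)) {
    comp <- vapply(flags, function(fl)
      compositionPercent(length(intersect(toupper(fl), ov)), length(ov)),
      numeric(1))
  }
  structure(list(overlap = ov, nA = length(a), nB = length(b),
                 nOverlap = length(ov), composition = comp),
            class = "overlapReport")
}

#' @export
print.overlapReport <- function(x, ...) {
  cat(sprintf("Panel overlap: %d genes (panel A: %d, panel B: %d)\n",
              x$nOverlap, x$nA, x$nB))
  if (!is.null(x$composition)) {
    for (nm in names(x$composition)) {
      pc <- x$composition[[nm]]
      cat(sprintf("  %s: %s\n", nm,
                  if (is.na(pc)) "not applicable (empty overlap)"
                  else sprintf("%d%%", as.integer(pc))))
    }
  }
  invisible(x)
}

#' One-sided over-representation test for a single gene set
#'
#' Hypergeometric upper tail: with a panel of \code{n} background genes and
#' a set of \code{K} background genes in a universe of \code{N}, the P value
#' is \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)} - the
#' Fisher exact test for enrichment. Panel or set genes outside the
#' conceptual background are the caller's responsibility; [enrichCollection()]
#' drops them with a warning.
#'
#' @param panel character vector of panel gene symbols (deduplicated,
#'   case-folded internally).
#' @param geneSet character vector of set members.
#' @param backgroundSize universe size N; must be at least
#'   \code{max(n, K)}.
#' @param alternative \code{"greater"} (over-representation, default) or
#'   \code{"two.sided"}.
#' @return list with \code{k}, \code{n}, \code{K}, \code{N},
#'   \code{expected = n*K/N}, \code{fold = (k/n)/(K/N)}, \code{p}.
#' @examples
#' fisherEnrichment(letters[1:20], letters[3:12], backgroundSize = 200)
#' @export
fisherEnrichment <- function(panel, geneSet, backgroundSize,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  panel <- unique(toupper(as.character(panel)))
  geneSet <- unique(toupper(as.character(geneSet)))
  n <- length(panel); K <- length(geneSet); N <- backgroundSize
  if (N < max(n, K))
    stop(sprintf("backgroundSize (%g) must be at least max(panel %d, set %d)",
                 N, n, K))
  k <- length(intersect(panel, geneSet))
  expected <- n * K / N
  ## fold = k/expected where defined; an empty overlap is zero enrichment
  fold <- if (expected > 0) k / expected else if (k == 0) 0 else NA_real_
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                       alternative = "two.sided")$p.value
  }
  list(k = k, n = n, K = K, N = N, expected = expected, fold = fold, p = p)
}

#' Over-representation across a gene-set collection
#'
#' Runs [fisherEnrichment()] per set against the collection's background
#' (or a caller-supplied universe, e.g. the tested genes of a design),
#' applies BH across the collection, and sorts by adjusted P then
#' decreasing fold enrichment.
#'
#' @param panel character vector of panel genes.
#' @param collection a [GeneSetCollection].
#' @param universe optional character vector of background genes (e.g. all
#'   tested genes); when supplied, it replaces the collection's
#'   \code{backgroundSize}, and panel/set genes outside it are dropped with
#'   a warning.
#' @param alternative passed to [fisherEnrichment()].
#' @return an [EnrichmentTable].
#' @examples
#' se <- simulateKnockdown(simParams(nGenes = 400, seed = 4))
#' gsc <- simulateGeneSets(truthTable(se), nSets = 5, seed = 4)
#' panel <- truthTable(se)$gene[truthTable(se)$class == "co_repressed"]
#' enrichCollection(panel, gsc)
#' @export
enrichCollection <- function(panel, collection, universe = NULL,
                             alternative = "greater") {
  stopifnot(is(collection, "GeneSetCollection"))
  if (length(geneSets(collection)) == 0L) stop("collection has no gene sets")
  panel <- unique(toupper(as.character(panel)))
  sets <- geneSets(collection)
  if (!is.null(universe)) {
    universe <- unique(toupper(as.character(universe)))
    outside <- setdiff(panel, universe)
    if (length(outside))
      warning(sprintf("%d panel gene(s) outside the universe dropped",
                      length(outside)))
    panel <- intersect(panel, universe)
    sets <- lapply(sets, intersect, universe)
    N <- length(universe)
  } else {
    N <- backgroundSize(collection)
  }
  res <- lapply(sets, function(s)
    fisherEnrichment(panel, s, N, alternative = alternative))
  tab <- S4Vectors::DataFrame(
    set = names(sets),
    k = vapply(res, `[[`, numeric(1), "k"),
    K = vapply(res, `[[`, numeric(1), "K"),
    expected = vapply(res, `[[`, numeric(1), "expected"),
    fold = vapply(res, `[[`, numeric(1), "fold"),
    p = vapply(res, `[[`, numeric(1), "p"),
    row.names = names(sets))
  tab$q <- bhAdjust(tab$p)
  ord <- order(tab$q, -tab$fold, tab$set, method = "radix")
  new("EnrichmentTable", tab[ord, , drop = FALSE],
      panelSize = length(panel), backgroundSize = as.numeric(N))
}
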