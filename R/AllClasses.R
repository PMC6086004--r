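#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Clone keys used throughout: two factors (A, B), two independent shRNA
## clones each. A1/B1 are the stringent clones (panel criteria i and ii),
## A2/B2 the confirmatory clones (criterion iii).
CLONE_KEYS <- c("A1", "A2", "B1", "B2")

## Gene classes planted by the simulator; "null" absorbs the remainder.
GENE_CLASSES <- c("co_repressed", "a_only", "b_only", "co_activated", "null")

#' Simulation parameters for the knockdown experiment generator
#'
#' Describes a five-condition shRNA knockdown design (one control, two
#' independent hairpin clones against each of two factors, replicated) and
#' the negative-binomial count model used to emulate it: per-gene log-normal
#' baseline means, a shared NB dispersion, per-class planted repression
#' strengths, and optional library-size distortions.
#'
#' @slot nGenes number of simulated genes (markers, if any, are extra rows).
#' @slot nReplicates replicates per condition; at least 2.
#' @slot classFractions named nonnegative fractions for the planted classes
#'   \code{co_repressed}, \code{a_only}, \code{b_only}, \code{co_activated};
#'   must sum to at most 1, the remainder is the null class.
#' @slot repressionStrength numeric matrix (class x clone) of true repression
#'   fractions \eqn{r = 1 - \mu_{kd}/\mu_{ctrl}}; values below 1, with
#'   activation encoded as negative repression on the \code{co_activated} row.
#' @slot dispersion NB dispersion (reciprocal of the size parameter); > 0.
#' @slot baselineMeanLog,baselineSdLog meanlog/sdlog of the log-normal
#'   baseline expression means.
#' @slot librarySizeFactors per-sample multipliers on expected counts;
#'   length 0 means all 1.
#' @slot seed integer seed; all draws flow from one generator seeded here.
#' @slot includeMarkerGenes add three marker genes carrying the
#'   cross-enhancement pattern (each factor's own transcript repressed by its
#'   clones and elevated by the other factor's clone 1, plus a neutral gene).
#' @slot markerElevation fold elevation of a factor's marker under the other
#'   factor's clone-1 knockdown (default 1.5).
#' @slot factorNames,controlName condition naming; conditions are
#'   \code{controlName} and \code{sh<factor>.<clone>}.
#'
#' @seealso [simParams()], [simulateKnockdown()]
#' @export
setClass("SimParams", representation(
  nGenes = "integer",
  nReplicates = "integer",
  classFractions = "numeric",
  repressionStrength = "matrix",
  dispersion = "numeric",
  baselineMeanLog = "numeric",
  baselineSdLog = "numeric",
  librarySizeFactors = "numeric",
  seed = "integer",
  includeMarkerGenes = "logical",
  markerElevation = "numeric",
  factorNames = "character",
  controlName = "character"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@nGenes) != 1L || is.na(object@nGenes) || object@nGenes < 1L)
    msg <- c(msg, "nGenes must be a positive integer")
  if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
      object@nReplicates < 2L)
    msg <- c(msg, "nReplicates must be >= 2 (group variances are undefined below that)")
  cf <- object@classFractions
  planted <- setdiff(GENE_CLASSES, "null")
  if (!all(planted %in% names(cf)))
    msg <- c(msg, sprintf("classFractions must name all of: %s",
                          paste(planted, collapse = ", ")))
  else {
    if (any(cf < 0)) msg <- c(msg, "class fractions must be nonnegative")
    if (sum(cf[planted]) > 1 + 1e-12)
      msg <- c(msg, "class fractions must sum to <= 1 (remainder is the null class)")
  }
  rs <- object@repressionStrength
  if (!identical(sort(rownames(rs)), sort(planted)) ||
      !identical(colnames(rs), CLONE_KEYS))
    msg <- c(msg, "repressionStrength must be a class x clone (A1,A2,B1,B2) matrix")
  else {
    if (any(rs >= 1)) msg <- c(msg, "repression strengths must be < 1")
    rep_rows <- setdiff(planted, "co_activated")
    if (any(rs[rep_rows, ] < 0))
      msg <- c(msg, "repressed-class strengths must lie in [0, 1)")
    if (any(rs["co_activated", ] > 0))
      msg <- c(msg, "co_activated strengths encode activation as negative repression (<= 0)")
  }
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0")
  if (any(object@librarySizeFactors <= 0))
    msg <- c(msg, "library size factors must be positive")
  if (length(object@factorNames) != 2L || anyDuplicated(object@factorNames))
    msg <- c(msg, "exactly two distinct factor names are required")
  if (length(msg)) msg else TRUE
})

#' Thresholds for panel calling
#'
#' Holds every tunable cut applied to a [RepressionProfile]: the stringent
#' clone-1 repression floor and adjusted-P ceiling, the confirmatory clone-2
#' floor, the exclusive-panel bounds, the co-activation floor, and the size
#' of the ranked top panel. Defaults reproduce the study's published cuts
#' (30\% repression, adjusted P <= 0.05, non-negative confirmatory
#' repression, <= 10\% repression by the other factor for exclusive panels,
#' >= 47\% co-activation, top 50).
#'
#' @slot r1Min minimum repression by both clone-1 hairpins (fraction).
#' @slot qMax maximum BH-adjusted P for both clone-1 contrasts.
#' @slot r2Min minimum repression by each clone-2 hairpin.
#' @slot exclMin minimum clone-averaged repression by the retained factor in
#'   exclusive panels.
#' @slot exclOtherMax maximum clone-averaged repression by the other factor.
#' @slot coactMin minimum clone-averaged activation by both factors.
#' @slot topK size of the ranked top panel.
#'
#' @seealso [panelThresholds()], [callPanels()]
#' @export
setClass("PanelThresholds", representation(
  r1Min = "numeric", qMax = "numeric", r2Min = "numeric",
  exclMin = "numeric", exclOtherMax = "numeric",
  coactMin = "numeric", topK = "integer"
))

setValidity("PanelThresholds", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@r1Min, object@qMax, object@r2Min,
                       object@exclMin, object@exclOtherMax, object@coactMin),
                  one, logical(1))))
    msg <- c(msg, "all thresholds must be finite scalars")
  else {
    if (object@qMax <= 0 || object@qMax > 1)
      msg <- c(msg, "qMax must lie in (0, 1]")
    if (object@exclOtherMax < 0 || object@exclOtherMax >= object@exclMin ||
        object@exclMin > 1)
      msg <- c(msg, "need 0 <= exclOtherMax < exclMin <= 1")
  }
  if (length(object@topK) != 1L || is.na(object@topK) || object@topK < 1L)
    msg <- c(msg, "topK must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Per-gene, per-clone repression profiles
#'
#' A \linkS4class{DFrame} with one row per gene and, for each clone
#' \code{c} in A1, A2, B1, B2, columns \code{fc_c} (fold change
#' knockdown/control on normalized means), \code{r_c = 1 - fc_c} (repression
#' efficiency; negative means enhancement), \code{p_c} (raw P) and
#' \code{q_c} (BH-adjusted P within the clone's contrast), plus a logical
#' \code{low_expression} flag for genes below the control expression floor
#' (flagged, never dropped). Provenance slots record how it was computed.
#'
#' @slot pseudocount pseudocount added to group means before the ratio.
#' @slot expressionFloor minimum mean normalized control count.
#' @slot test \code{"moderated"} or \code{"welch"}.
#' @slot sizeFactors per-sample median-of-ratios size factors used.
#' @slot cloneMap named character, clone key -> condition label.
#'
#' @seealso [repressionProfiles()]
#' @export
setClass("RepressionProfile", contains = "DFrame", representation(
  pseudocount = "numeric",
  expressionFloor = "numeric",
  test = "character",
  sizeFactors = "numeric",
  cloneMap = "character"
))

setValidity("RepressionProfile", function(object) {
  msg <- character()
  need <- c(paste0(rep(c("fc_", "r_", "p_", "q_"), each = 4), CLONE_KEYS),
            "low_expression")
  missing <- setdiff(need, colnames(object))
  if (length(missing))
    msg <- c(msg, sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  else {
    for (ck in CLONE_KEYS) {
      r <- object[[paste0("r_", ck)]]; fc <- object[[paste0("fc_", ck)]]
      p <- object[[paste0("p_", ck)]]; q <- object[[paste0("q_", ck)]]
      if (!isTRUE(all.equal(r, 1 - fc, tolerance = 1e-12)))
        msg <- c(msg, sprintf("r_%s must equal 1 - fc_%s", ck, ck))
      ok <- !(is.na(p) | is.na(q))
      if (any(q[ok] < p[ok] - 1e-12) || any(q[ok] > 1 + 1e-12) || any(p[ok] < -1e-12))
        msg <- c(msg, sprintf("p_%s/q_%s must satisfy 0 <= p <= q <= 1", ck, ck))
    }
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "rownames must carry gene identifiers")
  if (length(msg)) msg else TRUE
})

#' Called gene panels
#'
#' Result of applying [PanelThresholds] to a [RepressionProfile]: the
#' consensus (co-repressed) panel ordered by co-repression score, the two
#' factor-exclusive panels, and the co-activated panel, each with their
#' per-clone statistics, plus the thresholds used (provenance).
#'
#' @slot consensus,aOnly,bOnly,coactivated \linkS4class{DFrame}s with a
#'   \code{gene} column, a \code{score} column where ranked, and the
#'   per-clone \code{r_}/\code{q_} columns.
#' @slot thresholds the [PanelThresholds] applied.
#' @slot scoreConvention how the co-repression score reads "extent of
#'   overlap" (\code{"min_of_clone_averages"}).
#'
#' @seealso [callPanels()]
#' @export
setClass("GenePanels", representation(
  consensus = "DFrame", aOnly = "DFrame", bOnly = "DFrame",
  coactivated = "DFrame", thresholds = "PanelThresholds",
  scoreConvention = "character"
))

#' A named collection of gene sets over a background universe
#'
#' @slot name collection label (e.g. the GMT file stem).
#' @slot backgroundSize size N of the annotated background universe; the
#'   default universe of 21000 approximates a genome-wide functional
#'   annotation database.
#' @slot sets named list of character vectors of gene symbols; symbols are
#'   stored case-folded to upper case, without duplicates within a set.
#'
#' @seealso [readGmt()], [enrichCollection()]
#' @export
setClass("GeneSetCollection", representation(
  name = "character", backgroundSize = "numeric", sets = "list"
))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@backgroundSize) != 1L || object@backgroundSize < 1)
    msg <- c(msg, "backgroundSize must be a positive scalar")
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    msg <- c(msg, "every gene set must be named")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "gene sets must not contain duplicate genes")
  sizes <- lengths(object@sets)
  if (length(sizes) && object@backgroundSize < max(sizes))
    msg <- c(msg, "backgroundSize must be at least the size of every set")
  if (length(msg)) msg else TRUE
})

#' Over-representation results for a gene-set collection
#'
#' A \linkS4class{DFrame} with one row per gene set: overlap \code{k}, set
#' size \code{K}, expected overlap \code{n*K/N}, fold enrichment
#' \code{(k/n)/(K/N)}, one-sided hypergeometric \code{p} and BH-adjusted
#' \code{q}, sorted by \code{q} then decreasing fold.
#'
#' @slot panelSize n, the panel size within the background.
#' @slot backgroundSize N, the background universe size.
#'
#' @seealso [enrichCollection()]
#' @export
setClass("EnrichmentTable", contains = "DFrame", representation(
  panelSize = "numeric", backgroundSize = "numeric"
))
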