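## Knockdown-experiment simulator: negative-binomial counts over a
## five-condition design with planted truth labels, so every downstream
## stage (normalization, repression profiling, panel calls, enrichment) can
## be verified against known ground truth.

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so simulation never perturbs user code.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

.defaultStrength <- function() {
  rs <- matrix(0, nrow = 4, ncol = 4,
               dimnames = list(c("co_repressed", "a_only", "b_only", "co_activated"),
                               CLONE_KEYS))
  rs["co_repressed", ] <- 0.6
  rs["a_only", c("A1", "A2")] <- 0.6
  rs["b_only", c("B1", "B2")] <- 0.6
  rs["co_activated", ] <- -1.0          # 2-fold activation on knockdown
  rs
}

#' Construct simulation parameters
#'
#' Defaults emulate the study design this package is built around: 5,000
#' genes, triplicates of one control and four knockdown conditions (two
#' hairpin clones against each of two factors), 10\% of genes co-repressed
#' at 60\% efficiency by all four clones, small exclusive and co-activated
#' classes, a shared NB dispersion of 0.05, and log-normal baseline means
#' (meanlog = log(2000), sdlog = 1) so each sample carries a realistic
#' polyA-library depth (~15-20M counts over the simulated panel). Marker
#' genes reproduce the mutual cross-enhancement seen between the two target
#' transcripts (each factor's transcript is strongly repressed, 80\%, by its
#' own clones and elevated 1.5-fold by the other factor's clone 1) without
#' contaminating the class statistics.
#'
#' @param nGenes,nReplicates design size.
#' @param classFractions named fractions of planted classes; the remainder
#'   is null. Must name \code{co_repressed}, \code{a_only}, \code{b_only},
#'   \code{co_activated}.
#' @param repressionStrength class x clone matrix of true repression
#'   fractions; see \linkS4class{SimParams}.
#' @param dispersion NB dispersion (1/size).
#' @param baselineMeanLog,baselineSdLog log-normal baseline expression.
#' @param librarySizeFactors per-sample expected-count multipliers
#'   (default: all 1).
#' @param seed integer seed driving every draw.
#' @param includeMarkerGenes,markerElevation see \linkS4class{SimParams}.
#' @param factorNames,controlName condition naming.
#' @return a validated [SimParams].
#' @examples
#' sp <- simParams(nGenes = 200, seed = 1)
#' se <- simulateKnockdown(sp)
#' table(truthTable(se)$class)
#' @export
simParams <- function(nGenes = 5000,
                      nReplicates = 3,
                      classFractions = c(co_repressed = 0.10, a_only = 0.05,
                                         b_only = 0.05, co_activated = 0.05),
                      repressionStrength = .defaultStrength(),
                      dispersion = 0.05,
                      baselineMeanLog = log(2000),
                      baselineSdLog = 1,
                      librarySizeFactors = numeric(),
                      seed = 1L,
                      includeMarkerGenes = TRUE,
                      markerElevation = 1.5,
                      factorNames = c("MYC", "Tip60"),
                      controlName = "shGFP") {
  new("SimParams",
      nGenes = as.integer(nGenes), nReplicates = as.integer(nReplicates),
      classFractions = classFractions, repressionStrength = repressionStrength,
      dispersion = dispersion, baselineMeanLog = baselineMeanLog,
      baselineSdLog = baselineSdLog,
      librarySizeFactors = as.numeric(librarySizeFactors),
      seed = as.integer(seed), includeMarkerGenes = includeMarkerGenes,
      markerElevation = markerElevation, factorNames = factorNames,
      controlName = controlName)
}

#' Generate the knockdown sample design
#'
#' One control condition plus two hairpin clones per factor, each replicated.
#' The design is fully determined by its arguments (no randomness).
#'
#' @param nReplicates replicates per condition (>= 2).
#' @param factorNames two target factor names.
#' @param controlName control condition label.
#' @return a data.frame with columns \code{sample}, \code{condition},
#'   \code{factor} (\code{NA} for control), \code{clone_index},
#'   \code{is_control}; 5 x nReplicates rows.
#' @examples
#' simulateDesign(3)
#' @export
simulateDesign <- function(nReplicates = 3, factorNames = c("MYC", "Tip60"),
                           controlName = "shGFP") {
  nReplicates <- as.integer(nReplicates)
  if (is.na(nReplicates) || nReplicates < 2L)
    stop("nReplicates must be >= 2: group variances are undefined with fewer")
  if (length(factorNames) != 2L || anyDuplicated(factorNames))
    stop("exactly two distinct factor names are required")
  cond <- data.frame(
    condition = c(controlName,
                  paste0("sh", rep(factorNames, each = 2), ".", c(1L, 2L))),
    factor = c(NA_character_, rep(factorNames, each = 2)),
    clone_index = c(NA_integer_, rep(c(1L, 2L), 2)),
    is_control = c(TRUE, rep(FALSE, 4)),
    stringsAsFactors = FALSE)
  design <- cond[rep(seq_len(nrow(cond)), each = nReplicates), , drop = FALSE]
  design <- cbind(sample = paste0(design$condition, "_r",
                                  rep(seq_len(nReplicates), 5)),
                  design)
  rownames(design) <- design$sample
  design
}

## clone key (A1..B2) for each design row; NA for control samples
.cloneKeyOf <- function(design, factorNames) {
  key <- rep(NA_character_, nrow(design))
  ab <- c("A", "B")[match(design$factor, factorNames)]
  has <- !is.na(ab)
  key[has] <- paste0(ab[has], design$clone_index[has])
  key
}

## largest-remainder apportionment of planted class sizes; deterministic,
## sums to round(sum(fractions) * n)
.classCounts <- function(fractions, n) {
  target <- fractions * n
  base <- floor(target)
  extra <- round(sum(target)) - sum(base)
  if (extra > 0) {
    ord <- order(target - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Simulate a knockdown RNA-seq experiment with planted truth
#'
#' Draws a gene x sample count matrix from a negative-binomial model with
#' per-gene log-normal baseline means: the expected count of gene g in
#' sample s is \code{baseline[g] * (1 - r[g, clone(s)]) * libFactor[s]},
#' where \code{r} is the planted per-clone repression (0 for the control and
#' the null class, negative for activation). All draws flow from the single
#' seed in \code{params}; identical parameters give bitwise-identical output.
#'
#' @param params a [SimParams].
#' @return a \linkS4class{SummarizedExperiment} with a \code{counts} assay,
#'   the design as \code{colData}, and the truth table (class label, true
#'   per-clone repression, marker flags) as \code{rowData}. The params are
#'   stored in \code{metadata()}.
#' @examples
#' se <- simulateKnockdown(simParams(nGenes = 100, seed = 7))
#' dim(se)
#' @export
simulateKnockdown <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  design <- simulateDesign(params@nReplicates, params@factorNames,
                           params@controlName)
  nS <- nrow(design)
  lib <- params@librarySizeFactors
  if (length(lib) == 0L) lib <- rep(1, nS)
  if (length(lib) != nS)
    stop(sprintf("librarySizeFactors must have length %d (one per sample)", nS))

  planted <- c("co_repressed", "a_only", "b_only", "co_activated")
  kk <- .classCounts(params@classFractions[planted], params@nGenes)
  classes <- c(rep(planted, kk), rep("null", params@nGenes - sum(kk)))

  n <- params@nGenes
  ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  rTrue <- matrix(0, nrow = n, ncol = 4, dimnames = list(ids, CLONE_KEYS))
  for (cl in planted)
    rTrue[classes == cl, ] <- rep(params@repressionStrength[cl, ],
                                  each = sum(classes == cl))
  isMarker <- rep(FALSE, n)
  crossEnhanced <- rep(FALSE, n)

  if (params@includeMarkerGenes) {
    ## the factors' own transcripts: repressed 80% by their own clones,
    ## elevated by the other factor's clone 1 (mutual cross-enhancement)
    elev <- 1 - params@markerElevation      # negative repression
    mA <- c(A1 = 0.8, A2 = 0.8, B1 = elev, B2 = 0)
    mB <- c(A1 = elev, A2 = 0, B1 = 0.8, B2 = 0.8)
    mN <- c(A1 = 0, A2 = 0, B1 = 0, B2 = 0)
    mids <- c(toupper(params@factorNames), "NEUTRAL")
    rTrue <- rbind(rTrue, rbind(mA, mB, mN))
    rownames(rTrue) <- c(ids, mids)
    ids <- rownames(rTrue)
    classes <- c(classes, rep("marker", 3))
    isMarker <- c(isMarker, rep(TRUE, 3))
    crossEnhanced <- c(crossEnhanced, TRUE, TRUE, FALSE)
  }

  nG <- length(ids)
  cloneKey <- .cloneKeyOf(design, params@factorNames)
  counts <- .withSeed(params@seed, {
    baseline <- exp(stats::rnorm(nG, params@baselineMeanLog,
                                 params@baselineSdLog))
    mu <- matrix(0, nG, nS)
    for (j in seq_len(nS)) {
      r <- if (is.na(cloneKey[j])) 0 else rTrue[, cloneKey[j]]
      mu[, j] <- baseline * (1 - r) * lib[j]
    }
    draws <- stats::rnbinom(nG * nS, mu = as.vector(mu),
                            size = 1 / params@dispersion)
    matrix(as.integer(draws), nrow = nG, ncol = nS,
           dimnames = list(ids, design$sample))
  })

  truth <- S4Vectors::DataFrame(
    gene = ids, class = classes,
    true_r_A1 = rTrue[, "A1"], true_r_A2 = rTrue[, "A2"],
    true_r_B1 = rTrue[, "B1"], true_r_B2 = rTrue[, "B2"],
    is_marker = isMarker, cross_enhanced = crossEnhanced,
    row.names = ids)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = truth,
    colData = S4Vectors::DataFrame(design, row.names = design$sample))
  S4Vectors::metadata(se)$simParams <- params
  se
}

#' Truth table of a simulated experiment
#'
#' @param se a \linkS4class{SummarizedExperiment} from [simulateKnockdown()].
#' @return the \code{rowData} truth table (gene, class, true per-clone
#'   repression, marker flags).
#' @export
truthTable <- function(se) {
  SummarizedExperiment::rowData(se)
}

#' Simulate gene-set collections with one planted enriched set
#'
#' Builds a GMT-representable collection over the simulated genes: a
#' designated \code{cycle_like} set drawing a fraction
#' \code{plantedEnrichment} of its members from the co-repressed class (the
#' rest from the null class), plus \code{nSets} sets sampled uniformly from
#' all genes. The background universe is the simulated gene count.
#'
#' @param truth a truth table from [truthTable()].
#' @param nSets number of uniform (non-planted) sets.
#' @param plantedEnrichment fraction of the designated set drawn from the
#'   co-repressed class, in [0, 1].
#' @param setSize members per set.
#' @param seed integer seed.
#' @return a [GeneSetCollection].
#' @export
simulateGeneSets <- function(truth, nSets = 20, plantedEnrichment = 1.0,
                             setSize = 50, seed = 1L) {
  if (nrow(truth) == 0L) stop("truth table is empty")
  if (plantedEnrichment < 0 || plantedEnrichment > 1)
    stop("plantedEnrichment must lie in [0, 1]")
  genes <- as.character(truth$gene)
  co <- genes[truth$class == "co_repressed"]
  nul <- genes[truth$class == "null"]
  .withSeed(seed, {
    ## intended split first, then cap each side by its pool (the designated
    ## set shrinks rather than dilute its planted fraction)
    nCo <- min(round(plantedEnrichment * setSize), length(co))
    nNull <- min(setSize - round(plantedEnrichment * setSize), length(nul))
    planted <- c(sample(co, nCo), sample(nul, nNull))
    sets <- c(list(cycle_like = sort(planted)),
              stats::setNames(
                lapply(seq_len(nSets),
                       function(i) sort(sample(genes, min(setSize, length(genes))))),
                sprintf("random_set_%03d", seq_len(nSets))))
    new("GeneSetCollection", name = "simulated", backgroundSize = length(genes),
        sets = lapply(sets, toupper))
  })
}
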