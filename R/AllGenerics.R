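#' @rdname GenePanels-class
#' @param x a \linkS4class{GenePanels} object.
#' @export
setGeneric("consensusPanel", function(x) standardGeneric("consensusPanel"))

#' @rdname GenePanels-class
#' @export
setGeneric("aOnlyPanel", function(x) standardGeneric("aOnlyPanel"))

#' @rdname GenePanels-class
#' @export
setGeneric("bOnlyPanel", function(x) standardGeneric("bOnlyPanel"))

#' @rdname GenePanels-class
#' @export
setGeneric("coactivatedPanel", function(x) standardGeneric("coactivatedPanel"))

#' @rdname GenePanels-class
#' @export
setGeneric("panelThresholdsUsed", function(x) standardGeneric("panelThresholdsUsed"))

#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("backgroundSize", function(x) standardGeneric("backgroundSize"))

setMethod("consensusPanel", "GenePanels", function(x) x@consensus)
setMethod("aOnlyPanel", "GenePanels", function(x) x@aOnly)
setMethod("bOnlyPanel", "GenePanels", function(x) x@bOnly)
setMethod("coactivatedPanel", "GenePanels", function(x) x@coactivated)
setMethod("panelThresholdsUsed", "GenePanels", function(x) x@thresholds)
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
setMethod("backgroundSize", "GeneSetCollection", function(x) x@backgroundSize)

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nGenes, "genes x",
      5L * object@nReplicates, "samples (5 conditions x",
      object@nReplicates, "replicates)\n")
  cf <- object@classFractions
  cat("  planted fractions:",
      paste(sprintf("%s=%.3g", names(cf), cf), collapse = ", "),
      sprintf("(null=%.3g)\n", 1 - sum(cf)))
  cat(sprintf("  NB dispersion %.3g; baseline lognormal(meanlog=%.3g, sdlog=%.3g); seed %d\n",
              object@dispersion, object@baselineMeanLog, object@baselineSdLog,
              object@seed))
  if (object@includeMarkerGenes)
    cat(sprintf("  marker genes included (cross-enhancement x%.2g)\n",
                object@markerElevation))
})

setMethod("show", "PanelThresholds", function(object) {
  cat("PanelThresholds:\n")
  cat(sprintf("  consensus: r(clone 1) >= %.3g, q(clone 1) <= %.3g, r(clone 2) >= %.3g\n",
              object@r1Min, object@qMax, object@r2Min))
  cat(sprintf("  exclusive: own r-bar >= %.3g, other r-bar <= %.3g\n",
              object@exclMin, object@exclOtherMax))
  cat(sprintf("  co-activated: activation >= %.3g; top panel size %d\n",
              object@coactMin, object@topK))
})

setMethod("show", "RepressionProfile", function(object) {
  cat(sprintf("RepressionProfile: %d genes x 4 clone contrasts (%s test)\n",
              nrow(object), object@test))
  cat(sprintf("  pseudocount %.3g, expression floor %.3g (%d genes flagged low)\n",
              object@pseudocount, object@expressionFloor,
              sum(object$low_expression)))
  cat("  clones:", paste(sprintf("%s=%s", names(object@cloneMap),
                                 object@cloneMap), collapse = ", "), "\n")
  callNextMethod()
})

setMethod("show", "GenePanels", function(object) {
  cat("GenePanels (score convention:", object@scoreConvention, ")\n")
  cat(sprintf("  consensus %d | factor-A only %d | factor-B only %d | co-activated %d\n",
              nrow(object@consensus), nrow(object@aOnly),
              nrow(object@bOnly), nrow(object@coactivated)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection '%s': %d sets over a background of %d genes\n",
              object@name, length(object@sets), object@backgroundSize))
  sz <- lengths(object@sets)
  if (length(sz))
    cat(sprintf("  set sizes: %d-%d (median %.0f)\n",
                min(sz), max(sz), stats::median(sz)))
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable: %d sets, panel n=%d of N=%d background\n",
              nrow(object), as.integer(object@panelSize),
              as.integer(object@backgroundSize)))
  callNextMethod()
})
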