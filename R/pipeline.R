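## End-to-end orchestration: YAML config -> simulate or read counts ->
## normalize -> repression profiles -> panel calls -> optional prior-panel
## overlap and gene-set enrichment -> TSV outputs + JSON run report.
## Stage-level logging reports gene counts through every filter, which is
## the pipeline's story: its filter attrition.

.defaultConfig <- function() {
  list(
    seed = 1L,
    output_dir = "corepress_run",
    counts = NULL, design = NULL,
    simulate = list(),
    gmt = list(),
    prior_panel = NULL,
    diffexpr = list(pseudocount = 0.5, expression_floor = 5,
                    test = "moderated"),
    thresholds = list(r1_min = 0.30, q_max = 0.05, r2_min = 0.0,
                      excl_min = 0.30, excl_other_max = 0.10,
                      coact_min = 0.47, top_k = 50),
    enrichment = list(background = 21000, use_tested_universe = TRUE)
  )
}

## shallow-merge user config over defaults, one nesting level deep
.mergeConfig <- function(user, defaults = .defaultConfig()) {
  out <- defaults
  for (nm in names(user)) {
    if (nm %in% c("diffexpr", "thresholds", "enrichment") && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) out[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Read and resolve a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, applies dotted-path
#' overrides (e.g. \code{"thresholds.r1_min" = 0.4}), and validates
#' thresholds and referenced paths.
#'
#' @param config path to a YAML file, or a named list.
#' @param overrides named list of dotted-path overrides.
#' @return resolved configuration list.
#' @export
pipelineConfig <- function(config = list(), overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(config)
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) cfg[[parts]] <- overrides[[key]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
  }
  for (p in c(cfg$counts, cfg$design, cfg$prior_panel, unlist(cfg$gmt)))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("configured path does not exist: %s", p))
  th <- cfg$thresholds
  validObject(panelThresholds(th$r1_min, th$q_max, th$r2_min, th$excl_min,
                              th$excl_other_max, th$coact_min, th$top_k))
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full panel-calling pipeline
#'
#' Executes simulate/read -> normalize -> repression profiles -> consensus,
#' top, exclusive and co-activated panel calls -> prior-panel overlap (if a
#' prior panel is configured) -> gene-set enrichment (per configured GMT),
#' writing every intermediate as TSV into \code{output_dir} together with a
#' JSON run report and the resolved configuration. Deterministic given the
#' configuration: the only randomness is the simulator's seeded generator.
#'
#' @param config path to a YAML configuration, or a list (see
#'   [pipelineConfig()]).
#' @param overrides named list of dotted-path overrides.
#' @param quiet suppress stage messages.
#' @return invisibly, the run report (also written as
#'   \code{run_report.json}).
#' @examples
#' dir <- tempfile()
#' rep <- runPipeline(list(simulate = list(n_genes = 300), seed = 5,
#'                         output_dir = dir), quiet = TRUE)
#' rep$panel_counts
#' @export
runPipeline <- function(config = list(), overrides = list(), quiet = FALSE) {
  cfg <- pipelineConfig(config, overrides)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "corepress",
                 version = as.character(utils::packageVersion("corepress")),
                 seed = cfg$seed, thresholds = cfg$thresholds)

  if (is.null(cfg$counts)) {
    se <- .stage("simulate", {
      sim <- cfg$simulate
      params <- simParams(
        nGenes = if (is.null(sim$n_genes)) 5000 else sim$n_genes,
        nReplicates = if (is.null(sim$n_replicates)) 3 else sim$n_replicates,
        classFractions = if (is.null(sim$class_fractions))
          c(co_repressed = 0.10, a_only = 0.05, b_only = 0.05,
            co_activated = 0.05)
          else unlist(sim$class_fractions),
        dispersion = if (is.null(sim$dispersion)) 0.05 else sim$dispersion,
        seed = cfg$seed)
      simulateKnockdown(params)
    })
    counts <- SummarizedExperiment::assay(se, "counts")
    design <- as.data.frame(SummarizedExperiment::colData(se))
    writeCountsTsv(counts, file.path(cfg$output_dir, "counts.tsv"))
    writeDesignTsv(design, file.path(cfg$output_dir, "design.tsv"))
    .writeTsv(as.data.frame(truthTable(se)),
              file.path(cfg$output_dir, "truth.tsv"))
    report$input <- list(source = "simulated", n_genes = nrow(counts),
                         n_samples = ncol(counts))
    say("simulate: %d genes x %d samples", nrow(counts), ncol(counts))
  } else {
    counts <- .stage("read_counts", readCountsTsv(cfg$counts))
    if (is.null(cfg$design)) stop("a design table is required with counts")
    design <- .stage("read_design", readDesignTsv(cfg$design))
    report$input <- list(source = cfg$counts, n_genes = nrow(counts),
                         n_samples = ncol(counts))
    say("read: %d genes x %d samples", nrow(counts), ncol(counts))
  }

  profiles <- .stage("repression_profiles",
    repressionProfiles(counts, design,
                       pseudocount = cfg$diffexpr$pseudocount,
                       expressionFloor = cfg$diffexpr$expression_floor,
                       test = cfg$diffexpr$test))
  writeProfileTsv(profiles, file.path(cfg$output_dir, "repression_profiles.tsv"))
  nLow <- sum(profiles$low_expression)
  say("profiles: %d genes tested, %d flagged low-expression (floor %.3g)",
      nrow(profiles), nLow, cfg$diffexpr$expression_floor)

  th <- cfg$thresholds
  thresholds <- panelThresholds(th$r1_min, th$q_max, th$r2_min, th$excl_min,
                                th$excl_other_max, th$coact_min, th$top_k)
  panels <- .stage("call_panels", callPanels(profiles, thresholds))
  exportPanels(panels, cfg$output_dir)
  report$panel_counts <- list(
    genes_tested = nrow(profiles), low_expression = nLow,
    consensus = nrow(consensusPanel(panels)),
    top = min(th$top_k, nrow(consensusPanel(panels))),
    a_only = nrow(aOnlyPanel(panels)), b_only = nrow(bOnlyPanel(panels)),
    coactivated = nrow(coactivatedPanel(panels)))
  say("panels: consensus %d | A-only %d | B-only %d | co-activated %d",
      report$panel_counts$consensus, report$panel_counts$a_only,
      report$panel_counts$b_only, report$panel_counts$coactivated)

  if (!is.null(cfg$prior_panel)) {
    prior <- .stage("read_prior_panel", readGeneList(cfg$prior_panel))
    ov <- .stage("overlap_prior",
                 overlapPanels(consensusPanel(panels)$gene, prior))
    writeLines(ov$overlap, file.path(cfg$output_dir, "overlap_prior_genes.txt"))
    report$prior_overlap <- list(n_consensus = ov$nA, n_prior = ov$nB,
                                 n_overlap = ov$nOverlap)
    say("prior overlap: %d of %d consensus genes shared with prior panel (%d genes)",
        ov$nOverlap, ov$nA, ov$nB)
  }

  if (length(cfg$gmt)) {
    report$enrichment <- list()
    for (gmtPath in unlist(cfg$gmt)) {
      gsc <- .stage("read_gmt",
                    readGmt(gmtPath, backgroundSize = cfg$enrichment$background))
      universe <- if (isTRUE(cfg$enrichment$use_tested_universe))
        rownames(profiles) else NULL
      et <- .stage("enrich",
                   enrichCollection(consensusPanel(panels)$gene, gsc,
                                    universe = universe))
      out <- file.path(cfg$output_dir,
                       sprintf("enrichment_%s.tsv", gsc@name))
      .writeTsv(as.data.frame(et), out)
      report$enrichment[[gsc@name]] <-
        list(n_sets = nrow(et), top_set = if (nrow(et)) et$set[1] else NA,
             background = et@backgroundSize)
      say("enrichment[%s]: %d sets against N=%d; top set: %s",
          gsc@name, nrow(et), as.integer(et@backgroundSize),
          if (nrow(et)) et$set[1] else "-")
    }
  } else {
    report$enrichment <- "skipped (no GMT configured)"
    say("enrichment: skipped (no GMT configured)")
  }

  yaml::write_yaml(cfg, file.path(cfg$output_dir, "resolved_config.yaml"))
  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
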