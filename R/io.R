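## Plain-text formats: counts and design TSVs, GMT gene-set files, one-per-
## line gene lists, repression-profile TSVs. Every writer's output is
## accepted by its reader (round-trip identity).

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene x sample count matrix as TSV
#'
#' First column \code{gene} carries gene identifiers; remaining columns are
#' samples. Cells must be nonnegative integers; a violation is reported
#' with its row and column.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || colnames(df)[1] != "gene")
    stop("counts TSV must start with a 'gene' column followed by sample columns")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 genes[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' @rdname readCountsTsv
#' @param counts gene x sample matrix (rownames = gene ids).
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  .writeTsv(df, path)
}

#' Read / write a sample design table as TSV
#'
#' Columns: \code{sample}, \code{condition}, \code{factor} (empty for the
#' control), \code{clone_index}, \code{is_control}.
#'
#' @param path file path.
#' @return data.frame with the design columns, sample names as rownames.
#' @export
readDesignTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample", "condition", "factor", "clone_index", "is_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("design TSV lacks column(s): %s", paste(miss, collapse = ", ")))
  df$is_control <- as.logical(df$is_control)
  df$clone_index <- as.integer(df$clone_index)
  rownames(df) <- df$sample
  df
}

#' @rdname readDesignTsv
#' @param design design data.frame (as from [simulateDesign()]).
#' @export
writeDesignTsv <- function(design, path) {
  .writeTsv(design, path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Lines with fewer than three fields are rejected with their line number.
#'
#' @param path file path.
#' @param backgroundSize background universe N attached to the collection.
#' @param name collection label (default: the file stem).
#' @return a [GeneSetCollection]; set descriptions are kept as a
#'   \code{description} attribute on each member vector.
#' @export
readGmt <- function(path, backgroundSize = 21000, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i))
    members <- unique(toupper(fields[-(1:2)]))
    attr(members, "description") <- fields[2]
    sets[[fields[1]]] <- members
  }
  new("GeneSetCollection", name = name, backgroundSize = backgroundSize,
      sets = sets)
}

#' @rdname readGmt
#' @param collection a [GeneSetCollection].
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(names(geneSets(collection)), function(nm) {
    members <- geneSets(collection)[[nm]]
    desc <- attr(members, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with \code{#} are skipped; symbols are
#' case-folded to upper case and deduplicated.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' Read / write repression-profile tables as TSV
#'
#' Columns: \code{gene}, then \code{fc_}, \code{r_}, \code{p_}, \code{q_}
#' for each clone A1, A2, B1, B2, and \code{low_expression}.
#'
#' @param path file path.
#' @return a [RepressionProfile] (provenance marked external).
#' @export
readProfileTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  RepressionProfile(df)
}

#' @rdname readProfileTsv
#' @param profiles a [RepressionProfile].
#' @export
writeProfileTsv <- function(profiles, path) {
  df <- as.data.frame(profiles)
  df <- cbind(gene = rownames(df), df)
  .writeTsv(df, path)
}

#' Write called panels as TSVs plus a JSON provenance block
#'
#' One TSV per panel (\code{panel_consensus.tsv}, \code{panel_top.tsv},
#' \code{panel_a_only.tsv}, \code{panel_b_only.tsv},
#' \code{panel_coactivated.tsv}) and \code{panel_thresholds.json} recording
#' the thresholds and score convention.
#'
#' @param panels a [GenePanels].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportPanels <- function(panels, dir) {
  stopifnot(is(panels, "GenePanels"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- list(consensus = consensusPanel(panels),
                 top = suppressWarnings(topPanel(panels)),
                 a_only = aOnlyPanel(panels),
                 b_only = bOnlyPanel(panels),
                 coactivated = coactivatedPanel(panels))
  paths <- character()
  for (nm in names(frames)) {
    p <- file.path(dir, sprintf("panel_%s.tsv", nm))
    .writeTsv(as.data.frame(frames[[nm]]), p)
    paths <- c(paths, p)
  }
  th <- panels@thresholds
  prov <- list(thresholds = list(r1_min = th@r1Min, q_max = th@qMax,
                                 r2_min = th@r2Min, excl_min = th@exclMin,
                                 excl_other_max = th@exclOtherMax,
                                 coact_min = th@coactMin, top_k = th@topK),
               score_convention = panels@scoreConvention)
  jp <- file.path(dir, "panel_thresholds.json")
  jsonlite::write_json(prov, jp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, jp))
}
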