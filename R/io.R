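## Readers and writers for the tabular formats the pipeline touches.
## Identifiers are opaque, case-sensitive strings; TSV with a header row is
## the only dialect. No symbol/alias resolution is attempted.

readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' Read and clean an undirected edge table
#'
#' Reads a TSV edge list, trims whitespace from identifiers, drops rows
#' with empty ids, removes self-loops, and collapses duplicate unordered
#' pairs (keeping the first occurrence's orientation). Counts of removed
#' rows are reported with \code{message()}.
#'
#' @param path TSV file with a header row
#' @param source_col,target_col names of the two id columns
#' @return data.frame with columns \code{from}, \code{to} (the cleaned
#'   edge table)
#' @export
readEdgeTable <- function(path, source_col, target_col) {
  df <- readTSV(path)
  requireColumns(df, c(source_col, target_col), path)
  cleanEdgeTable(data.frame(from = df[[source_col]], to = df[[target_col]],
                            stringsAsFactors = FALSE))
}

#' Clean an edge table in memory
#'
#' Idempotent: trimming, self-loop removal and unordered-pair
#' de-duplication leave an already clean table unchanged.
#'
#' @param edges data.frame with columns \code{from}, \code{to}
#' @return cleaned data.frame with columns \code{from}, \code{to}
#' @export
cleanEdgeTable <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  n0 <- nrow(edges)
  from <- trimws2(as.character(edges$from))
  to <- trimws2(as.character(edges$to))
  keep <- nzchar(from) & nzchar(to)
  n_empty <- sum(!keep)
  from <- from[keep]; to <- to[keep]
  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]; to <- to[!loops]
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  out <- data.frame(from = from[!dup], to = to[!dup],
                    stringsAsFactors = FALSE)
  if (n_empty + n_loops + n_dup > 0)
    message("cleanEdgeTable: removed ", n_empty, " empty-id, ", n_loops,
            " self-loop, ", n_dup, " duplicate row(s) of ", n0)
  if (nrow(out) == 0) stop("empty table after cleaning", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a disease-gene association table
#'
#' Reads a TSV with disease, gene and (optionally) source columns and
#' returns the per-disease seed gene sets, optionally keeping only
#' associations from selected sources (e.g. OMIM and GWAS). Diseases whose
#' gene set becomes empty after filtering are dropped with a warning.
#'
#' @param path TSV file
#' @param source_filter character vector of sources to retain, or NULL to
#'   keep every row (the source column is then not required)
#' @param disease_col,gene_col,source_col column names
#' @return named list mapping each disease id to a character vector of
#'   unique gene ids
#' @export
readDiseaseGeneTable <- function(path, source_filter = NULL,
                                 disease_col = "disease", gene_col = "gene",
                                 source_col = "source") {
  df <- readTSV(path)
  requireColumns(df, c(disease_col, gene_col), path)
  disease <- trimws2(df[[disease_col]])
  gene <- trimws2(df[[gene_col]])
  keep <- nzchar(disease) & nzchar(gene)
  all_diseases <- unique(disease[keep])
  if (!is.null(source_filter)) {
    requireColumns(df, source_col, path)
    keep <- keep & trimws2(df[[source_col]]) %in% source_filter
  }
  if (!any(keep)) stop("no associations left after source filtering",
                       call. = FALSE)
  dg <- lapply(split(gene[keep], disease[keep]), unique)
  dropped <- setdiff(all_diseases, names(dg))
  if (length(dropped))
    warning(length(dropped),
            " disease(s) dropped: no associations from the selected sources",
            call. = FALSE)
  dg
}

#' Write / read a bipartite miRNA-disease network
#'
#' TSV with columns \code{disease}, \code{mirna}, \code{weight}; weights
#' are written with 17 significant digits so the round trip is exact.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param path output / input file
#' @return \code{writeMDN} returns \code{path} invisibly; \code{readMDN}
#'   returns a \code{BipartiteMDN} whose node universes are the observed
#'   disease and miRNA ids.
#' @export
writeMDN <- function(mdn, path) {
  stopifnot(is(mdn, "BipartiteMDN"))
  e <- mdn@edges
  if (nrow(e) == 0) stop("refusing to write an empty MDN", call. = FALSE)
  out <- data.frame(disease = e$disease, mirna = e$mirna,
                    weight = sprintf("%.17g", e$weight))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeMDN
#' @export
readMDN <- function(path) {
  df <- readTSV(path)
  requireColumns(df, c("disease", "mirna", "weight"), path)
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop("malformed weight '", df$weight[bad], "' on data line ", bad,
         " of ", path, call. = FALSE)
  }
  edges <- data.frame(disease = df$disease, mirna = df$mirna, weight = w,
                      stringsAsFactors = FALSE)
  new("BipartiteMDN", edges = edges,
      diseases = sort(unique(edges$disease)),
      mirnas = sort(unique(edges$mirna)),
      skipped = character())
}

#' Read experimental ground-truth miRNA-disease associations
#'
#' dbDEMC-style TSV with columns \code{disease}, \code{mirna} and an
#' optional \code{fold_change} column holding the differential expression
#' of the miRNA between diseased and healthy cohorts.
#'
#' @param path TSV file
#' @return list with \code{positives} (named list: disease -> miRNA ids)
#'   and \code{fold_change} (data.frame with disease, mirna, fold_change;
#'   NULL when the column is absent)
#' @export
readGroundTruth <- function(path) {
  df <- readTSV(path)
  requireColumns(df, c("disease", "mirna"), path)
  disease <- trimws2(df$disease); mirna <- trimws2(df$mirna)
  keep <- nzchar(disease) & nzchar(mirna)
  positives <- lapply(split(mirna[keep], disease[keep]), unique)
  fc <- NULL
  if ("fold_change" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$fold_change))
    if (anyNA(v[keep]))
      stop("malformed fold_change value in ", path, call. = FALSE)
    fc <- data.frame(disease = disease[keep], mirna = mirna[keep],
                     fold_change = v[keep], stringsAsFactors = FALSE)
  }
  list(positives = positives, fold_change = fc)
}

#' Read a disease-class (ICD-9 style) mapping table
#'
#' @param path TSV with columns \code{disease}, \code{icd9_class} and
#'   optionally \code{icd9_subtype} (the next level of the hierarchy)
#' @return data.frame with one row per disease
#' @export
readClassMap <- function(path) {
  df <- readTSV(path)
  requireColumns(df, c("disease", "icd9_class"), path)
  df <- df[nzchar(trimws2(df$disease)) & nzchar(trimws2(df$icd9_class)), ,
           drop = FALSE]
  if (anyDuplicated(df$disease))
    stop("duplicate disease ids in class map ", path, call. = FALSE)
  if (nrow(df) == 0) stop("empty class map", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Export a disease projection
#'
#' @param proj a \code{DiseaseProjection}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeProjectionGraphML <- function(proj, path) {
  g <- asIgraph(proj)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeProjectionGraphML
#' @export
writeProjectionTSV <- function(proj, path) {
  utils::write.table(proj@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
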