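## Thresholding of the bipartite MDN and construction of weighted
## disease-disease projections (miRNA space or gene space). All threshold
## comparisons are strict (>), matching the convention "edges with a
## weight greater than the threshold are retained".

#' Threshold a bipartite miRNA-disease network
#'
#' Keeps edges with weight strictly greater than \code{min_weight}. The
#' disease and miRNA universes are left untouched so graph density remains
#' comparable before and after filtering.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param min_weight non-negative weight cutoff (strict)
#' @return filtered \code{BipartiteMDN}
#' @export
thresholdBipartite <- function(mdn, min_weight) {
  stopifnot(min_weight >= 0)
  keep <- mdn@edges$weight > min_weight
  if (!any(keep)) stop("empty network: no edge exceeds ", min_weight,
                       call. = FALSE)
  e <- mdn@edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  message("thresholdBipartite: kept ", nrow(e), " of ", nrow(mdn@edges),
          " edges (> ", min_weight, ")")
  new("BipartiteMDN", edges = e, diseases = mdn@diseases,
      mirnas = mdn@mirnas, skipped = mdn@skipped)
}

#' @describeIn graphDensity bipartite density |E| / (|diseases| x |miRNAs|)
#' @export
setMethod("graphDensity", "BipartiteMDN", function(x) {
  nd <- length(x@diseases); nm <- length(x@mirnas)
  if (nd < 1 || nm < 1) stop("degenerate node universe", call. = FALSE)
  nrow(x@edges) / (nd * nm)
})

#' @describeIn graphDensity unipartite density 2|E| / (n(n-1)), isolated
#'   nodes included in n
#' @export
setMethod("graphDensity", "DiseaseProjection", function(x) {
  n <- length(x@nodes)
  if (n < 2) stop("graph density needs at least 2 nodes", call. = FALSE)
  2 * nrow(x@edges) / (n * (n - 1))
})

densityAtThreshold <- function(x, thr) {
  k <- sum(edgeWeights(x) > thr)
  if (is(x, "BipartiteMDN"))
    k / (length(x@diseases) * length(x@mirnas))
  else
    2 * k / (length(x@nodes) * (length(x@nodes) - 1))
}

edgeWeights <- function(x) {
  if (is(x, "BipartiteMDN")) x@edges$weight else x@edges$weight
}

matchDensityImpl <- function(x, target_density) {
  stopifnot(target_density > 0, target_density < 1)
  cur <- graphDensity(x)
  if (cur <= target_density)
    return(list(threshold = 0, density = cur))
  for (thr in sort(unique(edgeWeights(x)))) {
    k <- sum(edgeWeights(x) > thr)
    if (k == 0) break  # a threshold that empties the graph is not usable
    dens <- densityAtThreshold(x, thr)
    if (dens <= target_density)
      return(list(threshold = thr, density = dens))
  }
  stop("target density ", target_density,
       " unreachable without emptying the graph", call. = FALSE)
}

#' @describeIn matchDensityThreshold for bipartite networks
#' @export
setMethod("matchDensityThreshold", "BipartiteMDN", matchDensityImpl)

#' @describeIn matchDensityThreshold for disease projections
#' @export
setMethod("matchDensityThreshold", "DiseaseProjection", matchDensityImpl)

projectIncidence <- function(B, nodes) {
  S <- Matrix::tcrossprod(B)          # shared-partner counts
  tri <- Matrix::summary(S)
  tri <- tri[tri$i < tri$j & tri$x > 0, , drop = FALSE]
  from <- nodes[tri$i]; to <- nodes[tri$j]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  e <- data.frame(from = from, to = to, weight = as.numeric(tri$x),
                  stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new("DiseaseProjection", nodes = nodes, edges = e)
}

#' @describeIn projectDiseases miRNA-space projection (DPM) of a
#'   (typically thresholded) predicted MDN
#' @export
setMethod("projectDiseases", "BipartiteMDN", function(x) {
  if (nrow(x@edges) == 0) stop("empty bipartite input", call. = FALSE)
  B <- Matrix::sparseMatrix(
    i = match(x@edges$disease, x@diseases),
    j = match(x@edges$mirna, x@mirnas), x = 1,
    dims = c(length(x@diseases), length(x@mirnas)))
  projectIncidence(B, x@diseases)
})

#' @describeIn projectDiseases gene-space projection (DPG) of a named
#'   disease -> genes list
#' @export
setMethod("projectDiseases", "list", function(x) {
  if (length(x) == 0) stop("empty bipartite input", call. = FALSE)
  diseases <- sort(names(x))
  genes <- sort(unique(unlist(x, use.names = FALSE)))
  pairs <- data.frame(
    d = rep(diseases, lengths(x[diseases])),
    g = unlist(x[diseases], use.names = FALSE))
  pairs <- unique(pairs)
  B <- Matrix::sparseMatrix(i = match(pairs$d, diseases),
                            j = match(pairs$g, genes), x = 1,
                            dims = c(length(diseases), length(genes)))
  projectIncidence(B, diseases)
})

#' Threshold a disease projection
#'
#' Keeps edges whose shared count is strictly greater than
#' \code{min_shared}; zero-degree nodes are then removed from the node set
#' (set \code{drop_isolated = FALSE} to keep them, e.g. when comparing
#' densities over a fixed universe).
#'
#' @param proj a \code{DiseaseProjection}
#' @param min_shared integer cutoff (strict); \code{0} keeps all edges
#' @param drop_isolated remove zero-degree nodes after filtering
#'   (default TRUE)
#' @return filtered \code{DiseaseProjection}
#' @export
thresholdProjection <- function(proj, min_shared, drop_isolated = TRUE) {
  stopifnot(min_shared >= 0)
  keep <- proj@edges$weight > min_shared
  if (!any(keep)) stop("empty projection: no edge exceeds ", min_shared,
                       call. = FALSE)
  e <- proj@edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  nodes <- if (drop_isolated) sort(unique(c(e$from, e$to))) else proj@nodes
  new("DiseaseProjection", nodes = nodes, edges = e)
}

#' @describeIn asIgraph disease projection as a weighted undirected
#'   igraph graph (isolated nodes preserved)
#' @export
setMethod("asIgraph", "DiseaseProjection", function(x) {
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = data.frame(name = x@nodes))
})

#' Nodes of a disease projection
#' @param proj a \code{DiseaseProjection}
#' @return character vector of disease ids
#' @export
projectionNodes <- function(proj) proj@nodes

#' Edge table of a disease projection
#' @param proj a \code{DiseaseProjection}
#' @return data.frame with columns from, to, weight
#' @export
projectionEdges <- function(proj) proj@edges
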