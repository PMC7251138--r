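#' Node identifiers of a network object
#' @param x a network container
#' @return character vector of node ids
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Node kinds ("mirna"/"gene") of a heterogeneous network
#' @param x a \code{HeteroNetwork}
#' @return named character vector
#' @export
setGeneric("nodeKind", function(x) standardGeneric("nodeKind"))

#' Sparse symmetric adjacency matrix
#' @param x a \code{HeteroNetwork}
#' @return a \code{dgCMatrix}
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Graph density
#'
#' Fraction of realised edges: \eqn{|E|/(|A||B|)} for a bipartite network
#' with node universes A and B, \eqn{2|E|/(n(n-1))} for a unipartite graph
#' on n nodes. Node universes include isolated nodes.
#'
#' @param x a \code{BipartiteMDN} or \code{DiseaseProjection}
#' @return a single number in [0, 1]
#' @export
setGeneric("graphDensity", function(x) standardGeneric("graphDensity"))

#' Project a bipartite network onto its disease side
#'
#' Two diseases are connected if they share at least one partner (miRNA for
#' a predicted MDN, gene for a disease-gene map); the edge weight is the
#' number of shared partners. Membership is binary: edge weights of the
#' bipartite input play no role beyond having survived thresholding.
#'
#' @param x a \code{BipartiteMDN}, or a named list mapping disease ids to
#'   character vectors of gene ids (gene-space projection)
#' @return a \code{DiseaseProjection}
#' @export
setGeneric("projectDiseases", function(x) standardGeneric("projectDiseases"))

#' Smallest edge-weight threshold reaching a target density
#'
#' Scans the sorted distinct edge weights and returns the smallest
#' threshold whose strictly-greater-than filter brings the graph density
#' (computed over the fixed node universe) down to at most
#' \code{target_density} without emptying the edge set.
#'
#' @param x a \code{BipartiteMDN} or \code{DiseaseProjection}
#' @param target_density target density in (0, 1)
#' @return list with elements \code{threshold} and \code{density} (the
#'   density achieved by the strict filter at that threshold)
#' @export
setGeneric("matchDensityThreshold",
           function(x, target_density) standardGeneric("matchDensityThreshold"))

#' Convert to an igraph object
#' @param x a \code{DiseaseProjection} or \code{HeteroNetwork}
#' @return an undirected \code{igraph} graph (projections carry a
#'   \code{weight} edge attribute)
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
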