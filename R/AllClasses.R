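#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Heterogeneous miRNA-gene network
#'
#' Container for the merged network over which the random walk with restart
#' operates: the union of an undirected miRNA-target edge table and an
#' undirected protein-protein interaction edge table. Nodes are labelled as
#' either \code{"mirna"} or \code{"gene"}; diseases are never nodes of this
#' network, they enter the diffusion only through seed vectors.
#'
#' @slot nodes character vector of node identifiers (unique, sorted).
#' @slot kind character vector parallel to \code{nodes}, each entry
#'   \code{"mirna"} or \code{"gene"}.
#' @slot adjacency symmetric sparse 0/1 \code{dgCMatrix} with zero diagonal,
#'   dimnames equal to \code{nodes}; every node has degree >= 1.
#'
#' @seealso [buildHeteroNetwork()], [transitionMatrix()], [seedVector()]
#' @export
setClass("HeteroNetwork",
  slots = c(nodes = "character", kind = "character", adjacency = "dgCMatrix")
)

setValidity("HeteroNetwork", function(object) {
  n <- length(object@nodes)
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node ids must be unique")
  if (length(object@kind) != n) msg <- c(msg, "kind must be parallel to nodes")
  if (!all(object@kind %in% c("mirna", "gene")))
    msg <- c(msg, "kind entries must be 'mirna' or 'gene'")
  A <- object@adjacency
  if (nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency dimensions must match nodes")
  else {
    if (!identical(rownames(A), object@nodes) ||
        !identical(colnames(A), object@nodes))
      msg <- c(msg, "adjacency dimnames must equal nodes")
    if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (length(A@x) && !all(A@x %in% c(0, 1)))
      msg <- c(msg, "adjacency entries must be 0/1")
    if (n > 0 && any(Matrix::colSums(A) == 0))
      msg <- c(msg, "zero-degree nodes are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HeteroNetwork-class compact summary
#' @param object a \code{HeteroNetwork}
#' @export
setMethod("show", "HeteroNetwork", function(object) {
  nm <- sum(object@kind == "mirna")
  ne <- length(object@adjacency@x) / 2
  cat("HeteroNetwork with", length(object@nodes), "nodes (",
      nm, "miRNA,", length(object@nodes) - nm, "gene ) and",
      ne, "undirected edges\n")
})

#' Predicted bipartite miRNA-disease network (MDN)
#'
#' The output of the diffusion step: for each retained disease, every miRNA
#' of the network carries the steady-state probability of the restarting
#' walk as edge weight. Thresholding keeps the node universes fixed so that
#' graph density stays comparable across filtering steps.
#'
#' @slot edges data.frame with columns \code{disease}, \code{mirna},
#'   \code{weight}.
#' @slot diseases character, the disease node universe.
#' @slot mirnas character, the miRNA node universe.
#' @slot skipped character, diseases dropped because none of their seed
#'   genes were present in the network.
#'
#' @seealso [predictMDN()], [thresholdBipartite()], [projectDiseases()]
#' @export
setClass("BipartiteMDN",
  slots = c(edges = "data.frame", diseases = "character",
            mirnas = "character", skipped = "character")
)

setValidity("BipartiteMDN", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("disease", "mirna", "weight")
  if (!all(need %in% names(e)))
    return("edges must have columns disease, mirna, weight")
  if (!is.numeric(e$weight) || anyNA(e$weight))
    msg <- c(msg, "weights must be numeric and non-missing")
  else if (any(e$weight < 0)) msg <- c(msg, "weights must be non-negative")
  if (!all(e$disease %in% object@diseases))
    msg <- c(msg, "edge diseases outside the disease universe")
  if (!all(e$mirna %in% object@mirnas))
    msg <- c(msg, "edge miRNAs outside the miRNA universe")
  if (anyDuplicated(paste(e$disease, e$mirna, sep = "\r")))
    msg <- c(msg, "duplicate (disease, mirna) pairs")
  if (length(msg)) msg else TRUE
})

#' @describeIn BipartiteMDN-class compact summary
#' @param object a \code{BipartiteMDN}
#' @export
setMethod("show", "BipartiteMDN", function(object) {
  cat("BipartiteMDN:", nrow(object@edges), "edges over",
      length(object@diseases), "diseases x", length(object@mirnas),
      "miRNAs\n")
  if (length(object@skipped))
    cat("  skipped diseases (no seeds in network):",
        length(object@skipped), "\n")
})

#' Weighted disease-disease projection
#'
#' Unipartite projection of a bipartite network: two diseases are joined if
#' they share at least one partner (miRNA or gene) and the edge weight is
#' the number of shared partners. Nodes left isolated by projection (no
#' shared partner with anyone) remain in the node set until
#' [thresholdProjection()] removes zero-degree nodes.
#'
#' @slot nodes character, disease identifiers.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; pairs stored with \code{from < to}, no self-loops.
#'
#' @seealso [projectDiseases()], [thresholdProjection()],
#'   [detectCommunities()]
#' @export
setClass("DiseaseProjection",
  slots = c(nodes = "character", edges = "data.frame")
)

setValidity("DiseaseProjection", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored with from < to")
    if (any(e$weight < 1)) msg <- c(msg, "shared counts must be >= 1")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints outside the node set")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DiseaseProjection-class compact summary
#' @param object a \code{DiseaseProjection}
#' @export
setMethod("show", "DiseaseProjection", function(object) {
  cat("DiseaseProjection:", length(object@nodes), "diseases,",
      nrow(object@edges), "weighted edges\n")
})
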