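## Assembly of the heterogeneous miRNA-gene network and its
## column-stochastic transition matrix. Disease-gene edges never enter the
## walk matrix: diseases act on the diffusion only through seed vectors.

#' Build the heterogeneous miRNA-gene network
#'
#' Merges a miRNA-target edge table (miRNA in \code{from}, gene in
#' \code{to}) with a protein-protein interaction edge table into one
#' undirected, unweighted network. A node is a miRNA iff it appears in the
#' miRNA column of the miRNA-gene table; an identifier occurring both as a
#' miRNA and as a gene/protein is an error by default, or is disambiguated
#' by suffixing the miRNA copy when \code{on_conflict = "rename"}.
#'
#' @param mirna_gene cleaned edge table (columns \code{from} = miRNA,
#'   \code{to} = target gene)
#' @param ppi cleaned protein-protein edge table, or NULL for a
#'   miRNA-gene-only network
#' @param on_conflict \code{"error"} or \code{"rename"} (suffixes
#'   conflicting miRNA ids with \code{"_mirna"})
#' @return a [HeteroNetwork-class] object
#' @export
buildHeteroNetwork <- function(mirna_gene, ppi = NULL,
                               on_conflict = c("error", "rename")) {
  on_conflict <- match.arg(on_conflict)
  stopifnot(all(c("from", "to") %in% names(mirna_gene)))
  mirnas <- unique(mirna_gene$from)
  genes <- unique(c(mirna_gene$to,
                    if (!is.null(ppi)) c(ppi$from, ppi$to)))
  clash <- intersect(mirnas, genes)
  if (length(clash)) {
    if (on_conflict == "error")
      stop("id(s) appear both as miRNA and as gene/protein: ",
           paste(utils::head(clash, 5), collapse = ", "),
           if (length(clash) > 5) " ...", call. = FALSE)
    ren <- setNames(paste0(clash, "_mirna"), clash)
    hit <- mirna_gene$from %in% clash
    mirna_gene$from[hit] <- ren[mirna_gene$from[hit]]
    mirnas <- unique(mirna_gene$from)
  }
  nodes <- sort(unique(c(mirnas, genes)))
  if (length(nodes) < 2) stop("empty or degenerate node union", call. = FALSE)
  kind <- ifelse(nodes %in% mirnas, "mirna", "gene")

  ef <- c(mirna_gene$from, if (!is.null(ppi)) ppi$from)
  et <- c(mirna_gene$to, if (!is.null(ppi)) ppi$to)
  i <- match(ef, nodes); j <- match(et, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  A@x[A@x > 0] <- 1  # duplicated edges across the two tables collapse to 1
  net <- new("HeteroNetwork", nodes = nodes, kind = kind,
             adjacency = as(A, "generalMatrix"))
  message("heterogeneous network: ", length(nodes), " nodes (",
          sum(kind == "mirna"), " miRNA), ", length(net@adjacency@x) / 2,
          " edges")
  net
}

#' @describeIn nodeIds node ids of a heterogeneous network
#' @export
setMethod("nodeIds", "HeteroNetwork", function(x) x@nodes)

#' @describeIn nodeKind node kinds, named by node id
#' @export
setMethod("nodeKind", "HeteroNetwork",
          function(x) setNames(x@kind, x@nodes))

#' @describeIn adjacencyMatrix sparse adjacency of a heterogeneous network
#' @export
setMethod("adjacencyMatrix", "HeteroNetwork", function(x) x@adjacency)

#' miRNA node ids of a heterogeneous network
#' @param net a \code{HeteroNetwork}
#' @return character vector
#' @export
mirnaIds <- function(net) net@nodes[net@kind == "mirna"]

#' Gene node ids of a heterogeneous network
#' @param net a \code{HeteroNetwork}
#' @return character vector
#' @export
geneIds <- function(net) net@nodes[net@kind == "gene"]

#' @describeIn asIgraph heterogeneous network as an igraph graph with a
#'   \code{kind} vertex attribute
#' @export
setMethod("asIgraph", "HeteroNetwork", function(x) {
  g <- igraph::graph_from_adjacency_matrix(x@adjacency, mode = "undirected")
  igraph::V(g)$kind <- x@kind
  g
})

#' Column-stochastic transition matrix
#'
#' Degree-normalizes the adjacency matrix column-wise:
#' \eqn{W_{ij} = A_{ij} / \mathrm{deg}(j)}. Every column sums to one, so the
#' random walk conserves probability mass.
#'
#' @param net a \code{HeteroNetwork}
#' @return sparse \code{dgCMatrix} aligned to \code{nodeIds(net)}
#' @export
transitionMatrix <- function(net) {
  A <- net@adjacency
  deg <- Matrix::colSums(A)
  stopifnot(all(deg > 0))
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- dimnames(A)
  as(W, "CsparseMatrix")
}

#' Seed vector for a disease
#'
#' Uniform restart distribution over the disease's known genes that are
#' present in the network. Seed genes absent from the network are dropped
#' with a warning; if none remain the disease cannot be diffused and an
#' error is raised.
#'
#' @param disease_id disease identifier (must be a name of \code{dg_map})
#' @param dg_map named list mapping disease ids to gene id vectors
#' @param net a \code{HeteroNetwork}
#' @return named numeric vector over \code{nodeIds(net)} summing to 1
#' @export
seedVector <- function(disease_id, dg_map, net) {
  if (!disease_id %in% names(dg_map))
    stop("unknown disease: ", disease_id, call. = FALSE)
  genes <- dg_map[[disease_id]]
  present <- intersect(genes, net@nodes)
  if (length(present) == 0)
    stop("no seeds in network for disease ", disease_id, call. = FALSE)
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " seed gene(s) of ",
            disease_id, " absent from the network and dropped",
            call. = FALSE)
  x <- setNames(numeric(length(net@nodes)), net@nodes)
  x[present] <- 1 / length(present)
  x
}
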