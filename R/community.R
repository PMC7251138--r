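## Louvain communities in disease projections and their alignment with
## disease-class metadata, quantified as mutual information (bits) with a
## shuffle-based randomized baseline.

#' Louvain community detection on a disease projection
#'
#' Runs the Louvain modularity algorithm on the weighted projection
#' (shared counts as edge weights). Louvain is order-dependent, so a fixed
#' RNG seed is required for reproducibility; the modularity of the
#' returned partition is attached as attribute \code{"modularity"}.
#'
#' @param proj a \code{DiseaseProjection}
#' @param resolution Louvain resolution parameter; default 1
#' @param seed integer RNG seed
#' @return named character vector mapping each projection node to a
#'   community label, with attribute \code{"modularity"}
#' @export
detectCommunities <- function(proj, resolution = 1, seed = 1) {
  if (length(proj@nodes) == 0) stop("empty projection", call. = FALSE)
  g <- asIgraph(proj)
  cl <- withSeed(seed,
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution))
  memb <- igraph::membership(cl)
  structure(setNames(as.character(memb), names(memb)),
            modularity = igraph::modularity(g, memb,
                                            weights = igraph::E(g)$weight))
}

#' Mutual information between two labelings (bits)
#'
#' Plug-in mutual information \eqn{I(C;D) = \sum_c \sum_d p(c,d)
#' \log_2\!\frac{p(c,d)}{p(c)p(d)}} computed from the contingency counts of
#' two labelings of the same disease set. Zero-probability cells
#' contribute 0; no bias correction is applied.
#'
#' @param c,d named vectors assigning each disease a label; names must
#'   cover the same disease set
#' @return mutual information in bits (non-negative)
#' @export
mutualInformation <- function(c, d) {
  ids <- names(c)
  if (is.null(ids) || is.null(names(d)) ||
      !setequal(ids, names(d)) || length(ids) != length(d))
    stop("labelings must cover the identical disease set", call. = FALSE)
  A <- table(as.character(c[ids]), as.character(d[ids]))
  p <- A / sum(A)
  pc <- rowSums(p); pd <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pc, pd)[nz]))
}

#' Entropy of a labeling (bits)
#' @param labels named or unnamed label vector
#' @return entropy in bits
#' @export
labelEntropy <- function(labels) {
  p <- table(as.character(labels)) / length(labels)
  -sum(p[p > 0] * log2(p[p > 0]))
}

#' Assign class labels to diseases
#'
#' Maps diseases to their broad class (e.g. an ICD-9 chapter) or to the
#' next hierarchy level (subtype). Diseases absent from the map are
#' excluded with a warning.
#'
#' @param disease_ids diseases to label
#' @param class_map data.frame as returned by [readClassMap()] (columns
#'   \code{disease}, \code{icd9_class}, optionally \code{icd9_subtype})
#' @param level \code{"broad"} or \code{"subtype"}
#' @return named character vector of labels for the covered diseases
#' @export
assignClasses <- function(disease_ids, class_map,
                          level = c("broad", "subtype")) {
  level <- match.arg(level)
  col <- if (level == "broad") "icd9_class" else "icd9_subtype"
  if (!col %in% names(class_map))
    stop("class map lacks column ", col, call. = FALSE)
  idx <- match(disease_ids, class_map$disease)
  covered <- !is.na(idx)
  if (!any(covered)) stop("no disease covered by the class map",
                          call. = FALSE)
  if (any(!covered))
    warning(sum(!covered), " disease(s) not in the class map; excluded",
            call. = FALSE)
  setNames(class_map[[col]][idx[covered]], disease_ids[covered])
}

#' Induced subnetwork of one broad disease class
#'
#' Restricts a projection to the diseases of one class (for subtype-level
#' analyses); community detection is then re-run on the induced subgraph.
#'
#' @param proj a \code{DiseaseProjection}
#' @param classes named label vector (see [assignClasses()])
#' @param class_label the class to keep
#' @return a \code{DiseaseProjection} over the class's diseases
#' @export
classSubnetwork <- function(proj, classes, class_label) {
  keep <- intersect(proj@nodes, names(classes)[classes == class_label])
  if (length(keep) == 0) stop("no projection node in class ", class_label,
                              call. = FALSE)
  e <- proj@edges[proj@edges$from %in% keep & proj@edges$to %in% keep, ,
                  drop = FALSE]
  rownames(e) <- NULL
  new("DiseaseProjection", nodes = sort(keep), edges = e)
}

#' Randomized mutual-information baseline
#'
#' Negative control for community/class alignment: each replicate
#' shuffles the node labels of the bipartite MDN, re-runs the projection
#' pipeline (bipartite threshold, projection, projection threshold,
#' Louvain), and computes the mutual information of the resulting
#' communities with the class labels. Replicates whose projection empties
#' are skipped; more than 50% skips is an error.
#'
#' @param mdn the (unthresholded) predicted \code{BipartiteMDN}
#' @param classes named class labels covering (at least) the MDN diseases
#' @param n_reps number of replicates (>= 2); default 100
#' @param seed master seed; per-replicate seeds derive from it
#' @param bip_threshold strict weight cutoff for [thresholdBipartite()]
#' @param proj_threshold strict shared-count cutoff for
#'   [thresholdProjection()]
#' @param resolution Louvain resolution
#' @return list with \code{mean_mi}, \code{sd_mi}, \code{values},
#'   \code{n_skipped}
#' @export
randomizedMIBaseline <- function(mdn, classes, n_reps = 100, seed = 1,
                                 bip_threshold, proj_threshold,
                                 resolution = 1) {
  stopifnot(n_reps >= 2)
  rep_seeds <- deriveSeeds(seed, n_reps)
  vals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    mi <- tryCatch({
      sh <- shuffleNull(mdn, "node_label", rep_seeds[r])
      tb <- suppressMessages(thresholdBipartite(sh, bip_threshold))
      pr <- thresholdProjection(projectDiseases(tb), proj_threshold)
      comm <- detectCommunities(pr, resolution, seed = rep_seeds[r])
      ids <- intersect(names(comm), names(classes))
      if (length(ids) < 2) stop("too few labelled nodes")
      mutualInformation(comm[ids], classes[ids])
    }, error = function(e) NA_real_)
    vals[r] <- mi
  }
  skipped <- sum(is.na(vals))
  if (skipped > n_reps / 2)
    stop("more than half of the randomized replicates produced an empty ",
         "projection", call. = FALSE)
  ok <- vals[!is.na(vals)]
  list(mean_mi = mean(ok), sd_mi = stats::sd(ok), values = ok,
       n_skipped = skipped)
}
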