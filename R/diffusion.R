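## Core diffusion: random walk with restart (RWR) over the heterogeneous
## network. The steady state solves (I - (1-a)W) p = a x, the closed form
## of p_inf = a (I - (1-a)W)^{-1} x; a sparse linear solve replaces the
## dense inverse, and a power iteration provides an independent route to
## the same fixed point.

#' Steady-state RWR scores by sparse linear solve
#'
#' Solves \eqn{(I - (1-a)W)\,p = a\,x} for the stationary distribution of a
#' random walk that restarts at the seed distribution \code{x} with
#' probability \code{restart} at each step. The dense converged matrix
#' \eqn{a(I-(1-a)W)^{-1}} is never materialized. Tiny negative round-off is
#' clamped to zero; the vector is renormalized only if its sum drifts from
#' 1 by more than 1e-9.
#'
#' @param W column-stochastic sparse transition matrix
#'   (see [transitionMatrix()])
#' @param x seed vector aligned to \code{W}, summing to 1
#' @param restart restart probability \eqn{a \in (0, 1]}; default 0.7
#' @return named numeric steady-state vector, non-negative, summing to 1
#' @export
propagate <- function(W, x, restart = 0.7) {
  stopifnot(nrow(W) == ncol(W), length(x) == nrow(W))
  if (!(restart > 0 && restart <= 1))
    stop("restart probability must be in (0, 1]", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8)
    stop("seed vector must sum to 1", call. = FALSE)
  if (restart == 1) return(setNames(as.numeric(x), rownames(W)))
  M <- Matrix::Diagonal(nrow(W)) - (1 - restart) * W
  p <- as.numeric(Matrix::solve(M, restart * x))
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-9) p <- p / s
  setNames(p, rownames(W))
}

#' Steady-state RWR scores by power iteration
#'
#' Iterates \eqn{p \leftarrow a\,x + (1-a)\,W p} from \eqn{p^{(0)} = x}
#' until the L1 change drops below \code{tol} or \code{max_iter} is
#' reached (with a warning). The iteration count is attached as attribute
#' \code{"iterations"}.
#'
#' @inheritParams propagate
#' @param tol L1 convergence tolerance; default 1e-10
#' @param max_iter iteration cap; default 1000
#' @return named numeric steady-state vector with attribute
#'   \code{"iterations"}
#' @export
iterativeRWR <- function(W, x, restart = 0.7, tol = 1e-10, max_iter = 1000) {
  stopifnot(nrow(W) == ncol(W), length(x) == nrow(W))
  if (!(restart > 0 && restart <= 1))
    stop("restart probability must be in (0, 1]", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8)
    stop("seed vector must sum to 1", call. = FALSE)
  p <- as.numeric(x)
  iters <- 0L
  converged <- FALSE
  while (iters < max_iter) {
    pn <- restart * as.numeric(x) + (1 - restart) * as.numeric(W %*% p)
    iters <- iters + 1L
    delta <- sum(abs(pn - p))
    p <- pn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative RWR did not reach tol within ", max_iter,
            " iterations", call. = FALSE)
  structure(setNames(p, rownames(W)), iterations = iters)
}

#' Rank miRNAs by steady-state score
#'
#' Restricts a score vector to the miRNA nodes and sorts descending by
#' weight, breaking ties lexicographically by miRNA id so the ranking is
#' deterministic.
#'
#' @param p named score vector aligned to the network's nodes
#' @param net a \code{HeteroNetwork}
#' @return data.frame with columns \code{mirna}, \code{weight}, sorted
#' @export
rankMirnas <- function(p, net) {
  m <- mirnaIds(net)
  if (length(m) == 0) stop("network has no miRNA nodes", call. = FALSE)
  w <- unname(p[m])
  ord <- order(-w, m)
  data.frame(mirna = m[ord], weight = w[ord], stringsAsFactors = FALSE)
}

#' Predict the bipartite miRNA-disease network (MDN)
#'
#' Runs one diffusion per disease (all seed systems are solved in a single
#' factorized sparse solve for the analytic method) and collects, for every
#' retained disease, the steady-state probability of each miRNA as the
#' predicted association weight. Diseases with no seed genes in the network
#' are skipped and listed in the result's \code{skipped} slot.
#'
#' @param net a \code{HeteroNetwork}
#' @param dg_map named list: disease id -> character vector of seed genes
#' @param restart restart probability; default 0.7
#' @param method \code{"analytic"} (sparse linear solve) or
#'   \code{"iterative"} (power iteration)
#' @param tol,max_iter iterative-method controls
#' @param W optional precomputed transition matrix
#' @return a [BipartiteMDN-class] covering every (disease, miRNA) pair for
#'   the retained diseases
#' @export
predictMDN <- function(net, dg_map, restart = 0.7,
                       method = c("analytic", "iterative"),
                       tol = 1e-10, max_iter = 1000, W = NULL) {
  method <- match.arg(method)
  if (is.null(W)) W <- transitionMatrix(net)
  diseases <- sort(names(dg_map))
  seeds <- list(); skipped <- character()
  for (d in diseases) {
    x <- tryCatch(seedVector(d, dg_map, net), error = function(e) NULL)
    if (is.null(x)) skipped <- c(skipped, d) else seeds[[d]] <- x
  }
  if (length(seeds) == 0) stop("no disease has seeds in the network",
                               call. = FALSE)
  if (length(skipped))
    message("skipped ", length(skipped), " disease(s) without in-network seeds: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ...")
  kept <- names(seeds)
  mir <- sort(mirnaIds(net))
  if (length(mir) == 0) stop("network has no miRNA nodes", call. = FALSE)

  if (method == "analytic") {
    X <- do.call(cbind, seeds)           # n x n_diseases seed matrix
    if (restart == 1) {
      P <- X
    } else {
      M <- Matrix::Diagonal(nrow(W)) - (1 - restart) * W
      P <- as.matrix(Matrix::solve(M, restart * X))
    }
    P[P < 0] <- 0
    cs <- colSums(P)
    drift <- abs(cs - 1) > 1e-9
    if (any(drift)) P[, drift] <- sweep(P[, drift, drop = FALSE], 2,
                                        cs[drift], "/")
    rownames(P) <- rownames(W)
    scores <- P[mir, , drop = FALSE]
  } else {
    scores <- vapply(kept, function(d) {
      iterativeRWR(W, seeds[[d]], restart, tol, max_iter)[mir]
    }, numeric(length(mir)))
    rownames(scores) <- mir
  }

  edges <- data.frame(
    disease = rep(kept, each = length(mir)),
    mirna = rep(mir, times = length(kept)),
    weight = as.numeric(scores[, kept]),
    stringsAsFactors = FALSE)
  new("BipartiteMDN", edges = edges, diseases = kept, mirnas = mir,
      skipped = skipped)
}

#' Edge table of a predicted MDN
#' @param mdn a \code{BipartiteMDN}
#' @return data.frame with columns disease, mirna, weight
#' @export
mdnEdges <- function(mdn) mdn@edges

#' Disease universe of an MDN
#' @param mdn a \code{BipartiteMDN}
#' @return character vector
#' @export
mdnDiseases <- function(mdn) mdn@diseases

#' miRNA universe of an MDN
#' @param mdn a \code{BipartiteMDN}
#' @return character vector
#' @export
mdnMirnas <- function(mdn) mdn@mirnas

#' Diseases skipped during prediction
#' @param mdn a \code{BipartiteMDN}
#' @return character vector of disease ids with no in-network seeds
#' @export
skippedDiseases <- function(mdn) mdn@skipped
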