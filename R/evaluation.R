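## Validation of a predicted MDN against experimental ground truth:
## ROC/AUC per disease, DeLong comparison of correlated AUCs, shuffle null
## models, and correlation of predicted weights with differential
## expression (fold change).

#' ROC curve and AUC for one disease
#'
#' Positives are the ground-truth miRNAs for the disease (intersected with
#' the miRNAs actually scored; non-overlapping ids are dropped with a
#' message); negatives are every other scored miRNA. The AUC is the
#' trapezoidal area under the ROC built from the predicted edge weights,
#' which equals the Mann-Whitney statistic with the ties-count-half
#' convention.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param truth ground truth as returned by [readGroundTruth()] (list with
#'   a \code{positives} element)
#' @param disease_id disease to evaluate
#' @return an object of class \code{AUCResult}: list with \code{auc},
#'   \code{roc_points} (fpr/tpr data.frame from (0,0) to (1,1)),
#'   \code{n_pos}, \code{n_neg}, \code{scores}, \code{labels}, the
#'   underlying \code{pROC::roc} object, and \code{disease}
#' @export
computeROC <- function(mdn, truth, disease_id) {
  e <- mdn@edges[mdn@edges$disease == disease_id, , drop = FALSE]
  if (nrow(e) == 0) stop("disease not in MDN: ", disease_id, call. = FALSE)
  pos_all <- truth$positives[[disease_id]]
  if (is.null(pos_all)) stop("disease not in ground truth: ", disease_id,
                             call. = FALSE)
  pos <- intersect(pos_all, e$mirna)
  n_drop <- length(setdiff(pos_all, e$mirna))
  if (n_drop > 0)
    message(n_drop, " ground-truth miRNA(s) for ", disease_id,
            " not in the ranked universe; dropped")
  labels <- as.integer(e$mirna %in% pos)
  if (sum(labels) == 0) stop("no positives for ", disease_id, call. = FALSE)
  if (sum(labels) == length(labels)) stop("no negatives for ", disease_id,
                                          call. = FALSE)
  r <- pROC::roc(response = labels, predictor = e$weight,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(auc = as.numeric(pROC::auc(r)), roc_points = pts,
                 n_pos = sum(labels), n_neg = sum(labels == 0),
                 scores = e$weight, labels = labels, roc = r,
                 disease = disease_id),
            class = "AUCResult")
}

#' @export
print.AUCResult <- function(x, ...) {
  cat("AUCResult for", x$disease, ": AUC =", format(x$auc, digits = 4),
      "(", x$n_pos, "positives /", x$n_neg, "negatives )\n")
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares two ROC curves computed on the same positive/negative
#' instances (paired DeLong variance). Identical score vectors give
#' z = 0, p = 1 by convention.
#'
#' @param r1,r2 \code{AUCResult} objects on identical instance sets
#' @return list with \code{z} and two-sided \code{p_value}
#' @export
delongTest <- function(r1, r2) {
  stopifnot(inherits(r1, "AUCResult"), inherits(r2, "AUCResult"))
  if (!identical(r1$labels, r2$labels))
    stop("AUCResults are not on the same instance sets", call. = FALSE)
  if (identical(r1$scores, r2$scores))
    return(list(z = 0, p_value = 1))
  t <- pROC::roc.test(r1$roc, r2$roc, method = "delong", paired = TRUE)
  z <- unname(t$statistic); p <- t$p.value
  if (is.nan(z) && isTRUE(all.equal(r1$auc, r2$auc))) { z <- 0; p <- 1 }
  list(z = z, p_value = p)
}

#' Shuffle-based null model of an MDN
#'
#' \code{"node_label"} permutes the node identities of the bipartite
#' network globally (one permutation of the miRNA universe and one of the
#' disease universe), preserving topology and the weight multiset while
#' destroying any alignment between a disease's identity and its predicted
#' miRNA ranking. \code{"edge_weight"} permutes the weights within each
#' disease's edge set, preserving per-disease weight multisets.
#' Deterministic given \code{seed}.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param mode \code{"node_label"} or \code{"edge_weight"}
#' @param seed integer RNG seed
#' @return a shuffled \code{BipartiteMDN} over the same universes
#' @export
shuffleNull <- function(mdn, mode = c("node_label", "edge_weight"), seed) {
  mode <- match.arg(mode)
  e <- mdn@edges
  withSeed(seed, {
    if (mode == "node_label") {
      pm <- setNames(sample(mdn@mirnas), mdn@mirnas)
      pd <- setNames(sample(mdn@diseases), mdn@diseases)
      e$mirna <- unname(pm[e$mirna])
      e$disease <- unname(pd[e$disease])
    } else {
      e$weight <- stats::ave(e$weight, e$disease, FUN = resample)
    }
  })
  e <- e[order(e$disease, e$mirna), , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteMDN", edges = e, diseases = mdn@diseases,
      mirnas = mdn@mirnas, skipped = mdn@skipped)
}

#' Mean AUC of a shuffle null model
#'
#' Repeatedly shuffles the MDN, recomputes the per-disease AUC against the
#' (unshuffled) ground truth, and pools all per-disease AUCs across
#' replicates. With the rankings randomized the expectation is 0.5.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param truth ground truth list (see [readGroundTruth()])
#' @param n_reps number of shuffle replicates; default 100
#' @param seed master seed; per-replicate seeds are derived from it
#' @param mode shuffle mode passed to [shuffleNull()]
#' @return list with \code{mean_auc}, \code{sd_auc}, \code{per_rep_mean},
#'   \code{n_auc} (number of pooled disease-level AUCs)
#' @export
meanNullAUC <- function(mdn, truth, n_reps = 100, seed = 1,
                        mode = "node_label") {
  stopifnot(n_reps >= 1)
  rep_seeds <- deriveSeeds(seed, n_reps)
  diseases <- intersect(mdn@diseases, names(truth$positives))
  if (length(diseases) == 0)
    stop("no disease shared between MDN and ground truth", call. = FALSE)
  all_aucs <- numeric(); per_rep <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sh <- shuffleNull(mdn, mode, rep_seeds[r])
    aucs <- vapply(diseases, function(d) {
      res <- tryCatch(suppressMessages(computeROC(sh, truth, d)),
                      error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$auc
    }, numeric(1))
    aucs <- aucs[!is.na(aucs)]
    per_rep[r] <- mean(aucs)
    all_aucs <- c(all_aucs, aucs)
  }
  list(mean_auc = mean(all_aucs), sd_auc = stats::sd(all_aucs),
       per_rep_mean = per_rep, n_auc = length(all_aucs))
}

#' Correlation of predicted weights with differential expression
#'
#' Joins the predicted edge weights of one disease with the ground-truth
#' fold changes of its miRNAs and reports the Spearman rank correlation,
#' an ordinary least-squares slope with its t-test p-value, and
#' equal-count bins across the fold-change axis (per-bin mean and sd of
#' the predicted weight) for plotting.
#'
#' @param mdn a \code{BipartiteMDN}
#' @param truth ground truth list with a non-NULL \code{fold_change} table
#' @param disease_id disease to analyse
#' @param n_bins number of equal-count bins; default 10 (reduced if fewer
#'   pairs are available)
#' @param abs_foldchange take \code{abs(fold_change)} first (dbDEMC mixes
#'   over- and under-expression); default FALSE
#' @return list with \code{spearman_rho}, \code{spearman_p}, \code{slope},
#'   \code{slope_p}, \code{n}, and a \code{bins} data.frame
#' @export
foldchangeCorrelation <- function(mdn, truth, disease_id, n_bins = 10,
                                  abs_foldchange = FALSE) {
  fc <- truth$fold_change
  if (is.null(fc)) stop("ground truth has no fold_change data", call. = FALSE)
  fc <- fc[fc$disease == disease_id, , drop = FALSE]
  e <- mdn@edges[mdn@edges$disease == disease_id, , drop = FALSE]
  m <- merge(fc, e, by = c("disease", "mirna"))
  if (nrow(m) < 3) stop("fewer than 3 (fold change, weight) pairs for ",
                        disease_id, call. = FALSE)
  x <- if (abs_foldchange) abs(m$fold_change) else m$fold_change
  y <- m$weight
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant fold changes or weights: correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  nb <- max(1L, min(n_bins, nrow(m)))
  ord <- order(x)
  grp <- cut(seq_along(ord), breaks = nb, labels = FALSE)
  bins <- do.call(rbind, lapply(split(ord, grp), function(idx) {
    data.frame(n = length(idx), x_mean = mean(x[idx]),
               y_mean = mean(y[idx]),
               y_sd = if (length(idx) > 1) stats::sd(y[idx]) else 0)
  }))
  rownames(bins) <- NULL
  list(spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       slope = unname(sm["x", "Estimate"]),
       slope_p = unname(sm["x", "Pr(>|t|)"]),
       n = nrow(m), bins = bins)
}
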