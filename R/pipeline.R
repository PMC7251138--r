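## End-to-end orchestration: build -> diffuse -> (validate) -> project ->
## communities, with deterministic seeds and machine-readable metrics.

pipelineDefaults <- function() {
  list(source_filter = NULL, restart = 0.7, method = "analytic",
       tol = 1e-10, max_iter = 1000,
       bip_threshold = 0.001, bip_density_target = NULL,
       proj_threshold = 7, proj_density_target = NULL,
       resolution = 1, null_mode = "node_label", null_reps = 100,
       abs_foldchange = FALSE, seed = 1)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full prediction and analysis pipeline
#'
#' Executes network construction, diffusion, optional validation against
#' ground truth, disease projection, and community/mutual-information
#' analysis, writing \code{mdn.tsv}, \code{proj.tsv},
#' \code{proj.graphml}, \code{metrics.json} and \code{run.log} into the
#' output directory. Fully deterministic given the config (seeds are
#' explicit; there are no wall-clock defaults).
#'
#' @param config named list or path to a JSON file. Required fields:
#'   \code{mirna_gene}, \code{ppi}, \code{disease_gene} (paths to TSV
#'   tables). Optional: \code{truth}, \code{classes} (paths),
#'   \code{source_filter}, \code{restart} (0.7), \code{method},
#'   \code{bip_threshold} (0.001) or \code{bip_density_target},
#'   \code{proj_threshold} (7) or \code{proj_density_target},
#'   \code{resolution} (1), \code{null_mode} ("node_label"),
#'   \code{null_reps} (100), \code{abs_foldchange}, \code{seed} (1).
#'   When a density target is given it overrides the fixed threshold.
#' @param outdir output directory (created if needed)
#' @return the metrics list, invisibly (also serialized to
#'   \code{metrics.json})
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(pipelineDefaults(), config)
  for (f in c("mirna_gene", "ppi", "disease_gene"))
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config field '", f, "' must name an existing file",
           call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logfile,
                               append = TRUE)
  cat("", file = logfile)
  logline("mirMAP ", as.character(utils::packageVersion("mirMAP")),
          " on R ", paste(R.version$major, R.version$minor, sep = "."))
  logline("seed ", cfg$seed, "; restart ", cfg$restart)

  metrics <- list(seed = cfg$seed, restart = cfg$restart)

  net <- stage("build", {
    mg <- suppressMessages(readEdgeTable(cfg$mirna_gene, "mirna", "gene"))
    pp <- suppressMessages(readEdgeTable(cfg$ppi, "protein_a", "protein_b"))
    suppressMessages(buildHeteroNetwork(mg, pp))
  })
  logline("network: ", length(net@nodes), " nodes, ",
          length(net@adjacency@x) / 2, " edges")
  metrics$n_nodes <- length(net@nodes)
  metrics$n_mirnas <- length(mirnaIds(net))

  mdn <- stage("diffuse", {
    dg <- suppressWarnings(readDiseaseGeneTable(
      cfg$disease_gene, source_filter = cfg$source_filter))
    suppressMessages(suppressWarnings(
      predictMDN(net, dg, restart = cfg$restart, method = cfg$method,
                 tol = cfg$tol, max_iter = cfg$max_iter)))
  })
  writeMDN(mdn, file.path(outdir, "mdn.tsv"))
  metrics$n_diseases <- length(mdn@diseases)
  metrics$skipped_diseases <- as.list(mdn@skipped)
  logline("mdn: ", length(mdn@diseases), " diseases, ",
          length(mdn@skipped), " skipped")

  if (!is.null(cfg$truth)) {
    metrics$validation <- stage("validate", {
      truth <- readGroundTruth(cfg$truth)
      diseases <- intersect(mdn@diseases, names(truth$positives))
      aucs <- lapply(diseases, function(d) tryCatch(
        suppressMessages(computeROC(mdn, truth, d))$auc,
        error = function(e) NULL))
      names(aucs) <- diseases
      aucs <- aucs[!vapply(aucs, is.null, logical(1))]
      v <- list(auc_per_disease = aucs,
                mean_auc = mean(unlist(aucs)))
      nul <- meanNullAUC(mdn, truth, n_reps = cfg$null_reps,
                         seed = cfg$seed, mode = cfg$null_mode)
      v$null_mean_auc <- nul$mean_auc
      v$null_sd_auc <- nul$sd_auc
      if (!is.null(truth$fold_change)) {
        v$foldchange <- lapply(diseases, function(d) tryCatch({
          r <- foldchangeCorrelation(mdn, truth, d,
                                     abs_foldchange = cfg$abs_foldchange)
          r[c("spearman_rho", "spearman_p", "slope", "slope_p", "n")]
        }, error = function(e) NULL))
        names(v$foldchange) <- diseases
        v$foldchange <- v$foldchange[
          !vapply(v$foldchange, is.null, logical(1))]
      }
      v
    })
    logline("validation: mean AUC ",
            format(metrics$validation$mean_auc, digits = 4),
            " (null ", format(metrics$validation$null_mean_auc,
                              digits = 4), ")")
  } else logline("validation: skipped (no truth table)")

  prj <- stage("project", {
    bt <- cfg$bip_threshold
    if (!is.null(cfg$bip_density_target))
      bt <- matchDensityThreshold(mdn, cfg$bip_density_target)$threshold
    tmdn <- suppressMessages(thresholdBipartite(mdn, bt))
    pr <- projectDiseases(tmdn)
    pt <- cfg$proj_threshold
    if (!is.null(cfg$proj_density_target))
      pt <- matchDensityThreshold(pr, cfg$proj_density_target)$threshold
    list(proj = thresholdProjection(pr, pt), bip_threshold = bt,
         proj_threshold = pt, mdn_density = graphDensity(tmdn),
         proj_density_prefilter = graphDensity(pr))
  })
  proj <- prj$proj
  metrics$bip_threshold <- prj$bip_threshold
  metrics$proj_threshold <- prj$proj_threshold
  metrics$mdn_density <- prj$mdn_density
  metrics$proj_density_prefilter <- prj$proj_density_prefilter
  writeProjectionTSV(proj, file.path(outdir, "proj.tsv"))
  writeProjectionGraphML(proj, file.path(outdir, "proj.graphml"))
  logline("projection: ", length(proj@nodes), " diseases, ",
          nrow(proj@edges), " edges")

  if (!is.null(cfg$classes)) {
    metrics$communities <- stage("communities", {
      cm <- readClassMap(cfg$classes)
      classes <- suppressWarnings(
        assignClasses(proj@nodes, cm, level = "broad"))
      comm <- detectCommunities(proj, resolution = cfg$resolution,
                                seed = cfg$seed)
      ids <- intersect(names(comm), names(classes))
      mi <- mutualInformation(comm[ids], classes[ids])
      base <- randomizedMIBaseline(
        mdn, assignClasses(mdn@diseases, cm, level = "broad"),
        n_reps = cfg$null_reps, seed = cfg$seed,
        bip_threshold = metrics$bip_threshold,
        proj_threshold = metrics$proj_threshold,
        resolution = cfg$resolution)
      list(n_communities = length(unique(comm)),
           modularity = attr(comm, "modularity"),
           mi_observed = mi, mi_null_mean = base$mean_mi,
           mi_null_sd = base$sd_mi)
    })
    logline("communities: MI ",
            format(metrics$communities$mi_observed, digits = 4),
            " vs null ",
            format(metrics$communities$mi_null_mean, digits = 4),
            " +/- ", format(metrics$communities$mi_null_sd, digits = 4))
  } else logline("communities: skipped (no class map)")

  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
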