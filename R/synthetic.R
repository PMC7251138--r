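## Planted-structure synthetic tripartite networks: a stochastic block
## model PPI over class gene-modules, class-specific miRNA targeting, and
## per-disease seed sets drawn from the class module. Emulates the local
## impact hypothesis the diffusion method relies on (disease-related
## cellular components concentrate in a localized network neighborhood)
## so every pipeline stage can be exercised without external databases.

#' Specification of a planted synthetic network
#'
#' Validates and returns the parameter set for
#' [generatePlantedNetwork()]. Defaults describe a small two-class
#' benchmark with moderate cross-class noise.
#'
#' @param n_classes number of disease classes (planted blocks); default 2
#' @param diseases_per_class diseases drawn per class; default 10
#' @param genes_per_module genes in each class's PPI module; default 20
#' @param mirnas_per_class miRNAs wired to each class module; default 5
#' @param background_genes unaffiliated genes; default 40
#' @param p_within PPI edge probability inside a module; default 0.3
#' @param p_between PPI edge probability between modules / involving
#'   background genes; default 0.01
#' @param p_target_in probability a class miRNA targets each gene of its
#'   module; default 0.5
#' @param p_target_out probability it targets each other gene (noise);
#'   default 0.02
#' @param seeds_per_disease seed genes per disease, drawn from the class
#'   module; default 5
#' @param rng_seed integer seed making the generator fully deterministic
#' @return validated list of class \code{SyntheticSpec}
#' @export
syntheticSpec <- function(n_classes = 2, diseases_per_class = 10,
                          genes_per_module = 20, mirnas_per_class = 5,
                          background_genes = 40, p_within = 0.3,
                          p_between = 0.01, p_target_in = 0.5,
                          p_target_out = 0.02, seeds_per_disease = 5,
                          rng_seed = 1) {
  spec <- list(n_classes = n_classes, diseases_per_class = diseases_per_class,
               genes_per_module = genes_per_module,
               mirnas_per_class = mirnas_per_class,
               background_genes = background_genes, p_within = p_within,
               p_between = p_between, p_target_in = p_target_in,
               p_target_out = p_target_out,
               seeds_per_disease = seeds_per_disease, rng_seed = rng_seed)
  probs <- c(p_within, p_between, p_target_in, p_target_out)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!(p_within > p_between))
    stop("p_within must exceed p_between", call. = FALSE)
  if (!(p_target_in > p_target_out))
    stop("p_target_in must exceed p_target_out", call. = FALSE)
  counts <- c(n_classes, diseases_per_class, genes_per_module,
              mirnas_per_class, seeds_per_disease)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (background_genes < 0) stop("background_genes must be >= 0",
                                 call. = FALSE)
  if (seeds_per_disease > genes_per_module)
    stop("infeasible spec: module smaller than seeds_per_disease",
         call. = FALSE)
  class(spec) <- "SyntheticSpec"
  spec
}

## Bernoulli edges over all unordered pairs with per-pair probabilities.
sbmEdges <- function(ids, prob_fun) {
  n <- length(ids)
  if (n < 2) return(data.frame(from = character(), to = character()))
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pr <- prob_fun(idx[, 1], idx[, 2])
  hit <- stats::runif(nrow(idx)) < pr
  data.frame(from = ids[idx[hit, 1]], to = ids[idx[hit, 2]],
             stringsAsFactors = FALSE)
}

#' Generate a planted tripartite benchmark network
#'
#' Draws the five tables the pipeline consumes: a stochastic-block-model
#' PPI over class gene-modules plus background genes; class miRNAs wired
#' densely to their module (each guaranteed at least one in-module
#' target) and sparsely elsewhere; per-disease seed genes sampled from
#' the class module; ground truth marking each disease's class miRNAs as
#' positives, with synthetic fold changes increasing in the miRNA's
#' in-class targeting degree; and the planted class labels. Connectivity
#' is guaranteed by adding minimum bridge PPI edges between components.
#' Fully deterministic given \code{rng_seed}.
#'
#' @param spec a [syntheticSpec()]
#' @return list with \code{mirna_gene}, \code{ppi} (edge data.frames with
#'   columns from/to), \code{dg_map} (named list), \code{truth} (list
#'   with \code{positives} and \code{fold_change}), and \code{classes}
#'   (data.frame with disease, icd9_class)
#' @export
generatePlantedNetwork <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$rng_seed, {
    k <- spec$n_classes
    module_genes <- lapply(seq_len(k), function(c)
      sprintf("G_c%d_%03d", c, seq_len(spec$genes_per_module)))
    bg_genes <- if (spec$background_genes > 0)
      sprintf("G_bg_%03d", seq_len(spec$background_genes)) else character()
    genes <- c(unlist(module_genes), bg_genes)
    gene_module <- c(rep(seq_len(k), each = spec$genes_per_module),
                     rep(0L, spec$background_genes))

    ppi <- sbmEdges(genes, function(i, j)
      ifelse(gene_module[i] == gene_module[j] & gene_module[i] > 0,
             spec$p_within, spec$p_between))

    class_mirnas <- lapply(seq_len(k), function(c)
      sprintf("mir_c%d_%02d", c, seq_len(spec$mirnas_per_class)))
    mg_from <- character(); mg_to <- character()
    deg_in <- setNames(numeric(k * spec$mirnas_per_class),
                       unlist(class_mirnas))
    for (c in seq_len(k)) {
      own <- module_genes[[c]]
      other <- setdiff(genes, own)
      for (m in class_mirnas[[c]]) {
        tin <- own[stats::runif(length(own)) < spec$p_target_in]
        if (length(tin) == 0) tin <- sample(own, 1)  # keep the miRNA wired
        tout <- other[stats::runif(length(other)) < spec$p_target_out]
        mg_from <- c(mg_from, rep(m, length(tin) + length(tout)))
        mg_to <- c(mg_to, tin, tout)
        deg_in[m] <- length(tin)
      }
    }
    mirna_gene <- data.frame(from = mg_from, to = mg_to,
                             stringsAsFactors = FALSE)

    ## connectivity repair: minimum bridge PPI edges between components
    g <- igraph::graph_from_data_frame(rbind(ppi, mirna_gene),
                                       directed = FALSE,
                                       vertices = data.frame(
                                         name = c(genes, names(deg_in))))
    comp <- igraph::components(g)$membership
    if (max(comp) > 1) {
      reps <- vapply(seq_len(max(comp)), function(ci)
        min(genes[comp[genes] == ci]), character(1))
      reps <- sort(reps)
      ppi <- rbind(ppi, data.frame(from = reps[1], to = reps[-1],
                                   stringsAsFactors = FALSE))
    }

    diseases <- character(); dg_map <- list(); cls <- character()
    pos <- list(); fc_rows <- list()
    for (c in seq_len(k)) {
      for (i in seq_len(spec$diseases_per_class)) {
        d <- sprintf("dis_c%d_%02d", c, i)
        diseases <- c(diseases, d)
        cls <- c(cls, sprintf("C%d", c))
        dg_map[[d]] <- sample(module_genes[[c]], spec$seeds_per_disease)
        pos[[d]] <- class_mirnas[[c]]
        fc_rows[[d]] <- data.frame(
          disease = d, mirna = class_mirnas[[c]],
          fold_change = 1 + deg_in[class_mirnas[[c]]] +
            stats::rnorm(spec$mirnas_per_class, 0, 0.5),
          stringsAsFactors = FALSE)
      }
    }
    fc <- do.call(rbind, fc_rows)
    rownames(fc) <- NULL
    list(mirna_gene = mirna_gene, ppi = ppi, dg_map = dg_map,
         truth = list(positives = pos, fold_change = fc),
         classes = data.frame(disease = diseases, icd9_class = cls,
                              stringsAsFactors = FALSE))
  })
}

#' Write the five synthetic tables as TSV fixtures
#'
#' Emits \code{mirna_gene.tsv} (mirna, gene), \code{ppi.tsv} (protein_a,
#' protein_b), \code{disease_gene.tsv} (disease, gene, source =
#' "synthetic"), \code{truth.tsv} (disease, mirna, fold_change) and
#' \code{icd9.tsv} (disease, icd9_class) into \code{outdir}.
#'
#' @param gen output of [generatePlantedNetwork()]
#' @param outdir directory (created if missing)
#' @return named character vector of the five file paths, invisibly
#' @export
writeSyntheticTables <- function(gen, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    p
  }
  dg <- data.frame(
    disease = rep(names(gen$dg_map), lengths(gen$dg_map)),
    gene = unlist(gen$dg_map, use.names = FALSE),
    source = "synthetic")
  paths <- c(
    mirna_gene = wt(data.frame(mirna = gen$mirna_gene$from,
                               gene = gen$mirna_gene$to), "mirna_gene.tsv"),
    ppi = wt(data.frame(protein_a = gen$ppi$from,
                        protein_b = gen$ppi$to), "ppi.tsv"),
    disease_gene = wt(dg, "disease_gene.tsv"),
    truth = wt(data.frame(disease = gen$truth$fold_change$disease,
                          mirna = gen$truth$fold_change$mirna,
                          fold_change = sprintf(
                            "%.17g", gen$truth$fold_change$fold_change)),
               "truth.tsv"),
    classes = wt(gen$classes, "icd9.tsv"))
  invisible(paths)
}
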