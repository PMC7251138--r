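# Fixtures built in code: tiny deterministic networks and oracles used
# across the suite.

# Edge data.frame shorthand
edges <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

# Random heterogeneous network with guaranteed positive degree: genes on a
# ring plus Bernoulli chords; each miRNA targets >= 1 random gene.
erHetero <- function(n_genes = 20, n_mirnas = 5, p = 0.15, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  mirs <- sprintf("m%03d", seq_len(n_mirnas))
  ppi <- data.frame(from = genes, to = genes[c(2:n_genes, 1)])
  extra <- which(upper.tri(matrix(TRUE, n_genes, n_genes)), arr.ind = TRUE)
  hit <- runif(nrow(extra)) < p
  ppi <- rbind(ppi, data.frame(from = genes[extra[hit, 1]],
                               to = genes[extra[hit, 2]]))
  mg <- do.call(rbind, lapply(mirs, function(m) {
    k <- 1 + rbinom(1, n_genes - 1, p)
    data.frame(from = m, to = sample(genes, k))
  }))
  suppressMessages(buildHeteroNetwork(cleanEdgeTable(mg),
                                      cleanEdgeTable(ppi)))
}

# Minimal MDN constructor for hand-built cases
makeMDN <- function(df, diseases = sort(unique(df$disease)),
                    mirnas = sort(unique(df$mirna))) {
  new("BipartiteMDN", edges = df, diseases = diseases, mirnas = mirnas,
      skipped = character())
}

# Ground-truth list shorthand
makeTruth <- function(positives, fold_change = NULL) {
  list(positives = positives, fold_change = fold_change)
}

# Independent AUC oracle: brute-force Mann-Whitney pair counting with the
# ties-count-half convention.
aucBrute <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Write a TSV into a temp file and return the path
tsv <- function(df, ...) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
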