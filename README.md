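# mirMAP — miRNA–disease association prediction by network diffusion

microRNAs (miRNAs) regulate large gene programs, and mis-regulated miRNAs
are implicated in cancers, neurological and cardiovascular disease. Most
computational predictors of miRNA–disease associations bootstrap from
*known* miRNA–disease associations, which are scarce. mirMAP instead ranks
miRNAs for a disease using only three widely available inputs: miRNA→gene
target interactions, protein–protein interactions (PPI), and the disease's
known genes. It is aimed at computational biologists who want
network-based candidate miRNA rankings for diseases with no known miRNAs
at all, plus the downstream disease-subtyping analyses those rankings
enable.

## The model

The miRNA–target and PPI edge tables are merged into one undirected
heterogeneous network. For each disease, a random walk with restart (RWR)
starts from a uniform seed distribution *x* over the disease's known
genes; at every step the walker restarts at the seeds with probability
*a* = 0.7. The steady state is the solution of

```
p∞ = a (I − (1−a) W)⁻¹ x
```

where *W* is the column-normalized adjacency matrix
(W[i,j] = A[i,j]/deg(j)). `propagate()` computes `p∞` by a sparse linear
solve of `(I − (1−a)W) p = a x`; `iterativeRWR()` reaches the same fixed
point by power iteration and serves as an internal cross-check. Ranking
the miRNA entries of `p∞` for every disease yields a weighted bipartite
miRNA–disease network (MDN).

Downstream, the MDN is validated against experimental associations
(ROC/AUC with shuffle-null controls, DeLong tests, Spearman correlation
with expression fold changes) and projected into a weighted
disease–disease network (two diseases joined by the number of shared
miRNAs), where Louvain communities are compared with disease-class
metadata via mutual information I(C;D) in bits, against a randomized
baseline.

A planted-structure synthetic generator (`generatePlantedNetwork()`)
builds a complete five-table benchmark — modular PPI, class-specific
miRNA targeting, per-disease seed genes, ground truth with fold changes,
class labels — so the whole pipeline is testable without any database
downloads.

## Worked example

Generate a synthetic benchmark, predict, validate, project, and score
community/class alignment — either through the R API (see
`?predictMDN`, `?runPipeline`) or the bundled CLI:

```sh
MAP=$(Rscript -e 'cat(system.file("scripts/map.R", package="mirMAP"))')
Rscript $MAP simulate --seed 1 --outdir fx
Rscript $MAP diffuse --mirna-gene fx/mirna_gene.tsv --ppi fx/ppi.tsv \
        --disease-genes fx/disease_gene.tsv --out mdn.tsv
Rscript $MAP validate --mdn mdn.tsv --truth fx/truth.tsv \
        --disease dis_c1_01 --reps 20
Rscript $MAP communities --mdn mdn.tsv --classes fx/icd9.tsv \
        --threshold 0.004 --proj-threshold 2 --null-reps 20
```

which prints:

```
dis_c1_01: AUC = 1.0000 (5 pos / 5 neg)
  Spearman rho = 0.9000 (p = 0.0374); slope p = 0.0912
null model (node_label, 20 reps): mean AUC = 0.4887
communities: 2; modularity 0.4826; MI vs classes 1.0000 bits
randomized baseline: 0.0383 +/- 0.0432 (20 reps)
```

Read: the diffusion ranks all five planted class miRNAs of `dis_c1_01`
above every other miRNA (AUC 1.0); the predicted weights correlate with
the planted fold changes (rho 0.90); shuffling node labels collapses
performance to chance (mean AUC ≈ 0.49); and the Louvain communities of
the disease projection reproduce the two planted disease classes exactly
(1.0 bit of mutual information, ~25 standard deviations above the
randomized baseline).

## Layout

- `R/` — io readers/writers, network assembly, diffusion core,
  evaluation, projection, community/MI, synthetic generator, pipeline.
- `vignettes/network-diffusion-methods.Rmd` — the methods notes: model,
  parameter choices, thresholding conventions, generator design, and
  limitations.
- `inst/scripts/map.R` — CLI entry point (subcommands `simulate`,
  `build`, `diffuse`, `validate`, `project`, `communities`, `run`).
- `tests/testthat/` — unit, property and end-to-end recovery tests.
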