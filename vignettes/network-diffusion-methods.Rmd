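---
title: "Methods: network diffusion for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network diffusion for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

mirMAP scores candidate miRNAs for a disease by their diffusion
proximity to the disease's known genes in a heterogeneous network. The
motivation is the local-impact view of network medicine: the cellular
components of closely related diseases interact with each other and
concentrate in a localized network neighborhood, so a walker released at
a disease's genes visits disease-relevant miRNAs far more often than
distant ones. Diffusion also buys robustness: high-scoring nodes are
reached along many redundant paths, so missing edges in an incomplete
interactome perturb the ranking far less than they would perturb
shortest-path methods.

The network merges two undirected, unweighted edge layers over a common
gene universe: miRNA→target interactions and protein-protein
interactions. Although miRNA targeting is biologically directional,
an undirected walk does not distinguish direction, so both layers are
stored symmetrically. Disease-gene associations are deliberately **not**
edges of this network: the walk travels only via PPI and miRNA-gene
edges, and diseases enter solely through seed vectors. This keeps one
disease's predictions independent of every other disease's annotations —
the property that lets the method rank miRNAs for diseases with no known
miRNA associations at all.

With $W$ the column-normalized adjacency ($W_{ij} = A_{ij}/\deg(j)$,
every column summing to 1) and $x$ the uniform distribution over the
disease's in-network seed genes, the random walk with restart has
steady state

$$p^\infty = a\,(I - (1-a)W)^{-1}\,x,$$

where $a$ is the per-step restart probability. `propagate()` never forms
the dense inverse; it solves the sparse system $(I-(1-a)W)\,p = a\,x$
(one sparse LU shared across all diseases in `predictMDN()`), which is
algebraically identical and feasible at any scale. `iterativeRWR()`
iterates $p \leftarrow a\,x + (1-a)\,W p$ from $p^{(0)} = x$; any start
converges for $a > 0$ (the iteration contracts at rate $1-a$), so the
choice of start only affects the iteration count. The two routes agree
to solver precision, and the test suite checks their miRNA rankings
agree with Spearman correlation at least 0.98 on a ~500-node benchmark —
the same internal consistency check used when the method was introduced.

Because $W$ is column-stochastic and $x$ sums to one, $p^\infty$ is a
probability distribution; the suite asserts conservation at $10^{-9}$.
Tiny negative round-off from the solver is clamped to zero, with
renormalization only when the total drifts by more than $10^{-9}$ —
numerical hygiene that cannot change a ranking. Ties in miRNA weights
(e.g. symmetric leaves, or zero scores when seeds sit in another
connected component) are broken lexicographically by miRNA id so output
is deterministic. Disconnected networks are used as-is: seeds confined
to one component give zero mass elsewhere, which is mathematically
consistent and surfaces honestly as all-zero rankings rather than being
silently pruned.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.7 | per-step probability of returning to the seeds; higher values localize the walk around the disease module. 0.7 is the method's published operating point; `restart = 1` degenerates to the seed vector itself. |
| `tol` | 1e-10 | L1 stopping rule for the iterative route (dimensionless, on probability mass). |
| `max_iter` | 1000 | iteration cap; at $a = 0.7$ the error shrinks ~$0.3^k$, so convergence takes ~20 iterations and the cap is generous. |
| bipartite threshold | 0.001 | strict (>) weight filter on the predicted MDN before projection, at real-data scale. |
| projection threshold | 7 | strict (>) shared-miRNA count filter on the disease projection, at real-data scale. |
| Louvain `resolution` | 1.0 | standard modularity; the community analysis is not resolution-tuned. |

Threshold comparisons are strictly greater-than throughout, following
the convention "only edges with a weight greater than the threshold are
retained"; the projection threshold is read with the same strictness for
internal consistency. The absolute defaults (0.001 and 7) are tied to
the scale of the real databases (thousands of diseases, 1777 miRNAs).
On other scales the right approach — and the recommended path for
synthetic benchmarks — is density matching: `matchDensityThreshold()`
scans the sorted distinct weights and returns the smallest threshold
whose strict filter brings the graph density at or below a target,
computed over the *fixed* node universe so that densities before and
after filtering are comparable, and refusing thresholds that empty the
edge set. Isolated nodes are removed only from projections, never from
the bipartite network.

# Validation design

Per disease, positives are the ground-truth miRNAs and negatives are
**all other ranked miRNAs**: the method scores the full miRNA universe
and experimental databases supply only positives, so the complement is
the only consistent negative set. AUC is computed by `pROC` (trapezoid
with the ties-count-half convention) and is verified in the suite
against brute-force Mann-Whitney pair counting, exactly, on instances up
to 50+50 including ties. DeLong's test compares correlated AUCs on the
same instances; identical score vectors return $z=0, p=1$ by convention.

Two null models are provided because both appear in practice:
`edge_weight` permutes predicted weights within each disease, and
`node_label` (the default) permutes the node identities of the bipartite
network. A subtlety dictates the node_label design: permuting only the
miRNA side leaves every pairwise shared-miRNA count — hence the entire
disease projection and its mutual information — exactly invariant, which
would make the randomized projection baseline degenerate. The nodes of
the bipartite network are diseases *and* miRNAs, so `shuffleNull`
permutes both universes; this preserves the topology and weight multiset
while randomizing both the AUC and the projection baseline, and the mean
null AUC lands at 0.5 as a sound negative control.

Fold-change correlation uses Spearman's rank test (monotone association,
no linearity assumption) plus an OLS slope t-test, with 10 equal-count
bins across the fold-change axis for display. Fold changes are used as
supplied; `abs_foldchange = TRUE` folds over- and under-expression
together, since expression databases mix both signs and either x-axis
convention is defensible.

# Community / class alignment

Communities come from weighted Louvain (shared counts as weights).
Louvain is order-dependent, so a fixed RNG seed is mandatory and part of
every API. Mutual information between the community partition $C$ and
the disease-class partition $D$,

$$I(C;D) = \sum_{c}\sum_{d} p(c,d)\,\log_2 \frac{p(c,d)}{p(c)\,p(d)},$$

is the raw plug-in estimate in bits from the contingency counts — no
bias correction, matching the quantity as originally defined. Plug-in MI
is biased upward on finite samples, which is precisely why the
randomized baseline matters: each of the (default 100) replicates
re-runs the full shuffle → threshold → project → threshold → Louvain
pipeline and the observed MI is judged against the baseline mean and sd.
The baseline re-runs Louvain per replicate because the pipeline order
implies it; diseases missing from the class map are excluded (with a
count) rather than imputed. Subnetwork analyses (`classSubnetwork()`)
re-run Louvain on the induced subgraph of one broad class rather than
reusing full-graph communities, since subtype structure is a
within-class question.

# The synthetic benchmark

`generatePlantedNetwork()` emulates exactly the statistical structure
the diffusion method assumes: disease classes whose genes form PPI
modules (a stochastic block model with within-module probability
`p_within = 0.3` against background `p_between = 0.01`), class miRNAs
that target their own module densely (`p_target_in = 0.5`, with a
guaranteed minimum of one in-module target so every miRNA is reachable)
and everything else sparsely (`p_target_out = 0.02`), diseases that draw
`seeds_per_disease = 5` seed genes from their class module, ground truth
marking each disease's class miRNAs as positives, and fold changes
generated as $1 + \text{in-class targeting degree} + \mathcal N(0,0.5)$
so the fold-change analysis has a planted monotone signal to recover
(only the rank structure matters for Spearman; the scale is arbitrary).
The default benchmark uses 2 classes, 20 genes per module, 5 miRNAs per
class, 40 background genes and 10 diseases per class — small enough to
run in seconds, large enough that 20 diseases give stable community and
null statistics. Connectivity is guaranteed by adding minimum bridge PPI
edges between components (deterministic, unlike resampling); with 20-gene
modules at `p_within = 0.3` the modules themselves are essentially always
connected, so bridges mostly attach stray background genes.

What the generator does *not* emulate: scale-free degree distributions,
literature bias toward well-studied miRNAs, tissue specificity, and the
sheer scale of the real databases. Passing recovery tests on this
benchmark therefore demonstrates that the implementation correctly
exploits modular diffusion structure — not that real-data performance
numbers transfer. On the default benchmark the pipeline recovers the
planted truth with mean per-disease AUC ≥ 0.9, the planted classes with
MI far above the randomized baseline, and degrades monotonically as
`p_target_out` noise grows; with zero cross-class wiring
(`p_target_out = 0`, `p_between = 0`, no background) every disease
reaches AUC 1 because class miRNAs are the only miRNAs reachable from
class seeds. Synthetic-mode analyses select thresholds by density
matching (bipartite target 0.5 — keep the top half of each ranking —
and projection target 0.5) rather than borrowing the real-data absolute
cutoffs.

# Problem sizes and determinism

The shipped tests and the acceptance script run on benchmarks between
~50 and ~500 nodes with 100-replicate null models; every stochastic
step takes an explicit integer seed (no wall-clock defaults), child
seeds are derived reproducibly from a master seed, and the RNG state of
the calling session is always restored. `runPipeline()` writes
`metrics.json` byte-identically for identical configs.

# Known limitations

- Edges are unweighted; PPI confidence scores and weighted disease-gene
  associations are ignored by design (no principled weighting scheme is
  part of the method).
- Identifiers are opaque strings; no miRBase/HGNC harmonization is
  attempted, and an id colliding between the miRNA and protein universes
  is an error (or renamed on request) rather than silently merged.
- Plug-in MI is biased on small projections; compare against the
  bundled randomized baseline, never against zero.
- The negative set "every non-positive miRNA" understates performance
  when ground truth is incomplete — true associations missing from the
  database count as false positives.
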