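---
title: "Methods: vote-count meta-analysis with a connectivity-weighted overlap null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vote-count meta-analysis with a connectivity-weighted overlap null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votenet)
```

## The problem

Bulk transcriptomic studies of multiple-sclerosis white matter (and many
other tissues) rarely share raw data in a form that supports a pooled
re-analysis: platforms differ (microarray, RNA-seq, RT-PCR), tissue
classifications differ, and often only the filtered DEG lists survive in
supplements. What can be integrated is the *lists*. `votenet` formalizes a
list-level integration: vote counting to rank genes by cross-study
agreement, a resampling null to decide whether the observed overlap between
lists is surprising, and network analyses to organize the recurrent genes
into complexes and hubs that can be checked against in-vivo perturbation
evidence.

Because no combined effect size or combined p-value is estimable from
heterogeneous filtered lists, the package deliberately does not attempt
one; the ranking is ordinal and the inference is about overlap counts.

## Ingestion model

A canonical record is one gene's report in one comparison of one study:
log2 fold change, p-value, adjusted p-value, comparison label
(`NAWM_vs_ctrl`, `AL_vs_ctrl`, `CAL_vs_ctrl`, `other`), and the comparison's
sample counts. Choices worth stating:

* **Fold-change scale.** All records are stored on the log2 scale. Linear
  fold changes convert as `log2(x)` for `x > 0` and, for sign-magnitude
  down-regulation reporting ("2-fold down" written as −2), `−log2(|x|)`.
  The source scale is declared per study (`fc_scale`), because published
  tables are silent about it more often than not.
* **Filtering.** The default policy keeps |log2FC| > 1 and p < 0.05
  (strict inequalities). Three alternative modes cover studies usable only
  through a linear fold-change threshold (kept when the linear magnitude is
  ≥ the cutoff, default 2.5), a plain p-value threshold, or a
  Benjamini–Hochberg adjusted threshold. A record lacking the field a mode
  needs is excluded *and counted*, never silently kept.
* **Within-study merging.** A gene reported by several comparisons of one
  study keeps the record with the highest |log2FC|. An exact tie with
  opposite signs is resolved by a fixed comparison priority — CAL > AL >
  NAWM > other, the later lesion stages carrying the larger lists — flagged
  in the output and warned about. Determinism was preferred over silent
  arbitrariness; the flag makes the handful of affected genes auditable.
* **Identity.** Genes are keyed by Entrez id downstream; the symbol is
  display-only. The mapping is a local two-column table plus manual
  overrides (overrides win), so no network service is ever consulted.

## Vote-count ranking

Per gene, the study lists that contain it vote by fold-change direction.
The modal direction defines the agreeing subset; `n_agree` is its size; an
exact tie makes the gene *inconsistent* (`n_agree = 0`). Ranking is
lexicographic: `n_agree`, then the sum of samples over agreeing
comparisons, then |mean log2FC| in agreement, with Entrez id as a final
deterministic tie-break and inconsistent genes after all consistent ones.

Two readings were genuinely open:

* *Partial agreement.* A gene up in three lists and down in one is counted
  as agreeing in three (modal rule), not as globally inconsistent. This
  preserves both an agreeing count and an inconsistent category, which is
  what published overlap tables report.
* *"Samples".* Studies count both donors and tissue samples; the package
  reads criterion (ii) as tissue samples by default and accepts
  `samples_unit = "donors"` where donor columns exist.

The overlap profile exposes two totals: `total_multi` (direction-consistent
genes in ≥ 2 lists) and `total_multi_any` (genes in ≥ 2 lists regardless of
direction). The distinction matters for testing, below.

## The Monte Carlo overlap null

For each of `iterations` (default 10,000) iterations, one gene list per
study is drawn from the universe without replacement, each with its
observed size; genes present in ≥ 2 sampled lists are counted in total and
by exact level k. Summaries are the mean, SD and empirical 2.5/97.5
percentiles of the integer counts. The empirical p-value for an observed
count uses the add-one permutation convention, `(r + 1)/(N + 1)`, and is
rendered as the bound `p < 1/N` when no null draw reaches the observation.

* **Weighted sampling.** Under the weighted mode genes are drawn with
  probability proportional to a connectivity score, by successive
  renormalized draws. The implementation uses exponential keys — the `s`
  smallest values of `Exp(1)/w_i` are exactly the genes a sequential
  renormalized scheme would select — which reduces each list from
  O(universe × size) to one sort. Tests verify the draw frequencies against
  exact enumeration of the sequential probabilities on small universes.
* **Directions.** The null draws gene *identities* only; the default test
  statistic is therefore `total_multi_any`, the identity overlap, compared
  against an identity null. Using the direction-consistent count against an
  identity null would be systematically conservative. For a direction-aware
  test, `simulate_directions` assigns independent random signs (per-list
  up-fractions) and the null then counts majority-consistent overlap.
* **Null independence.** Lists are mutually independent; no study-level
  correlation structure is simulated.

### Why connectivity weights

Genes are not exchangeable: co-expressed genes travel together into DEG
lists, so a uniform null understates chance overlap and overstates
significance. Connectivity is measured on a weighted co-expression network
over the universe: Pearson correlation, soft-threshold adjacency
`a_ij = |cor_ij|^β` (unsigned by default; signed available), topological
overlap `TOM_ij = (ℓ_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij)` with
`ℓ_ij = Σ_u a_iu a_uj`, and per-gene connectivity `k_i = Σ_{j≠i} TOM_ij`
(adjacency-based connectivity is a config alternative). β is the smallest
power in 1..20 whose signed scale-free fit R² reaches 0.8; the fit bins
connectivities on the linear scale (equal-width bins) and regresses
log10 p(k) on log10 k, which is the conventional fit index for this model.
If no power reaches the target the best-fitting power is used with a
warning. Genes present in DEG lists but absent from the expression universe
receive the universe's median connectivity (flagged), since excluding them
would shrink the universe asymmetrically.

The weighted and uniform nulls are run side by side with a shared seed
schedule (`compare_sampling_modes()`); heterogeneous weights concentrate
draws on high-connectivity genes and raise the null overlap, which is the
point: the weighted test is harder to pass for co-regulated genes.

## MCODE-style complex detection and hubs

Vertex weights follow the core-clustering-coefficient scheme: for nodes
with degree ≥ 2, the density of the highest k-core of the closed
neighbourhood times that core's order. Clusters grow greedily from the
highest-weight unused seed, admitting neighbours within 20% of the seed
weight (node score cutoff 0.2) breadth-first to depth 100; a node joins at
most one cluster. Clusters without a 4-core are discarded; haircut (on by
default) removes singly-connected members in a single pass — so it never
removes a node with in-cluster degree ≥ 2; fluff (off by default) adds
boundary nodes whose *open* neighbourhood density exceeds 0.3. The open
neighbourhood matters: with the candidate's own spokes included, any sparse
hub of degree ≥ 5 would qualify on its own star. Fluff is the right switch
when complexes are dense but incomplete (edge probability < 1), which is
why the synthetic-recovery analyses enable it; on clean cliques it changes
nothing.

Betweenness centrality is normalized per connected component by
`(n−1)(n−2)/2` and candidate hubs are nodes above 0.5 on the whole graph
(`scope = "whole_graph"`; a per-cluster scope exists for sensitivity). The
0.5 threshold is demanding: on graphs without a dominating bottleneck the
candidate set can legitimately be empty. Each cluster's main hub is its
member with maximal betweenness, ties to the lower node id.

## Perturbation evidence

The classification is a pure truth table over five perturbation classes and
three outcomes: reduced activity (knockout, knockdown, inhibiting
treatment) followed by amelioration, or increased activity
(overexpression, activating treatment) followed by exacerbation, is
*detrimental* evidence; the reverse pairings are *beneficial*; no-effect
outcomes are neutral. Per-gene tallies report all three counts plus a net
label; balanced nonzero opposing evidence is *mixed* rather than forced to
a side, and genes with only neutral evidence are *none*. The literature
search that produces the annotation table is out of scope; the module
consumes the table.

## The synthetic generator

The generator emulates, at desk scale, a nine-study white-matter
meta-analysis and is the package's test bed. Its defaults are fixed study
conditions, not tuning knobs:

* Universe of 2,000 Entrez-style genes; 50 planted genes, each entering a
  given study list with probability 0.6 and carrying its true direction
  with probability 1.0; background genes drawn uniformly with a 0.5 up
  fraction; all |log2FC| > 1 and p < 0.05 so records pass the default
  filter, isolating the ranking and testing stages from the filter.
* List sizes 50–80 per study. This is the published list-to-universe ratio
  (a few hundred genes against a 15–20k universe, i.e. 3–5%) scaled to the
  2,000-gene universe, and keeps the planted set no larger than the
  smallest list.
* Expression matrix of 50 samples with a latent-factor block structure:
  gene = √ρ·factor + √(1−ρ)·noise gives expected within-module correlation
  ρ (default 0.7) in closed form. Modules have geometrically decaying sizes
  (ratio 0.7) over 75% of the universe; the remaining quarter is
  unstructured noise. The size decay makes the soft-thresholded degree
  distribution decay like a real co-expression network, so the scale-free
  fit target is reachable, and the module/background split keeps
  connectivity heterogeneous — which is what the weighted-vs-uniform
  comparison needs. Planted genes sit inside modules by default
  (`plant_in = "modules"`), stressing the weighted null; a uniform
  placement is available.
* Interaction graphs plant Erdős–Rényi-dense complexes (edge probability
  0.9) of sizes 25/20/15 over disjoint gene subsets on a 0.05 background.
  Complexes touch the rest of the network only through background nodes:
  with direct complex-to-complex background edges a single chance bridge
  would merge two dense complexes under any seeded-expansion algorithm.
  The sizes are chosen so each complex almost surely contains the 4-core
  the MCODE filter demands (a 6-node block at p = 0.9 contains one only
  ~85% of the time; ≥ 7 nodes is safe, and the larger defaults also keep
  the per-node weight spread inside the 20% expansion tolerance).
* Perturbation tables are generated by inverting the classification truth
  table from a per-gene ground truth, so classification accuracy has a
  known target of 1.

What the generator does *not* emulate: platform-specific noise, probe-level
artifacts, donor overlap between studies, correlated study lists (each
study samples background genes independently), or realistic gene-length /
expression-level biases. Passing tests therefore show the pipeline's logic
is correct under its own assumptions, not that any particular biological
dataset satisfies those assumptions.

## Statistical power at desk scale

One property of the overlap statistic deserves emphasis. The total count
of genes in ≥ 2 lists is barely sensitive to a planted signal at this
scale: 50 planted genes occupy list slots that background genes would
otherwise fill, so the planted co-occurrences displace almost exactly as
many chance co-occurrences as they add. Published analyses at full scale do
not face this because real lists share hundreds of genes beyond any small
core. The *deep* overlap — genes in ≥ 3 lists — is where a planted
consistent signal is essentially unreachable by chance (null mean ≈ 5
against ≈ 50 observed at defaults), so the end-to-end recovery test asserts
the empirical p at level ≥ 3, and `empirical_pvalue()` takes a `min_level`
argument for exactly this purpose. The total-level tests are still
computed and reported by the acceptance script.

Calibration is checked the only way an identity null can be checked: when
observed lists are drawn by the same mechanism as the null, p-values over
200 replicates are uniform (Kolmogorov–Smirnov). With no planted genes the
generator's observed identity overlap sits inside the null 95% band at the
nominal rate.

## Numerical choices and degenerate inputs

* Zero-variance expression rows are an error naming the gene; correlation
  needs ≥ 3 samples.
* The soft-threshold scan with no structure (near-identity correlation)
  has an undefined or failing fit for every power; the scan warns and
  falls back to the best-fitting (or smallest) candidate.
* Blocked TOM computation (`block_size`) agrees with the unblocked product
  to machine precision (tested at 1e−14); exact bit-identity across block
  sizes is not promised because BLAS kernels differ by operand shape.
* Empirical CIs use type-1 (inverse-ECDF) quantiles so bounds are observed
  integer counts.
* All cluster, ranking and hub orderings carry explicit deterministic
  tie-breaks (node/gene id), so identical inputs give identical output
  files; every simulation is reproducible from `seed`.
* Problem sizes in the shipped tests (universe 2,000, 10,000-iteration
  nulls where the claim demands them, 150-node graphs, 200-replicate
  calibration at 1,000 iterations) were chosen so the full suite documents
  the method at realistic scaled-down size while remaining quick to run.

## Known limitations

* Vote counting ignores effect-size precision and study quality; a
  3-sample RT-PCR comparison votes like a 40-sample RNA-seq study, except
  through the sample-sum tie-break.
* The overlap null conditions on observed list sizes and treats lists as
  independent; shared donors or shared platforms between studies would
  inflate the observed overlap without inflating the null.
* The connectivity weighting inherits every WGCNA modelling choice
  (network type, β, correlation estimator); these are config-exposed but
  the defaults are one reasonable parameterization, not a fitted one.
* MCODE with the standard strict parameters (score cutoff 0.2, k-core 4)
  fragments dense-but-incomplete complexes below ~15 nodes; fluff
  mitigates but does not eliminate this.
* The perturbation module classifies what it is given; it does not read
  the literature, and annotation errors propagate directly.
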