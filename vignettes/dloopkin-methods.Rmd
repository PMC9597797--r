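---
title: "Tracing breed kinship from D-loop trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing breed kinship from D-loop trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Mitochondrial control-region (D-loop) haplotypes are the classic marker for
maternal lineages in livestock. In sheep, five deep maternal clades — the
haplogroups A to E — predate domestication, so most of the variance between
any two breeds reflects haplogroup composition rather than recent shared
history. Two complementary summaries are therefore used side by side:

* **phylogenetic connection counts**, which look only at the *local* topology
  of a tree of individual haplotypes and ask how often individuals of two
  breeds are immediate phylogenetic neighbours — a signal of recent maternal
  exchange that is largely insensitive to haplogroup frequencies; and
* **pairwise ΦST**, the molecular-variance fixation index, which measures
  overall differentiation and *is* dominated by haplogroup composition.

`dloopkin` implements both, together with the input-preparation steps
(database dedup rules, end trimming, conserved-block masking, missing-data
filters), haplogroup assignment from a reference-anchored tree, ordination
and clustering of the resulting matrices, and a structured-coalescent
simulator used to validate the whole chain against known truth.

## Connection counting

Given a rooted tree whose tips are individual sequences labeled by breed:

* a **type-1 connection** joins the two tips of a *cherry* (an internal node
  whose children are exactly two tips) — "strictly sister sequences";
* a **type-2 connection** arises at every internal node whose two children
  are a tip *t* and a cherry *{x, y}*: it contributes the two links *t–x*
  and *t–y*. The internal *x–y* pair is deliberately **not** re-counted by
  type 2 — it is already a type-1 link — so the two matrices stay
  independently interpretable.

Counts accumulate into a symmetric breed × breed matrix; within-breed links
sit on the diagonal. Between-breed links increment both mirrored cells, so
the upper triangle plus diagonal of the type-1 matrix sums to the number of
cherries, and of the type-2 matrix to twice the number of triples.

Likelihood programs export strictly binary trees, but `find_type1_pairs()`
generalizes to polytomies (all tip pairs under a multifurcating node) and
says so with a `message()`, because silently different counts on a
multifurcating input would be worse than a noisy generalization. Sisterhood
is read off the rooted tree exactly as exported, and the root's own children
are eligible nodes.

Per-breed **profiles** (`breed_profile()`) merge partners by a region map,
express counts as percentages of the focal breed's total, and retain
partners greedily (largest first) until a retention fraction — default 0.77
— of the links is covered; this mirrors the usual histogram presentation of
such counts. Profile rows are compared across breeds either by
`1 - Pearson correlation` (excluding the two self cells pairwise) or by the
similarity transform `1 - count / max(count)`.

## ΦST by analysis of molecular variance

For two populations with `N` sequences in total, and `d(i, j)` the count of
differing resolved positions (pairwise deletion of `-`, `N`, `?`):

* `SSD_total = Σ d²/(2N)` over ordered pairs, `SSD_within` the analogous
  per-population sum;
* `σ²_w = SSD_within / (N − P)` with `P = 2`;
* `σ²_a = (SSD_among/(P − 1) − σ²_w) / n̄`, where
  `n̄ = (N − Σ n_p²/N)/(P − 1)`;
* `ΦST = σ²_a / (σ²_a + σ²_w)`.

A plain difference count is used rather than a model-corrected distance:
haplotype data in molecular-variance analyses conventionally default to it,
and on the short, closely related sequences involved the correction is
negligible relative to the sampling noise. Negative estimates are a normal
finite-sample outcome and are reported as computed (a `clamp_negative` flag
exists, and the pipeline clamps at zero only where a dissimilarity input is
required, i.e. before NMDS/UPGMA). When the total molecular variance is
exactly zero the statistic is undefined; it is reported as 0 with a warning
rather than `NaN`, since "no variance" operationally means "no
differentiation". Before the matrix is computed, populations with fewer than
3 individuals are removed, then alignment columns with more than 5% missing
data — in that order, matching standard practice for these filters.

A permutation test (`phi_st_permutation_p()`) with the `(b + 1)/(n + 1)`
correction is provided as the standard companion, although the connection
analysis itself does not rely on it.

## Trees, distances, haplogroups

`parse_newick()`/`write_newick()`, `nj_tree()` and `root_with_outgroup()`
wrap the corresponding `ape` machinery with stricter validation (duplicate
tips, unbalanced parentheses with position, symmetric input, outgroup
monophyly on the unrooted tree). One behaviour is added on top of `ape`:
rooting splits the attachment branch *evenly* between the two root edges, so
re-rooting an already-rooted tree is a no-op topologically and in length.

K2P distances use the closed form
`d = ½ ln 1/(1 − 2P − Q) + ¼ ln 1/(1 − 2Q)` over shared resolved sites.
Because public-database D-loop fragments differ in coverage, the
dataset-level `k2p_matrix()` rejects pairs sharing fewer than 50 resolved
sites (a spuriously short overlap produces spuriously short distances); the
single-pair `k2p_distance()` exposes `min_shared` with a permissive default
so that small worked examples remain computable. The NJ builder is a
deliberate desk-scale surrogate: a production analysis should feed an
externally estimated ML tree to `pipeline_config(tree = ...)`, which then
takes precedence (and the log records that the NJ stage was skipped).

Haplogroup assignment walks from each query tip rootward to the smallest
ancestral clade containing at least one reference; if all references in that
clade agree, their haplogroup is assigned (`method = "clade"`). Mosaic
clades fall back to the nearest reference by patristic distance
(`method = "nearest"`), which requires branch lengths — a topology-only tree
errors there rather than guessing. The clade rule comes first because
assignment should follow tree structure, not raw distance; the fallback only
resolves clades that the references themselves render ambiguous.

## Ordination and clustering

NMDS minimizes Kruskal stress-1 with monotone (isotonic) regression, via
`vegan::monoMDS`, from a classical-scaling start plus random restarts
(default 20) under a caller-supplied seed; the best configuration is
returned with its stress, centered at the origin. NMDS is non-convex, hence
the restarts and the recorded seed. UPGMA uses average-linkage `hclust` with
heights halved on conversion to a tree, so cophenetic distances reproduce
ultrametric inputs exactly; dendrograms are exported as Newick so any tree
viewer applies.

## The conserved-block mask

`conserved_block_mask()` is a faithful-in-spirit re-implementation of the
classic conserved-block selection used before tree building, not a
byte-compatible clone. With `n` sequences, a column is *conserved* when its
majority residue count reaches `floor(n/2) + 1` and *highly conserved* at
`ceiling(0.85 n)`; retained columns form blocks of ≥ 10 columns whose
termini are highly conserved, containing no run of > 8 non-conserved
columns; with `allow_gaps = FALSE` (default) a gap-bearing column is never
retained, even inside an otherwise kept block. All thresholds are exposed,
so the ~91% retention typical of published control-region alignments can be
approached or tightened at will. Column reports are 1-based inclusive;
internally coordinates are 0-based half-open.

## The simulator

`sim_config()`/`simulate_dataset()` generate data with exactly the structure
the analysis assumes, plus a truth table:

* **haplogroups** are deep clades joined along a fixed pectinate backbone,
  so clade identity is unambiguous across seeds;
* **breeds** coalesce internally (Kingman, time scale `within_depth`,
  default 1) until `split_depth` (default 10), then surviving lineages join
  their haplogroup's pool. The default split depth makes breeds essentially
  monophyletic, the regime in which haplogroup assignment is well-posed;
  shallow values (≪ 1) model breeds drawing on a shared ancestral pool;
* **introgression pulses** re-assign a stated fraction of a recipient
  breed's lineages (rounded, at least one) to coalesce within the donor —
  a discrete event with an exact truth table, rather than a continuous
  migration rate;
* **mutation** is Poisson on branches at rate θ/2 per lineage per coalescent
  unit (so a pair from one deme carries θ differences in expectation), with
  gamma site-rate multipliers (shape 0.2 by default — the strong rate
  heterogeneity of the control region) and an HKY jump kernel (κ = 20,
  transition-biased as in mammalian mtDNA; base frequencies 0.33/0.26/0.13/
  0.28). Defaults: 20 breeds of 10, 789 sites, θ = 5 — a dataset of the
  scale and diversity of a typical multi-breed control-region compilation.

Coalescent-unit time with θ scaling (no explicit Ne or µ) keeps the
expectations closed-form: the two-tip check `E(pairwise differences) = θ`
holds up to the small multiple-hit deficit expected on a finite sequence.

What the simulator does **not** emulate: alignment error and indel
placement, sequencing artifacts, uneven GenBank sampling, recombination
(mtDNA is clonal), selection, and demographic growth. Passing
recovery tests therefore validates the statistical chain — they do not
certify behaviour on misaligned or heavily incomplete real data, which is
what the QC filters are for.

## Validation design and problem sizes

The test suite checks every statistic against an independent oracle written
as a direct transcription of its defining rule: exhaustive cherry /
tip-plus-cherry enumeration on random coalescent trees (up to 200 tips),
brute-force AMOVA sums over all ordered pairs (to 1e-10), step-by-step
average-linkage agglomeration, and window enumeration for the block mask.
Recovery experiments run at deliberately modest sizes chosen to keep the
default suite fast while leaving the conclusions unambiguous: haplogroup
recovery on 10 breeds × 8 tips × 5 clades (≥ 99% of tips correct with one
reference per clade); introgression detectability as a one-sided sign test
over 50 paired seeds of a 3 × 8-tip design (pulse 0.5); and the
shared-ancestry check on two 20-tip breeds drawing on one nearly panmictic
pool (`split_depth = 0.05`) against a deep outgroup breed, where the
NJ → type-2 chain must rank the sharing pair first in ≥ 95% of 100
replicates. `scripts/acceptance.R` re-runs the same designs from a single
command-line seed.

## Known limitations

* Connection counts are conditional on one estimated tree; no uncertainty
  (e.g. bootstrap over trees) is propagated.
* The type-2 statistic is sparse on small samples: absence of links is weak
  evidence of absence.
* `ΦST` uses plain difference counts; highly saturated or heavily gapped
  alignments deserve model-based distances upstream.
* The NJ builder is for synthetic validation and quick looks, not a
  substitute for a proper likelihood tree on real data.
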