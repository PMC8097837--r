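---
title: "Gene-level metagenomics with co-abundant gene groups: models and methods"
author: "cagpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level metagenomics with co-abundant gene groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `cagpipe`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

# The analysis model

## Multi-mapping read resolution

Short reads aligned against a deduplicated protein gene catalog often hit
several homologous genes comparably well. `resolveMultimappers()` settles
each read on a single gene by iterative reweighting guided by evenness of
sequencing coverage. Genes that are truly present accumulate reads across
their whole length; decoy homologs receive scattered hits that cover only
fragments. Each candidate gene is scored as

\[ E_g = \frac{\bar c_g}{1 + \mathrm{CV}(c_g)} , \]

where \(c_g\) is the per-amino-acid-position coverage implied by the
current read weights, \(\bar c_g\) its mean and \(\mathrm{CV}\) its
coefficient of variation. Weights start proportional to alignment score;
each iteration reassigns every read's full weight to its best-scoring
candidate, stopping at a fixed point of the assignment, when the largest
weight change drops below `tol` (default `1e-6`), or after `max_iter`
(default 100) iterations. Ties break toward the lexicographically smaller
gene identifier, so resolution is deterministic. Resolution is independent
per specimen: the same gene can win a read in one specimen and lose it in
another, which is the desired behaviour when community composition
differs.

Two consequences worth knowing: a uniquely mapping read is always kept on
its only candidate, and a gene supported by a single stray read can lose
that read to a well-covered homolog — the procedure deliberately trades a
small false-negative rate at the detection margin for a large reduction in
false positives from spurious homology.

Depth uses fully resolved (single-gene) assignments, not fractional
weights: depth is \( \sum \text{aligned nucleotides} / (3 \times
\text{length}_{aa}) \), and relative abundance normalizes depth within a
specimen. Aligned bases are counted in nucleotides against the amino-acid
axis of the catalog (factor 3), and coordinates are 1-based inclusive,
matching GFF conventions used downstream.

## Clustering into co-abundant gene groups

Genes detected in at least one specimen (depth > 0, no minimum-depth
threshold) are clustered by average-linkage agglomeration under the cosine
distance between depth profiles, merging while the minimum average
pairwise distance is at or below the threshold (inclusive). Cosine
distance is the natural choice for depth profiles: it is insensitive to
the overall abundance scale of a gene and measures only the shape of its
profile across specimens.

Exact agglomeration is quadratic, so `shardedCluster()` uses the
multi-round scheme: in each of the first `n_rounds - 1` (default 4)
pre-clustering rounds, genes (later, cluster centroids) are assigned to
shards of at most `shard_size` members and clustered exactly within each
shard at the stringent threshold \( \tau/2 \); each cluster is replaced by
the unweighted mean depth profile of its member genes and shards are
reshuffled. The final round applies the user-specified \( \tau \) globally.
Because pre-rounds use half the threshold, the final CAGs are supersets of
the tight early-round groups, which bounds the damage a bad shard split
can do. The final threshold \( \tau \) is deliberately a required argument
with no default — it is the single most consequential user decision.

Design choices that were open:

* **Shard assignment** is a deterministic hash of (centroid id, round,
  seed), so the partition is invariant to the order genes arrive in, and
  reshuffling between rounds is automatic.
* **Cluster representative** between rounds is the unweighted mean member
  profile — simple and adequate for cosine geometry.
* **The neighbour pre-filter** in the final round generates candidate
  pairs from each centroid's exact top-`ann_neighbors` (default 20)
  cosine neighbours, computed with one matrix product. Exact retrieval is
  affordable at the centroid counts the final round sees and is strictly
  conservative: restricting candidates can only miss merges, never create
  wrong ones, and exact average-linkage distances are recomputed for every
  candidate pair. `exact_final = TRUE` removes the restriction and is the
  reference path for verification.
* **Tie-breaks** in merge order follow the deterministic first-minimum
  scan of the working distance matrix over rows sorted by gene id.
* **CAG naming** ranks groups by descending member count, ties broken by
  smallest member gene id (`CAG00001` is the largest group).

CAG abundance is the summed member depth divided by the specimen's total
depth over all detected genes, so CAG abundances, like gene relative
abundances, are per-specimen probability vectors.

## Per-CAG association model

For specimen \(s\), let \(W_s\) be the reads resolved to genes of the CAG
and \(M_s\) the specimen's total resolved reads (reads assigned to the
catalog, not raw sequencer output). The model is

\[ W_s \sim \mathrm{BetaBinomial}(M_s, \mu_s, \phi), \qquad
   \mathrm{logit}(\mu_s) = X_s \beta , \]

with shapes \( a = \mu(1-\phi)/\phi \), \( b = (1-\mu)(1-\phi)/\phi \)
(mean/correlation parameterization) and a single overdispersion \(\phi\)
per CAG, on the grounds that the user's formula describes the mean only.
Fitting is maximum likelihood: a logistic-regression warm start, \(\phi\)
initialized at 0.01 on a logit internal scale, BFGS, standard errors from
the observed information. Wald p-values use a Student-t reference with
\( n - \#\text{parameters} \) degrees of freedom; at \(n = 50\) null
simulations put the normal reference at a rejection rate of about 0.059
and the t reference at 0.054 at \(\alpha = 0.05\), so the t reference is
the default. Degenerate CAGs (all-zero or all-saturated counts) are
flagged as separation and excluded from fitting and FDR; non-converged
fits are likewise excluded from the BH adjustment, which is the standard
step-up procedure (`p.adjust(method = "BH")`).

## Taxon- and function-level aggregation

Each annotation label collects the fitted coefficient \(y_c\) and standard
error \(se_c\) of every converged CAG containing at least one gene with
that label (a CAG carrying several labels contributes to each). The
errors-in-response model is

\[ y_c = \beta_0 + \varepsilon_c + u_c, \qquad
   u_c \sim N(0, se_c^2)\ \text{known}, \quad
   \varepsilon_c \sim N(0, \sigma^2)\ \text{estimated} , \]

with \((\beta_0, \sigma^2)\) estimated by profile maximum likelihood
(\(\sigma^2\) constrained to \([0, \infty)\); boundary estimates are
reported with a `clamped` flag). The reported `se0` is the conventional
inverse-variance standard error \( (\sum w_c)^{-1/2} \),
\( w_c = 1/(\sigma^2 + se_c^2) \), which matches standard random-effects
meta-analysis output. The test of \(\beta_0 = 0\), however, uses the
Knapp–Hartung adjusted statistic (scaled variance estimator, t reference
with \(k - 1\) degrees of freedom): in null simulations with \(k = 15\)
CAGs per label the plug-in normal Wald test rejected at ~0.12 instead of
0.05, while Knapp–Hartung sits at ~0.058 — the plug-in test is simply not
calibrated at realistic CAG counts, so the package deviates from the
plainest plug-in design on this one point.

## Genome islands

Member genes of significant CAGs (default FDR threshold 0.01) are located
on reference genomes via gene-to-genome alignment tables, filtered at
`min_identity` (default 90%) and, when the catalog supplies gene lengths,
`min_coverage` (default 50% of the gene's nucleotide length) — mirroring
the thresholds used to build deduplicated catalogs. Islands are
single-linkage merges along the genome: alignments whose intervals are
separated by a gap of at most `max_gap` join one island, with the gap
defined as \( \text{start}_2 - \text{end}_1 - 1 \). The default
`max_gap = 5000` bp tolerates a few unannotated or unassociated genes
inside an island while keeping islands well below typical
between-locus distances; it is exposed because no single value suits all
genome architectures. Strand is recorded but ignored for contiguity —
islands are physical regions. Islands never span contigs.

Per-genome summaries divide the union length (overlaps counted once, via
interval reduction) of associated-gene alignments by the genome length. A
CAG present (≥ 1 member-gene alignment) in at least
`core_genome_fraction` (default 0.9) of the focal taxon's reference
genomes is classified core, otherwise accessory. GFF3 features that
overlap an island by at least one base are attached verbatim (type and
product text); GFF files are structurally pre-validated so malformed lines
are reported with their line number.

# The synthetic-data generator

`generateExperiment()` emulates the data model the pipeline consumes, with
every stage's truth recorded:

* **Community**: genes are partitioned into CAGs (sizes drawn from a
  gamma profile, minimum 2). Each CAG has a log-normal base abundance
  (`baseline_sigma = 0.75`) and an independent per-specimen log-normal
  fluctuation (`specimen_sigma = 0.8`) shared by its member genes — the
  fluctuation is what makes member genes co-abundant and distinct CAGs
  separable under cosine distance. These values were fixed by an upfront
  design computation: they put between-CAG cosine distances comfortably
  above usable thresholds (mean separation \( \approx 1 - e^{-\sigma^2}
  \)) while keeping the lowest-abundance CAGs powered for the default
  effect size (see below). Notably, larger `specimen_sigma` does **not**
  monotonically improve separability — heavy-tailed profiles become
  dominated by single specimens and collide by chance.
* **Outcome effect**: a binary outcome shifts the latent relative
  abundance of `n_associated` CAGs on the logit scale by `effect_size`
  (default 1.5). Signs are allocated greedily so the expected total
  community abundance is balanced between groups; without this, the
  compositional renormalization would impose a genuine opposite shift on
  every unassociated CAG and "false positives" against the planted truth
  would not actually be false.
* **Read sampling**: per specimen, CAG proportions receive beta-binomial
  wobble at dispersion `phi` (default 0.01), reads (default 20,000 per
  specimen) are drawn multinomially over CAGs and then over member genes
  proportionally to gene length, so depth is even within a CAG. Read
  positions are uniform along the gene.
* **Multi-mapping**: a fraction (default 0.05) of reads receives a second
  alignment, at slightly lower score, to a deterministic homolog in a
  different CAG.
* **Genomes**: one contiguous island of an associated CAG's genes
  (default 18 genes at 400 bp spacing, spanning ≈ 20 kb) is planted on a
  subset of reference genomes (default 2 of 5, i.e. accessory), one
  unassociated CAG is placed on every genome (core), background genes
  from unassociated CAGs are scattered at ≥ 6 kb spacing, and GFF3
  features (including a labelled secretion-system feature inside the
  island) are emitted.

With the default 40 + 40 specimens the lowest-abundance CAGs have logit
shifts detectable at roughly \(z \gtrsim 3\) (per-specimen logit variance
\( \approx \sigma_{spec}^2 + \phi/\mu \)), which is what makes the
default experiment an informative end-to-end check rather than a coin
flip.

What the generator does **not** emulate: real catalogs are orders of
magnitude larger; gene lengths, abundances and overdispersion are not
log-normal/beta-binomial in any exact sense; homology is pairwise rather
than a similarity continuum; reference genomes have no gene content
beyond what is planted; and there is no sequencing error, assembly noise
or annotation error. Passing tests therefore demonstrate correctness of
the algorithms under the stated model, not performance guarantees on any
particular real dataset.

`generateBlockProfiles()` skips read-level sampling entirely and emits
depth matrices with planted blocks (block-level log-normal profile at
`specimen_sigma = 1`, per-gene multiplicative noise `noise_sd = 0.05`),
for clustering studies where read noise is irrelevant. The scale study in
the tests and acceptance script uses 2,000 genes in 120 blocks over 100
specimens — sizes at which the exact oracle is still computable for
comparison while the sharded path is exercised across several rounds.

# Numerical and reporting choices

* Cosine distances are clamped to \([0, 1]\) against floating-point
  drift; zero-norm profiles are an error rather than a silent NaN.
* Merging uses the exact Lance–Williams average-linkage update; with a
  candidate restriction, a merged cluster inherits the union of its
  parents' candidate sets.
* The beta-binomial likelihood clamps \(\mu\) and \(\phi\) to
  \([10^{-10}, 1 - 10^{-10}]\) inside the objective only.
* `phi` is reported on its natural \((0,1)\) scale; its sampling
  uncertainty is not reported (it is a nuisance parameter).
* All randomness in the generator and the shard assignment flows from a
  single integer seed; identical inputs and seed reproduce partition and
  fit tables bit-identically.
* The HDF5 results store writes matrices in long format (id columns plus
  value), which round-trips exactly; `/meta/params` records every
  threshold and seed of the run.
* Reporting views conventionally restrict to CAGs with at least five
  member genes; this is a display filter, never a fitting filter.

# Known limitations

* The evenness-EM reassigns whole reads; it does not model fractional
  assignment, and a truly shared region between two present homologs will
  be attributed to the better-covered one.
* Average linkage with an inclusive threshold is order-deterministic but,
  like all agglomerative schemes, not globally optimal; the sharded
  scheme adds a documented, conservative approximation on top.
* The beta-binomial model conditions on the specimen's total resolved
  reads; compositional effects of very large, strongly shifted CAGs are
  attributed to the remaining CAGs, as in any relative-abundance
  analysis.
* Island calls depend on `max_gap` and on the completeness of the
  gene-to-genome alignment table; a missing alignment can split an
  island.
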