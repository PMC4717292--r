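---
title: "Methods: from fungal signal metabolites to root sensor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fungal signal metabolites to root sensor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycolink)
```

## The inference problem

Ectomycorrhizal symbiosis begins before contact: plant root and fungus
exchange diffusible molecules across the apoplast, and the root commits
to a transcriptional response long before hyphae touch the root surface.
`mycolink` models that conversation as a chain of testable couplings:

1. the fungus *synthesizes* signal metabolites (inferred from its
   transcriptome via metabolic turnover scores),
2. root *sensor complexes* — receptor, cascade and transcription-factor
   proteins that are co-expressed and co-localized — detect them,
3. the complexes' transcription factors act through *binding motifs*
   upstream of
4. *co-regulated gene clusters*, whose enriched annotations are read as
5. the predicted *phenotype*.

Each arrow is estimated from a different data layer and joined by
explicit rules, so every edge in the final model carries one provenance
rule and its quantitative evidence (a shared gene list, a correlation
coefficient, or an enrichment p-value).

## Stage-by-stage model

### Bootstrap expression quantification

The quantifier consumes read-to-gene alignment tables in which
multi-mapped reads keep *all* their candidate genes. Each bootstrap
iteration resamples the $N$ aligned reads with replacement and assigns
every sampled multi-mapped read to exactly one candidate uniformly at
random; the per-gene RPKM is $10^9 c / (N L)$ for count $c$ and gene
length $L$ (bases). The mean and SD over iterations summarize the
estimate, and expression is significant when the lower normal tail at
zero is below $\alpha = 10^{-4}$ (uncorrected, by design — the
downstream filter demands significance in *every* sample, which is
already conjunctive).

Two deliberate choices:

* **Random single assignment, not fractional weighting.** Assigning a
  multi-mapped read to one candidate per iteration propagates mapping
  ambiguity into the bootstrap SD, which is the reason to bootstrap
  alignments at all. Fractional $1/k$ weighting is available
  (`fractional = TRUE`) and converges to the same means; it narrows the
  SD because the ambiguity is averaged out within each iteration. Under
  either rule a gene's per-iteration count is marginally
  $\mathrm{Binomial}(N, q)$ with $q$ the mean over reads of
  $[\text{gene} \in \text{candidates}]/k$ — the closed form the test
  suite checks against.
* **Degenerate SDs.** SD $= 0$ with mean $> 0$ yields $p = 0$; SD $= 0$
  with mean $= 0$ yields $p = 1$ (the limits of the normal tail). The
  RPKM denominator is the number of aligned reads in the sample, the
  only library-size proxy an alignment table carries.

The SAM reader uses only QNAME and RNAME: with an aligner reporting all
placements, the candidate *set* is the unit of information, so flags,
positions and qualities are ignored.

### Filtering, profiles, clusters

Genes enter clustering when (i) significantly expressed in all ten
in-house samples and (ii) coefficient of variation $\sigma/\mu > 0.33$
on the *untransformed* per-sample scale — CV is scale-dependent and is
defined on the measurement itself, not its logarithm. Replicates are
averaged per condition on the linear scale; the profile entry for
condition $c$ is $\log_2 \bar x_c - \overline{\log_2 \bar x}$, so every
profile is centred over equally weighted conditions. K-means uses
Euclidean distance, $K = 9$ and 50 restarts by default, keeping the
restart with the lowest within-cluster sum of squares. Initial centers
are drawn from the *distinct* profile rows, which makes noise-free
worlds (exactly repeated profiles) clusterable instead of aborting on
duplicate centers; restarts that still fail (e.g. an empty cluster under
Hartigan–Wong) fall back to Lloyd iterations and are otherwise redrawn,
so the returned clustering is always a total partition.

### Cumulative-binomial enrichment

Annotation and motif enrichment share one kernel:
$p = P(X \ge x),\; X \sim \mathrm{Binomial}(n_C, f)$, for a cluster of
$n_C$ genes with $x$ carriers against background frequency $f$. The
upper tail is forced by the semantics (over-representation); the
printed thresholds differ by use: $p < 0.05$ for annotation/phenotype
terms, $p < 0.01$ *and* $\ge 10$ carrier genes for motifs — the carrier
floor keeps a motif from being called regulatory when it merely
co-occurs in a handful of functionally related genes. The motif
background $f$ is computed over the differentially regulated (filtered)
gene set, not the whole genome, because that is the population clusters
are drawn from.

Motif scanning is strict IUPAC presence/absence on the forward strand of
the provided 1000 bp upstream regions: a match requires every motif
symbol's base set to contain the sequence base, an `N` in the *sequence*
is matched only by the motif wildcard `N` (an unresolved base must never
create a specific match), and multiplicity is deliberately not counted.
Reverse-complement scanning is available (`both_strands = TRUE`) but off
by default — the conservative reading when motif strand annotation is
inconsistent.

### Sensor-complex prediction

The co-expression network is rank-based: over the external compendium,
each allowed gene proposes edges to its top-5 Pearson partners (ranking
by $r$, boundary ties broken lexicographically by gene id for
determinism), and a proposal survives when the two-sided $t$-test on $r$
with $n-2$ df gives $p < 0.01$. The edge set is the union of proposals;
a reciprocity requirement is not imposed, matching the constant
neighborhood-size construction. Constant-expression genes are excluded
with a warning (their correlation is undefined).

Likelihood-of-interaction scores ask, for every unordered pair of
subcellular-localization labels, whether proteins so labelled interact
in the reference PPI set more often than chance. The null re-pairs the
pooled $2m$ edge endpoints into $m$ edges uniformly (a configuration-
model draw), which preserves every protein's degree in every iteration
and lets label pairings mix even when the observed list is structurally
bipartite; 10,000 iterations give $Z = (O - \mu_0)/\sigma_0$, with
$Z = 0$ when the null is degenerate ($\sigma_0 = 0$). Localization
labels come from predictor scores by argmax; score ties assign *all*
tied labels and compound predictions such as `nuclear:cytoplasm` are
split into both components. A candidate edge's LOI score is the
*maximum* $Z$ over the two proteins' label pairs — an interaction is
possible if any compatible compartment pairing supports it. Edges
survive when both proteins are significant in every in-house sample,
both carry an allow-listed sensing/signalling annotation, and LOI
$> 1$. Connected components of the surviving network are the predicted
complexes; node roles follow annotation precedence receptor →
transcription factor → defense → cascade. The functional allow-list is
a required configuration input (the generator ships a documented example
vocabulary); two-protein components are reported rather than dropped.

### Metabolic turnover

Enzyme-function (EC) abundance is the sum of quantile-normalized RPKM
over all gene models carrying the EC — a gene with $k$ EC labels
contributes fully to each, since each annotation asserts the function is
present. Reactions are restricted to allowed pathways; the signed
incidence counts, per (EC, metabolite), consuming minus producing
reactions, so a metabolite on both sides of one reaction nets to zero
(kept, flagged by a zero weight). Per EC and condition,
$\Delta_e(c) = \log_2 a_e(c) - \overline{\log_2 a_e}$ with a floor of
half the smallest positive abundance applied before the logarithm
(unexpressed conditions stay finite). The turnover score is

$$s(m, c) = \frac{1}{N_m} \sum_e w(e, m)\, \Delta_e(c),$$

with $N_m$ the number of expressed ECs touching $m$. The $1/N_m$
normalization is this package's normative definition — it keeps scores
comparable across metabolites of different connectivity while preserving
the sign semantics (positive = predicted consumption); the raw signed
sum sits behind `normalize = FALSE`. Reversible reactions are scored as
written (reaction rate is assumed proportional to enzyme amount, not to
substrate concentrations); the cross-condition mean is the default
baseline, with any reference condition available via `baseline =`.
Scores are linear in $\Delta$, antisymmetric under reaction reversal,
and centred over conditions — properties the tests assert directly.

### Integration

Metabolite score profiles are correlated with cluster mean profiles over
the shared condition axis (host replicates averaged; at least three
shared conditions; zero-variance profiles yield missing coefficients).
"Strong" links are the top and bottom 0.001 *fraction* of the pooled
empirical distribution of all metabolite × cluster coefficients —
pooled, not per-cluster, as the literal reading of "all possible
correlation coefficients"; comparisons with the quantile cutoffs are
strict, so an all-equal pool selects nothing (with a warning), and a
pool smaller than $1/\text{percentile}$ degrades to the single extreme
pair per tail (warned). Negative-$r$ links are flagged
synthesis-coupled: increased predicted synthesis tracking increased
cluster expression is the biologically expected direction for an
exported signal.

Assembly applies the four rules in order and canonically sorts nodes and
edges, making the model idempotent and order-independent in its inputs.
A strongly correlated cluster with no linked complex produces a
*dangling* signal edge plus a warning rather than a silent drop — the
case is biologically open (an unobserved sensor) and should stay
visible.

## What the synthetic generator emulates

`world_config()` defaults encode the emulated study design:

| parameter | default | meaning |
|---|---|---|
| conditions | FL, 6h…96h, Myc | free-living, six interaction time points, mycorrhizal |
| replicates | 2,1,1,1,1,1,1,2 | ten host samples, replicated end conditions |
| clusters × size | 9 × 24 | planted co-regulation clusters, cosine profiles of amplitude 2 log₂ units |
| noise_sd | 0.25 | per-sample log₂ noise; symbiont gene noise scales as 0.4·noise_sd, compendium co-expression noise as 0.6·noise_sd |
| motifs | 8-symbol IUPAC, carrier fraction 0.8, background 0.08 | 8-mers keep the chance-hit rate per kilobase near 0.03 so planted fractions stay identifiable |
| complexes | 3 × 6 proteins | one receptor (plasma membrane), four cascade (cytoplasm, one localization tie), one TF (nuclear; one compound label) |
| reference PPI | 400 edges / 120 proteins | edge propensity 8:1 for compatible vs incompatible label pairs |
| metabolites | 333 (6 planted links, signs +−+−+−) | planted enzymes consume their metabolite and feed a 20-enzyme hub that dilutes the by-product signal |

Several defaults are deliberate consequences of the inference rules
rather than free dials. Complex size 6 equals the network neighborhood
plus one, so each member's top-5 partners are exactly its own complex
and planted complexes cannot bridge. Six planted metabolite links among
$9 \times 333 = 2997$ metabolite × cluster pairs place three links in
each 0.001 tail of the pooled correlation distribution, so the selection
rule can recover all of them without admitting noise pairs. Motif
planting inserts one concrete instance of the (possibly degenerate)
pattern at a uniform forward-strand offset; carriers are drawn
per-gene Bernoulli at the target fraction, so observed fractions
converge binomially as worlds grow.

What the generator does *not* emulate: read error models, intronic
structure, strand-specific libraries, genome sequence for the fungus,
upstream-region truncation by neighboring genes, correlated annotation
noise, and any real phylogenetic or pathway structure. Passing the
recovery tests therefore demonstrates that the inference machinery
recovers the planted couplings it formalizes — not that real tissue
data meet the model's assumptions.

## Numerical choices and degenerate inputs

* Binomial tails come from `pbinom` and are verified against direct
  summation of $\binom{n}{y} f^y (1-f)^{n-y}$ to $10^{-10}$ over a grid
  up to $n = 50$.
* Quantile normalization delegates to `limma::normalizeQuantiles`; an
  independent rank-then-average implementation serves as the test
  oracle. Constant columns still normalize (ties receive averaged
  order statistics).
* Bootstrap SDs are snapped to exactly zero when the iteration variance
  is at representation-noise level relative to the mean, so constant
  counts give constant estimates.
* `log2` floors: 0.01 for expression profiles (RPKM-scale values), half
  the smallest positive abundance for enzyme functions.
* Deterministic tie-breaks: lexicographic gene ids at ranking
  boundaries; fixed seeds thread through every resampling step
  (`seed` arguments on all stochastic operations; `run_pipeline(seed=)`
  covers clustering and the LOI null).
* Problem sizes: the shipped tests and the acceptance script run worlds
  of 300 host genes, 200 symbiont genes, 40 compendium samples and a
  400-edge reference PPI, twenty seeds end-to-end — sizes chosen so the
  planted-structure analysis above holds and a full verification run
  completes in about a minute on a laptop core. All sizes scale through
  `world_config()`.

## Known limitations

* The inferred "complexes" are co-expression components that pass
  localization-compatibility and annotation gates — co-complex
  membership is a hypothesis, not a demonstration of physical binding.
* Turnover scores ignore stoichiometry, compartmentalization and
  metabolite concentrations (well-mixed assumption; rate proportional to
  enzyme abundance).
* Motif analysis is presence/absence library matching: no
  position-weight scoring, no discovery of novel motifs, no multiplicity.
* GO-like annotation terms are flat labels; no ontology propagation.
* K is fixed (default 9) rather than selected by a gap statistic; the
  choice should be revisited per data set.
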