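# mycolink

Infers how a symbiotic soil fungus talks to the roots of its host tree
before physical contact is ever made. During pre-mycorrhizal interaction
the two partners communicate only through diffusible molecules: the
fungus synthesizes and exports signal metabolites, membrane-bound sensor
complexes in the root detect them, and signal cascades rewire the root's
transcriptional program. None of those links can be observed directly in
a single assay, but each leaves a footprint in a different omics layer.
`mycolink` reconstructs the whole chain —

```
fungal metabolite → root sensor complex → binding motif → co-regulated
gene cluster → predicted phenotype
```

— from transcriptomes, genome annotations, a reference protein–protein
interaction set and a reaction database, and ships a synthetic-data
generator with planted, recoverable ground truth so that every stage of
the inference is testable without any external download.

## Methods at the core

* **Bootstrap expression quantification.** Aligned reads (unique and
  multi-mapped) are resampled with replacement; in each of 10,000
  iterations every multi-mapped read is assigned to one of its candidate
  genes uniformly at random, and RPKM = 10⁹·c/(N·L) is accumulated.
  Expression is significant when P(Normal(μ, σ) ≤ 0) < 10⁻⁴
  (uncorrected), with μ, σ the bootstrap mean and SD.
* **Co-regulated gene clusters.** Genes significant in every sample with
  coefficient of variation σ/μ > 0.33 are profiled as per-condition log₂
  fold changes (log₂ condition mean − mean log₂ over conditions) and
  partitioned by Euclidean K-means (best of 50 restarts, K = 9 by
  default).
* **Cumulative-binomial enrichment.** For a cluster of n genes of which
  x carry a feature with background frequency f, the enrichment p-value
  is P(X ≥ x), X ~ Binomial(n, f). The same kernel scores annotation
  (phenotype) enrichment (p < 0.05) and upstream-motif enrichment
  (p < 0.01 and ≥ 10 carrier genes). Motifs are IUPAC patterns scanned
  for presence/absence in 1000 bp upstream regions.
* **Sensor complexes.** A rank-based co-expression network over an
  external expression compendium (each gene proposes its top-5 Pearson
  partners, kept at two-sided significance 0.01) is refined by
  likelihood-of-interaction (LOI) Z-scores: how often proteins with a
  given pair of subcellular-localization labels interact in a reference
  PPI set versus a degree-preserving resampled null (10,000 iterations).
  Edges need both proteins expressed everywhere, sensing/signalling
  annotations, and LOI > 1. Connected components are the predicted
  complexes, role-typed into receptor / cascade / transcription factor /
  defense.
* **Predicted relative metabolic turnover (PRMT).** Enzyme-function
  abundances (summed quantile-normalized RPKM per EC number) propagate
  their log₂ deviations through a pathway-restricted, signed
  enzyme–metabolite incidence; positive scores predict net consumption
  of a metabolite, negative scores net synthesis.
* **Integration rules.** (1) complexes regulate clusters they share
  genes with; (2) metabolites in the top/bottom 0.001 fraction of all
  metabolite × cluster correlations signal through the cluster's
  complex; (3) motifs link in from complex transcription factors and
  from cluster enrichment; (4) enriched annotation terms become the
  cluster's predicted phenotype.

## Worked example

```r
library(mycolink)

world <- generate_world(world_config(seed = 42))
world
#> synthetic_world: 300 host genes (216 clustered), 200 symbiont genes,
#>   8 conditions, seed 42

res <- run_pipeline(world, seed = 42)
res
#> pipeline_result: 216 filtered genes in 9 clusters; 9 passing motif
#>   enrichments; 3 sensor complexes; 333 metabolites scored; 6 strong
#>   links; model 48 nodes / 50 edges

head(res$strong_links)
#>   metabolite cluster          r            coupling
#> 2 met_link_2       2 -0.9994645   synthesis_coupled
#> 4 met_link_5       5  0.9977105 consumption_coupled
#> 1 met_link_1       1  0.9970717 consumption_coupled
#> 5 met_link_4       6 -0.9970112   synthesis_coupled
#> 6 met_link_3       8  0.9922327 consumption_coupled
#> 3 met_link_6       4 -0.9911057   synthesis_coupled
```

The six strongest metabolite–cluster correlations are exactly the six
planted couplings, with their planted signs: a negative r flags a
synthesis-coupled signal (the fungus is predicted to synthesize the
metabolite while the root cluster is induced). Motif enrichments report
the binomial test inputs directly:

```r
subset(res$motif_enrichments, passes)[1:2, ]
#>   cluster    motif  n  x         f            p passes
#> 1       1 motif_01 24 19 0.1574074 1.048399e-11   TRUE
#> 13      2 motif_02 24 21 0.1898148 7.777320e-13   TRUE
```

i.e. 19 of the 24 genes of cluster 1 carry `motif_01` upstream against a
background frequency of 0.157 across all 216 differentially regulated
genes. The assembled model can be exported for network tools:

```r
write_model_graphml(res$model, "model.graphml")
write_model_json(res$model, "model.json")
```

Every input can also be written to (and read back from) standard flat
formats — upstream FASTA, expression/annotation/PPI/reaction TSVs — with
`export_world()` / `import_world()`.

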