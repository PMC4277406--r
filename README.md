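# tissuespec

Tissue-specificity classification of bulk RNA-seq expression profiles.

Large tissue panels profiled by RNA-seq are routinely summarised by asking,
for every gene, *where* it is expressed: everywhere (housekeeping), in one
tissue, in a small group of related tissues, or nowhere at all. `tissuespec`
implements the widely used seven-category fold-change scheme for
replicate-averaged FPKM profiles, together with the comparative analyses
that usually accompany it, for transcriptomics researchers working with
gene × sample abundance matrices.

## The classification scheme

For each gene, per-tissue expression is the arithmetic mean FPKM over the
tissue's biological replicates; FPKM ≥ 1 counts as detected. With
v<sub>t</sub> the mean FPKM in tissue *t*, categories are assigned
top-down, first match wins:

| category | criterion |
|---|---|
| not detected | v<sub>t</sub> < 1 in every tissue (focus mode: in every focus tissue) |
| highly tissue enriched | max v ≥ 50 × second-highest v, and ≥ 1 |
| moderately tissue enriched | max v ≥ 5 × second-highest v, and ≥ 1 |
| group enriched | mean v over a group of 2–7 tissues ≥ 5 × the highest v outside the group, and ≥ 1 |
| enhanced | v<sub>t</sub> ≥ 5 × mean v over all other tissues, and ≥ 1 |
| expressed in all | v<sub>t</sub> ≥ 1 in every tissue |
| mixed | everything else |

Group search uses the descending top-*k* prefix of the profile, which is
provably equivalent to exhaustive subset enumeration (the prefix
simultaneously maximises the group mean and minimises the outside
maximum). "Elevated" is the union of the enriched and enhanced categories.

Around the classifier the package provides Spearman correlation at sample
and tissue level, average-linkage clustering on 1 − ρ of log2(FPKM+1) with
Newick export, differential-detection gene sets with cross-referencing, a
bipartite tissue/enriched-set network with SIF and GraphML export, count
and transcript-fraction summaries, and a synthetic FPKM generator that
plants all seven categories with known truth, multiplicative replicate
noise and barcode-leakage mixing.

## Worked example

```r
library(tissuespec)

sim <- simulate_fpkm(simulation_config(
  category_counts = c(not_detected = 200, highly_tissue_enriched = 100,
                      moderately_tissue_enriched = 100, group_enriched = 100,
                      enhanced = 100, expressed_in_all = 300, mixed = 100),
  noise_cv = 0.1, seed = 42))
sim
#> fpkm_simulation: 1000 genes x 88 samples (27 tissues), CV 0.1, leakage 0.001
#>
#>                   enhanced           expressed_in_all
#>                        100                        300
#>             group_enriched     highly_tissue_enriched
#>                        100                        100
#>                      mixed moderately_tissue_enriched
#>                        100                        100
#>               not_detected
#>                        200

profile <- average_replicates(sim$expression)
cls <- classify_profile(profile)
summary(cls)
#> classification of 1000 genes (1000 total):
#>   not_detected                    200  (20%)
#>   highly_tissue_enriched          100  (10%)
#>   moderately_tissue_enriched      100  (10%)
#>   group_enriched                  100  (10%)
#>   enhanced                        101  (10%)
#>   expressed_in_all                301  (30%)
#>   mixed                            98  (9.8%)
#>   elevated (enriched or enhanced): 401 (40%)
```

401 of 1000 genes are called elevated (enriched in one tissue, in a group,
or enhanced) against 400 planted: at replicate-noise CV 0.1 a couple of
borderline mixed genes drift across the 5-fold enhanced boundary or the
detection cutoff, while every planted enriched gene is recovered, as a
comparison with the generator's truth table `sim$truth` shows. Downstream:

```r
g <- build_network(cls, focus = lymphohematopoietic_tissues())
export_graph(g, "network.graphml", "graphml")
as_newick(cluster_samples(sim$expression), "dendrogram.nwk")
tissue_stats(sim$expression)   # % detected, top FPKM, replicate rho range
```

`run_pipeline("out/")` wires all stages together and writes a JSON run
manifest with file digests for reproducibility.

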