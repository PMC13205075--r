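# cernascreen

Whole-transcriptome competing endogenous RNA (ceRNA) screening with a
planted-truth simulator.

## The problem

Bulk RNA-seq studies of two-group designs — here modelled on cold-exposed
vs control piglets, where cold exposure drives intramuscular fat
deposition — profile four RNA classes at once: mRNA, lncRNA, miRNA and
circRNA. The biological question is which long RNAs act as *ceRNAs*:
lncRNAs or circRNAs that share miRNA binding sites with an mRNA and
de-repress it by sequestering ("sponging") the shared miRNA. The screening
logic is a chain of standard steps whose joint behaviour is hard to audit
piecemeal:

1. **Differential expression** per RNA class: median-of-ratios
   normalization, negative-binomial (NB) testing, and volcano
   classification at |log₁₀ FC| ≥ 0.6 (≈ 4-fold) with raw-p cutoffs 0.05
   (mRNA, lncRNA) and 0.01 (miRNA, circRNA).
2. **Targeting**: canonical miRNA seed sites (6mer / 7mer-A1 / 7mer-m8 /
   8mer — complementarity to miRNA positions 2–7/8) on candidate targets,
   plus lncRNA→mRNA relations by genomic proximity (*cis*, gap ≤ 100 kb)
   or expression correlation (*trans*, |r| ≥ 0.9).
3. **Direction-consistent triad assembly**: a triad (mRNA *m*, miRNA *μ*,
   sponge *s*) is kept iff all three are differential, status(*m*) ≠
   status(*μ*), status(*s*) = status(*m*), *μ* has seed sites in both *m*
   and *s*, and a lncRNA sponge additionally has a cis/trans relation to
   *m*.
4. **Enrichment**: hypergeometric over-representation of up- and
   down-regulated gene sets, ranked by gene ratio k/n.
5. **Marker normalization** for genes whose bulk signal may track
   cell-type composition (e.g. an adipokine in fat-infiltrated muscle):
   `x_target / sqrt(x_markA · x_markB)` per sample on normalized counts,
   followed by a pooled two-sample t-test.

Because such studies rarely deposit raw data, the package ships a
**synthetic-data generator** that emulates the full study design — NB
counts for a 3 vs 3 design, planted differential features in all four
classes, planted 8mer seed sites, cis-located lncRNA sponges, an enriched
term, and marker genes — with a completely known truth, so every stage and
the whole chain can be validated by recovery of the planted network.

## The statistics at the core

For feature *i* with normalized group means *m₁* (control), *m₂* (cold),
pseudocount *c* = 0.5 and NB dispersion *α* (variance = μ + αμ²):

```
log10_fc = log10((m2 + c) / (m1 + c))
SE²      = (1/n1)(1/(m1 + c) + α) + (1/n2)(1/(m2 + c) + α)
z        = ln((m2 + c) / (m1 + c)) / SE ,   p = 2 Φ(−|z|)
```

*α* is estimated per feature by method of moments on normalized counts,
`α = (s² − m̄)/m̄²` with *s²* the pooled within-group variance, then floored
at the class median (see the methods vignette for why this moderation is
needed at n = 3).

## Worked example

A complete synthetic screen, two commands:

```r
library(cernascreen)
cfg <- pipeline_config(outdir = "cerna_run", sim = list(
  n_mrna = 500, n_lncrna = 80, n_mirna = 50, n_circrna = 120,
  n_de_per_class = c(mRNA = 30, lncRNA = 10, miRNA = 16, circRNA = 12),
  n_triads = 12), seed = 101)
run <- run_pipeline(cfg)
cat(run$log, sep = "\n")
```

```
[simulate] 750 features x 6 samples, 12 planted triads
[de] differential features: circRNA=12, lncRNA=10, mRNA=30, miRNA=16
[targets] 2772 seed interactions, 14 cis pairs, 265 trans pairs
[cerna] 12 triads
[enrich] 41 term records
[normalize] target mRNA_0015: t = -9.011, p = 0.0008401
```

The screen recovered exactly the 12 planted triads; `run$results$triads`
begins:

```
   mrna_id   mirna_id sponge_id sponge_class mrna_status mirna_status
 1 mRNA_0001 mir_0001 circ_0001 circRNA      up          down
 2 mRNA_0002 mir_0002 lnc_0001  lncRNA       down        up
 3 mRNA_0003 mir_0003 circ_0002 circRNA      up          down
```

Each row is one ceRNA axis: e.g. row 1 reads "mir_0001 is down in cold,
its target mRNA_0001 is up, and circ_0001 (also up) carries the same seed
site, consistent with the circRNA sponging the miRNA and de-repressing the
mRNA". The planted "lipid storage" term dominates the up-regulated
enrichment (`gene_ratio = 1`, p ≈ 9e-24), and the marker-normalized target
gene is significantly reduced in the cold group (t = −9.0, p = 8.4e-4),
mirroring the marker-normalization use case. Figures:
`plot_volcano(run$results$de)`, `autoplot(run$results$pca)`,
`plot_enrichment(run$results$enrichment_top)`.

Every output is also written under `outdir` as TSV/GraphML with a JSON
manifest of MD5 hashes; identical config + seed reproduce identical
hashes.

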