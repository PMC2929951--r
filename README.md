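# pcflink

Linking drug physico-chemical features (PCFs) to pathway-level
transcriptional activity and toxicity outcome.

## The problem

Classic QSAR predicts toxicity from a chemical's descriptors; toxicogenomics
predicts it from the expression response of the exposed tissue. `pcflink`
connects the two layers for repeat-dose study designs (a panel of compounds,
each with a few treated replicates and matched controls, binary toxicity
labels, a pathway database stand-in, and a compounds × descriptors table):

1. **Pathway activity indices** — each pathway's expression submatrix
   (pathways with > 5 matched genes) is reduced to its leading principal
   components, retained up to 80% cumulative variance and capped at two, so
   the transcriptional state becomes a small set of per-pathway scores.
2. **Perturbation and differential statistics** — the Hotelling statistic
   `T² = nm/(n+m) · d' S⁻¹ d` on the retained components scores each drug's
   perturbation against its matched controls, and (at the compound level,
   Benjamini–Hochberg adjusted, q < 0.01) finds pathways differentially
   modulated between toxic and non-toxic exposure. Drugs are clustered by the
   correlation of their perturbation profiles.
3. **QSPR interaction models** — a genetic algorithm searches descriptor
   triples for the regression
   `PC₂ₖ = a + bD₁ + cD₂ + dD₃ + eD₁D₂ + fD₁D₃ + gD₂D₃ + ε`,
   with 5-fold cross-validated R² on a 2/3 training split as fitness;
   pathways with a model reaching R² ≥ 0.5 are flagged PCF-linked.
4. **Pathway map** — Jaccard overlap between gene sets, average-linkage
   clustering verified by cophenetic correlation, and a permutation test of
   whether the PCF-linked and toxicity-linked pathway sets sit close together
   on the map.
5. **Toxicity classifiers** — maximum-likelihood Gaussian discriminants with
   GA feature selection compare the PCF-linked descriptor subset against
   descriptors uncorrelated with it (|r| < 0.5), including a representative
   three-feature model with cross-validated sensitivity/specificity.

A synthetic-data module generates expression studies, gene-set collections
and descriptor tables with planted, recorded ground truth (toxicity factor on
the second pathway component, causal descriptor triples with dominant
interaction terms), so every stage has a recovery and calibration test
without any external data.

## A worked example

```r
library(pcflink)
res <- runAll(defaultConfig(), "demo_run")
```

The demo generates 40 compounds (10 toxic) × 3 replicates with matched
controls, 60 pathways in 6 overlap blocks (10 planted differential, 8 of
them descriptor-linked), and 60 descriptors. With the default seed the run
prints:

```
inputs: 727 genes, 40 compounds, 60 gene sets, 60 descriptors
pathway indices: 60 retained
differential pathways at FDR 0.01: 10
PCF-linked pathways: 10
map association: p = 5e-04 (cophenetic r = 0.996)
feature split: 30 linked / 27 uncorrelated
classifier accuracy (linked vs uncorrelated): 86.1% vs 61.5%; representative sensitivity 0.8, specificity 0.967
```

meaning: all 10 planted differential pathways — and no others — were
recovered at FDR 1%; 10 pathways got a validated descriptor model (the 8
planted causal ones plus their shared-factor block mates, Jaccard 0.8
against the planted set); the two pathway sets cluster together on the map
far more tightly than random label sets (permutation p ≈ 5·10⁻⁴, and the
dendrogram faithfully represents the overlap matrix, cophenetic r ≈ 1); and
descriptors selected through the transcriptional layer classify toxicity
~25 points better than descriptors uncorrelated with them. `resultTable(res$differential)`,
`qsprSummary(res$populations, res$descriptors)` and
`res$classifier$representative` hold the per-pathway and per-model detail;
all artifacts (TSV/JSON/Newick plus a checksummed manifest) are written to
the output directory.

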