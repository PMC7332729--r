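# mirloop

Inference of nutrient-modulated miRNA-TF-mRNA regulatory networks from
paired miRNA/mRNA expression profiles of unreplicated RNA-seq libraries.

## The problem

Maternal calorie restriction represses embryonic myogenesis. Profiling
fetal muscle mRNA and miRNA at the stages bracketing the two waves of
myofiber formation (35, 55, 90 days of gestation) under normal (NE) and
restricted (RE) diets gives six paired libraries — and the question of
which miRNAs drive which expression changes. Sequence-based target
prediction alone is too permissive; `mirloop` implements an integrative
procedure that layers expression evidence on top of the sequence scan:

- **Quantification**: RPKM for mRNA (`1e9 * C / (N * L)`), CPM for
  miRNA, an inclusive >= 10 reads abundance filter, and Pearson sample
  correlation matrices with average-linkage clustering to stage the
  samples.
- **Differential expression** for unreplicated libraries: two-sided
  Fisher's exact test on (feature reads, other reads) x (library A,
  library B), called at fold change > 2 and p < 0.01 (both strict).
- **Target scanning**: a seed-weighted Smith-Waterman duplex aligner
  (Watson-Crick +5, G:U +2, mismatch -3, affine gaps -9/-4, seed
  positions 2-8 scaled x4) with a nearest-neighbor stacking free-energy
  model; sites retained at score > 145 and energy < -10 kcal/mol, with
  strict Watson-Crick seed pairing by default.
- **Anticorrelation filter**: a sequence-predicted pair becomes a
  miRNA->mRNA edge only if its expression correlation satisfies
  r < -0.58 and p < 0.05 (t transform on n - 2 df).
- **miRNA-TF-mRNA loops**: predicted targets are intersected with a TF
  catalog; each TF's coexpressed genes (r > 0.90, p < 0.01) extend the
  network into regulatory loops.
- **Synthetic benchmark**: a fully seeded generator plants DE features,
  complementary UTR sites, anticorrelated miRNA-target relations and TF
  modules, with ground truth for precision/recall scoring of every
  stage.

## A worked example

```r
library(mirloop)

cfg <- pipeline_config(out_dir = "run42",
                       simulate = simulate_config(seed = 42))
res <- run_pipeline(cfg, quiet = TRUE)
res$network
res$recovery
```

```
RegulatoryNetwork
  miRNA->mRNA/TF pairs: 79 (29 miRNAs, 77 targets)
  TFs targeted by miRNAs: 10
  TF->mRNA pairs: 218
  miRNA->TF->mRNA loops: 218
    edge_type n_predicted n_truth tp precision    recall        f1 defined
1 miRNA->mRNA          79      60 55 0.6962025 0.9166667 0.7913669    TRUE
2    TF->mRNA         218      80 72 0.3302752 0.9000000 0.4832215    TRUE
```

The network recovered 79 miRNA->mRNA edges, of which 55 are planted
ground-truth regulations (precision 0.70) covering 55 of the 60 planted
edges (recall 0.92); ten of the targeted genes are transcription
factors, whose 218 coexpression targets close 218 miRNA->TF->mRNA loops.
The remaining false edges sit at the structural floor set by chance
seed matches times the null rate of the anticorrelation filter at six
samples (see the methods vignette, `vignettes/methods.Rmd`).

All stage outputs (DE tables, duplex hit report, edge table, GraphML
graph, correlation matrices, recovery metrics, checksummed manifest)
are written under `out_dir`. The same pipeline runs from data on disk
(`pipeline_config(input = "dataset-dir", ...)`) in the formats written
by `write_dataset()`: count TSVs, miRNA/UTR FASTA, TF catalog, sample
sheet.

A thin command-line wrapper ships in `inst/cli/mirloop.R`
(subcommands `simulate`, `run-all`, `quantify`, `de`, `scan`,
`network`, `evaluate`), driven by the same YAML config as
`read_pipeline_config()`.

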