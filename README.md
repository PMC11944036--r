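# pathcolor

Predicting the pathway involvement of small molecules from
substructure-count features.

Most detectable metabolites and xenobiotics carry no pathway annotation,
which blunts pathway-enrichment analysis and omics integration.  Given a
knowledgebase's compound-to-pathway annotations and the compounds'
structures (MDL V2000 molfiles, e.g. ChEBI structures mapped to Reactome
pathways), `pathcolor` builds a single binary classifier that answers, for
*any* (compound, pathway) pair, "is this compound involved in this
pathway?".  It is aimed at computational metabolomics / cheminformatics
researchers who want the whole pipeline -- featurization, dataset
construction, cross-validated training, and hierarchy-aware evaluation --
as composable R functions with a fully synthetic benchmark that needs no
downloads.

## Method

* **Atom coloring.**  Each heavy atom gets a canonical string color per
  radius: element (plus formal charge) at radius 0, then iteratively the
  sorted `(bond order : neighbor color)` multiset -- a Weisfeiler-Lehman
  style refinement.  A compound's feature vector counts color occurrences,
  so each feature is a molecular substructure count.
* **Pathway features.**  A pathway's raw feature row is the sum of its
  member compounds' rows.  Duplicate compound and pathway feature vectors
  are removed (annotations merged onto the representative), and both
  matrices are column-max normalized to [0, 1].
* **Cross-join dataset.**  Every compound is paired with every pathway;
  entry features are the concatenated rows and the boolean label marks
  annotation membership.  |C| compounds and |P| pathways always give
  |C|x|P| entries.
* **Model and CV.**  A class-weighted MLP (ReLU hidden layers, dropout,
  AdamW, early stopping) is trained under repeated stratified 9:1
  shuffle-splits; confusion counts are kept per iteration at the overall,
  per-compound, and per-pathway scopes.
* **Evaluation.**  MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
  reported as *undefined* (`NA`) whenever a marginal is zero.  The overall
  MCC (oMCC) of a compound, pathway, or hierarchy level sums the counts
  across iterations (and across a level's pathways) before computing MCC
  once.  Iteration summaries (mean/median/SD), Cohen's d (pooled SD), and
  relative improvement support cross-dataset comparisons; pathway
  hierarchy levels L1..L5 and L6+ (levels 6-9 pooled) support
  level-resolved analysis and the L2+/L3+ dataset subsets.

The synthetic generator plants star-shaped substructure motifs (centered
on S/P, which never occur in background scaffolds) into random molecular
graphs, one motif per pathway, annotates carriers with configurable signal
and noise rates, and propagates annotations to ancestor pathways -- so the
planted signal is provably recoverable and every pipeline stage is
testable offline.

## Worked example

```r
library(pathcolor)

ethanol <- parse_molfile(write_molfile(molecule_graph(
  "ethanol", c("C", "C", "O"),
  bonds = rbind(c(1, 2, 1), c(2, 3, 1)))))
color_counts(ethanol, max_radius = 1)
#>            C            O      C|(1:C) C|(1:C)(1:O)      O|(1:C)
#>            2            1            1            1            1
```

Radius-0 counts say ethanol has two carbons and one oxygen; radius-1
colors distinguish the methyl carbon (`C|(1:C)`) from the carbinol carbon
(`C|(1:C)(1:O)`).

```r
cfg <- synth_config(n_compounds = 60, n_pathways = 12,
                    hierarchy_depth = 4, seed = 42)
study <- synth_study(cfg)
pd <- build_pathway_dataset(study$graphs, study$annotations,
                            study$hierarchy, max_radius = 1)
pd$dataset
#> <xjoin_dataset> 60 compounds x 12 pathways = 720 entries (179 positive, 24.9%)

model <- mlp_config(hidden_sizes = c(32, 16), max_epochs = 80,
                    batch_size = 256, learning_rate = 3e-3,
                    weight_decay = 1e-3, val_fraction = 0, patience = 15)
cv <- run_cv(pd$dataset, 5, model, base_seed = 1, levels = pd$levels)
summary(cv)
#> <iteration_summary> n=5 mean MCC=0.8924 median MCC=0.8915 sd=0.0333
overall_metric(cv, "dataset")
#> <metric_set> mcc=0.8903 acc=0.9583 f1=0.9180 precision=0.9032 recall=0.9333 specificity=0.9667
sapply(sort(unique(cv$levels)), function(lv) overall_metric(cv, "level", lv)$mcc)
#>        L1        L2        L3        L4
#> 0.8555195 0.8769199 0.9583937 0.8703883
```

The five-iteration mean MCC of 0.89 says the classifier recovers most of
the planted motif-to-pathway signal on this small corpus; the summed-count
oMCC per hierarchy level shows how performance distributes over depth.
(The package's standard benchmark -- 200 compounds x 50 pathways, 20
iterations -- reaches mean MCC around 0.94-0.96; see the vignette.)

A thin CLI covering the same pipeline lives at `inst/scripts/pathcolor`
(subcommands `synth`, `build-dataset`, `train-cv`).

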