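# immunophen

Tumour-immune phenotype classification from compartmental CD8 densities
and bulk RNA-seq.

## What this is for

Solid tumours fall into three immune phenotypes by where their CD8+
T cells sit: **infiltrated** (T cells inside the tumour epithelium),
**excluded** (T cells confined to the stroma) and **desert** (few T cells
anywhere). These phenotypes matter for immunotherapy, but calling them by
eye from CD8 immunohistochemistry is subjective, and most cohorts have
expression data without imaging. `immunophen` is for computational
biologists who want a reproducible, fully testable version of the whole
chain: digital CD8 quantification → polar spatial metrics → signature-gene
discovery → consensus phenotyping → a portable expression-only classifier.

## The model in brief

Compartmental CD8 densities (tumour epithelium *t*, stroma *s*, cells/mm²)
are summarized by polar metrics

    R = sqrt(t² + s²)        (CD8 quantity)
    θ = atan(s / t) ∈ [0, π/2]   (spatial distribution; π/2 = fully stromal)

For each gene a random-forest regression `gene ~ R + θ` (bootstrap over
patients, no predictor subsampling) yields permutation importances
(%IncMSE); genes above the third quartile for exactly one metric form the
signature. Samples are consensus-clustered on the signature (k-means on
Pearson-standardized profiles, k = 6, 1,000 × 80% subsamples), clusters
are merged to the three phenotypes by their mean (R, θ), and a nearest
shrunken centroid classifier (soft-thresholded standardized centroid
offsets, shrinkage chosen by 10-fold CV) predicts phenotype posteriors. A
tumour is confidently called only when its top posterior exceeds 0.7 and
the other two are below 0.5; otherwise it is `unclassified`.

A synthetic-cohort generator (negative-binomial counts with planted
cytotoxic / antigen-presentation / TGF-β-stromal / desert / housekeeping
modules, plus invertible latent (R, θ)) and a cartoon IHC image generator
(elliptical nuclei, disk CD8 cells, planted compartment masks) provide
ground truth for every stage; training labels always come from consensus
clustering, truth is only used for scoring.

## Worked example

```r
library(immunophen)

cohort <- generate_cohort(sim_config(seed = 11))     # 2,000 genes x 150 samples
cfg    <- pipeline_config(master_seed = 3)
run    <- run_training_pipeline(cohort$counts, cohort$densities, cfg,
                                truth = cohort$truth)
str(run$manifest$recovery)
#> List of 4
#>  $ ari_vs_truth           : num 0.982
#>  $ phenotype_agreement    : num 0.993
#>  $ confident_call_accuracy: num 1
#>  $ gene_selection         :List of 3
#>   ..$ quantity_sensitivity    : num 0.89
#>   ..$ distribution_sensitivity: num 1
#>   ..$ noise_fpr               : num 0.0405

held_out <- generate_cohort(sim_config(n_samples = 200, seed = 77))
cls <- run_classification(run$model, held_out$counts, cfg)
cls$summary
#>          label  n fraction
#> 1       desert 88    0.440
#> 2     excluded 48    0.240
#> 3  infiltrated 63    0.315
#> 4 unclassified  1    0.005
```

Reading the numbers: consensus clustering on the discovered signature
recovers the planted phenotypes almost perfectly (ARI 0.98; 99.3% of
samples labelled correctly before any classifier is involved); 89% of the
planted R-tracking genes land in quantity categories, 100% of the planted
θ-linked genes in distribution categories, with a 4% noise false-positive
rate. On a held-out cohort the confidence-gated classifier leaves 1/200
samples unclassified and every confident call matches the planted truth.

Quantify a synthetic IHC image:

```r
img <- generate_ihc_image(ihc_image_spec(seed = 4))  # 10 tumour + 20 stroma CD8
q   <- quantify_image(img$hema, img$dab, pixel_size = 0.5)
q$densities[, c("cd8_tumour_count", "cd8_stroma_count")]
#>   cd8_tumour_count cd8_stroma_count
#> 1               10               20
```

## Command line

`inst/cli/immunophen.R` exposes per-stage subcommands
(`simulate-cohort`, `simulate-ihc`, `quantify`, `metrics`, `prep`,
`select-genes`, `cluster`, `train`, `classify`, `run-all`) with TSV/JSON
interchange and YAML configs; see the script header.

## Scope

Wet-lab assays, survival analysis, enrichment/deconvolution analyses,
molecular subtyping and methylation are out of scope. The digital
pathology module is a reconstruction of described rules with documented
default thresholds, not a port of the discontinued original software.
See `vignettes/immune-phenotyping.Rmd` for the full methods account.
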