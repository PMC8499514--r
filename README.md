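# vistrackr

Quantitative, longitudinal clonal tracking of lentiviral **vector
integration sites (VIS)** from LTR-junction sequencing reads.

When a lentiviral vector integrates into the genome of a hematopoietic
stem/progenitor cell (HSPC), the vector–host junction coordinate is a
permanent, unique barcode for that clone and all of its progeny. Sequencing
junction fragments therefore measures which clones contribute to
repopulation and how much — the core readout for gene-therapy safety
studies and for the clonal dynamics of transplanted HSPC in animal models.
`vistrackr` implements the computational side of such an assay for
small-volume longitudinal samples, where vector populations are multiplexed
by short **LTR indexes** (barcodes in the terminal bases of the 3' U5 LTR,
e.g. H1/H5/WT) and read counts are taken through whole-genome-amplified
(MDA) replicates.

The package covers:

* **Junction calling** — LTR-anchor detection (ungapped, ≤ 2 mismatches),
  LTR-index demultiplexing (unique minimal Hamming distance, ties
  unclassified), and two-pass host mapping: exact-seeded candidate search,
  then ungapped rescoring over a ±500 bp window; a read is a VIS readout
  only with ≥ 25 host bases at ≥ 95% identity and a unique best placement.
* **Quantification** — VIS × sample count matrix; signal-crossover
  (index-hopping) correction and cross-animal collision removal by 10:1
  count dominance; per-animal minimum-count filtering; clone frequencies
  `p_i = s_i / S`.
* **Clone analytics** — frequency bands by quartiles of the per-clone
  maximum frequency (strictly below Q1 = low, strictly above Q3 = high),
  persistent clones (frequency > 0 at every tracked week), top-k clones,
  clone sharing between timepoints/tissues, and replicate concordance via
  Pearson's r and the single-rater absolute-agreement intraclass
  correlation

      ICC = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E))

* **Diversity** — Rényi entropy profiles
  `H_α = log(Σ p_i^α) / (1 − α)` (nats) over
  α ∈ {0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, ∞}, replicate-averaged at the
  statistic level; H_0 = log richness, H_1 = Shannon, H_2 = log(1/Simpson),
  H_∞ = −log(top-clone share).
* **Genomic context** — a restriction-motif-matched random-IS null
  (positions within ±1500 bp of a CviQI/RsaI `GTAC` site, mirroring what
  the assay can recover), nearest-gene/biotype/activity annotation
  (active ⇔ FPKM > 1), distances to chromatin-feature peaks (0 inside a
  peak), distance histograms, coverage matrices around sites or along gene
  bodies, and enrichment testing with Pearson's chi-squared statistic with
  Yates continuity correction.
* **Synthetic data** — a generator that emulates the full assay (genome
  with controlled GTAC density, genes + FPKM, feature peaks, coverage
  tracks, junction reads with sequencing error, index hopping, cross-animal
  collisions, and negative-binomial amplification overdispersion) with
  known clonal truth, so the whole pipeline is testable offline.

## Worked example

Simulate a small cohort (80 clones, blood at weeks 13–19 in MDA
duplicates), run the pipeline, and look at concordance, diversity and
integration-site context:

```r
library(vistrackr)

cfg   <- sim_config(seed = 7, genome_length = 5e5, n_chromosomes = 2,
                    n_genes = 50, n_clones = 80, depth = 4000)
ref   <- make_reference(cfg)
truth <- simulate_clones(ref, cfg)
reads <- simulate_reads(truth, ref, cfg)

res <- run_vis_pipeline(reads$reads, ref$genome, truth$samples)
res$matrix
#> clonal_matrix: 80 sites x 10 samples; 31934 total reads

fp <- res$frequencies
pearson_r(fp$p[, 1], fp$p[, 2])   # MDA replicates, week 13
#> 0.959
icc_a1(fp$p[, 1:2])
#> 0.96

dp <- diversity_profile(res$matrix$counts[, 1:8],
                        replicate_groups = rep(c(13, 15, 17, 19), each = 2))
round(dp$averaged_H[c("0", "1", "2", "Inf"), ], 3)
#>        13    15    17    19
#> 0   4.376 4.376 4.350 4.350
#> 1   3.797 3.799 3.651 3.630
#> 2   3.447 3.449 3.248 3.227
#> Inf 2.655 2.609 2.356 2.362

cls <- classify_clones(merge_replicates(res$matrix, "mean_frequency"),
                       animal = "m1")
sum(cls$persistent); table(cls$band)
#> 79 persistent of 80
#>    low medium   high
#>     20     40     20
```

The diversity profile drops with α (uneven clone sizes) and with time
(expansion of fewer clones), while richness (α = 0) stays nearly flat —
the signature of stable polyclonal repopulation driven by a subset of
clones. Enrichment of integration sites near H3K36me3-marked gene bodies is
tested against the motif-matched random null:

```r
ris <- generate_random_is(ref$genome, n = 1000, seed = 8)
nv  <- sum(peak_distance(res$matrix$sites, ref$peaks$H3K36me3) <= 1000,
           na.rm = TRUE)
nr  <- sum(peak_distance(ris, ref$peaks$H3K36me3) <= 1000, na.rm = TRUE)
chisq_yates(nv, nrow(res$matrix$sites) - nv, nr, 1000 - nr)
#> VIS near H3K36me3: 56/80 (70.0%) vs random 164/1000 (16.4%),
#> chisq = 127.9, p = 1.17e-29
```

A thin command-line front-end over the same functions ships in
`inst/cli/vistrack.R` (subcommands `simulate`, `call`, `quantify`, `track`,
`diversity`, `context`).

## Vignette

`vignettes/vis-clonal-tracking.Rmd` documents the models, thresholds,
numerical choices, what the synthetic generator does and does not emulate,
and known limitations.
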