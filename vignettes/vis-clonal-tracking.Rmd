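---
title: "Quantitative clonal tracking of vector integration sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative clonal tracking of vector integration sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vistrackr)
```

# The measurement

A lentiviral vector integrates once per transduced cell, so the vector-host
junction coordinate — chromosome, base position, orientation — is a
permanent clonal barcode. A junction-sequencing assay amplifies fragments
spanning the 3' U5 LTR end into host DNA (restriction digestion with
CviQI/RsaI releases the fragment, so only junctions with a `GTAC` site
within reach are recoverable), sequences them, and counts reads per
junction. Two or three vector populations can repopulate the same animal
simultaneously when each vector carries a distinct **LTR index** — a
barcode occupying the terminal 16 nt of the U5 LTR (here `H1`, `H5`, `WT`).
For small-volume longitudinal samples (tens of microliters of blood), DNA
is first whole-genome amplified (MDA) in duplicate; amplification noise is
then part of the error budget and is what the replicate-concordance
statistics quantify.

`vistrackr` turns raw junction reads into a VIS × sample count matrix and
the clone-level statistics built on it. This vignette records the models,
the tunable parameters, the numerical choices, and what the synthetic data
generator does and does not establish.

# Junction calling

A junction read is modelled as `[anchor][index][host...]`:

* **Anchor location.** The constant U5 terminal sequence
  (`default_ltr_anchor()`, 15 nt) is scanned ungapped against the read with
  at most 2 mismatches; the leftmost best match wins. Indels are not
  allowed in the anchor: the anchor is short, substitutions dominate
  Illumina error, and an ungapped scan keeps the caller linear in read
  length and conservative. No in-budget match → `no_ltr`.
* **Index classification.** The 16 nt after the anchor are compared to
  every index by Hamming distance; the read gets the label with the
  uniquely smallest distance ≤ 1. H1 and H5 differ at a single base, so a
  tie is demoted to `unclassified` rather than guessed — a wrong guess
  would systematically move reads between the two co-repopulating
  populations, which is exactly the artifact the assay must not create.
* **Host requirements.** At least 25 host bases must remain after the
  index (`short_host` otherwise).
* **Two-pass mapping.** Pass 1 seeds candidate loci by exact-matching the
  first and last 20 bases of the host segment (and of its reverse
  complement) against the genome; any segment with at most one error in
  each terminal seed region is found, and rare doubly-errored segments fall
  back to a bounded genome-wide mismatch scan. Pass 2 rescores the full
  segment ungapped at every offset of a ±500 bp window around each
  candidate. Acceptance requires identity ≥ 0.95 over ≥ 25 aligned bases
  *and* a unique best placement; equal-best placements at distinct loci are
  `multimapped`. Identity is the fraction of matching columns over the full
  segment, so a 30-base segment with 2 mismatches scores 28/30 ≈ 0.933 and
  is rejected.

The rescoring is deliberately ungapped. Junction fragments are short
(tens of bases) and their dominant error mode is substitution; an ungapped
best-offset scan is exact under that model, deterministic, and orders of
magnitude faster than a gapped local aligner, which matters at the default
problem size (~150k reads). A clone whose junction genuinely spans an
indel-polymorphic locus would lose a read or two to `low_identity` — a
conservative failure.

Coordinates are 1-based inclusive throughout, the native convention of the
R/Bioconductor interval stack this package is built on; emitted tables are
1-based inclusive. Reported `pos` is always the first host base at the
junction (the rightmost aligned base for a minus-strand placement).

# Quantification

* **Site aggregation** merges accepted reads on the same chromosome,
  strand and index whose positions lie within 5 bp (chain clustering, modal
  position, ties toward the smaller coordinate). The window absorbs
  end-trimming jitter; real distinct integrations essentially never fall
  within 5 bp of each other in a mammalian-scale genome.
* **Signal crossover** (index hopping): if one genomic site carries two or
  more labels and a minor label's total is below 0.1 × the major's, the
  minor counts are folded into the major. At realistic hop rates (~1%), the
  hopped fraction sits far below the 10:1 threshold.
* **Collisions**: the same site key in more than one animal is physically
  implausible; with a 10:1 dominant animal the site is removed from the
  others, with no dominant animal it is removed everywhere. Both ratios are
  exposed as parameters, since the counting literature treats them as assay
  configuration rather than universal constants.
* **Minimum-count filter**: sites whose total count across an animal's
  samples is below the number of samples for that animal are removed —
  junctions this rare are indistinguishable from PCR artifacts. The filter
  is strict (`<`) and idempotent.
* **Frequencies**: `p_i = s_i / S` per sample. Replicates are merged either
  by summing raw counts (used for diversity) or by averaging frequency
  vectors (used for clone-level tracking); averaging always happens at the
  statistic level, never by mixing counts of unequal depth.

# Clone analytics

Per-clone **maximum frequency** across tracked timepoints drives banding:
strictly below the first quartile is `low`, strictly above the third is
`high`, boundary values are `medium` because the banding rule is stated
with strict inequalities. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7, the common default). **Persistent**
clones have frequency > 0 at every tracked timepoint. **Top-k** clones are
the k highest at a timepoint with lexicographic tie-breaks, and the union
over timepoints forms the top-clone set. **Sharing** between two units is
`|V_i ∩ V_j|`, reported also as a row-relative percentage
(100·|V_i∩V_j|/|V_i|); row-relative is a documented convention — the
column- and union-relative variants are trivial to derive from the
returned counts.

**Replicate concordance** uses two statistics with different sensitivity:
Pearson's r (shape of the profile; invariant to affine shifts) and the
intraclass correlation in the single-rater, absolute-agreement form

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

from the two-way ANOVA decomposition of the n-clone × k-replicate matrix.
Absolute agreement penalises systematic between-replicate shifts that
Pearson ignores. The naming conventions for ICC forms conflict across the
literature ("ICC(3,1)" is usually the consistency form, yet "absolute
agreement" names the form above); this package implements the
absolute-agreement formula as the default and exposes
`type = "consistency"` for the other reading, so either convention is a
flag away.

# Diversity

Rényi entropy of order α, natural log:

$$H_\alpha = \frac{1}{1-\alpha}\log\sum_i p_i^\alpha$$

with analytic limits at α ∈ {1, ∞} and zero-frequency clones excluded from
the power sum. The default grid {0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, ∞}
includes every interpretable order: exp(H_0) is richness, H_1 Shannon, H_2
the log inverse Simpson index, and exp(−H_∞) the top clone's share. The
profile is non-increasing in α; a flat profile means perfectly even clones,
and a steeper profile means more uneven expansion. Profiles are computed
per replicate from raw counts, pooling vector populations (the index label
plays no role), then averaged per timepoint at the H level.

For the top-clone contribution both `exp(−H_∞)` (the share, in [0, 1]) and
its reciprocal `exp(H_∞)` (the Hill number of order ∞) are exposed; the
two are sometimes conflated in figure legends, and returning both makes
the choice explicit in downstream tables.

# Genomic and epigenomic context

* **Random-IS null**: the assay only recovers junctions within reach of a
  `GTAC` restriction site, so a fair null rejection-samples uniform genome
  positions until n lie within 1500 bp of a motif occurrence. The
  constraint is checked against motif *intervals* (distance 0 inside,
  else bp to the nearer edge); a motif-free genome raises an error rather
  than looping forever. A seed argument makes the null reproducible.
* **Nearest gene**: distance 0 inside a gene body, else bp to the nearest
  boundary; the biotype call (`protein_coding` / `lncRNA` / `other`,
  pseudogenes and remaining non-coding classes collapsing to `other`)
  applies within ±1 kb, beyond which a site is `distal`. Exact-distance
  ties break by biotype priority then gene id. Gene-body distance is the
  default because "within ±1 kb of a gene" is a body-relative statement;
  TSS-relative distance is available via `mode = "tss"`.
* **Activity**: a genic site is active iff its nearest gene has
  FPKM strictly greater than 1; distal sites have no activity call.
* **Peak distance**: 0 inside a peak interval, else bp to the nearest edge
  on the same chromosome (no peak on the chromosome → NA). Edge distance
  is the default since it is what makes "distance 0 inside the peak"
  exact; centre distance is a flag.
* **Distance histograms** bin |distance| into 100-bp bins over [0, 1 kb]
  (bin width is configuration, not a biological claim).
* **Enrichment**: 2×2 tables (VIS near / not near vs random near / not
  near) tested with the Pearson chi-squared statistic with Yates continuity
  correction, computed from the closed form and referred to the
  chi-squared distribution with 1 df.
* **Coverage matrices**: mean track coverage in bins across ±1 kb of each
  site (`reference_point`) or along gene bodies rescaled to a fixed bin
  count with 2 kb unscaled flanks, 5'→3' on the gene strand
  (`scale_regions`). Windows running off a chromosome end are zero-filled
  and flagged `clipped`. `coverage_pca` summarises each feature by its
  per-site mean coverage and projects features onto variance-maximising
  axes (`stats::prcomp`), which is how a gene-body-biased integration
  pattern separates H3K36me3-like marks from TSS marks.

# The synthetic generator

`sim_config()` fixes the study conditions; the defaults are the canonical
fixture used across the test suite: a 2 Mb, two-chromosome genome; 150
non-overlapping genes with a 70/15/15 biotype mix and log-normal FPKM
(meanlog 0, sdlog 1.5, putting about half the genes above the FPKM > 1
activity cutoff); peaks laid out in the canonical epigenomic geometry
(H3K36me3/H3K79me2 in active gene bodies, H3K4me3/H3K9ac/H3K9cr/H3K27ac/
RNApolII/ATAC at active TSSs, H3K4me1 at enhancer-like offsets, H3K27me3
over inactive bodies) with peak-consistent coverage tracks; 300 clones
placed by bias weights (0.5 H3K36me3 / 0.3 gene body / 0.05 TSS / 0.15
intergenic) under the GTAC-recoverability constraint; blood sampled at
weeks 13/15/17/19 in MDA duplicates at 19,000 reads per sample (~152k
reads).

Specific modelling choices:

* **Controlled motif density.** The background sequence is scrubbed of
  incidental `GTAC` occurrences and motifs are Poisson-planted at a
  configured rate (default 2/kb), so the motif density — which the random
  null and the recoverability constraint both depend on — is a controlled
  quantity rather than an accident of base composition.
* **Abundance model.** Initial clone abundances are log-normal
  (sdlog 1.2); across timepoints each clone takes multiplicative
  log-normal steps (sdlog 0.35 per two-week interval), so a minority of
  clones expands while richness stays nearly constant — the qualitative
  shape of post-transplant repopulation, without claiming any particular
  animal's dynamics.
* **Amplification noise.** Whole-genome amplification adds count
  overdispersion beyond Poisson sampling; per-clone, per-sample read
  counts are negative-binomial around depth × frequency. The dispersion
  default (size 30) is calibrated so that MDA-duplicate frequency profiles
  correlate at r ≈ 0.95 at the default depth, the replicate-concordance
  regime the assay is designed to operate in; it is fully configurable.
* **Artifact channels.** Per-base substitution error (0.002), LTR-index
  hopping (0.01, creating crossover signal below the 10:1 correction
  threshold), and a collision channel that copies the most abundant clones
  into a second animal at low count (so dominance resolution is exercised
  in the direction that occurs in practice). Clone junctions are kept at
  least 10 bp apart: two integrations within the 5-bp merge window would
  be indistinguishable from read jitter by construction, and base-level
  coincidence is vanishingly rare at genome scale.

What the generator does **not** emulate: real genome composition (repeats,
GC structure, segmental duplication — the mapper's multimapping path is
exercised with synthetic repeats instead), chimeric/PCR-recombinant reads,
indel sequencing error, locus-specific MDA bias correlated across
replicates, and engraftment kinetics. Passing the end-to-end suite
therefore shows the pipeline's logic is correct under the modelled error
channels, not that real-sample performance is bounded.

# Problem sizes and determinism

The default fixture (~152k reads, 2 Mb genome) runs through the full
pipeline in about 1–2 minutes on one CPU; unit tests use a 0.4 Mb / 60
clone / 50-reads-per-clone configuration chosen as the smallest size at
which the frequency-recovery property (per-sample Pearson r ≥ 0.9 against
truth) is meaningfully exercised. Every stochastic component — generator,
null sampler — is seeded, and fixture outputs are byte-identical under a
repeated seed. All analytics are deterministic given input order, with
explicit tie-break rules (modal positions toward smaller coordinates,
top-k by key order, nearest-gene ties by biotype priority).

# Known limitations

* The pipeline counts sequence reads, not sheared-fragment families; there
  is no UMI deduplication, so PCR jackpotting beyond the NB noise model is
  not corrected.
* Only the 3'-LTR (right) junction is analysed; left-junction support
  would double sensitivity but requires a second anchor configuration.
* The uniqueness rule (strictly better best placement) discards junctions
  in perfect repeats; on a real genome this biases against repetitive
  regions, as any unique-mapping rule does.
* ICC assumes homoscedastic clone frequencies; heavily skewed profiles are
  dominated by the largest clones, which is also true of Pearson's r. Rank
  statistics are deliberately out of scope.
* The distal/genic boundary (±1 kb), the activity threshold (FPKM > 1),
  and the distance bin width (100 bp) are conventions of the assay's
  literature, exposed as parameters rather than inferred from data.
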