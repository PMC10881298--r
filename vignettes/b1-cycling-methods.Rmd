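---
title: "Methods: tracing vitamin B1 cycling through genomes, transcripts and chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing vitamin B1 cycling through genomes, transcripts and chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b1cycle)
```

`b1cycle` joins four lines of evidence about thiamin (B1) supply and
demand in a microbial community: genome-resolved gene content, normalized
gene and transcript abundances, targeted LC--MS chemistry, and a growth
bioassay. This vignette explains the models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## Genotype model

A population synthesizes B1 de novo only if it can make the pyrimidine
moiety (`thiC`), the thiazole moiety (`thiG`) and condense them
(`thiE`). `classify_gene_set()` therefore applies a strict cascade:
prototroph requires all three; losing only `thiC` or only `thiG` while
keeping `thiE` yields the corresponding partial auxotrophy (those
organisms salvage the missing moiety from vitamers); everything else is
classified by its acquisition repertoire --- dedicated B1 transporters
(`thiB`, `thiT`), then putative pyrimidine/B1 transporters (`thiV`,
`thiY`, `cytX`, `ykoF`, `thiPerm`, `omr1`), and finally "no known
route". Three choices deserve comment:

* **`thiE` is required for any synthesis-based category.** A genome with
  `thiC` and `thiG` but no `thiE` cannot condense the moieties, so it
  falls through to the transport rules rather than being called a
  near-prototroph.
* **Salvage genes never set the category.** `tenA` (pyrimidine) and
  `thiM` (thiazole) describe how an auxotroph meets its requirement; they
  are reported in the repertoire only.
* **Presence means presence in at least one MAG** of the cluster
  (`presence_threshold = 0`). Gene loss in individual MAGs is common at
  realistic completeness, so any detection within the 95 % ANI cluster
  counts; the threshold is exposed for stricter definitions.

Absence is only evidence when the genomes are near-complete. A cluster
with no MAG at ≥ 90 % completeness / < 5 % contamination gets confidence
`low_completeness` and is excluded from community summaries by default.
Community auxotroph fractions are emitted both as cluster counts and
abundance-weighted, since either convention is defensible and they can
differ substantially.

## Normalization model

Raw mapped-read counts are converted to RPKM,
$\mathrm{RPKM} = c \,/\, \big((L/10^3)(M/10^6)\big)$, with $L$ the
feature length and $M$ the sample's mapped reads, then divided by the
per-sample **median RPKM of 21 single-copy marker genes**. The marker
median estimates "genome equivalents per sample", so the normalized value
of a gene is its mean copy number per genome --- exactly 1 for a
universal single-copy gene. The marker set is an input, not hard-coded.
Medians over an even marker count use the midpoint of the two central
values. When features sharing a gene label are aggregated, per-feature
RPKM values are summed: per-copy abundances add, and this keeps
community gene ratios exact in the noiseless limit.

Two published conventions exist for relating transcripts to genes, and
both are implemented behind `transcript_activity(mode =)`: `"marker"`
(default) divides metatranscriptome RPKM by the metatranscriptome's own
marker median; `"metagenome"` divides elementwise by the
marker-normalized metagenome value. The mode is recorded on the output.
Per-cluster thiC contributions (`thic_contribution()`) scale each
timepoint to 100 %, flagging all-zero timepoints rather than dividing by
zero.

## LC--MS reduction

Calibration lines are fitted by ordinary least squares on peak areas per
compound and batch; at least three distinct levels are required and a
non-positive slope is rejected as non-quantifiable. Limits follow the
3σ/10σ convention: LOD = 3 × and LOQ = 10 × the *sample standard
deviation* of the inter-sample blank responses ("variation" is not
otherwise defined; SD is the standard reading). For dissolved samples
the QC-response variation can substitute (`mode = "qc"`).

A concentration is the mean of two technical injections, reported only
when both exceed the LOD. Values between LOD and LOQ require an explicit
`accept` annotation --- a declarative stand-in for visual inspection of
the chromatograms --- and default to rejected, so unreviewed borderline
values never enter summaries. Outliers are removed only via a declarative
exclusion list; there is no automatic rejection rule.

**Internal-standard handling.** The ¹³C-B1 internal standard is spiked
before extraction, so its measured area scales with the same per-sample
recovery as the analyte, while calibration standards (run in the pooled
QC matrix) carry it at full strength. Dividing sample areas by the IS
area *and* separately dividing by an IS-derived recovery estimate would
correct twice. The pipeline therefore back-calculates from raw areas
against the area-based calibration and divides once by the per-sample
recovery `is_area / is_expected_area`; this is algebraically identical to
normalizing sample areas to ¹³C-B1 and reading them off an IS-normalized
curve. Recoveries outside (0, 1.5] flag the sample as excluded. Vitamers
without their own labeled standard use per-compound literature constants
supplied in configuration.

## Bioassay inversion

Reporter growth yield is modeled as linear in B1 over the standard range
(5--75 pM plus negative controls at 0, four replicates each); samples are
diluted 1:10 into assay medium, so the reported value is
$\hat{C} = (\bar{y} - b_0)/b_1 \times 10$. Uncertainty comes from a
nonparametric bootstrap (default 200 draws) that resamples the sample
replicates and the standard replicates within level and refits the curve
each draw. The default interval is $\hat{C} \pm t_{0.975,\,n-1}\,
\mathrm{SD}_{boot}$: with four replicates, percentile intervals
undercover noticeably, while the t-scaled normal interval compensates
for the small-sample downward bias of the bootstrap SD. A percentile
option is provided. Estimates below the negative-control mean are
flagged `below_assay_floor`, and in-tube estimates outside the standard
range are flagged `extrapolated` rather than suppressed.

## Correlation screening

`kendall_screen()` uses tie-corrected tau-b (environmental series
routinely contain ties) on pairwise-complete observations, requiring at
least three pairs. For short series (n ≤ 8 by default) the p-value is an
exact two-sided permutation test: the tie correction in tau-b's
denominator is invariant under permutation, so the null distribution of
the concordance numerator is enumerated over all $n!$ permutations.
Beyond `exact_max` the tie-corrected normal approximation takes over.
The cap sits at 8 because enumeration grows factorially (8! = 40 320
permutations run in milliseconds; 10! is 3.6 million) and is exposed as
a parameter for users who want exact tests on longer series.
Significance is exactly p < .05 with no multiplicity correction, which
matches common practice for exploratory seasonal screens; treat the
flags as screening, not inference. Biomass conversion uses 20 fg C per
cell: $10^6$ cells ml⁻¹ ↦ 20 µg C l⁻¹.

## What the synthetic generator emulates

The generator produces every input with known truth:

* **Genomes and MAGs.** Each genome gets its B1 genes (typical bacterial
  lengths), 21 single-copy markers, and filler genes (default 60--100) so
  that realized completeness is estimated over a realistic gene count.
  MAG incompleteness is per-gene independent Bernoulli retention --- the
  simplest model consistent with a CheckM-style completeness percentage
  --- and contamination inserts foreign genes at a per-gene rate.
  Reported quality values are the *realized* ones. TDP riboswitches are
  placed 20--200 bp upstream of linked genes, inside the 500 bp
  adjacency window.
* **Counts.** Expected counts are proportional to relative abundance ×
  gene length × depth, rescaled to the sample depth; noise is Poisson by
  default with negative-binomial overdispersion as an option, and a
  noiseless mode for exact algebra. Metatranscriptome mode multiplies by
  per-gene log-normal expression factors (markers and filler at 1),
  retained as ground truth.
* **Chemistry.** Peak areas are slope × concentration × recovery ×
  log-normal(1, CV) --- multiplicative noise with a concentration-
  proportional CV, typical of triple-quadrupole data --- with blanks at a
  noise floor, calibration and QC rows, and exactly two injections per
  sample. The default simulated recovery regime is 24 ± 7 %.
* **Bioassay.** Yields linear in B1 with Gaussian noise, the 5--75 pM
  standard series with four replicates, negative controls, and 1:10
  sample dilution.

What it does **not** emulate: read-level sequencing artifacts (assembly
and binning errors beyond Bernoulli gene loss, chimeric contigs,
strain-level variation), compositional coupling between populations,
chromatogram shapes and peak-integration error, matrix effects that bend
calibration lines, or growth kinetics beyond endpoint yields. Passing
tests therefore demonstrate that the *computations* are correct and that
the pipeline recovers truth under its own stated noise models --- not
that those models capture every failure mode of real field data.

## Numerical choices and degenerate inputs

* Best-hit ties in annotation break by lower e-value, then lexicographic
  profile id --- fully deterministic curation.
* A zero marker median makes the sample's normalized values missing (with
  a warning), never infinite; zero denominators in activities and ratios
  become `NA`; an absent numerator gene gives ratio 0, an absent
  denominator `NA`.
* Gene-ratio aggregation, LOD/LOQ, presence fractions and thiC
  contributions are all tested against independent brute-force oracles;
  the genotype cascade is verified against an independently coded rule
  ladder over all $2^{13}$ gene subsets.
* Standard-curve slopes that are numerically zero (constant yields) are
  rejected as assay failures rather than producing huge inversions.
* Problem sizes in the test suite are chosen for tight feedback: e.g.
  200 clusters × 3 MAGs at 90 % completeness for genotype recovery, 100
  replicate batches for quantification bias, 100 assays × 200 bootstrap
  draws for interval coverage.

## Known limitations

Genotype calls inherit the annotation: a gene absent from the profile
library, or below its bit-score cutoff, is invisible. The pipeline does
not model phosphorylated B1 forms (TMP/TDP quantification is out of
scope beyond flagging), does not assign taxonomy, and treats the marker
set as given. The two metatranscriptome normalization conventions give
different absolute scales --- comparisons across studies must check the
recorded mode.
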