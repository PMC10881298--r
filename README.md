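# b1cycle

Vitamin B1 (thiamin) is an essential cofactor, yet most marine
bacterioplankton cannot synthesize it de novo and depend on external B1 or
on B1-related compounds (vitamers: HMP, HET, FAMP, AmMP, cHET) that can be
salvaged into the intact vitamin. Understanding who produces, who consumes
and who salvages B1 in a coastal community requires joining four very
different measurements: genome-resolved gene content, community gene and
transcript abundances, trace-level chemical quantification, and bioassays.
`b1cycle` implements that full analysis chain as a tested R package, aimed
at microbial ecologists working with metagenome-assembled genomes (MAGs)
and targeted metabolite data. A synthetic-data module generates every
input with known ground truth, so each stage of the pipeline is scored
against what it should recover.

## What it computes

**Cluster genotyping.** MAGs are grouped into 95 % ANI clusters and each
cluster is screened for thirteen B1-related genes. The rule cascade is:

* `thiC ∧ thiG ∧ thiE` → **prototroph** (full de novo synthesis);
* `¬thiC ∧ thiG ∧ thiE` → **pyrimidine auxotroph** (needs HMP-type vitamers);
* `thiC ∧ ¬thiG ∧ thiE` → **thiazole auxotroph**;
* otherwise `thiB ∨ thiT` → **auxotroph with B1 transport**;
* otherwise any of `thiV, thiY, cytX, ykoF, thiPerm, omr1` → **auxotroph
  with putative transport**;
* else **no known route**.

Salvage genes (`tenA`, `thiM`) are reported as capabilities but never set
the category. Absence calls are only trusted for clusters containing at
least one high-quality MAG (≥ 90 % completeness, < 5 % contamination);
others are flagged `low_completeness`. TDP-riboswitch adjacency
(end-to-start gap ≤ 500 bp on the same contig) supports the B1-related
role of transporter genes.

**Abundance statistics.** Counts are normalized as
`RPKM = count / ((L/10³)(M/10⁶))` and then divided by the per-sample
median RPKM of 21 single-copy marker genes, giving gene abundance per
genome equivalent. Community synthesis-gene ratios (thiC:thiE, thiG:thiE)
measure auxotroph prevalence — an all-prototroph community sits at 1:1:1.
Transcript activity and per-cluster percentages of total thiC
transcription localize de novo production in time and taxonomy.

**LC–MS quantification.** Matrix-matched calibration per compound and
batch; LOD = 3 × and LOQ = 10 × the standard deviation of inter-sample
blanks; concentrations reported as the mean of two technical injections
only when both exceed the LOD, with borderline (LOD–LOQ) values requiring
an explicit review annotation; dissolved B1 corrected by the per-sample
recovery of the ¹³C-B1 internal standard.

**Bioassay.** Growth yields of a B1-auxotrophic reporter are calibrated
against an internal standard curve (5–75 pM plus negative controls); the
sample estimate is `(ȳ − b₀)/b₁ × dilution` with bootstrap uncertainty.

**Screening.** Kendall tau-b correlations over environmental, chemical
and gene-abundance time series, exact permutation p-values for short
series, significance at p < .05 without multiplicity correction; bacterial
biomass from cell counts at 20 fg C per cell.

## Worked example

The `analysis/` drivers run the whole chain on a 12-population,
12-timepoint synthetic coastal community (all six genotype archetypes,
seasonal abundances, 24 ± 7 % extraction recovery):

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_genotype_clusters.R
Rscript analysis/03_gene_transcript_profiles.R
Rscript analysis/04_vitamin_quantification.R
Rscript analysis/05_correlation_screen.R
```

which prints, among other things:

```
Called 12 clusters; 5 callable, 7 flagged low-completeness
Auxotroph fraction among callable clusters: 60% (abundance-weighted range 45-76%)
Genotype recovery vs ground truth: 100.0%
Community synthesis-gene ratios: thiC:thiE = 0.49, thiG:thiE = 0.97
Dissolved B1 across the series: 72-113 pM (mean 92 pM), 12/12 timepoints quantified
Mean internal-standard recovery: 24% (true regime 24%)
Bioassay bioavailable B1 (t06): 90 +/- 6.4 pM (true 90 pM)
```

Read: of the twelve simulated populations only five clusters had a
high-quality MAG and could be genotyped with trusted absences; 60 % of
those are auxotrophs. The community thiC:thiE ratio of 0.49 is well below
the prototroph expectation of 1, reflecting the simulated prevalence of
pyrimidine auxotrophs; thiG:thiE ≈ 1 because nearly all thiG carriers
also carry thiE. The quantification stage recovers the simulated seasonal
B1 series and the 24 % recovery regime, and the bioassay inversion hits
the generating truth within its bootstrap uncertainty. Tables land under
`results/`.

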