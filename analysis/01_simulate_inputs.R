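#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume —
# annotated genomes, MAGs with realistic incompleteness, metagenome and
# metatranscriptome counts — and write them with their ground truth.

source("analysis/00_scenario.R")

sc <- make_study_scenario()
gen <- sc$genomes
out <- results_dir("synthetic")

# MAGs: 2 per population, completeness drawn from the medium-to-high range
set.seed(STUDY_SEED + 3)
comp <- stats::runif(length(unique(gen$features$genome_id)), 0.7, 0.99)
mags <- sample_mags(gen, completeness = comp, contamination_rate = 0.01,
                    n_mags_per_genome = 2, seed = STUDY_SEED + 4)

write_features_gff3(gen$features, file.path(out, "genomes.gff3"))
write_features_gff3(mags$features, file.path(out, "mags.gff3"))
write_tsv_table(mags$quality, file.path(out, "mag_quality.tsv"))
write_tsv_table(mags$cluster_map, file.path(out, "cluster_map.tsv"))

mg <- simulate_counts(sc, "metagenome", noise = "poisson", seed = STUDY_SEED + 5)
mt <- simulate_counts(sc, "metatranscriptome", noise = "poisson",
                      seed = STUDY_SEED + 6)
save_matrix <- function(m, stem) {
  write_tsv_table(cbind(m$features, as.data.frame(m$values)),
                  file.path(out, paste0(stem, "_counts.tsv")))
  write_tsv_table(tibble::tibble(sample_id = names(m$mapped_reads),
                                 mapped_reads = m$mapped_reads),
                  file.path(out, paste0(stem, "_mapped_reads.tsv")))
}
save_matrix(mg, "metagenome")
save_matrix(mt, "metatranscriptome")

write_ground_truth(list(
  genotypes = gen$truth,
  cluster_truth = mags$cluster_truth,
  abundances = as.data.frame(sc$abundances),
  seed = STUDY_SEED), file.path(out, "ground_truth.yaml"))

n_high <- sum(mag_quality_tier(mags$quality$completeness,
                               mags$quality$contamination) == "high")
cat("Simulated", length(unique(gen$features$genome_id)), "populations,",
    nrow(mags$quality), "MAGs (", n_high, "high-tier ),",
    ncol(sc$abundances), "timepoints at depth", format(sc$depth[1]), "\n")
cat("Inputs and ground truth written under", out, "\n")
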