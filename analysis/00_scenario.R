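# Shared study scenario for the analysis drivers: a 12-timepoint coastal
# community of twelve populations spanning all six B1 genotype archetypes,
# with seasonally varying relative abundances. Sourced by the numbered
# drivers so every stage works from the same ground truth.

library(b1cycle)

STUDY_SEED <- 20200604L

make_study_genomes <- function(seed = STUDY_SEED) {
  archetypes <- list(
    vulcano1  = list(genes = c("thiC", "thiG", "thiE")),                        # prototroph (picocyanobacterium-like)
    vulcano2  = list(genes = c("thiC", "thiG", "thiE")),
    bacl14    = list(genes = c("thiC", "thiG", "thiE", "thiB")),                # prototroph that can also transport
    pelagi1   = list(genes = c("thiG", "thiE", "thiV", "tenA"), rs = "thiV"),   # pyrimidine auxotroph, riboswitch-linked thiV
    pelagi2   = list(genes = c("thiG", "thiE", "thiV", "tenA"), rs = "thiV"),
    punicei   = list(genes = c("thiC", "thiE", "thiM")),                        # thiazole auxotroph with salvage
    actino1   = list(genes = c("thiB")),                                        # B1 transporter
    actino2   = list(genes = c("thiB", "ykoF")),
    sar86     = list(genes = c("omr1"), rs = "omr1"),                           # putative transporter near a riboswitch
    flavo1    = list(genes = c("cytX", "thiPerm")),
    flavo2    = list(genes = character()),                                      # no known route
    firmi     = list(genes = c("thiT"))
  )
  specs <- lapply(names(archetypes), function(id) {
    a <- archetypes[[id]]
    genome_spec(id, a$genes, riboswitch_links = a$rs %||% character(),
                n_other_genes = 60)
  })
  generate_genomes(specs, seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_study_scenario <- function(seed = STUDY_SEED, n_timepoints = 12,
                                depth = 2e6) {
  gen <- make_study_genomes(seed)
  ids <- unique(gen$features$genome_id)
  set.seed(seed + 1)
  # smooth seasonal trajectories: gamma baseline modulated by a sinusoid so
  # picocyanobacteria peak mid-series (summer) as in temperate systems
  t <- seq_len(n_timepoints)
  ab <- sapply(seq_along(ids), function(i) {
    phase <- stats::runif(1, 0, 2 * pi)
    base <- stats::rgamma(1, 2)
    base * exp(0.8 * sin(2 * pi * t / n_timepoints + phase))
  })
  ab <- t(ab)
  ab <- sweep(ab, 2, colSums(ab), "/")
  rownames(ab) <- ids
  colnames(ab) <- sprintf("t%02d", t)
  community_scenario(gen, ab, depth = depth, seed = seed + 2)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
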