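#' Specify a ground-truth genome for simulation
#'
#' Builds a validated genome specification: its B1 gene complement, the
#' genotype category that complement implies, the single-copy marker
#' complement used downstream for normalization, and which genes sit next
#' to a TDP riboswitch. The gene set must be consistent with the declared
#' genotype under the classification rules; inconsistent specifications are
#' refused with the conflicting rule named.
#'
#' @param genome_id Identifier.
#' @param gene_set Character vector of B1 gene labels
#'   (subset of [b1_gene_vocabulary()]).
#' @param true_genotype Category label; default derived from `gene_set`.
#' @param n_marker_genes Number of single-copy marker genes (default 21,
#'   mirroring the Pfam marker models used for normalization).
#' @param n_other_genes Number of unlabelled filler genes, so realized MAG
#'   completeness is estimated over a realistic gene count (default 100).
#' @param genome_length Genome size in bp (informational).
#' @param riboswitch_links Gene labels to be placed adjacent to a TDP
#'   riboswitch feature (subset of `gene_set`).
#' @return A `b1_genome_spec` list.
#' @export
genome_spec <- function(genome_id, gene_set, true_genotype = NULL,
                        n_marker_genes = 21, n_other_genes = 100,
                        genome_length = 3e6, riboswitch_links = character()) {
  gene_set <- unique(gene_set)
  implied <- classify_gene_set(gene_set)
  if (is.null(true_genotype)) true_genotype <- implied
  if (!identical(true_genotype, implied)) {
    stop("gene_set {", paste(gene_set, collapse = ","),
         "} classifies as ", implied, " under the genotype rule cascade, ",
         "not ", true_genotype)
  }
  if (n_marker_genes < 1) stop("n_marker_genes must be >= 1")
  if (!all(riboswitch_links %in% gene_set)) {
    stop("riboswitch_links must be a subset of gene_set")
  }
  structure(list(genome_id = genome_id, true_genotype = true_genotype,
                 gene_set = gene_set, n_marker_genes = n_marker_genes,
                 n_other_genes = n_other_genes, genome_length = genome_length,
                 riboswitch_links = riboswitch_links),
            class = "b1_genome_spec")
}

#' Generate annotated synthetic genomes
#'
#' Lays out one feature per B1 gene, `n_marker_genes` marker features and
#' `n_other_genes` filler genes on a single contig per genome, with 1-based
#' inclusive coordinates and random strands. For every gene in
#' `riboswitch_links` a `riboswitch_TDP` feature is placed on the same
#' contig with an end-to-start gap below `riboswitch_window`. Deterministic
#' for a fixed seed.
#'
#' @param specs List of [genome_spec()] objects.
#' @param seed Integer seed.
#' @param riboswitch_window Maximum gap (bp) between a linked gene and its
#'   riboswitch (default 500, matching the adjacency detector's default).
#' @return List: `features` (tibble with genome_id, contig_id, feature_id,
#'   gene_label, start, end, strand, length, is_marker), `truth` (tibble of
#'   genome_id, true_genotype).
#' @export
generate_genomes <- function(specs, seed = 1L, riboswitch_window = 500L) {
  if (inherits(specs, "b1_genome_spec")) specs <- list(specs)
  lapply(specs, function(s) {
    if (!inherits(s, "b1_genome_spec")) stop("specs must be genome_spec objects")
  })
  set.seed(seed)
  glen <- default_gene_lengths()
  feats <- lapply(specs, function(s) {
    labels <- c(s$gene_set,
                sprintf("marker_%02d", seq_len(s$n_marker_genes)),
                if (s$n_other_genes > 0) sprintf("other_%04d", seq_len(s$n_other_genes)))
    lens <- c(unname(glen[s$gene_set]),
              round(stats::runif(s$n_marker_genes, 800, 1400)),
              if (s$n_other_genes > 0) round(stats::runif(s$n_other_genes, 500, 2000)))
    is_marker <- c(rep(FALSE, length(s$gene_set)),
                   rep(TRUE, s$n_marker_genes),
                   rep(FALSE, s$n_other_genes))
    ord <- sample(length(labels))
    labels <- labels[ord]; lens <- lens[ord]; is_marker <- is_marker[ord]

    n_est <- length(labels) + length(s$riboswitch_links)
    r_label <- character(n_est); r_start <- integer(n_est)
    r_end <- integer(n_est); r_strand <- character(n_est)
    r_len <- integer(n_est); r_mark <- logical(n_est)
    j <- 0L; pos <- 1L
    for (i in seq_along(labels)) {
      if (labels[i] %in% s$riboswitch_links) {
        # riboswitch immediately upstream, gap strictly inside the window
        rs_len <- 110L
        gap <- sample(20:min(200L, riboswitch_window - 1L), 1)
        j <- j + 1L
        r_label[j] <- "riboswitch_TDP"; r_start[j] <- pos
        r_end[j] <- pos + rs_len - 1L; r_strand[j] <- "+"
        r_len[j] <- rs_len; r_mark[j] <- FALSE
        pos <- pos + rs_len + gap
      }
      j <- j + 1L
      r_label[j] <- labels[i]; r_start[j] <- pos
      r_end[j] <- pos + lens[i] - 1L
      r_strand[j] <- sample(c("+", "-"), 1)
      r_len[j] <- lens[i]; r_mark[j] <- is_marker[i]
      pos <- pos + lens[i] + sample(50:500, 1)
    }
    df <- tibble::tibble(gene_label = r_label[1:j], start = r_start[1:j],
                         end = r_end[1:j], strand = r_strand[1:j],
                         length = r_len[1:j], is_marker = r_mark[1:j])
    df$genome_id <- s$genome_id
    df$contig_id <- paste0(s$genome_id, "_contig1")
    df$feature_id <- paste0(s$genome_id, ":", df$gene_label,
                            ":", seq_len(nrow(df)))
    df[, c("genome_id", "contig_id", "feature_id", "gene_label",
           "start", "end", "strand", "length", "is_marker")]
  })
  list(
    features = dplyr::bind_rows(feats),
    truth = tibble::tibble(
      genome_id = vapply(specs, `[[`, character(1), "genome_id"),
      true_genotype = vapply(specs, `[[`, character(1), "true_genotype"))
  )
}

#' Sample MAGs from synthetic genomes
#'
#' Emulates incomplete, possibly contaminated genome binning: each gene of
#' the source genome is retained independently with probability
#' `completeness`, and for each source gene a foreign gene drawn from the
#' other genomes is inserted with probability `contamination_rate`. The
#' quality table reports *realized* completeness (retained fraction of
#' source genes) and contamination (foreign genes as a percentage of source
#' genes). Each source genome defines one ANI cluster containing all its
#' MAGs.
#'
#' @param genomes Output of [generate_genomes()].
#' @param completeness Retention probability in [0, 1]; scalar or one value
#'   per genome.
#' @param contamination_rate Per-gene foreign insertion probability.
#' @param n_mags_per_genome MAGs sampled per genome (>= 1).
#' @param seed Integer seed.
#' @return List: `features` (MAG feature tibble with `mag_id` and
#'   `cluster_id`), `quality` (tibble mag_id, cluster_id, completeness,
#'   contamination in percent), `cluster_map` (mag_id, cluster_id),
#'   `cluster_truth` (cluster_id, true_category).
#' @export
sample_mags <- function(genomes, completeness, contamination_rate = 0,
                        n_mags_per_genome = 1L, seed = 1L) {
  if (n_mags_per_genome < 1) stop("n_mags_per_genome must be >= 1")
  stopifnot(all(completeness >= 0 & completeness <= 1),
            contamination_rate >= 0, contamination_rate <= 1)
  set.seed(seed)
  feats <- genomes$features
  genome_ids <- unique(feats$genome_id)
  comp <- rep_len(completeness, length(genome_ids))
  names(comp) <- genome_ids

  mag_rows <- list(); qual_rows <- list()
  for (g in genome_ids) {
    src <- feats[feats$genome_id == g, , drop = FALSE]
    pool <- feats[feats$genome_id != g & !feats$is_marker &
                    feats$gene_label != "riboswitch_TDP", , drop = FALSE]
    for (k in seq_len(n_mags_per_genome)) {
      mag_id <- sprintf("%s_mag%02d", g, k)
      keep <- stats::runif(nrow(src)) < comp[g]
      mag <- src[keep, , drop = FALSE]
      n_foreign <- stats::rbinom(1, nrow(src), contamination_rate)
      if (n_foreign > 0 && nrow(pool) > 0) {
        fg <- pool[sample(nrow(pool), n_foreign, replace = TRUE), , drop = FALSE]
        fg$contig_id <- paste0(mag_id, "_contamination")
        mag <- dplyr::bind_rows(mag, fg)
      } else {
        n_foreign <- 0L
      }
      mag$mag_id <- mag_id
      mag$cluster_id <- paste0("cluster_", g)
      mag_rows[[mag_id]] <- mag
      qual_rows[[mag_id]] <- tibble::tibble(
        mag_id = mag_id, cluster_id = paste0("cluster_", g),
        completeness = 100 * sum(keep) / nrow(src),
        contamination = 100 * n_foreign / nrow(src))
    }
  }
  quality <- dplyr::bind_rows(qual_rows)
  truth <- genomes$truth
  list(
    features = dplyr::bind_rows(mag_rows),
    quality = quality,
    cluster_map = quality[, c("mag_id", "cluster_id")],
    cluster_truth = tibble::tibble(
      cluster_id = paste0("cluster_", truth$genome_id),
      true_category = truth$true_genotype)
  )
}
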