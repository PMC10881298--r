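#' Filter profile-search hits into curated gene calls
#'
#' Applies per-profile bit-score cutoffs to hmmsearch-style hits and
#' resolves multi-profile proteins to a single gene label: a protein keeps
#' the highest-scoring hit that passes its profile's cutoff. Ties on bit
#' score break by lower e-value, then lexicographic profile id. Proteins on
#' the manual false-positive list are retained with `fp_override = TRUE`
#' and are excluded from genotyping downstream.
#'
#' @param hits Data frame: `protein_id`, `profile_id`, `bit_score`,
#'   `e_value`, and optionally `mag_id`. Duplicate (protein, profile) rows
#'   are rejected.
#' @param cutoffs Data frame `profile_id`, `cutoff`, and optionally
#'   `gene_label` mapping the profile to the B1 vocabulary (default: the
#'   profile id is the gene label). Profiles absent from the table get
#'   `default_cutoff`, with a message.
#' @param overrides Character vector of protein ids considered false
#'   positives after manual evaluation.
#' @param default_cutoff Bit-score cutoff for unlisted profiles.
#' @return Tibble of curated calls: `protein_id`, `mag_id`, `gene_label`,
#'   `profile_id`, `bit_score`, `e_value`, `curated`, `fp_override`.
#' @export
filter_hits <- function(hits, cutoffs, overrides = character(),
                        default_cutoff = 50) {
  stopifnot(all(c("protein_id", "profile_id", "bit_score", "e_value") %in% names(hits)))
  if (any(hits$e_value < 0)) stop("e_value must be >= 0")
  dup <- duplicated(hits[, c("protein_id", "profile_id")])
  if (any(dup)) {
    stop("duplicate (protein, profile) row(s): ",
         paste(paste(hits$protein_id[dup], hits$profile_id[dup], sep = "/"),
               collapse = ", "))
  }
  if (!"mag_id" %in% names(hits)) hits$mag_id <- NA_character_
  if (!"gene_label" %in% names(cutoffs)) cutoffs$gene_label <- cutoffs$profile_id

  idx <- match(hits$profile_id, cutoffs$profile_id)
  missing_prof <- unique(hits$profile_id[is.na(idx)])
  if (length(missing_prof) > 0) {
    message("profile(s) without a cutoff, using default ", default_cutoff,
            ": ", paste(missing_prof, collapse = ", "))
  }
  hits$cutoff <- ifelse(is.na(idx), default_cutoff, cutoffs$cutoff[idx])
  hits$gene_label <- ifelse(is.na(idx), hits$profile_id, cutoffs$gene_label[idx])

  passed <- hits[hits$bit_score >= hits$cutoff, , drop = FALSE]
  if (nrow(passed) > 0) {
    ord <- order(passed$protein_id, -passed$bit_score, passed$e_value,
                 passed$profile_id)
    passed <- passed[ord, , drop = FALSE]
    passed <- passed[!duplicated(passed$protein_id), , drop = FALSE]
  }
  tibble::tibble(
    protein_id = passed$protein_id, mag_id = passed$mag_id,
    gene_label = passed$gene_label, profile_id = passed$profile_id,
    bit_score = passed$bit_score, e_value = passed$e_value,
    curated = TRUE, fp_override = passed$protein_id %in% overrides)
}

interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Detect genes adjacent to a TDP riboswitch
#'
#' A gene is riboswitch-associated when a `riboswitch_TDP` feature lies on
#' the same contig with an end-to-start gap of at most `window_bp`
#' (overlap counts as gap 0). Strand-agnostic; invariant to feature order.
#'
#' @param features Feature data frame with `contig_id`, `gene_label`,
#'   `start`, `end` (1-based inclusive) and optionally `mag_id`,
#'   `feature_id`. Riboswitch features carry label "riboswitch_TDP".
#' @param window_bp Maximum gap in bp (default 500).
#' @return Tibble of associations: one row per (gene feature, riboswitch)
#'   pair within the window, with `gap_bp`.
#' @export
detect_riboswitch_adjacency <- function(features, window_bp = 500L) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (nrow(features) == 0) {
    return(tibble::tibble(mag_id = character(), contig_id = character(),
                          gene_label = character(), gene_start = integer(),
                          gene_end = integer(), gap_bp = integer()))
  }
  stopifnot(all(c("contig_id", "gene_label", "start", "end") %in% names(features)),
            all(features$start <= features$end))
  if (!"mag_id" %in% names(features)) features$mag_id <- NA_character_
  rs <- features[features$gene_label == "riboswitch_TDP", , drop = FALSE]
  genes <- features[features$gene_label != "riboswitch_TDP", , drop = FALSE]
  out <- list()
  for (ct in intersect(unique(genes$contig_id), unique(rs$contig_id))) {
    g <- genes[genes$contig_id == ct, , drop = FALSE]
    r <- rs[rs$contig_id == ct, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      gaps <- interval_gap(g$start[i], g$end[i], r$start, r$end)
      hit <- which(gaps <= window_bp)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          mag_id = g$mag_id[i], contig_id = ct, gene_label = g$gene_label[i],
          gene_start = g$start[i], gene_end = g$end[i],
          gap_bp = as.integer(gaps[hit]))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mag_id = character(), contig_id = character(),
                          gene_label = character(), gene_start = integer(),
                          gene_end = integer(), gap_bp = integer()))
  }
  dplyr::bind_rows(out)
}
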