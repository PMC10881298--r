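#' Classify a gene set into a B1 physiology category
#'
#' Applies the rule cascade used for cluster genotyping. A population is a
#' prototroph if it carries all three de novo synthesis genes (`thiC`,
#' `thiG`, `thiE`); lacking only `thiC` (pyrimidine branch) or only `thiG`
#' (thiazole branch) while retaining `thiE` gives the corresponding partial
#' auxotrophy; otherwise the category is decided by the acquisition
#' repertoire: dedicated B1 transport (`thiB`/`thiT`), then putative
#' pyrimidine/B1 transporters, and finally `NO_KNOWN_ROUTE` when no
#' recognized synthesis or acquisition gene is present. `thiE` is required
#' for any synthesis-based category; salvage genes (`tenA`, `thiM`) never
#' change the category.
#'
#' @param genes Character vector of present gene labels (subset of
#'   [b1_gene_vocabulary()]), or a named logical vector over the vocabulary.
#' @return A single category string, one of [b1_genotype_categories()].
#' @export
#' @examples
#' classify_gene_set(c("thiC", "thiG", "thiE"))   # PROTOTROPH
#' classify_gene_set(c("thiG", "thiE", "thiV"))   # PYRIMIDINE_AUXOTROPH
classify_gene_set <- function(genes) {
  vocab <- b1_gene_vocabulary()
  if (is.logical(genes)) {
    stopifnot(!is.null(names(genes)))
    genes <- names(genes)[genes]
  }
  bad <- setdiff(genes, vocab)
  if (length(bad) > 0) {
    stop("unknown gene label(s): ", paste(bad, collapse = ", "))
  }
  has <- vocab %in% genes
  names(has) <- vocab
  roles <- b1_gene_roles()
  if (has["thiC"] && has["thiG"] && has["thiE"]) return("PROTOTROPH")
  if (!has["thiC"] && has["thiG"] && has["thiE"]) return("PYRIMIDINE_AUXOTROPH")
  if (has["thiC"] && !has["thiG"] && has["thiE"]) return("THIAZOLE_AUXOTROPH")
  if (any(has[roles$b1_transport])) return("AUXOTROPH_B1_TRANSPORT")
  if (any(has[roles$putative_transport])) return("AUXOTROPH_PUTATIVE_TRANSPORT")
  "NO_KNOWN_ROUTE"
}

#' Acquisition/salvage repertoire of a gene set
#'
#' All transport and salvage genes present, reported regardless of the
#' category (capabilities, not category definitions).
#'
#' @param genes Character vector of present gene labels.
#' @return Character vector (possibly empty) in vocabulary order.
#' @export
gene_repertoire <- function(genes) {
  roles <- b1_gene_roles()
  rep_genes <- c(roles$b1_transport, roles$putative_transport, roles$salvage)
  intersect(intersect(b1_gene_vocabulary(), rep_genes), genes)
}

#' Assign MAG quality tiers
#'
#' Tiers follow the standard draft-genome thresholds: medium quality needs
#' >= 50% completeness and < 10% contamination; high quality needs >= 90%
#' completeness and < 5% contamination.
#'
#' @param completeness,contamination Numeric vectors in percent (0-100).
#' @return Character vector: "high", "medium" or "below_medium".
#' @export
mag_quality_tier <- function(completeness, contamination) {
  stopifnot(all(completeness >= 0 & completeness <= 100, na.rm = TRUE),
            all(contamination >= 0, na.rm = TRUE))
  tier <- rep("below_medium", length(completeness))
  tier[completeness >= 50 & contamination < 10] <- "medium"
  tier[completeness >= 90 & contamination < 5] <- "high"
  tier
}

#' Per-cluster gene presence fractions
#'
#' For every cluster and gene label, the fraction of member MAGs whose
#' curated feature set contains the gene. Features flagged as manual false
#' positives (`fp_override`) are excluded before counting.
#'
#' @param features Data frame of curated gene features with columns
#'   `mag_id`, `gene_label` and optionally `fp_override` (logical).
#' @param cluster_map Data frame with columns `mag_id`, `cluster_id`. Every
#'   MAG must appear here; MAGs with no B1 features still count in the
#'   denominator.
#' @param quality Optional MAG quality table (`mag_id`, `completeness`);
#'   when given, each cluster row carries `max_completeness`.
#' @return Tibble with one row per cluster: `cluster_id`, `n_mags`,
#'   optionally `max_completeness`, and one column per vocabulary gene
#'   holding the presence fraction in [0, 1].
#' @export
cluster_gene_presence <- function(features, cluster_map, quality = NULL) {
  stopifnot(all(c("mag_id", "cluster_id") %in% names(cluster_map)))
  if (nrow(cluster_map) == 0) stop("empty cluster map")
  missing_mags <- setdiff(unique(features$mag_id), cluster_map$mag_id)
  if (length(missing_mags) > 0) {
    stop("MAG(s) absent from cluster map: ", paste(missing_mags, collapse = ", "))
  }
  vocab <- b1_gene_vocabulary()
  feats <- features
  if (!"fp_override" %in% names(feats)) feats$fp_override <- FALSE
  feats$fp_override[is.na(feats$fp_override)] <- FALSE
  feats <- feats[!feats$fp_override & feats$gene_label %in% vocab, , drop = FALSE]

  clusters <- unique(cluster_map$cluster_id)
  out <- lapply(clusters, function(cl) {
    mags <- unique(cluster_map$mag_id[cluster_map$cluster_id == cl])
    n <- length(mags)
    if (n == 0) stop("empty cluster: ", cl)
    sub <- feats[feats$mag_id %in% mags, , drop = FALSE]
    frac <- vapply(vocab, function(g) {
      length(unique(sub$mag_id[sub$gene_label == g])) / n
    }, numeric(1))
    row <- tibble::tibble(cluster_id = cl, n_mags = n, !!!as.list(frac))
    if (!is.null(quality)) {
      row$max_completeness <- max(quality$completeness[quality$mag_id %in% mags])
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Call the B1 genotype of each cluster
#'
#' A gene counts as present in a cluster when its presence fraction exceeds
#' `presence_threshold` (default: present in at least one MAG). Clusters
#' with no high-tier MAG get confidence `low_completeness`: an absence call
#' from incomplete genomes is not trustworthy.
#'
#' @param presence Output of [cluster_gene_presence()].
#' @param quality Data frame with `mag_id`, `cluster_id`, `completeness`,
#'   `contamination` (percent).
#' @param presence_threshold Presence fraction strictly above which a gene
#'   is considered present. Default 0.
#' @return Tibble: `cluster_id`, `category`, `repertoire`
#'   (comma-separated), `confidence` ("callable" or "low_completeness").
#' @export
call_genotype <- function(presence, quality, presence_threshold = 0) {
  vocab <- b1_gene_vocabulary()
  stopifnot(all(vocab %in% names(presence)))
  tiers <- mag_quality_tier(quality$completeness, quality$contamination)
  high_clusters <- unique(quality$cluster_id[tiers == "high"])
  out <- lapply(seq_len(nrow(presence)), function(i) {
    row <- presence[i, ]
    present <- vocab[vapply(vocab, function(g) row[[g]] > presence_threshold, logical(1))]
    tibble::tibble(
      cluster_id = row$cluster_id,
      category   = classify_gene_set(present),
      repertoire = paste(gene_repertoire(present), collapse = ","),
      confidence = if (row$cluster_id %in% high_clusters) "callable" else "low_completeness"
    )
  })
  dplyr::bind_rows(out)
}

#' Community-level genotype summary
#'
#' Per-timepoint fractions of clusters in each genotype category, both
#' unweighted (cluster counts) and weighted by cluster relative abundance.
#' Clusters with confidence `low_completeness` are excluded by default. The
#' auxotroph fraction is 1 minus the prototroph fraction among callable
#' clusters.
#'
#' @param calls Output of [call_genotype()].
#' @param abundances Data frame with `cluster_id`, `timepoint`, `abundance`
#'   (relative; each timepoint sums to <= 1). If `NULL`, only unweighted
#'   fractions are returned for a single pseudo-timepoint "all".
#' @param include_low_completeness Include uncallable clusters? Default FALSE.
#' @return Tibble: `timepoint`, `category`, `fraction_clusters`,
#'   `fraction_abundance`, `auxotroph_fraction_clusters`,
#'   `auxotroph_fraction_abundance`. Zero callable clusters gives a
#'   zero-row result with attribute `empty = TRUE`.
#' @export
community_genotype_summary <- function(calls, abundances = NULL,
                                       include_low_completeness = FALSE) {
  keep <- calls
  if (!include_low_completeness) {
    keep <- keep[keep$confidence == "callable", , drop = FALSE]
  }
  cats <- b1_genotype_categories()
  if (nrow(keep) == 0) {
    out <- tibble::tibble(timepoint = character(), category = character(),
                          fraction_clusters = numeric(),
                          fraction_abundance = numeric(),
                          auxotroph_fraction_clusters = numeric(),
                          auxotroph_fraction_abundance = numeric())
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (is.null(abundances)) {
    abundances <- tibble::tibble(cluster_id = keep$cluster_id,
                                 timepoint = "all",
                                 abundance = 1 / nrow(keep))
  }
  ab <- abundances[abundances$cluster_id %in% keep$cluster_id, , drop = FALSE]
  tps <- unique(abundances$timepoint)
  out <- lapply(tps, function(tp) {
    ab_tp <- ab[ab$timepoint == tp, , drop = FALSE]
    w <- ab_tp$abundance[match(keep$cluster_id, ab_tp$cluster_id)]
    w[is.na(w)] <- 0
    wtot <- sum(w)
    frac_cl <- vapply(cats, function(cc) mean(keep$category == cc), numeric(1))
    frac_ab <- if (wtot > 0) {
      vapply(cats, function(cc) sum(w[keep$category == cc]) / wtot, numeric(1))
    } else rep(NA_real_, length(cats))
    tibble::tibble(
      timepoint = tp, category = cats,
      fraction_clusters = unname(frac_cl),
      fraction_abundance = unname(frac_ab),
      auxotroph_fraction_clusters = 1 - unname(frac_cl[cats == "PROTOTROPH"]),
      auxotroph_fraction_abundance = 1 - unname(frac_ab[cats == "PROTOTROPH"])
    )
  })
  dplyr::bind_rows(out)
}

#' Score genotype calls against known truth
#'
#' Validation harness for synthetic communities: compares called categories
#' with the generating truth and reports a confusion matrix plus the overall
#' recovery rate among callable clusters.
#'
#' @param calls Output of [call_genotype()].
#' @param truth Data frame with `cluster_id`, `true_category`.
#' @return List: `confusion` (table truth x called, callable clusters only),
#'   `recovery_rate` (fraction of callable clusters whose category matches
#'   truth), `n_callable`, `n_low_completeness`.
#' @export
genotype_recovery_score <- function(calls, truth) {
  missing <- setdiff(calls$cluster_id, truth$cluster_id)
  if (length(missing) > 0) {
    stop("cluster(s) missing from truth: ", paste(missing, collapse = ", "))
  }
  merged <- dplyr::inner_join(calls, truth, by = "cluster_id")
  callable <- merged[merged$confidence == "callable", , drop = FALSE]
  cats <- b1_genotype_categories()
  confusion <- table(
    truth = factor(callable$true_category, levels = cats),
    called = factor(callable$category, levels = cats)
  )
  list(
    confusion = confusion,
    recovery_rate = if (nrow(callable) > 0)
      mean(callable$category == callable$true_category) else NA_real_,
    n_callable = nrow(callable),
    n_low_completeness = sum(merged$confidence == "low_completeness")
  )
}
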