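#' Define a synthetic community scenario
#'
#' Couples a set of ground-truth genomes to per-timepoint relative
#' abundances and sequencing depths, plus per-gene expression factors used
#' in metatranscriptome mode.
#'
#' @param genomes Output of [generate_genomes()].
#' @param abundances Matrix genome x timepoint of relative abundances; each
#'   column must sum to 1 (tolerance 1e-9) and be non-negative. Rows named
#'   by genome_id.
#' @param depth Mapped reads per sample; scalar or per-timepoint vector.
#' @param expression Named numeric vector of per-feature expression factors
#'   (relative transcription rates), or `NULL` to draw them: log-normal
#'   (sdlog 1) for B1 genes, 1 for marker and filler genes. Stored as
#'   ground truth.
#' @param seed Integer seed used when drawing expression factors.
#' @return A `b1_scenario` list.
#' @export
community_scenario <- function(genomes, abundances, depth = 1e6,
                               expression = NULL, seed = 1L) {
  abundances <- as.matrix(abundances)
  if (any(abundances < 0)) stop("abundances must be non-negative")
  csums <- colSums(abundances)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("each timepoint's abundances must sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  }
  genome_ids <- unique(genomes$features$genome_id)
  if (is.null(rownames(abundances))) rownames(abundances) <- genome_ids
  stopifnot(setequal(rownames(abundances), genome_ids))
  if (is.null(colnames(abundances))) {
    colnames(abundances) <- sprintf("t%02d", seq_len(ncol(abundances)))
  }
  feats <- genomes$features
  if (is.null(expression)) {
    set.seed(seed)
    expression <- stats::setNames(rep(1, nrow(feats)), feats$feature_id)
    b1 <- feats$gene_label %in% b1_gene_vocabulary()
    expression[b1] <- stats::rlnorm(sum(b1), meanlog = 0, sdlog = 1)
  }
  structure(list(genomes = genomes, abundances = abundances,
                 n_timepoints = ncol(abundances),
                 depth = rep_len(depth, ncol(abundances)),
                 expression = expression, seed = seed),
            class = "b1_scenario")
}

#' Simulate mapped-read count matrices
#'
#' Expected counts are proportional to genome relative abundance times
#' feature length times sequencing depth, rescaled so a sample's expected
#' total equals its depth. Metatranscriptome mode additionally multiplies
#' by the scenario's per-feature expression factor before rescaling. Noise
#' is Poisson by default, with negative-binomial overdispersion or a
#' noiseless expected-count mode as options. Riboswitch features receive no
#' counts (they are regulatory elements, not ORFs).
#'
#' @param scenario A [community_scenario()].
#' @param mode "metagenome" or "metatranscriptome".
#' @param noise "poisson" (default), "nbinom", or "none" (expected counts,
#'   possibly non-integer).
#' @param size Negative-binomial size parameter when `noise = "nbinom"`.
#' @param seed Integer seed.
#' @return A [b1_matrix()] of raw counts (features x timepoints) with
#'   per-sample mapped-read totals; ground-truth expression factors are
#'   attached as attribute `expression` in metatranscriptome mode.
#' @export
simulate_counts <- function(scenario, mode = c("metagenome", "metatranscriptome"),
                            noise = c("poisson", "nbinom", "none"),
                            size = 10, seed = 1L) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  stopifnot(inherits(scenario, "b1_scenario"))
  if (any(scenario$depth <= 0)) stop("zero or negative depth")
  set.seed(seed)
  feats <- scenario$genomes$features
  orf <- feats$gene_label != "riboswitch_TDP"
  feats <- feats[orf, , drop = FALSE]
  ab <- scenario$abundances
  expr <- if (mode == "metatranscriptome") {
    scenario$expression[feats$feature_id]
  } else rep(1, nrow(feats))

  lambda <- matrix(0, nrow(feats), ncol(ab),
                   dimnames = list(feats$feature_id, colnames(ab)))
  for (j in seq_len(ncol(ab))) {
    w <- ab[feats$genome_id, j] * feats$length * expr
    lambda[, j] <- scenario$depth[j] * w / sum(w)
  }
  counts <- switch(noise,
    none    = lambda,
    poisson = matrix(stats::rpois(length(lambda), lambda),
                     nrow(lambda), dimnames = dimnames(lambda)),
    nbinom  = matrix(stats::rnbinom(length(lambda), mu = lambda, size = size),
                     nrow(lambda), dimnames = dimnames(lambda)))
  mapped <- if (noise == "none") scenario$depth else colSums(counts)
  names(mapped) <- colnames(ab)
  out <- b1_matrix(counts,
                   features = feats[, c("feature_id", "genome_id", "gene_label",
                                        "length", "is_marker")],
                   mapped_reads = mapped, state = "raw")
  if (mode == "metatranscriptome") attr(out, "expression") <- expr
  out
}
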