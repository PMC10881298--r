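#' Feature-by-sample abundance matrix with normalization state
#'
#' A light container tracking what a value means: raw mapped-read counts,
#' RPKM, marker-normalized genome equivalents, or transcript activity.
#' State moves only forward (raw -> rpkm -> marker_normalized /
#' transcript_activity); each operation checks the state it needs.
#'
#' @param values Numeric matrix, features x samples; row and column names
#'   required.
#' @param features Tibble describing rows: `feature_id` plus any of
#'   `gene_label`, `genome_id`, `length`, `is_marker`.
#' @param mapped_reads Named per-sample mapped-read totals.
#' @param state One of "raw", "rpkm", "marker_normalized",
#'   "transcript_activity".
#' @return A `b1_matrix` object.
#' @export
b1_matrix <- function(values, features, mapped_reads = NULL, state = "raw") {
  values <- as.matrix(values)
  states <- c("raw", "rpkm", "marker_normalized", "transcript_activity")
  stopifnot(state %in% states, !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(values < 0, na.rm = TRUE)) stop("abundance values must be >= 0")
  stopifnot("feature_id" %in% names(features),
            identical(rownames(values), features$feature_id))
  if (!is.null(mapped_reads)) {
    stopifnot(all(colnames(values) %in% names(mapped_reads)))
    mapped_reads <- mapped_reads[colnames(values)]
  }
  structure(list(values = values, features = features,
                 mapped_reads = mapped_reads, state = state),
            class = "b1_matrix")
}

#' @export
print.b1_matrix <- function(x, ...) {
  cat("<b1_matrix> ", nrow(x$values), " features x ", ncol(x$values),
      " samples, state: ", x$state, "\n", sep = "")
  invisible(x)
}

state_rank <- function(state) {
  match(state, c("raw", "rpkm", "marker_normalized", "transcript_activity"))
}

#' Reads Per Kilobase per Million mapped reads
#'
#' `rpkm = count / ((length / 1e3) * (mapped_reads / 1e6))`, per feature
#' and sample. Requires a raw-count matrix with positive feature lengths
#' and per-sample mapped-read totals.
#'
#' @param x A raw-state [b1_matrix()].
#' @return A [b1_matrix()] with state "rpkm".
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "b1_matrix"))
  if (x$state != "raw") stop("rpkm() expects a raw count matrix, got state ", x$state)
  if (is.null(x$mapped_reads) || any(x$mapped_reads <= 0)) {
    stop("positive per-sample mapped_reads required")
  }
  len <- x$features$length
  if (is.null(len) || any(is.na(len))) {
    bad <- x$features$feature_id[is.na(len)]
    stop("missing gene length for feature(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(len <= 0)) stop("gene lengths must be positive")
  vals <- sweep(x$values / (len / 1e3), 2, x$mapped_reads / 1e6, `/`)
  out <- x
  out$values <- vals
  out$state <- "rpkm"
  out
}

#' Aggregate features sharing a label
#'
#' Sums values over features with identical grouping keys (gene label, or
#' cluster x gene label). For RPKM matrices this sums per-copy abundances,
#' the natural additive scale; raw counts are simply summed. Lengths are
#' dropped (a group mixes lengths); `is_marker` is carried through.
#'
#' @param x A [b1_matrix()] in state "raw" or "rpkm".
#' @param by Grouping columns of `x$features`, default "gene_label".
#' @return A [b1_matrix()] whose features are the distinct groups.
#' @export
aggregate_features <- function(x, by = "gene_label") {
  stopifnot(inherits(x, "b1_matrix"), all(by %in% names(x$features)))
  key <- do.call(paste, c(x$features[by], sep = "|"))
  groups <- unique(key)
  vals <- rowsum(x$values, group = key, reorder = FALSE)
  vals <- vals[groups, , drop = FALSE]
  feats <- x$features[match(groups, key), by, drop = FALSE]
  feats$feature_id <- groups
  if ("is_marker" %in% names(x$features)) {
    feats$is_marker <- x$features$is_marker[match(groups, key)]
  }
  b1_matrix(vals, features = feats[, c("feature_id", by,
                                       intersect("is_marker", names(feats)))],
            mapped_reads = x$mapped_reads, state = x$state)
}

marker_median <- function(x, marker_ids = NULL) {
  if (is.null(marker_ids)) {
    stopifnot("is_marker" %in% names(x$features))
    marker_ids <- x$features$feature_id[x$features$is_marker]
  }
  if (length(marker_ids) == 0) stop("no marker features available")
  stopifnot(all(marker_ids %in% rownames(x$values)))
  apply(x$values[marker_ids, , drop = FALSE], 2, stats::median)
}

#' Normalize to single-copy marker genes
#'
#' Divides every value in a sample by the median RPKM of the single-copy
#' marker features of that sample, expressing abundance per genome
#' equivalent. A sample whose marker median is zero is set to missing and
#' reported via a warning.
#'
#' @param x A [b1_matrix()] in state "rpkm".
#' @param marker_ids Feature ids to use as markers; default: rows flagged
#'   `is_marker`.
#' @return A [b1_matrix()] with state "marker_normalized".
#' @export
marker_normalize <- function(x, marker_ids = NULL) {
  stopifnot(inherits(x, "b1_matrix"))
  if (x$state != "rpkm") {
    stop("marker_normalize() expects state rpkm, got ", x$state)
  }
  med <- marker_median(x, marker_ids)
  vals <- x$values
  zero <- med == 0
  if (any(zero)) {
    warning("marker median is zero in sample(s): ",
            paste(names(med)[zero], collapse = ", "), "; values set to NA")
    vals[, zero] <- NA_real_
  }
  vals[, !zero] <- sweep(vals[, !zero, drop = FALSE], 2, med[!zero], `/`)
  out <- x
  out$values <- vals
  out$state <- "marker_normalized"
  attr(out, "marker_median") <- med
  out
}

#' Relative transcript activity
#'
#' Expresses metatranscriptome abundance relative to gene presence. Two
#' published conventions are supported: `mode = "marker"` (default)
#' divides metatranscriptome RPKM by the per-sample median marker RPKM of
#' the metatranscriptome itself; `mode = "metagenome"` divides elementwise
#' by the marker-normalized metagenome value of the same feature and
#' sample. Zero denominators become missing and are reported.
#'
#' @param metat A [b1_matrix()] of metatranscriptome RPKM.
#' @param metag A [b1_matrix()] with state "marker_normalized"; required
#'   for `mode = "metagenome"`.
#' @param mode "marker" or "metagenome"; recorded on the result.
#' @return A [b1_matrix()] with state "transcript_activity" and attribute
#'   `mode`.
#' @export
transcript_activity <- function(metat, metag = NULL,
                                mode = c("marker", "metagenome")) {
  mode <- match.arg(mode)
  stopifnot(inherits(metat, "b1_matrix"))
  if (metat$state != "rpkm") {
    stop("transcript_activity() expects metatranscriptome state rpkm, got ",
         metat$state)
  }
  out <- metat
  if (mode == "marker") {
    norm <- marker_normalize(metat)
    out$values <- norm$values
  } else {
    stopifnot(inherits(metag, "b1_matrix"))
    if (metag$state != "marker_normalized") {
      stop("metagenome matrix must be marker_normalized")
    }
    common_f <- intersect(rownames(metat$values), rownames(metag$values))
    common_s <- intersect(colnames(metat$values), colnames(metag$values))
    if (length(common_f) == 0 || length(common_s) == 0) {
      stop("no shared features/samples between metaT and metaG")
    }
    denom <- metag$values[common_f, common_s, drop = FALSE]
    num <- metat$values[common_f, common_s, drop = FALSE]
    act <- num / denom
    act[denom == 0] <- NA_real_
    if (any(denom == 0, na.rm = TRUE)) {
      warning(sum(denom == 0, na.rm = TRUE),
              " zero-denominator cell(s) set to NA")
    }
    out$values <- act
    out$features <- metat$features[match(common_f, metat$features$feature_id), ]
  }
  out$state <- "transcript_activity"
  attr(out, "mode") <- mode
  out
}

#' Community-level gene abundance ratio
#'
#' The ratio of two genes' normalized abundances. An all-prototroph
#' community carries the three synthesis genes at 1:1:1, so the
#' community-level thiC:thiE ratio measures the prevalence of pyrimidine
#' auxotrophy.
#'
#' @param x A [b1_matrix()] aggregated by gene label (typically
#'   marker-normalized).
#' @param numerator,denominator Gene labels.
#' @return List: `overall` (ratio of study-wide summed abundances) and
#'   `per_sample` (named vector). Zero denominators give `NA`.
#' @export
gene_ratio <- function(x, numerator, denominator) {
  stopifnot(inherits(x, "b1_matrix"))
  ids <- x$features$feature_id[match(c(numerator, denominator),
                                     x$features$gene_label)]
  if (is.na(ids[2])) {
    # denominator gene absent everywhere: ratio undefined
    ns <- colnames(x$values)
    return(list(overall = NA_real_,
                per_sample = stats::setNames(rep(NA_real_, length(ns)), ns)))
  }
  num <- if (is.na(ids[1])) rep(0, ncol(x$values)) else x$values[ids[1], ]
  den <- x$values[ids[2], ]
  per_sample <- ifelse(den == 0, NA_real_, num / den)
  tot_den <- sum(den, na.rm = TRUE)
  list(overall = if (tot_den == 0) NA_real_ else sum(num, na.rm = TRUE) / tot_den,
       per_sample = per_sample)
}

#' Per-cluster contribution to total thiC transcription
#'
#' Scales cluster-level activities so each timepoint sums to 100 percent.
#' All-zero timepoints are flagged and returned as `NA`.
#'
#' @param activity Matrix (clusters x timepoints) of non-negative
#'   activities, or a [b1_matrix()] whose rows are clusters.
#' @return Matrix of percentages with attribute `all_zero` naming flagged
#'   timepoints.
#' @export
thic_contribution <- function(activity) {
  vals <- if (inherits(activity, "b1_matrix")) activity$values else as.matrix(activity)
  if (any(vals < 0, na.rm = TRUE)) stop("activities must be >= 0")
  tot <- colSums(vals, na.rm = TRUE)
  zero <- tot == 0
  out <- sweep(vals, 2, ifelse(zero, NA_real_, tot), `/`) * 100
  out[, zero] <- NA_real_
  attr(out, "all_zero") <- colnames(vals)[zero] %||% which(zero)
  out
}
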