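#' Write gene features as GFF3
#'
#' Serializes a feature table (as produced by [generate_genomes()] or
#' [sample_mags()]) to GFF3 with 1-based inclusive coordinates, via
#' rtracklayer. `gene_label`, `mag_id`/`genome_id` and `is_marker` travel
#' as attributes.
#'
#' @param features Feature data frame with `contig_id`, `gene_label`,
#'   `start`, `end`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 output")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  gr$type <- ifelse(features$gene_label == "riboswitch_TDP",
                    "riboswitch", "gene")
  gr$gene_label <- features$gene_label
  if ("mag_id" %in% names(features)) gr$mag_id <- features$mag_id
  if ("genome_id" %in% names(features)) gr$genome_id <- features$genome_id
  if ("feature_id" %in% names(features)) gr$ID <- features$feature_id
  if ("is_marker" %in% names(features)) gr$is_marker <- features$is_marker
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Inverse of [write_features_gff3()]: returns a tibble with `contig_id`,
#' `gene_label`, `start`, `end`, `strand`, `length` and any attribute
#' columns present.
#'
#' @param path GFF3 file.
#' @return Feature tibble.
#' @export
read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 input")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  out <- tibble::tibble(
    contig_id = as.character(df$seqnames),
    gene_label = df$gene_label,
    start = df$start, end = df$end,
    strand = as.character(df$strand),
    length = df$end - df$start + 1L)
  for (col in c("mag_id", "genome_id", "ID", "is_marker")) {
    if (col %in% names(df)) out[[if (col == "ID") "feature_id" else col]] <- df[[col]]
  }
  if ("is_marker" %in% names(out)) out$is_marker <- as.logical(out$is_marker)
  out
}

#' Parse an hmmsearch --tblout file
#'
#' Reads the whitespace-delimited per-target table written by
#' `hmmsearch --tblout`: comment lines start with `#`, the first 18 fields
#' are fixed, and everything after is free-text description. Returns the
#' fields the pipeline needs, named for [filter_hits()].
#'
#' @param path tblout file.
#' @return Tibble: `protein_id`, `profile_id`, `e_value`, `bit_score`,
#'   plus `target_accession`, `query_accession`.
#' @export
read_hmmer_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), profile_id = character(),
                          e_value = numeric(), bit_score = numeric(),
                          target_accession = character(),
                          query_accession = character()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(fields, length, integer(1)) < 18
  if (any(bad)) stop("malformed tblout line(s): ", which(bad)[1])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  tibble::tibble(
    protein_id = get(1), target_accession = get(2),
    profile_id = get(3), query_accession = get(4),
    e_value = as.numeric(get(5)), bit_score = as.numeric(get(6)))
}

#' Write a table as TSV
#' @param x Data frame. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path Input file.
#' @return Tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a ground-truth bundle as YAML
#'
#' @param truth Named list of ground-truth values/tables (data frames are
#'   converted to row lists).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  conv <- lapply(truth, function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  })
  yaml::write_yaml(conv, path)
  invisible(path)
}
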