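#' Controlled vocabularies for B1 cycling analysis
#'
#' Gene labels for thiamin-related enzymes and transporters, the compound
#' vocabulary for targeted LC-MS quantification, and the genotype categories
#' used throughout the package.
#'
#' @name b1_vocab
NULL

#' B1-related gene labels
#'
#' The thirteen thiamin-related genes tracked by the pipeline: de novo
#' synthesis (`thiC` pyrimidine branch, `thiG` thiazole branch, `thiE`
#' condensation), intact-B1 transport (`thiB`, `thiT`), putative
#' pyrimidine/B1 transport (`thiV`, `thiY`, `cytX`, `ykoF`, `thiPerm`,
#' `omr1`) and vitamer salvage (`tenA` pyrimidine, `thiM` thiazole).
#'
#' @return Character vector of gene labels.
#' @export
b1_gene_vocabulary <- function() {
  c("thiC", "thiG", "thiE", "thiB", "thiT", "thiV", "thiY",
    "cytX", "ykoF", "tenA", "thiM", "thiPerm", "omr1")
}

#' Gene role groups
#'
#' @return Named list of character vectors partitioning the vocabulary into
#'   synthesis, B1 transport, putative transport and salvage roles.
#' @export
b1_gene_roles <- function() {
  list(
    synthesis          = c("thiC", "thiG", "thiE"),
    b1_transport       = c("thiB", "thiT"),
    putative_transport = c("thiV", "thiY", "cytX", "ykoF", "thiPerm", "omr1"),
    salvage            = c("tenA", "thiM")
  )
}

#' Genotype categories
#'
#' @return Character vector of the six cluster-level B1 physiology
#'   categories, in rule-cascade order.
#' @export
b1_genotype_categories <- function() {
  c("PROTOTROPH", "PYRIMIDINE_AUXOTROPH", "THIAZOLE_AUXOTROPH",
    "AUXOTROPH_B1_TRANSPORT", "AUXOTROPH_PUTATIVE_TRANSPORT",
    "NO_KNOWN_ROUTE")
}

#' LC-MS compound vocabulary
#'
#' B1 and its vitamers: TMP (thiamin monophosphate), pyrimidine vitamers
#' HMP, AmMP, FAMP, and thiazole vitamers HET, cHET.
#'
#' @return Character vector of compound labels.
#' @export
b1_compound_vocabulary <- function() {
  c("B1", "TMP", "HMP", "HET", "FAMP", "AmMP", "cHET")
}

# Typical coding-gene lengths (bp) used by the genome generator. Values are
# round figures in the range seen for these families in bacteria; only their
# relative magnitudes matter downstream (RPKM divides them out).
default_gene_lengths <- function() {
  c(thiC = 1900, thiG = 770, thiE = 640, thiB = 1000, thiT = 580,
    thiV = 1450, thiY = 990, cytX = 1300, ykoF = 600, tenA = 700,
    thiM = 800, thiPerm = 1200, omr1 = 2100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
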