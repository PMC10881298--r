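Package: b1cycle
Title: Vitamin B1 Cycling Analysis for Coastal Bacterioplankton Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing thiamin (vitamin B1) cycling in
    marine microbial communities: B1 genotype classification of genome
    clusters from gene presence/absence, single-copy-marker-normalized
    metagenome and metatranscriptome abundance statistics, targeted LC-MS
    vitamer quantification with LOD/LOQ gating and internal-standard
    recovery correction, bioassay-based bioavailable B1 estimation, and
    Kendall correlation screening of environmental time series. A synthetic
    data module generates every input with known ground truth so all stages
    are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    tidyr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
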