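#' Simulate a targeted LC-MS peak-area batch
#'
#' Emulates a triple-quadrupole batch for B1 and vitamers: inter-sample
#' blank rows, calibration rows at stated levels (run in the QC matrix, so
#' they carry the internal standard at its full expected area), pooled-QC
#' rows, and two technical-replicate injections per sample. Sample peak
#' areas follow `slope * concentration * recovery * lognormal(1, noise_cv)`
#' and the internal-standard (13C-B1) areas are scaled by the same
#' per-sample recovery, so downstream recovery estimation can be scored
#' against truth.
#'
#' @param true_concentrations Tibble with `sample_id`, `compound`,
#'   `conc_pM` (>= 0).
#' @param calibration_levels Numeric vector of calibration levels (pM).
#' @param recovery Per-sample extraction recovery in (0, 1]; scalar or
#'   named vector by sample_id. The study regime for dissolved B1 was
#'   24 +/- 7 percent.
#' @param noise_cv Multiplicative coefficient of variation (>= 0).
#' @param n_blanks Number of inter-sample blank rows (default 5).
#' @param n_qc Number of pooled-QC rows (default 3).
#' @param slope Calibration slope, area units per pM (scalar or named by
#'   compound).
#' @param is_expected_area Internal-standard area at full recovery.
#' @param blank_area_sd Noise floor of blank areas; defaults to the area
#'   equivalent of a 1 pM signal scaled by `noise_cv`.
#' @param batch Batch label.
#' @param seed Integer seed.
#' @return Tibble of peak measurements (`sample_id`, `compound`,
#'   `replicate`, `batch`, `row_type`, `level_pM`, `peak_area`, `is_area`)
#'   with the generating truth attached as attribute `truth`.
#' @export
simulate_ms_dataset <- function(true_concentrations, calibration_levels,
                                recovery = 1, noise_cv = 0,
                                n_blanks = 5L, n_qc = 3L,
                                slope = 1000, is_expected_area = 5e4,
                                blank_area_sd = NULL, batch = "batch1",
                                seed = 1L) {
  tc <- true_concentrations
  stopifnot(all(c("sample_id", "compound", "conc_pM") %in% names(tc)))
  if (any(tc$conc_pM < 0)) stop("concentrations must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  samples <- unique(tc$sample_id)
  rec <- if (length(recovery) == 1 && is.null(names(recovery))) {
    stats::setNames(rep(recovery, length(samples)), samples)
  } else recovery
  if (any(rec <= 0 | rec > 1)) stop("recovery must be in (0, 1]")
  compounds <- unique(tc$compound)
  sl <- if (length(slope) == 1 && is.null(names(slope))) {
    stats::setNames(rep(slope, length(compounds)), compounds)
  } else slope
  if (is.null(blank_area_sd)) blank_area_sd <- noise_cv * mean(sl) * 1

  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lnoise <- function(n) if (noise_cv == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  rows <- list()
  for (cmp in compounds) {
    s <- sl[[cmp]]
    # inter-sample blanks: zero analyte plus an instrument noise floor
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("blank_%02d", seq_len(n_blanks)), compound = cmp,
      replicate = 1L, batch = batch, row_type = "blank", level_pM = NA_real_,
      peak_area = pmax(0, stats::rnorm(n_blanks, 0, blank_area_sd)),
      is_area = is_expected_area * lnoise(n_blanks))
    # calibration in the QC matrix, full internal standard
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("cal_%02d", seq_along(calibration_levels)),
      compound = cmp, replicate = 1L, batch = batch, row_type = "calibration",
      level_pM = as.numeric(calibration_levels),
      peak_area = unname(s * as.numeric(calibration_levels) *
                           lnoise(length(calibration_levels))),
      is_area = is_expected_area * lnoise(length(calibration_levels)))
    # pooled QC at the mean true concentration
    qc_conc <- mean(tc$conc_pM[tc$compound == cmp])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = sprintf("qc_%02d", seq_len(n_qc)), compound = cmp,
      replicate = 1L, batch = batch, row_type = "qc", level_pM = NA_real_,
      peak_area = s * qc_conc * lnoise(n_qc),
      is_area = is_expected_area * lnoise(n_qc))
    # two technical-replicate injections per sample
    sub <- tc[tc$compound == cmp, , drop = FALSE]
    for (r in 1:2) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sub$sample_id, compound = cmp, replicate = r,
        batch = batch, row_type = "sample", level_pM = NA_real_,
        peak_area = unname(s * sub$conc_pM * rec[sub$sample_id] *
                             lnoise(nrow(sub))),
        is_area = unname(is_expected_area * rec[sub$sample_id] *
                           lnoise(nrow(sub))))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(true_concentrations = tc, recovery = rec,
                             slope = sl, is_expected_area = is_expected_area,
                             noise_cv = noise_cv)
  out
}

#' Simulate a reporter-strain growth bioassay
#'
#' Emulates an auxotrophic-reporter assay: growth yields are linear in
#' added B1 with Gaussian noise. Standards span the stated levels,
#' negative-control tubes sit at zero addition, and sample tubes contain
#' the true concentration after 1:10 (by default) dilution into medium.
#'
#' @param true_b1 True bioavailable B1 of the undiluted sample (pM).
#' @param slope,intercept Linear response: yield = intercept + slope * pM
#'   in tube.
#' @param standards Strictly positive, sorted standard levels (pM);
#'   default c(5, 10, 25, 50, 75).
#' @param noise_sd Gaussian yield noise SD.
#' @param n_replicates Replicates per level and per sample (default 4).
#' @param dilution_factor Sample dilution before incubation (default 10).
#' @param seed Integer seed.
#' @return Tibble: `role` (standard/control/sample), `level_pM` (B1 added;
#'   in-tube sample concentration for sample rows), `replicate`, `yield`;
#'   truth attached as attribute `truth`.
#' @export
simulate_bioassay <- function(true_b1, slope, intercept,
                              standards = c(5, 10, 25, 50, 75),
                              noise_sd = 0, n_replicates = 4L,
                              dilution_factor = 10, seed = 1L) {
  if (length(standards) == 0) stop("standards must be non-empty")
  if (any(standards <= 0) || is.unsorted(standards)) {
    stop("standards must be strictly positive and sorted")
  }
  set.seed(seed)
  mk <- function(role, conc) tibble::tibble(
    role = role, level_pM = conc,
    replicate = rep(seq_len(n_replicates), times = length(conc) / n_replicates),
    yield = intercept + slope * conc +
      stats::rnorm(length(conc), 0, noise_sd))
  conc_std <- rep(standards, each = n_replicates)
  in_tube <- true_b1 / dilution_factor
  out <- dplyr::bind_rows(
    mk("standard", conc_std),
    mk("control", rep(0, n_replicates)),
    mk("sample", rep(in_tube, n_replicates)))
  attr(out, "truth") <- list(true_b1 = true_b1, slope = slope,
                             intercept = intercept,
                             dilution_factor = dilution_factor)
  out
}
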