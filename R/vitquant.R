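#' Fit matrix-matched calibration curves
#'
#' Ordinary least-squares line of peak area versus calibration level, per
#' compound and batch. Calibration standards are run in the pooled
#' quality-control matrix with the internal standard at full strength, so
#' normalizing their areas to the internal standard is a constant rescale;
#' fitting is done on peak areas, and per-sample internal-standard recovery
#' is divided out once at quantification (see [recovery_correct()]).
#'
#' @param peaks Peak-measurement table (see [simulate_ms_dataset()] for the
#'   schema); only `row_type == "calibration"` rows are used.
#' @param min_levels Minimum number of distinct levels (default 3).
#' @return Tibble: `compound`, `batch`, `slope`, `intercept`, `r_squared`,
#'   `n_levels`, `level_min`, `level_max`.
#' @export
fit_calibration <- function(peaks, min_levels = 3L) {
  cal <- peaks[peaks$row_type == "calibration", , drop = FALSE]
  if (nrow(cal) == 0) stop("no calibration rows")
  groups <- unique(cal[, c("compound", "batch")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- cal[cal$compound == groups$compound[i] & cal$batch == groups$batch[i], ]
    levels <- unique(sub$level_pM)
    if (length(levels) < min_levels) {
      stop("calibration for ", groups$compound[i], "/", groups$batch[i],
           " has only ", length(levels), " distinct level(s); >= ",
           min_levels, " required")
    }
    fit <- stats::lm(peak_area ~ level_pM, data = sub)
    slope <- unname(stats::coef(fit)[2])
    if (slope <= 0) {
      stop("non-quantifiable calibration for ", groups$compound[i], "/",
           groups$batch[i], ": slope <= 0")
    }
    ss_tot <- sum((sub$peak_area - mean(sub$peak_area))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    tibble::tibble(compound = groups$compound[i], batch = groups$batch[i],
                   slope = slope, intercept = unname(stats::coef(fit)[1]),
                   r_squared = r2, n_levels = length(levels),
                   level_min = min(levels), level_max = max(levels))
  })
  dplyr::bind_rows(out)
}

#' Limits of detection and quantitation
#'
#' LOD and LOQ are 3x and 10x the variation (sample standard deviation) of
#' the inter-sample blanks, per compound and batch. For dissolved samples
#' the variation of the pooled quality-control responses can be used
#' instead (`mode = "qc"`). If a calibration table is supplied the limits
#' are also expressed in pM via the slope.
#'
#' @param peaks Peak-measurement table.
#' @param mode "blanks" (default) or "qc".
#' @param calibration Optional output of [fit_calibration()].
#' @return Tibble: `compound`, `batch`, `sd_response`, `lod_area`,
#'   `loq_area`, and `lod_pM`/`loq_pM` when calibration is given.
#' @export
compute_lod_loq <- function(peaks, mode = c("blanks", "qc"),
                            calibration = NULL) {
  mode <- match.arg(mode)
  src <- peaks[peaks$row_type == ifelse(mode == "blanks", "blank", "qc"), ,
               drop = FALSE]
  if (nrow(src) == 0) stop("no ", mode, " rows")
  groups <- unique(src[, c("compound", "batch")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- src[src$compound == groups$compound[i] & src$batch == groups$batch[i], ]
    if (nrow(sub) < 3) {
      stop("need >= 3 ", mode, " rows for ", groups$compound[i], "/",
           groups$batch[i], ", got ", nrow(sub))
    }
    s <- stats::sd(sub$peak_area)
    res <- tibble::tibble(compound = groups$compound[i],
                          batch = groups$batch[i], sd_response = s,
                          lod_area = 3 * s, loq_area = 10 * s)
    if (!is.null(calibration)) {
      cal <- calibration[calibration$compound == res$compound &
                           calibration$batch == res$batch, , drop = FALSE]
      if (nrow(cal) == 1) {
        res$lod_pM <- res$lod_area / cal$slope
        res$loq_pM <- res$loq_area / cal$slope
      }
    }
    res
  })
  dplyr::bind_rows(out)
}

#' Estimate per-sample internal-standard recovery
#'
#' Recovery is the measured 13C-B1 internal-standard area divided by its
#' expected (fully recovered) area, averaged over a sample's injections.
#' Samples with recovery <= 0 or > 1.5 are flagged and excluded from
#' correction.
#'
#' @param peaks Peak-measurement table; sample rows must carry `is_area`.
#' @param is_expected_area Internal-standard area at full recovery.
#' @return Tibble: `sample_id`, `recovery`, `excluded`.
#' @export
recovery_correct <- function(peaks, is_expected_area) {
  smp <- peaks[peaks$row_type == "sample", , drop = FALSE]
  if (any(is.na(smp$is_area))) stop("is_area required on sample rows")
  agg <- stats::aggregate(is_area ~ sample_id, data = smp, FUN = mean)
  rec <- agg$is_area / is_expected_area
  tibble::tibble(sample_id = agg$sample_id, recovery = rec,
                 excluded = rec <= 0 | rec > 1.5)
}

#' Back-calculate concentrations with replicate gating
#'
#' Each sample x compound needs exactly two technical-replicate injections.
#' A concentration is reported as the mean of the two back-calculated,
#' recovery-corrected values only when both injections exceed the LOD.
#' Values between LOD and LOQ additionally require an accept annotation
#' (emulating visual inspection of the chromatograms); unreviewed
#' borderline values keep the flag but no concentration. One missing
#' injection yields `single_injection_reject`; more than two injections is
#' an error.
#'
#' @param peaks Peak-measurement table.
#' @param calibration Output of [fit_calibration()].
#' @param limits Output of [compute_lod_loq()].
#' @param recovery Output of [recovery_correct()] (applied to B1), or NULL
#'   for no per-sample correction.
#' @param vitamer_recovery Named per-compound recovery constants applied to
#'   compounds other than B1 (literature values); default 1.
#' @param review Data frame `sample_id`, `compound`, `review`
#'   ("accept"/"reject") for LOD-to-LOQ values; default: none reviewed.
#' @param exclusions Data frame `sample_id`, `compound` of measurements
#'   removed as outliers (declarative list; no automatic rejection).
#' @return Tibble of concentration records: `sample_id`, `compound`,
#'   `concentration_pM`, `flag`, `recovery_applied`, `reviewed`.
#' @export
quantify <- function(peaks, calibration, limits, recovery = NULL,
                     vitamer_recovery = NULL, review = NULL,
                     exclusions = NULL) {
  smp <- peaks[peaks$row_type == "sample", , drop = FALSE]
  if (nrow(smp) == 0) stop("no sample rows")
  combos <- unique(smp[, c("sample_id", "compound", "batch")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sid <- combos$sample_id[i]; cmp <- combos$compound[i]; bt <- combos$batch[i]
    sub <- smp[smp$sample_id == sid & smp$compound == cmp & smp$batch == bt, ]
    if (nrow(sub) > 2) stop("more than two injections for ", sid, "/", cmp)
    rec_row <- tibble::tibble(sample_id = sid, compound = cmp,
                              concentration_pM = NA_real_, flag = NA_character_,
                              recovery_applied = NA_real_, reviewed = FALSE)
    if (!is.null(exclusions) &&
        any(exclusions$sample_id == sid & exclusions$compound == cmp)) {
      rec_row$flag <- "outlier_removed"
      return(rec_row)
    }
    if (nrow(sub) < 2) {
      rec_row$flag <- "single_injection_reject"
      return(rec_row)
    }
    cal <- calibration[calibration$compound == cmp & calibration$batch == bt, ]
    lim <- limits[limits$compound == cmp & limits$batch == bt, ]
    if (nrow(cal) != 1 || nrow(lim) != 1) {
      stop("missing calibration or limits for ", cmp, "/", bt)
    }
    if (any(sub$peak_area <= lim$lod_area)) {
      rec_row$flag <- "below_LOD"
      return(rec_row)
    }
    conc <- (sub$peak_area - cal$intercept) / cal$slope
    rec <- if (cmp == "B1" && !is.null(recovery)) {
      r <- recovery[recovery$sample_id == sid, , drop = FALSE]
      if (nrow(r) == 1 && !r$excluded) r$recovery else NA_real_
    } else {
      (vitamer_recovery[[cmp]] %||% 1)
    }
    if (is.na(rec)) {
      rec_row$flag <- "recovery_excluded"
      return(rec_row)
    }
    value <- mean(conc) / rec
    rec_row$recovery_applied <- rec
    if (all(sub$peak_area >= lim$loq_area)) {
      rec_row$flag <- "ok"
      rec_row$concentration_pM <- value
      rec_row$reviewed <- TRUE
    } else {
      rec_row$flag <- "LOD_to_LOQ"
      accepted <- !is.null(review) &&
        any(review$sample_id == sid & review$compound == cmp &
              review$review == "accept")
      rec_row$reviewed <- accepted
      if (accepted) rec_row$concentration_pM <- value
    }
    rec_row
  })
  dplyr::bind_rows(out)
}

#' Pool summaries: combined concentrations and per-POC ratios
#'
#' Per sample, the combined pool is the sum of the mean concentrations of
#' the requested compounds; compounds below the LOD contribute zero and
#' are counted in `n_below_lod`. With particulate organic carbon supplied,
#' per-compound concentrations are also expressed per POC.
#'
#' @param records Output of [quantify()] (one pool).
#' @param compounds Compounds entering the combined pool; default B1 and
#'   the measured vitamers HET, HMP, FAMP.
#' @param poc Optional data frame `sample_id`, `poc_uM` (micromolar C).
#' @return List: `combined` (tibble sample_id, combined_pM, n_below_lod,
#'   n_missing) and, when `poc` is given, `per_poc` (tibble sample_id,
#'   compound, pmol_per_umolC).
#' @export
pool_summaries <- function(records, compounds = c("B1", "HET", "HMP", "FAMP"),
                           poc = NULL) {
  rec <- records[records$compound %in% compounds, , drop = FALSE]
  samples <- unique(rec$sample_id)
  combined <- lapply(samples, function(sid) {
    sub <- rec[rec$sample_id == sid, ]
    usable <- !is.na(sub$concentration_pM)
    tibble::tibble(
      sample_id = sid,
      combined_pM = sum(sub$concentration_pM[usable]),
      n_below_lod = sum(sub$flag == "below_LOD"),
      n_missing = sum(!usable & sub$flag != "below_LOD"))
  })
  out <- list(combined = dplyr::bind_rows(combined))
  if (!is.null(poc)) {
    if (!all(samples %in% poc$sample_id)) {
      stop("POC missing for sample(s): ",
           paste(setdiff(samples, poc$sample_id), collapse = ", "))
    }
    idx <- match(rec$sample_id, poc$sample_id)
    out$per_poc <- tibble::tibble(
      sample_id = rec$sample_id, compound = rec$compound,
      pmol_per_umolC = rec$concentration_pM / poc$poc_uM[idx])
  }
  out
}
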