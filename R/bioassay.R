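#' Fit a bioassay standard curve
#'
#' Least-squares line of reporter growth yield versus added B1, fitted on
#' the standard levels together with the negative-control tubes at zero
#' addition. A non-positive slope means the assay failed (the reporter did
#' not respond to B1) and is rejected.
#'
#' @param standards Data frame with `level_pM` (0 for negative controls)
#'   and `yield` (cells per volume, or any linear growth proxy).
#' @return A `b1_bioassay_curve` list: `slope`, `intercept`,
#'   `residual_sd`, `n`, `level_range`, `data`.
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("level_pM", "yield") %in% names(standards)))
  levels <- unique(standards$level_pM)
  if (length(levels) < 3) {
    stop("need >= 3 distinct standard levels, got ", length(levels))
  }
  fit <- stats::lm(yield ~ level_pM, data = standards)
  slope <- unname(stats::coef(fit)[2])
  # numerically-zero slopes (non-responding reporter) are assay failures too
  if (slope <= .Machine$double.eps * max(abs(standards$yield), 1)) {
    stop("assay failure: standard-curve slope <= 0")
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 residual_sd = stats::sigma(fit), n = nrow(standards),
                 level_range = range(levels), data = standards),
            class = "b1_bioassay_curve")
}

#' Invert a bioassay to bioavailable B1
#'
#' The in-tube estimate is `(mean yield - intercept) / slope`; the
#' reported value multiplies by the dilution factor (samples are diluted
#' 1:10 into assay medium by default). Uncertainty comes from a
#' nonparametric bootstrap that resamples both the sample replicates and
#' the standard-curve replicates (within level) and refits the curve each
#' draw. The default interval is `estimate +/- t * SD(bootstrap)` with a
#' t quantile on the sample-replicate degrees of freedom; a percentile
#' interval is available. Sample yields below the negative-control mean
#' are flagged `below_assay_floor`; yields outside the calibrated range
#' are flagged `extrapolated`.
#'
#' @param sample_yields Numeric vector of replicate yields for one sample.
#' @param curve A [fit_standard_curve()] object.
#' @param dilution_factor Default 10.
#' @param n_boot Bootstrap draws (default 200).
#' @param conf Confidence level (default 0.95).
#' @param method "normal" (default) or "percentile".
#' @param seed Optional integer seed for the bootstrap.
#' @return List: `estimate_pM`, `ci_lower`, `ci_upper`, `se`,
#'   `in_tube_pM`, `dilution_factor`, `flags` (character vector, possibly
#'   empty), `method`.
#' @export
invert_bioassay <- function(sample_yields, curve, dilution_factor = 10,
                            n_boot = 200L, conf = 0.95,
                            method = c("normal", "percentile"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "b1_bioassay_curve"), length(sample_yields) >= 1)
  if (!is.null(seed)) set.seed(seed)
  est_tube <- (mean(sample_yields) - curve$intercept) / curve$slope
  estimate <- est_tube * dilution_factor

  flags <- character()
  ctrl <- curve$data$yield[curve$data$level_pM == 0]
  if (length(ctrl) > 0 && mean(sample_yields) < mean(ctrl)) {
    flags <- c(flags, "below_assay_floor")
  }
  if (est_tube < curve$level_range[1] || est_tube > curve$level_range[2]) {
    flags <- c(flags, "extrapolated")
  }

  std <- curve$data
  boot <- vapply(seq_len(n_boot), function(b) {
    ys <- sample(sample_yields, replace = TRUE)
    idx <- unlist(lapply(split(seq_len(nrow(std)), std$level_pM),
                         function(ii) ii[sample.int(length(ii), replace = TRUE)]))
    fit <- stats::lm(yield ~ level_pM, data = std[idx, , drop = FALSE])
    b1 <- unname(stats::coef(fit)[2])
    if (b1 <= 0) return(NA_real_)
    (mean(ys) - unname(stats::coef(fit)[1])) / b1 * dilution_factor
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  if (method == "normal") {
    df <- max(length(sample_yields) - 1, 1)
    half <- stats::qt(1 - alpha / 2, df) * stats::sd(boot)
    ci <- c(estimate - half, estimate + half)
  } else {
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  }
  list(estimate_pM = estimate, ci_lower = ci[1], ci_upper = ci[2],
       se = stats::sd(boot), in_tube_pM = est_tube,
       dilution_factor = dilution_factor, flags = flags, method = method)
}
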