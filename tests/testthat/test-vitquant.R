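noiseless_batch <- function(conc, levels = c(10, 50, 100, 200),
                            recovery = 1, slope = 800) {
  tc <- tibble::tibble(sample_id = sprintf("s%02d", seq_along(conc)),
                       compound = "B1", conc_pM = conc)
  simulate_ms_dataset(tc, calibration_levels = levels, recovery = recovery,
                      noise_cv = 0, slope = slope, seed = 1)
}

test_that("calibration fits recover exact and noisy lines", {
  ms <- noiseless_batch(c(40, 90), slope = 2)
  cal <- fit_calibration(ms)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$r_squared, 1)

  # noisy points match the closed-form least-squares oracle
  set.seed(5)
  lev <- c(5, 10, 25, 50, 100)
  area <- 3 * lev + stats::rnorm(5, 0, 4)
  peaks <- tibble::tibble(sample_id = paste0("cal", 1:5), compound = "HMP",
                          replicate = 1L, batch = "b1",
                          row_type = "calibration", level_pM = lev,
                          peak_area = area, is_area = NA_real_)
  cal2 <- fit_calibration(peaks)
  oracle <- ols_oracle(lev, area)
  expect_equal(cal2$slope, unname(oracle["slope"]))
  expect_equal(cal2$intercept, unname(oracle["intercept"]))

  # fewer than three distinct levels is rejected
  expect_error(fit_calibration(peaks[1:2, ]), "3")
  # a non-responsive compound (slope <= 0) is flagged non-quantifiable
  bad <- peaks; bad$peak_area <- rev(area)
  expect_error(fit_calibration(bad), "non-quantifiable")
})

test_that("LOD and LOQ are 3x and 10x the blank variation", {
  blanks <- tibble::tibble(
    sample_id = paste0("bl", 1:5), compound = "B1", replicate = 1L,
    batch = "b1", row_type = "blank", level_pM = NA_real_,
    peak_area = c(0, 1, 2, 3, 4), is_area = NA_real_)
  lim <- compute_lod_loq(blanks)
  s <- stats::sd(c(0, 1, 2, 3, 4))
  expect_equal(lim$lod_area, 3 * s)
  expect_equal(lim$loq_area, 10 * s)
  expect_lte(lim$lod_area, lim$loq_area)

  # identical blanks: zero-variance limit
  blanks0 <- blanks; blanks0$peak_area <- 7
  lim0 <- compute_lod_loq(blanks0)
  expect_equal(lim0$lod_area, 0)
  expect_equal(lim0$loq_area, 0)

  # random blanks: equals the definition, scales linearly, ratio fixed
  set.seed(8)
  for (rep in 1:5) {
    b <- blanks; b$peak_area <- stats::rlnorm(5, 2, 0.4)
    lm1 <- compute_lod_loq(b)
    expect_equal(lm1$lod_area, 3 * stats::sd(b$peak_area))
    expect_equal(lm1$loq_area / lm1$lod_area, 10 / 3)
    b2 <- b; b2$peak_area <- b$peak_area * 5
    expect_equal(compute_lod_loq(b2)$lod_area, 5 * lm1$lod_area)
  }
  expect_error(compute_lod_loq(blanks[1:2, ]), ">= 3")
  # dissolved-sample convention: variation of the QC responses instead
  qc <- blanks; qc$row_type <- "qc"; qc$peak_area <- c(10, 12, 11, 13, 9)
  limqc <- compute_lod_loq(qc, mode = "qc")
  expect_equal(limqc$lod_area, 3 * stats::sd(qc$peak_area))
})

test_that("recovery correction divides once by the IS-derived fraction", {
  ms <- noiseless_batch(c(10), recovery = 0.5)
  cal <- fit_calibration(ms)
  lim <- compute_lod_loq(ms, calibration = cal)
  rec <- recovery_correct(ms, is_expected_area = 5e4)
  expect_equal(rec$recovery, 0.5)
  q <- quantify(ms, cal, lim, rec)
  expect_equal(q$concentration_pM, 10)  # raw 5 pM back to 10 pM
  expect_equal(q$recovery_applied, 0.5)

  # recovery 1 leaves values unchanged
  ms1 <- noiseless_batch(c(10))
  q1 <- quantify(ms1, fit_calibration(ms1), compute_lod_loq(ms1),
                 recovery_correct(ms1, 5e4))
  expect_equal(q1$concentration_pM, 10)
})

test_that("estimated recovery matches the simulated 24 percent regime", {
  tc <- tibble::tibble(sample_id = sprintf("s%02d", 1:12), compound = "B1",
                       conc_pM = stats::runif(12, 60, 120))
  ms <- simulate_ms_dataset(tc, c(10, 50, 100, 200), recovery = 0.24,
                            noise_cv = 0.07, seed = 21)
  rec <- recovery_correct(ms, 5e4)
  expect_lt(abs(mean(rec$recovery) - 0.24), 0.02)
  expect_false(any(rec$excluded))
})

test_that("quantification gates on two injections and the LOD/LOQ band", {
  cal <- tibble::tibble(compound = "B1", batch = "b1", slope = 1,
                        intercept = 0, r_squared = 1, n_levels = 4,
                        level_min = 10, level_max = 200)
  lim <- tibble::tibble(compound = "B1", batch = "b1", sd_response = 5,
                        lod_area = 15, loq_area = 50)
  mk <- function(areas, sid = "s1") tibble::tibble(
    sample_id = sid, compound = "B1",
    replicate = seq_along(areas), batch = "b1", row_type = "sample",
    level_pM = NA_real_, peak_area = areas, is_area = NA_real_)

  ok <- quantify(mk(c(100, 110)), cal, lim)
  expect_equal(ok$flag, "ok")
  expect_equal(ok$concentration_pM, 105)

  below <- quantify(mk(c(100, 10)), cal, lim)
  expect_equal(below$flag, "below_LOD")
  expect_true(is.na(below$concentration_pM))

  single <- quantify(mk(100), cal, lim)
  expect_equal(single$flag, "single_injection_reject")

  # between LOD and LOQ: value only passes with an accept review
  mid <- quantify(mk(c(30, 40)), cal, lim)
  expect_equal(mid$flag, "LOD_to_LOQ")
  expect_true(is.na(mid$concentration_pM))
  mid_ok <- quantify(mk(c(30, 40)), cal, lim,
                     review = tibble::tibble(sample_id = "s1", compound = "B1",
                                             review = "accept"))
  expect_equal(mid_ok$concentration_pM, 35)
  expect_equal(mid_ok$flag, "LOD_to_LOQ")

  excl <- quantify(mk(c(100, 110)), cal, lim,
                   exclusions = tibble::tibble(sample_id = "s1", compound = "B1"))
  expect_equal(excl$flag, "outlier_removed")

  expect_error(quantify(mk(c(90, 95, 99)), cal, lim), "more than two")
})

test_that("noiseless batches round-trip exactly above the LOQ", {
  conc <- c(1, 5, 20, 75, 126, 400)
  ms <- noiseless_batch(conc)
  cal <- fit_calibration(ms)
  lim <- compute_lod_loq(ms, calibration = cal)
  expect_equal(lim$lod_area, 0)  # no noise floor without noise
  q <- quantify(ms, cal, lim, recovery_correct(ms, 5e4))
  expect_equal(q$concentration_pM[match(sprintf("s%02d", seq_along(conc)),
                                        q$sample_id)], conc)
  expect_true(all(q$flag == "ok"))
})

test_that("every sample-compound pair gets exactly one flag", {
  set.seed(12)
  tc <- tidyr::expand_grid(sample_id = sprintf("s%02d", 1:6),
                           compound = c("B1", "HMP"))
  tc$conc_pM <- stats::runif(nrow(tc), 0, 40)
  ms <- simulate_ms_dataset(tc, c(5, 20, 60, 120), recovery = 0.8,
                            noise_cv = 0.1, seed = 13)
  cal <- fit_calibration(ms)
  lim <- compute_lod_loq(ms, calibration = cal)
  q <- quantify(ms, cal, lim, recovery_correct(ms, 5e4),
                vitamer_recovery = c(HMP = 0.9))
  expect_equal(nrow(q), nrow(tc))
  expect_false(any(is.na(q$flag)))
  expect_false(any(duplicated(q[, c("sample_id", "compound")])))
  # concentrations only under ok / accepted LOD_to_LOQ
  expect_true(all(q$flag[!is.na(q$concentration_pM)] %in% c("ok", "LOD_to_LOQ")))
})

test_that("pool summaries add compound means and normalize to POC", {
  rec <- tibble::tibble(
    sample_id = "d1", compound = c("B1", "HET", "HMP", "FAMP"),
    concentration_pM = c(10, 20, 30, 40),
    flag = "ok", recovery_applied = 1, reviewed = TRUE)
  ps <- pool_summaries(rec)
  expect_equal(ps$combined$combined_pM, 100)
  expect_equal(ps$combined$n_below_lod, 0)

  rec2 <- rec
  rec2$concentration_pM[2] <- NA
  rec2$flag[2] <- "below_LOD"
  ps2 <- pool_summaries(rec2)
  expect_equal(ps2$combined$combined_pM, 80)  # below-LOD contributes zero
  expect_equal(ps2$combined$n_below_lod, 1)

  poc <- tibble::tibble(sample_id = "d1", poc_uM = 20)
  ps3 <- pool_summaries(rec, poc = poc)
  expect_equal(ps3$per_poc$pmol_per_umolC, c(10, 20, 30, 40) / 20)
  expect_error(pool_summaries(rec, poc = poc[0, ]), "POC missing")

  # random record sets match a brute-force group sum
  set.seed(4)
  rr <- tidyr::expand_grid(sample_id = c("a", "b", "c"),
                           compound = c("B1", "HET", "HMP", "FAMP"))
  rr$concentration_pM <- stats::runif(12, 0, 50)
  rr$flag <- "ok"; rr$recovery_applied <- 1; rr$reviewed <- TRUE
  got <- pool_summaries(rr)$combined
  want <- tapply(rr$concentration_pM, rr$sample_id, sum)
  expect_equal(got$combined_pM[match(names(want), got$sample_id)],
               as.numeric(want))
})
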