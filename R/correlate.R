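# All permutations of 1..n as an (n!) x n matrix; recursive, deterministic
# row order. Intended for small n (n! rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

# Concordance numerator S = sum_{i<j} sign(x_i - x_j) sign(y_i - y_j)
kendall_numerator <- function(x, y) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  sum(sign(x[pairs[1, ]] - x[pairs[2, ]]) * sign(y[pairs[1, ]] - y[pairs[2, ]]))
}

# Exact two-sided permutation p-value for Kendall's tau. The tie-corrected
# denominator of tau-b is invariant under permutation of y, so the test on
# |tau| reduces to the permutation distribution of the numerator S.
kendall_exact_p <- function(x, y) {
  n <- length(x)
  s_obs <- kendall_numerator(x, y)
  perms <- all_permutations(n)
  pairs <- utils::combn(n, 2)
  sx <- sign(x[pairs[1, ]] - x[pairs[2, ]])
  s_perm <- numeric(nrow(perms))
  for (k in seq_len(ncol(pairs))) {
    yi <- y[perms[, pairs[1, k]]]
    yj <- y[perms[, pairs[2, k]]]
    s_perm <- s_perm + sx[k] * sign(yi - yj)
  }
  mean(abs(s_perm) >= abs(s_obs) - 1e-9)
}

#' Kendall correlation screen over a series table
#'
#' Computes tie-corrected Kendall's tau-b for every pair of variables on
#' pairwise-complete observations, with an exact permutation p-value for
#' small series (n <= `exact_max`) and the tie-corrected normal
#' approximation otherwise. Significance is flagged at p < .05 with no
#' multiplicity correction. Constant series give an undefined tau and are
#' flagged.
#'
#' @param table Data frame or matrix with one column per variable and one
#'   row per timepoint; missing values allowed.
#' @param exact_max Largest n for which the exact permutation null is
#'   enumerated (default 8; enumeration is n!).
#' @param min_n Minimum paired observations per pair (default 3).
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `var1`, `var2`, `tau`, `p_value`, `n_pairs`, `method`
#'   ("exact"/"normal"/"undefined"), `significant`.
#' @export
kendall_screen <- function(table, exact_max = 8L, min_n = 3L, alpha = 0.05) {
  m <- as.data.frame(table)
  m <- m[, vapply(m, is.numeric, logical(1)), drop = FALSE]
  vars <- names(m)
  if (length(vars) < 2) stop("need at least two numeric variables")
  combos <- utils::combn(vars, 2)
  out <- lapply(seq_len(ncol(combos)), function(k) {
    v1 <- combos[1, k]; v2 <- combos[2, k]
    ok <- stats::complete.cases(m[[v1]], m[[v2]])
    x <- m[[v1]][ok]; y <- m[[v2]][ok]
    n <- length(x)
    row <- tibble::tibble(var1 = v1, var2 = v2, tau = NA_real_,
                          p_value = NA_real_, n_pairs = n,
                          method = "undefined", significant = FALSE)
    if (n < min_n) return(row)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(row)
    row$tau <- stats::cor(x, y, method = "kendall")
    if (n <= exact_max) {
      row$p_value <- kendall_exact_p(x, y)
      row$method <- "exact"
    } else {
      row$p_value <- suppressWarnings(
        stats::cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
      row$method <- "normal"
    }
    row$significant <- row$p_value < alpha
    row
  })
  dplyr::bind_rows(out)
}

#' Bacterial biomass from cell counts
#'
#' Converts flow-cytometry bacterioplankton counts to biomass with a fixed
#' carbon content of 20 fg C per cell, expressed as micrograms of carbon
#' per litre.
#'
#' @param cells_per_ml Numeric vector of cell concentrations (cells/ml).
#' @param fg_c_per_cell Carbon conversion factor (default 20 fg C/cell).
#' @return Biomass in ug C per litre.
#' @export
#' @examples
#' bacterial_biomass(1e6)    # 20 ug C / l
bacterial_biomass <- function(cells_per_ml, fg_c_per_cell = 20) {
  if (any(cells_per_ml < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  # cells/ml * fg/cell * 1e3 ml/l * 1e-9 ug/fg
  cells_per_ml * fg_c_per_cell * 1e-6
}
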