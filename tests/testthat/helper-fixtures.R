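# Shared builders for synthetic test communities.

# One genome spec per genotype category, with realistic accessory genes.
category_specs <- function(n_other_genes = 20) {
  list(
    genome_spec("proto", c("thiC", "thiG", "thiE"),
                n_other_genes = n_other_genes),
    genome_spec("pyrim", c("thiG", "thiE", "thiV", "tenA"),
                riboswitch_links = "thiV", n_other_genes = n_other_genes),
    genome_spec("thiaz", c("thiC", "thiE", "thiM"),
                n_other_genes = n_other_genes),
    genome_spec("transp", c("thiB"), n_other_genes = n_other_genes),
    genome_spec("putat", c("cytX", "ykoF"), n_other_genes = n_other_genes),
    genome_spec("none", character(), n_other_genes = n_other_genes)
  )
}

# All-prototroph community: every genome carries exactly one copy of each
# synthesis gene.
prototroph_community <- function(n_genomes = 4, n_timepoints = 3, seed = 11,
                                 depth = 1e6) {
  specs <- lapply(seq_len(n_genomes), function(i) {
    genome_spec(sprintf("p%02d", i), c("thiC", "thiG", "thiE"),
                n_other_genes = 10)
  })
  gen <- generate_genomes(specs, seed = seed)
  set.seed(seed + 1)
  ab <- matrix(stats::rgamma(n_genomes * n_timepoints, 2), n_genomes)
  ab <- sweep(ab, 2, colSums(ab), "/")
  rownames(ab) <- sprintf("p%02d", seq_len(n_genomes))
  community_scenario(gen, ab, depth = depth, seed = seed + 2)
}

# Independently coded genotype rule oracle: a flat nested-if ladder kept
# deliberately separate from classify_gene_set()'s implementation.
oracle_genotype <- function(genes) {
  h <- function(g) g %in% genes
  if (h("thiE") && h("thiG") && h("thiC")) {
    "PROTOTROPH"
  } else if (h("thiE") && h("thiG") && !h("thiC")) {
    "PYRIMIDINE_AUXOTROPH"
  } else if (h("thiE") && !h("thiG") && h("thiC")) {
    "THIAZOLE_AUXOTROPH"
  } else if (h("thiB") || h("thiT")) {
    "AUXOTROPH_B1_TRANSPORT"
  } else if (h("thiV") || h("thiY") || h("cytX") || h("ykoF") ||
             h("thiPerm") || h("omr1")) {
    "AUXOTROPH_PUTATIVE_TRANSPORT"
  } else {
    "NO_KNOWN_ROUTE"
  }
}

# Independent permutation oracle for Kendall screening: enumerate
# permutations recursively through a code path separate from the
# implementation's, computing tau with stats::cor per permutation.
oracle_kendall_p <- function(x, y) {
  n <- length(y)
  perm_rec <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  tau_obs <- stats::cor(x, y, method = "kendall")
  taus <- vapply(perm_rec(seq_len(n)),
                 function(p) stats::cor(x, y[p], method = "kendall"),
                 numeric(1))
  mean(abs(taus) >= abs(tau_obs) - 1e-9)
}

# Closed-form simple-linear-regression oracle (normal equations).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
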