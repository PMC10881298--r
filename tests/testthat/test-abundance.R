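toy_matrix <- function(values, lengths, mapped, is_marker = NULL) {
  features <- tibble::tibble(
    feature_id = rownames(values), gene_label = rownames(values),
    length = lengths,
    is_marker = is_marker %||% grepl("^marker", rownames(values)))
  b1cycle::b1_matrix(values, features, mapped_reads = mapped, state = "raw")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rpkm matches its closed form", {
  vals <- matrix(c(10, 10), 2, 1,
                 dimnames = list(c("g1", "g2"), "s1"))
  x <- toy_matrix(vals, lengths = c(1000, 500), mapped = c(s1 = 1e6))
  r <- rpkm(x)
  expect_equal(unname(r$values[, 1]), c(10, 20))
  expect_equal(r$state, "rpkm")
  # state machine: rpkm of rpkm is refused
  expect_error(rpkm(r), "raw")
})

test_that("rpkm equals the elementwise brute-force formula on random matrices", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:15, 1); m <- sample(2:4, 1)
    vals <- matrix(stats::rpois(n * m, 50), n,
                   dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:m)))
    lens <- sample(200:3000, n)
    mapped <- stats::setNames(sample(5e5:2e6, m), colnames(vals))
    r <- rpkm(toy_matrix(vals, lens, mapped))
    brute <- vals
    for (i in 1:n) for (j in 1:m) {
      brute[i, j] <- vals[i, j] / ((lens[i] / 1e3) * (mapped[j] / 1e6))
    }
    expect_equal(r$values, brute)
  }
})

test_that("missing feature length is rejected by name", {
  vals <- matrix(1, 1, 1, dimnames = list("gX", "s1"))
  x <- toy_matrix(vals, lengths = NA_real_, mapped = c(s1 = 1e6))
  expect_error(rpkm(x), "gX")
})

test_that("marker normalization divides by the per-sample marker median", {
  labels <- c("thiC", sprintf("marker_%02d", 1:21))
  vals <- matrix(c(5, 1:21), ncol = 1, dimnames = list(labels, "s1"))
  x <- toy_matrix(vals, lengths = rep(1000, 22), mapped = c(s1 = 1e6))
  r <- rpkm(x)
  mn <- marker_normalize(r)
  # 21 distinct marker values: divisor is the rank-11 value
  divisor <- sort(r$values[-1, 1])[[11]]
  expect_equal(mn$values["thiC", 1], r$values["thiC", 1] / divisor)
  expect_equal(mn$state, "marker_normalized")
  # all markers equal: result is invariant to how many markers there are
  vals2 <- matrix(c(5, rep(10, 21)), ncol = 1, dimnames = list(labels, "s1"))
  r2 <- rpkm(toy_matrix(vals2, rep(1000, 22), c(s1 = 1e6)))
  mn2 <- marker_normalize(r2)
  r3 <- rpkm(toy_matrix(vals2[1:6, , drop = FALSE], rep(1000, 6), c(s1 = 1e6)))
  mn3 <- marker_normalize(r3)
  expect_equal(mn2$values["thiC", 1], mn3$values["thiC", 1])
  # zero marker median: sample becomes missing, with a warning
  vals0 <- matrix(c(5, rep(0, 21)), ncol = 1, dimnames = list(labels, "s1"))
  r0 <- rpkm(toy_matrix(vals0, rep(1000, 22), c(s1 = 1e6)))
  expect_warning(mn0 <- marker_normalize(r0), "zero")
  expect_true(all(is.na(mn0$values[, 1])))
})

test_that("normalization is invariant to per-sample depth rescaling", {
  set.seed(13)
  sc <- prototroph_community(n_genomes = 3, n_timepoints = 3)
  cnt <- simulate_counts(sc, noise = "none")
  scale <- c(3, 0.5, 10)
  cnt2 <- cnt
  cnt2$values <- sweep(cnt$values, 2, scale, `*`)
  cnt2$mapped_reads <- cnt$mapped_reads * scale
  expect_equal(rpkm(cnt2)$values, rpkm(cnt)$values)
  # marker normalization additionally cancels global per-sample RPKM scaling
  r <- aggregate_features(rpkm(cnt))
  r2 <- r
  r2$values <- sweep(r$values, 2, scale, `*`)
  expect_equal(marker_normalize(r2)$values, marker_normalize(r)$values)
})

test_that("transcript activity supports both published normalizations", {
  # identity scenario: uniform unit expression means activity equals the
  # per-genome-equivalent gene abundance (1 for a universal single-copy gene)
  sc <- prototroph_community(n_genomes = 3, n_timepoints = 2)
  sc$expression[] <- 1
  mg <- aggregate_features(rpkm(simulate_counts(sc, "metagenome", noise = "none")))
  mt <- aggregate_features(rpkm(simulate_counts(sc, "metatranscriptome", noise = "none")))
  act_marker <- transcript_activity(mt, mode = "marker")
  expect_equal(unname(act_marker$values["thiC", ]), rep(1, 2))
  mg_norm <- marker_normalize(mg)
  act_mg <- transcript_activity(mt, mg_norm, mode = "metagenome")
  # metagenome mode is the elementwise quotient of metaT RPKM by the
  # marker-normalized metagenome value
  expect_equal(act_mg$values, mt$values / mg_norm$values)
  expect_equal(attr(act_mg, "mode"), "metagenome")
  # direct ratio check: metaT RPKM 4 over metaG normalized 2 gives 2
  mt4 <- mt; mt4$values["thiC", 1] <- 4
  mgn2 <- mg_norm; mgn2$values["thiC", 1] <- 2
  expect_equal(transcript_activity(mt4, mgn2, mode = "metagenome")$values["thiC", 1], 2)
})

test_that("activity rank order tracks the ground-truth expression factors", {
  spec <- genome_spec("g1", c("thiC", "thiG", "thiE", "thiB", "tenA"),
                      n_other_genes = 10)
  gen <- generate_genomes(list(spec), seed = 3)
  ab <- matrix(1, 1, 1, dimnames = list("g1", "t1"))
  sc <- community_scenario(gen, ab, depth = 1e6, seed = 4)
  mt <- simulate_counts(sc, "metatranscriptome", noise = "none")
  act <- transcript_activity(aggregate_features(rpkm(mt)), mode = "marker")
  genes <- c("thiC", "thiG", "thiE", "thiB", "tenA")
  expr <- attr(mt, "expression")
  truth <- vapply(genes, function(g) {
    expr[[sc$genomes$features$feature_id[sc$genomes$features$gene_label == g]]]
  }, numeric(1))
  expect_equal(order(act$values[genes, 1]), order(truth))
})

test_that("gene ratios reflect copy numbers", {
  sc <- prototroph_community(n_genomes = 4, n_timepoints = 2)
  mn <- marker_normalize(aggregate_features(rpkm(simulate_counts(sc, noise = "none"))))
  r <- gene_ratio(mn, "thiC", "thiE")
  expect_equal(r$overall, 1)
  expect_equal(unname(r$per_sample), rep(1, 2))
  # a gene with itself is 1 wherever defined
  expect_equal(gene_ratio(mn, "thiG", "thiG")$overall, 1)

  # half the genomes lack thiC at equal abundance: ratio 0.5
  specs <- c(lapply(1:2, function(i) genome_spec(sprintf("a%d", i),
                                                 c("thiC", "thiG", "thiE"))),
             lapply(1:2, function(i) genome_spec(sprintf("b%d", i),
                                                 c("thiG", "thiE", "thiV"))))
  gen <- generate_genomes(specs, seed = 6)
  ab <- matrix(0.25, 4, 1, dimnames = list(c("a1", "a2", "b1", "b2"), "t1"))
  sc2 <- community_scenario(gen, ab, depth = 1e6)
  mn2 <- marker_normalize(aggregate_features(rpkm(simulate_counts(sc2, noise = "none"))))
  expect_equal(gene_ratio(mn2, "thiC", "thiE")$overall, 0.5)

  # numerator absent everywhere: 0; denominator absent: undefined
  expect_equal(gene_ratio(mn2, "omr1", "thiE")$overall, 0)
  expect_true(is.na(gene_ratio(mn2, "thiE", "omr1")$overall))
})

test_that("thiC contributions scale each timepoint to 100 percent", {
  m <- matrix(c(3, 1, 5, 0, 0, 0), 2,
              dimnames = list(c("clA", "clB"), c("t1", "t2", "t3")))
  pc <- thic_contribution(m)
  expect_equal(unname(pc[, "t1"]), c(75, 25))
  expect_equal(unname(pc[, "t2"]), c(100, 0))
  expect_true(all(is.na(pc[, "t3"])))
  expect_equal(attr(pc, "all_zero"), "t3")
  # random tables: columns sum to exactly 100 and match brute force
  set.seed(9)
  for (rep in 1:5) {
    m2 <- matrix(stats::rexp(12), 4, 3, dimnames = list(paste0("c", 1:4),
                                                        paste0("t", 1:3)))
    pc2 <- thic_contribution(m2)
    expect_equal(unname(colSums(pc2)), rep(100, 3))
    expect_equal(pc2, sweep(m2, 2, colSums(m2), "/") * 100,
                 ignore_attr = TRUE)
  }
})
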