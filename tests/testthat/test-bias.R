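test_that("replicate aggregation is the gene-wise arithmetic mean", {
  tpm <- matrix(c(2, 4, 10, 1, 3, 5), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     subregion = c("ISC", "ISC", "CPT"),
                     stage = c("OV", "OV", "OV"),
                     replicate = c(1, 2, 1))
  cond <- aggregate_replicates(tpm, meta)
  expect_equal(cond["g1", "ovISC"], 3)       # mean of 2 and 4
  expect_equal(cond["g1", "ovCPT"], 10)      # single replicate: identity
  info <- attr(cond, "conditions")
  expect_equal(info$n_replicates[info$condition == "ovISC"], 2L)

  set.seed(3)
  tpm3 <- matrix(runif(30, 0, 100), 10, 3,
                 dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2", "s3")))
  meta3 <- data.frame(sample_id = colnames(tpm3), subregion = "EP",
                      stage = "HEART", replicate = 1:3)
  expect_equal(unname(aggregate_replicates(tpm3, meta3)[, "hEP"]),
               unname(rowMeans(tpm3)))
})

test_that("condition labels follow the stage-prefix convention", {
  expect_equal(condition_label(c("OV", "GLOB", "HEART", "MG"),
                               c("CPT", "ISC", "EP", "COT")),
               c("ovCPT", "gISC", "hEP", "mgCOT"))
})

test_that("pair_bias computes the pseudocounted log2 ratio and the universe rule", {
  sg <- c(gA = "A", gC = "C")
  expr <- matrix(c(40, 8, 0.5,
                   10, 8, 0.8), 2, 3, byrow = TRUE,
                 dimnames = list(c("gA", "gC"), c("c1", "c2", "c3")))
  pairs <- data.frame(pair_id = "p1", gene_A = "gA", gene_C = "gC")
  pb <- pair_bias(expr, pairs)

  # closed form with eps = 0.01 lands just under the strong boundary
  expect_equal(pb$values["p1", "c1"], log2(40.01 / 10.01), tolerance = 1e-12)
  expect_equal(pb$classes["p1", "c1"], "INTERMEDIATE")
  expect_equal(pb$values["p1", "c2"], 0)
  expect_equal(pb$classes["p1", "c2"], "LOW_BIAS")
  # neither member above 1 TPM: out of the universe
  expect_true(is.na(pb$values["p1", "c3"]))
  expect_equal(pb$classes["p1", "c3"], "UNDETECTED")
})

test_that("pairs with members absent from the matrix are dropped with a message", {
  expr <- matrix(c(5, 5), 2, 1, dimnames = list(c("gA", "gC"), "c1"))
  pairs <- data.frame(pair_id = c("p1", "p2"),
                      gene_A = c("gA", "gX"), gene_C = c("gC", "gY"))
  expect_message(pb <- pair_bias(expr, pairs), "1 pair")
  expect_equal(rownames(pb$values), "p1")
  expect_equal(pb$n_dropped, 1L)
})

test_that("classification boundaries are inclusive and classes partition the line", {
  v <- c(2.0, -2.0, 0.1, -0.1, 1.9989, -1.0, 0, 5, -7, 0.100001, 1.999999)
  expect_equal(classify_bias(v),
               c("A_BIAS", "C_BIAS", "LOW_BIAS", "LOW_BIAS", "INTERMEDIATE",
                 "INTERMEDIATE", "LOW_BIAS", "A_BIAS", "C_BIAS",
                 "INTERMEDIATE", "INTERMEDIATE"))
  # total function: exactly one class for any finite value
  set.seed(9)
  grid <- c(runif(2000, -6, 6), -2, 2, -0.1, 0.1, 0)
  expect_false(anyNA(classify_bias(grid)))
})

test_that("bias values are antisymmetric under subgenome label exchange", {
  sim <- simulate_homoeologs(tiny_config(seed = 4))
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  fwd <- pair_bias(cond, sim$pairs)
  swapped <- data.frame(pair_id = sim$pairs$pair_id,
                        gene_A = sim$pairs$gene_C,
                        gene_C = sim$pairs$gene_A)
  rev <- pair_bias(cond, swapped)
  expect_equal(rev$values, -fwd$values, tolerance = 1e-12)
  tf <- bias_tally(fwd)
  tr <- bias_tally(rev)
  expect_equal(tr$n_A_bias, tf$n_C_bias)
  expect_equal(tr$n_C_bias, tf$n_A_bias)
  expect_equal(tr$n_low_bias, tf$n_low_bias)
})

test_that("with no pseudocount the ratio is exactly scale invariant", {
  sg <- c(gA = "A", gC = "C")
  expr <- matrix(c(30, 7), 2, 1, dimnames = list(names(sg), "c1"))
  pairs <- data.frame(pair_id = "p1", gene_A = "gA", gene_C = "gC")
  th0 <- bias_thresholds(pseudocount = 1e-300)
  v1 <- pair_bias(expr, pairs, th0)$values[1, 1]
  v2 <- pair_bias(expr * 13, pairs, th0)$values[1, 1]
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("tallies partition the universe and degenerate conditions yield NA", {
  sim <- simulate_homoeologs(tiny_config(seed = 6))
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  pb <- pair_bias(cond, sim$pairs)
  tal <- bias_tally(pb)
  expect_equal(tal$n_A_bias + tal$n_C_bias + tal$n_low_bias + tal$n_intermediate,
               tal$n_universe)

  # all-undetected condition
  expr <- matrix(c(0.2, 0.3), 2, 1, dimnames = list(c("gA", "gC"), "c1"))
  pb0 <- pair_bias(expr, data.frame(pair_id = "p1", gene_A = "gA",
                                    gene_C = "gC"))
  t0 <- bias_tally(pb0)
  expect_equal(t0$n_universe, 0L)
  expect_true(is.na(t0$pct_strong) && is.na(t0$pct_low))
})

test_that("flag_gene_family restricts the matrix to named pairs", {
  sim <- simulate_homoeologs(tiny_config(seed = 2))
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  pb <- pair_bias(cond, sim$pairs)
  sub <- flag_gene_family(pb, sim$pairs$pair_id[1:3])
  expect_equal(nrow(sub), 3L * ncol(pb$values))
  expect_equal(flag_gene_family(pb, character(0))$pair_id, character(0))
  full <- flag_gene_family(pb, rownames(pb$values))
  expect_equal(matrix(full$log2_ratio, nrow(pb$values),
                      dimnames = dimnames(pb$values)),
               pb$values)
  expect_error(flag_gene_family(pb, "nope"), "nope")
})
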