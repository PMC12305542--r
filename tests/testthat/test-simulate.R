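test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_homoeologs(tiny_config(seed = 3))
  s2 <- simulate_homoeologs(tiny_config(seed = 3))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$pair_class, s2$truth$pair_class)
  s3 <- simulate_homoeologs(tiny_config(seed = 4))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("config validation rejects infeasible settings", {
  expect_error(simulation_config(class_probs = c(A_BIAS = 0.5, C_BIAS = 0.5,
                                                 LOW_BIAS = 0.1,
                                                 INTERMEDIATE = 0.1)),
               "sum to 1")
  expect_error(simulation_config(mature_embryo = list(fraction_expressed = 0.3,
                                                      storage_gene_count = 20,
                                                      storage_share = 1.2)),
               "infeasible")
  expect_error(simulation_config(strong_effect_log2 = 1), ">= 2")
})

test_that("an all-low-bias simulation is recovered as overwhelmingly low bias", {
  # deep libraries and near-zero dispersion: the low-noise limit in which
  # the +/-0.1 low-bias band is recoverable
  cfg <- tiny_config(seed = 5,
                     class_probs = c(A_BIAS = 0, C_BIAS = 0, LOW_BIAS = 1,
                                     INTERMEDIATE = 0),
                     library_size = 5e6, nb_dispersion = 1e-4)
  sim <- simulate_homoeologs(cfg)
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  tal <- bias_tally(pair_bias(cond, sim$pairs))
  expect_true(all(tal$n_low_bias / tal$n_universe >= 0.95))
})

test_that("a symmetric configuration yields a balanced subgenome share", {
  cfg <- tiny_config(seed = 6, global_c_share = 0.5)
  sim <- simulate_homoeologs(cfg)
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  sh <- tpm_share(tpm, sim$subgenomes)
  expect_true(all(abs(sh$share_C - 0.5) < 0.02))
})

test_that("the C-share estimate converges toward the configured value with size", {
  est <- vapply(c(150, 600), function(np) {
    cfg <- tiny_config(seed = 7, n_pairs = np,
                       n_singletons_A = np / 2, n_singletons_C = np / 2)
    sim <- simulate_homoeologs(cfg)
    tpm <- tpm_normalize(sim$counts, sim$lengths)
    mean(tpm_share(tpm, sim$subgenomes)$share_C)
  }, numeric(1))
  expect_lt(abs(est[2] - 0.55), abs(est[1] - 0.55) + 0.01)
  expect_lt(abs(est[2] - 0.55), 0.02)
})

test_that("mature-embryo conditions express few genes and are storage dominated", {
  cfg <- simulation_config(
    n_pairs = 300, n_singletons_A = 75, n_singletons_C = 75,
    conditions = data.frame(subregion = c("ISC", "COT"),
                            stage = c("MG", "MG")),
    replicates = 2, library_size = 1e6, seed = 9)
  sim <- simulate_homoeologs(cfg)
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  det <- colSums(detect_genes(cond, 1))
  expect_lt(det[["mgCOT"]], 0.6 * det[["mgISC"]])
  storage_genes <- with(sim$pairs,
                        c(gene_A[pair_id %in% sim$truth$storage_pairs],
                          gene_C[pair_id %in% sim$truth$storage_pairs]))
  storage_share <- sum(cond[storage_genes, "mgCOT"]) / sum(cond[, "mgCOT"])
  expect_gt(storage_share, 0.5)
  expect_lt(sum(cond[storage_genes, "mgISC"]) / sum(cond[, "mgISC"]), 0.3)
})

test_that("recovery_report flags perfect and null cluster assignments correctly", {
  sim <- simulate_homoeologs(tiny_config(seed = 10))
  perfect <- data.frame(pair_id = sim$pairs$pair_id,
                        top_cluster = as.integer(factor(sim$truth$pair_class)),
                        sub_cluster = NA_integer_, included_in_report = TRUE)
  class(perfect) <- c("cluster_assignment", "data.frame")
  expect_equal(recovery_report(sim$truth, assignment = perfect)$ari, 1)

  set.seed(99)
  null <- perfect
  null$top_cluster <- sample(1:4, nrow(null), replace = TRUE)
  expect_lt(abs(recovery_report(sim$truth, assignment = null)$ari), 0.05)

  bad <- perfect
  bad$pair_id[1] <- "unknown_pair"
  expect_error(recovery_report(sim$truth, assignment = bad), "mismatched")
})

test_that("per-cell strong-class recall is high at the default noise level", {
  sim <- simulate_homoeologs(simulation_config(
    n_pairs = 500, n_singletons_A = 125, n_singletons_C = 125, seed = 1))
  tpm <- tpm_normalize(sim$counts, sim$lengths)
  cond <- aggregate_replicates(tpm, sim$metadata)
  rec <- recovery_report(sim$truth, bias = pair_bias(cond, sim$pairs))
  expect_gte(rec$strong_recall, 0.9)
  expect_equal(sum(rec$confusion), sum(rec$confusion))  # well-formed table
  expect_setequal(colnames(rec$confusion),
                  intersect(c("A_BIAS", "C_BIAS", "LOW_BIAS", "INTERMEDIATE"),
                            colnames(rec$confusion)))
})

test_that("write_bundle round-trips through the package readers", {
  sim <- simulate_homoeologs(tiny_config(seed = 11))
  dir <- tempfile("bundle")
  write_bundle(sim, dir)
  raw <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(raw$counts, sim$counts + 0)
  expect_equal(raw$lengths, sim$lengths, tolerance = 1e-12)
  sg <- read_subgenomes(file.path(dir, "subgenomes.tsv"))
  expect_identical(sg, sim$subgenomes)
  pr <- read_pairs(file.path(dir, "pairs.tsv"), sg)
  expect_equal(pr, sim$pairs)
  gmt <- read_gmt(file.path(dir, "annotations.gmt"))
  expect_identical(names(gmt), names(sim$gmt))
  expect_identical(gmt[[1]], sim$gmt[[1]])
})
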