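test_that("condition dendrogram merges identical columns first", {
  set.seed(21)
  base <- rnorm(20)
  vals <- cbind(c1 = base, c2 = base, c3 = base + 50)
  rownames(vals) <- sprintf("p%02d", 1:20)
  hc <- condition_dendrogram(as_bias(vals))
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("c1", "c2"))
  expect_error(condition_dendrogram(as_bias(vals[, 1, drop = FALSE])),
               ">= 2 conditions")
})

test_that("condition dendrogram topology is invariant to column order", {
  set.seed(22)
  vals <- matrix(rnorm(60), 15, 4,
                 dimnames = list(sprintf("p%02d", 1:15), paste0("c", 1:4)))
  hc1 <- condition_dendrogram(as_bias(vals))
  hc2 <- condition_dendrogram(as_bias(vals[, c(3, 1, 4, 2)]))
  expect_equal(sort(ape::as.phylo(hc1)$tip.label),
               sort(ape::as.phylo(hc2)$tip.label))
  expect_true(ape::all.equal.phylo(ape::as.phylo(hc1), ape::as.phylo(hc2),
                                   use.edge.length = FALSE))
})

test_that("merge order equals brute-force agglomeration on small instances", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    vals <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(sprintf("p%02d", 1:n), paste0("c", 1:4)))
    oracle <- brute_force_partitions(vals, "complete")
    b <- as_bias(vals)
    for (k in seq_len(n)) {
      ours <- kcut_rows(b, k = k)
      expect_true(same_partition(ours$top_cluster[match(rownames(vals),
                                                        ours$pair_id)],
                                 oracle[[as.character(k)]]),
                  info = sprintf("rep %d, n %d, k %d", rep, n, k))
    }
  }
})

test_that("k-cuts are trivial at the extremes and nest monotonically", {
  set.seed(24)
  vals <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(sprintf("p%03d", 1:200), paste0("c", 1:5)))
  b <- as_bias(vals)
  expect_equal(sort(unique(kcut_rows(b, 1)$top_cluster)), 1L)
  expect_equal(length(unique(kcut_rows(b, 200)$top_cluster)), 200L)
  expect_error(kcut_rows(b, 201), "exceeds")

  # hierarchical nesting: a cut at larger k refines the cut at smaller k
  cuts <- lapply(c(2, 4, 6, 9), function(k) kcut_rows(b, k)$top_cluster)
  for (i in 1:3) {
    finer <- cuts[[i + 1]]
    coarser <- cuts[[i]]
    expect_true(all(tapply(coarser, finer,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("rows with undetected cells are excluded from clustering", {
  set.seed(25)
  vals <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("p%02d", 1:10), paste0("c", 1:4)))
  vals[3, 2] <- NA
  expect_message(asg <- kcut_rows(as_bias(vals), 2), "excluded")
  expect_equal(nrow(asg), 9L)
  expect_false("p03" %in% asg$pair_id)
})

test_that("cluster labels are assigned by decreasing size", {
  set.seed(26)
  vals <- rbind(matrix(rnorm(5 * 3, mean = 0), 5, 3),
                matrix(rnorm(30 * 3, mean = 50), 30, 3))
  rownames(vals) <- sprintf("p%02d", 1:35)
  asg <- kcut_rows(as_bias(vals), 2)
  expect_equal(sum(asg$top_cluster == 1), 30L)
  expect_equal(sum(asg$top_cluster == 2), 5L)
})

test_that("subcluster splits targeted clusters only, recovering nested blobs", {
  set.seed(27)
  # three top blobs; the first contains two sub-blobs
  vals <- rbind(matrix(rnorm(20 * 4, mean = 0), 20, 4),
                matrix(rnorm(20 * 4, mean = 8), 20, 4),
                matrix(rnorm(15 * 4, mean = 60), 15, 4),
                matrix(rnorm(12 * 4, mean = -60), 12, 4))
  rownames(vals) <- sprintf("p%02d", 1:67)
  truth_top <- rep(c(1, 1, 2, 3), c(20, 20, 15, 12))
  truth_sub <- rep(c(1, 2, NA, NA), c(20, 20, 15, 12))
  b <- as_bias(vals)
  asg <- kcut_rows(b, 3)
  expect_true(same_partition(asg$top_cluster, truth_top))
  asg <- subcluster(b, asg, list("1" = 2))
  got_sub <- asg$sub_cluster[match(rownames(vals), asg$pair_id)]
  expect_true(all(is.na(got_sub[41:67])))
  expect_true(same_partition(got_sub[1:40], truth_sub[1:40]))

  # k_sub = 1 labels the whole cluster as one sub-cluster
  asg2 <- subcluster(b, kcut_rows(b, 3), list("2" = 1))
  expect_equal(unique(asg2$sub_cluster[asg2$top_cluster == 2]), 1L)
  expect_error(subcluster(b, asg, list("3" = 99)), "cluster 3")
})

test_that("identical rows sub-split deterministically with a degeneracy warning", {
  vals <- rbind(matrix(1, 10, 3), matrix(9, 10, 3))
  rownames(vals) <- sprintf("p%02d", 1:20)
  b <- as_bias(vals)
  asg <- kcut_rows(b, 2)
  expect_warning(s1 <- subcluster(b, asg, list("1" = 2)), "degenerate")
  expect_warning(s2 <- subcluster(b, asg, list("1" = 2)), "degenerate")
  expect_identical(s1$sub_cluster, s2$sub_cluster)
})

test_that("the small-cluster filter uses a strict 'fewer than' boundary", {
  asg <- data.frame(pair_id = sprintf("p%03d", 1:119),
                    top_cluster = rep(c(1L, 2L), c(60, 59)),
                    sub_cluster = NA_integer_,
                    included_in_report = TRUE)
  class(asg) <- c("cluster_assignment", "data.frame")
  out <- filter_small(asg, min_size = 60)
  expect_true(all(out$included_in_report[out$top_cluster == 1]))
  expect_false(any(out$included_in_report[out$top_cluster == 2]))
  # membership itself is never deleted
  expect_equal(nrow(out), 119L)
  expect_true(all(filter_small(asg, min_size = 0)$included_in_report))
  sizes <- cluster_sizes(out)
  expect_equal(sizes$size, c(60L, 59L))
})

test_that("row permutation yields the same partition up to label renaming", {
  set.seed(28)
  vals <- matrix(rnorm(50 * 4), 50, 4,
                 dimnames = list(sprintf("p%02d", 1:50), paste0("c", 1:4)))
  a1 <- kcut_rows(as_bias(vals), 5)
  perm <- sample(50)
  a2 <- kcut_rows(as_bias(vals[perm, ]), 5)
  m <- match(a1$pair_id, a2$pair_id)
  expect_true(same_partition(a1$top_cluster, a2$top_cluster[m]))
})
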