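# Shared fixtures and independent oracles, built in code at test time.

# A small dissection design: 2 subregions x 2 stages x 2 replicates.
tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    n_pairs = 200, n_singletons_A = 50, n_singletons_C = 50,
    conditions = expand.grid(subregion = c("ISC", "CPT"),
                             stage = c("OV", "GLOB"),
                             stringsAsFactors = FALSE),
    replicates = 2, library_size = 5e5, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

maternal_conditions <- function() {
  condition_label(rep(c("OV", "GLOB", "HEART", "MG"), each = 4),
                  rep(c("ISC", "OSC", "CZSC", "CPT"), times = 4))
}

write_counts_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Wraps a plain value matrix as a minimal bias_matrix for clustering tests.
as_bias <- function(values) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  }
  structure(list(values = values,
                 classes = matrix("INTERMEDIATE", nrow(values), ncol(values),
                                  dimnames = dimnames(values)),
                 pairs = data.frame(pair_id = rownames(values),
                                    gene_A = paste0(rownames(values), "_A"),
                                    gene_C = paste0(rownames(values), "_C"),
                                    stringsAsFactors = FALSE),
                 thresholds = bias_thresholds(), n_dropped = 0L,
                 conditions = NULL),
            class = "bias_matrix")
}

# Independent brute-force agglomeration oracle: returns the partition (an
# integer assignment vector) for every k from n rows down to 1, merging the
# minimum-linkage pair at each step.
brute_force_partitions <- function(x, linkage = "complete") {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  out <- list()
  assignment <- seq_len(n)
  out[[as.character(n)]] <- assignment
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        link <- switch(linkage, complete = max(dd), average = mean(dd))
        if (link < best_d) {
          best_d <- link
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
    assignment <- integer(n)
    for (ci in seq_along(clusters)) assignment[clusters[[ci]]] <- ci
    out[[as.character(length(clusters))]] <- assignment
  }
  out
}

# Partition equality up to label renaming: canonicalize by first occurrence.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Exhaustive hypergeometric tail by direct summation over the support.
enum_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
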