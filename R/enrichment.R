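#' Enrichment configuration
#'
#' Raw p-values against `alpha = 0.001` by default (no multiple-testing
#' correction), with a pair-level support filter: a term is called
#' significant only if at least `min_pair_support` pairs in the cluster
#' carry it (default 2, i.e. more than one pair). Benjamini-Hochberg
#' correction is available; when selected, significance is judged on the
#' adjusted p-values.
#'
#' @param alpha significance level, 0 < alpha < 1.
#' @param min_pair_support minimum annotated pairs in the cluster (>= 1).
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @param pair_annotation_rule `"either_homoeolog"` (union of the two
#'   members' terms) or `"both_homoeologs"` (intersection).
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.001, min_pair_support = 2,
                              correction = c("none", "benjamini_hochberg"),
                              pair_annotation_rule = c("either_homoeolog",
                                                       "both_homoeologs")) {
  stopifnot(alpha > 0, alpha < 1, min_pair_support >= 1)
  structure(list(alpha = alpha, min_pair_support = min_pair_support,
                 correction = match.arg(correction),
                 pair_annotation_rule = match.arg(pair_annotation_rule)),
            class = "enrichment_config")
}

#' Map gene-level annotation sets onto homoeolog pairs
#'
#' Under `either_homoeolog` a pair carries the union of its two members'
#' terms; under `both_homoeologs`, the intersection. Pairs whose members
#' are both unannotated get an empty term set.
#'
#' @param pairs pair table (`pair_id`, `gene_A`, `gene_C`).
#' @param annotations GMT-style named list of gene vectors
#'   (see [read_gmt()]).
#' @param rule `"either_homoeolog"` or `"both_homoeologs"`.
#' @return named list: pair_id -> character vector of term ids; the GMT's
#'   `term_names` attribute is carried over.
#' @export
annotate_pairs <- function(pairs, annotations,
                           rule = c("either_homoeolog", "both_homoeologs")) {
  rule <- match.arg(rule)
  gene2terms <- list()
  for (term in names(annotations)) {
    for (g in annotations[[term]]) {
      gene2terms[[g]] <- c(gene2terms[[g]], term)
    }
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    tA <- gene2terms[[pairs$gene_A[i]]] %||% character(0)
    tC <- gene2terms[[pairs$gene_C[i]]] %||% character(0)
    if (rule == "either_homoeolog") union(tA, tC) else intersect(tA, tC)
  })
  names(out) <- pairs$pair_id
  structure(out, term_names = attr(annotations, "term_names"))
}

#' Hypergeometric term enrichment of a pair cluster
#'
#' For each term with at least one annotated pair in the population, the
#' one-sided hypergeometric upper-tail probability
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n)}
#' where `N` is the population size, `K` the annotated pairs in the
#' population, `n` the cluster size and `k` the annotated pairs in the
#' cluster (Fisher's exact upper tail). A term is flagged significant iff
#' its (possibly BH-adjusted) p-value is below `alpha` and `k` meets the
#' pair-support filter. Rows are sorted by p ascending, ties by term id.
#'
#' @param cluster_pairs pair ids in the cluster (subset of the population).
#' @param population_pairs pair ids forming the background universe.
#' @param pair_annotations pair -> term map from [annotate_pairs()].
#' @param config an [enrichment_config()].
#' @return data.frame: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, (`p_adjusted`,) `significant`.
#' @examples
#' anns <- list(p1 = "T1", p2 = "T1", p3 = "T1", p4 = character(0),
#'              p5 = character(0), p6 = character(0))
#' enrich(c("p1", "p2", "p3"), names(anns), anns)  # p = 1/20
#' @export
enrich <- function(cluster_pairs, population_pairs, pair_annotations,
                   config = enrichment_config()) {
  stopifnot(inherits(config, "enrichment_config"))
  population_pairs <- unique(population_pairs)
  cluster_pairs <- unique(cluster_pairs)
  if (length(population_pairs) == 0L) stop("population is empty")
  if (!all(cluster_pairs %in% population_pairs)) {
    stop("cluster is not a subset of the population")
  }
  pop_terms <- pair_annotations[population_pairs]
  clu_terms <- pair_annotations[cluster_pairs]
  K <- table(unlist(pop_terms, use.names = FALSE))
  if (length(K) == 0L) {
    return(empty_enrichment(config))
  }
  k <- table(factor(unlist(clu_terms, use.names = FALSE), levels = names(K)))
  N <- length(population_pairs)
  n <- length(cluster_pairs)
  p <- stats::phyper(as.integer(k) - 1L, as.integer(K),
                     N - as.integer(K), n, lower.tail = FALSE)
  term_names <- attr(pair_annotations, "term_names")
  res <- data.frame(term_id = names(K),
                    term_name = if (is.null(term_names)) names(K)
                                else unname(term_names[names(K)]),
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  if (config$correction == "benjamini_hochberg") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < config$alpha &
      res$k >= config$min_pair_support
  } else {
    res$significant <- res$p_value < config$alpha &
      res$k >= config$min_pair_support
  }
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment of an enrichment table
#'
#' Step-up FDR adjustment over the whole table; re-evaluates the
#' `significant` flag against `alpha` on the adjusted values (keeping the
#' pair-support filter).
#'
#' @param results table from [enrich()].
#' @param config an [enrichment_config()] providing `alpha` and
#'   `min_pair_support`.
#' @return `results` with a `p_adjusted` column.
#' @export
correct_pvalues <- function(results, config = enrichment_config()) {
  results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
  results$significant <- results$p_adjusted < config$alpha &
    results$k >= config$min_pair_support
  results
}

empty_enrichment <- function(config) {
  res <- data.frame(term_id = character(0), term_name = character(0),
                    k = integer(0), K = integer(0), n = integer(0),
                    N = integer(0), p_value = numeric(0),
                    stringsAsFactors = FALSE)
  if (config$correction == "benjamini_hochberg") res$p_adjusted <- numeric(0)
  res$significant <- logical(0)
  res
}
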