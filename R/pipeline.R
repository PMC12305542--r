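#' Run the full bias-analysis pipeline on an input bundle
#'
#' Orchestrates the stages end to end: read and validate inputs, TPM
#' normalization (skipped when `tpm = TRUE` inputs are already
#' normalized), subgenome summaries, replicate aggregation, the log2(A/C)
#' bias matrix with class tallies, hierarchical clustering with optional
#' recursive sub-clustering and small-cluster filtering, per-cluster term
#' enrichment (when a GMT is present), and the eFP-style long-format
#' export. Every result table is written as TSV into `out_dir` together
#' with a JSON run manifest (config snapshot, input checksums, per-stage
#' row counts). Reruns on identical inputs and config reproduce identical
#' tables.
#'
#' Expected bundle files (as produced by [write_bundle()]): `counts.tsv`
#' (first column gene ids, optional `length` column), `subgenomes.tsv`,
#' `pairs.tsv`, `metadata.tsv`, optionally `annotations.gmt`.
#'
#' @param input_dir directory holding the input bundle.
#' @param out_dir output directory (created if needed).
#' @param tpm set `TRUE` when `counts.tsv` already holds TPM values.
#' @param thresholds a [bias_thresholds()].
#' @param clustering a [clustering_config()].
#' @param enrichment an [enrichment_config()] (used when a GMT exists).
#' @param top_n top-N list lengths for the subgenome summary; entries
#'   exceeding the gene count are dropped.
#' @param cluster_conditions optional condition subset used for pair
#'   clustering (complete-case rows are required across the clustered
#'   columns only).
#' @return invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(input_dir, out_dir, tpm = FALSE,
                         thresholds = bias_thresholds(),
                         clustering = clustering_config(),
                         enrichment = enrichment_config(),
                         top_n = c(500, 1000, 1500, 5000),
                         cluster_conditions = NULL) {
  paths <- file.path(input_dir, c(counts = "counts.tsv",
                                  subgenomes = "subgenomes.tsv",
                                  pairs = "pairs.tsv",
                                  metadata = "metadata.tsv",
                                  gmt = "annotations.gmt"))
  names(paths) <- c("counts", "subgenomes", "pairs", "metadata", "gmt")
  for (p in paths[1:4]) if (!file.exists(p)) stop("missing input file: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  raw <- read_counts(paths[["counts"]])
  subgenomes <- read_subgenomes(paths[["subgenomes"]])
  meta <- read_metadata(paths[["metadata"]])
  pairs <- read_pairs(paths[["pairs"]], subgenomes,
                      gene_universe = rownames(raw$counts))

  expr <- if (tpm) raw$counts else tpm_normalize(raw$counts, raw$lengths)

  summary_tab <- subgenome_summary(expr, subgenomes, meta, n_list = top_n)
  write_tsv(summary_tab, file.path(out_dir, "subgenome_summary.tsv"))

  cond <- aggregate_replicates(expr, meta)
  bias <- pair_bias(cond, pairs, thresholds)
  write_tsv(bias$values, file.path(out_dir, "bias_matrix.tsv"),
            id_col = "pair_id")
  write_tsv(bias$classes, file.path(out_dir, "bias_classes.tsv"),
            id_col = "pair_id")
  tally <- bias_tally(bias)
  write_tsv(tally, file.path(out_dir, "bias_tally.tsv"))

  cbias <- if (is.null(cluster_conditions)) bias else
    subset_bias(bias, cluster_conditions)
  if (ncol(cbias$values) >= 2L) {
    hc <- condition_dendrogram(cbias, linkage = clustering$linkage)
    write_dendrogram(hc, file.path(out_dir, "condition_dendrogram.nwk"))
  }
  assignment <- kcut_rows(cbias, k = clustering$k_top,
                          linkage = clustering$linkage)
  if (length(clustering$k_sub) > 0L) {
    assignment <- subcluster(cbias, assignment, clustering$k_sub)
  }
  assignment <- filter_small(assignment, clustering$min_cluster_size)
  write_tsv(as.data.frame(assignment), file.path(out_dir, "clusters.tsv"))
  write_tsv(cluster_sizes(assignment), file.path(out_dir, "cluster_sizes.tsv"))

  enrich_tab <- NULL
  if (file.exists(paths[["gmt"]])) {
    gmt <- read_gmt(paths[["gmt"]])
    pair_terms <- annotate_pairs(pairs, gmt,
                                 rule = enrichment$pair_annotation_rule)
    population <- assignment$pair_id
    tabs <- lapply(sort(unique(assignment$top_cluster)), function(cl) {
      members <- assignment$pair_id[assignment$top_cluster == cl]
      tab <- enrich(members, population, pair_terms, enrichment)
      if (nrow(tab) > 0L) cbind(cluster = cl, tab) else NULL
    })
    enrich_tab <- do.call(rbind, tabs)
    if (!is.null(enrich_tab)) {
      write_tsv(enrich_tab, file.path(out_dir, "enrichment.tsv"))
    }
  }

  efp <- export_efp(cond, pairs = pairs, subgenomes = subgenomes,
                    pseudocount = thresholds$pseudocount)
  write_tsv(efp, file.path(out_dir, "efp_long.tsv"))

  write_manifest(
    file.path(out_dir, "manifest.json"),
    config = list(tpm_input = tpm, thresholds = unclass(thresholds),
                  clustering = unclass(clustering),
                  enrichment = unclass(enrichment), top_n = top_n,
                  cluster_conditions = cluster_conditions),
    inputs = unname(paths),
    stage_rows = list(genes = nrow(expr), samples = ncol(expr),
                      conditions = ncol(cond), pairs = nrow(bias$values),
                      clustered_pairs = nrow(assignment),
                      summary_rows = nrow(summary_tab),
                      enrichment_rows = if (is.null(enrich_tab)) 0L
                                        else nrow(enrich_tab),
                      efp_rows = nrow(efp)))

  invisible(list(tpm = expr, condition_tpm = cond, summary = summary_tab,
                 bias = bias, tally = tally, assignment = assignment,
                 enrichment = enrich_tab, efp = efp))
}
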