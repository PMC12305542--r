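#' eFP-style relative expression profile of one gene
#'
#' For each condition, the value is
#' \deqn{\log_2\frac{TPM_c + \epsilon}{\mathrm{median}(TPM) + \epsilon}}
#' with the median taken over all conditions of the supplied matrix (the
#' standard even/odd midpoint convention). A constant positive profile
#' therefore maps to all zeros.
#'
#' @param gene_id gene identifier (must exist in `expr`).
#' @param expr gene x condition TPM matrix.
#' @param pseudocount epsilon added to numerator and denominator
#'   (default 0.01 TPM; use 0 for the exact published form).
#' @return list of class `relative_profile`: `gene_id`, `median_tpm`,
#'   `tpm` (named numeric), `rel_log2` (named numeric).
#' @examples
#' m <- matrix(c(1, 2, 4, 8), 1, dimnames = list("g", paste0("c", 1:4)))
#' relative_profile("g", m, pseudocount = 0)$rel_log2
#' @export
relative_profile <- function(gene_id, expr, pseudocount = 0.01) {
  if (!gene_id %in% rownames(expr)) stop("unknown gene: ", gene_id)
  stopifnot(pseudocount >= 0)
  v <- expr[gene_id, ]
  med <- stats::median(v)
  structure(list(gene_id = gene_id, median_tpm = med, tpm = v,
                 rel_log2 = log2((v + pseudocount) / (med + pseudocount))),
            class = "relative_profile")
}

#' Export a long-format eFP data table
#'
#' One row per gene x condition with TPM and the relative log2 value of
#' [relative_profile()]. When a pair table and subgenome map are supplied,
#' rows carry `pair_id` and `subgenome`; unpaired or unlabeled genes get
#' `NA`. Subregion and stage columns come from the `conditions` attribute
#' attached by [aggregate_replicates()] (NA otherwise).
#'
#' @param expr gene x condition TPM matrix.
#' @param pairs optional pair table (`pair_id`, `gene_A`, `gene_C`).
#' @param subgenomes optional named `"A"`/`"C"` vector.
#' @param pseudocount epsilon for the relative value (default 0.01).
#' @return data.frame: `gene_id`, `pair_id`, `subgenome`, `condition`,
#'   `subregion`, `stage`, `tpm`, `rel_log2`.
#' @export
export_efp <- function(expr, pairs = NULL, subgenomes = NULL,
                       pseudocount = 0.01) {
  genes <- rownames(expr)
  conds <- colnames(expr)
  med <- apply(expr, 1L, stats::median)
  rel <- log2((expr + pseudocount) / (med + pseudocount))

  pair_of <- rep(NA_character_, length(genes))
  if (!is.null(pairs)) {
    pair_of[match(pairs$gene_A, genes)] <- pairs$pair_id
    pair_of[match(pairs$gene_C, genes)] <- pairs$pair_id
  }
  sub_of <- if (is.null(subgenomes)) rep(NA_character_, length(genes)) else
    unname(subgenomes[genes])

  info <- attr(expr, "conditions")
  if (is.null(info)) {
    info <- data.frame(condition = conds, subregion = NA_character_,
                       stage = NA_character_, stringsAsFactors = FALSE)
  }
  ci <- match(conds, info$condition)
  data.frame(
    gene_id = rep(genes, times = length(conds)),
    pair_id = rep(pair_of, times = length(conds)),
    subgenome = rep(sub_of, times = length(conds)),
    condition = rep(conds, each = length(genes)),
    subregion = rep(info$subregion[ci], each = length(genes)),
    stage = rep(info$stage[ci], each = length(genes)),
    tpm = as.vector(expr),
    rel_log2 = as.vector(rel),
    row.names = NULL, stringsAsFactors = FALSE)
}
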