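#' TPM normalization
#'
#' Transcripts-per-million: for gene g in sample i,
#' \deqn{TPM_{gi} = 10^6 \cdot \frac{c_{gi}/L_g}{\sum_j c_{ji}/L_j}}
#' where `c` are read counts and `L` effective gene lengths in bp. Every
#' column of the result sums to one million (to 1e-6 relative), and the
#' transform is invariant to rescaling a sample's counts.
#'
#' @param counts gene x sample non-negative numeric matrix with rownames.
#' @param lengths named positive numeric vector covering every gene.
#' @return gene x sample TPM matrix.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpm_normalize(m, c(g1 = 1000, g2 = 2000))
#' @export
tpm_normalize <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (is.null(lengths)) stop("gene lengths are required for TPM normalization")
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len) > 0L) {
    stop("missing length for gene(s): ",
         paste(utils::head(missing_len, 10L), collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) stop("all gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Detected genes per sample
#'
#' A gene counts as detected in a sample iff its TPM strictly exceeds the
#' threshold (default 1 TPM; the boundary value itself is not detected).
#'
#' @param tpm gene x sample TPM matrix.
#' @param threshold detection threshold, TPM (>= 0).
#' @return logical gene x sample matrix.
#' @export
detect_genes <- function(tpm, threshold = 1) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  tpm > threshold
}

#' Per-sample subgenome shares of summed TPM
#'
#' @param tpm gene x sample TPM matrix.
#' @param subgenomes named `"A"`/`"C"` vector covering every gene.
#' @return data.frame with `sample_id`, `share_A`, `share_C` (fractions
#'   summing to 1).
#' @export
tpm_share <- function(tpm, subgenomes) {
  lab <- subgenome_of(tpm, subgenomes)
  tot <- colSums(tpm)
  a <- colSums(tpm[lab == "A", , drop = FALSE])
  data.frame(sample_id = colnames(tpm),
             share_A = a / tot,
             share_C = 1 - a / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subgenome composition of the top-N expressed genes
#'
#' Genes are ranked per sample by TPM descending (ties broken by
#' lexicographic gene id, so results are deterministic); the fraction of
#' the top `n` belonging to each subgenome is reported.
#'
#' @param tpm gene x sample TPM matrix.
#' @param subgenomes named `"A"`/`"C"` vector.
#' @param n_list integer vector of list lengths (default 500/1000/1500/5000).
#' @return long data.frame: `sample_id`, `n`, `frac_A`, `frac_C`.
#' @export
top_n_composition <- function(tpm, subgenomes, n_list = c(500, 1000, 1500, 5000)) {
  lab <- subgenome_of(tpm, subgenomes)
  if (any(n_list > nrow(tpm))) {
    stop("n (", max(n_list), ") exceeds the number of genes (", nrow(tpm), ")")
  }
  if (any(n_list < 1)) stop("n must be positive")
  res <- lapply(colnames(tpm), function(s) {
    ord <- order(-tpm[, s], rownames(tpm), method = "radix")
    vapply(n_list, function(n) {
      mean(lab[ord[seq_len(n)]] == "A")
    }, numeric(1))
  })
  data.frame(sample_id = rep(colnames(tpm), each = length(n_list)),
             n = rep(as.integer(n_list), times = ncol(tpm)),
             frac_A = unlist(res),
             frac_C = 1 - unlist(res),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-transcriptome subgenome summary
#'
#' For each sample (and, when metadata are given, additionally for each
#' replicate-mean condition profile): the number of detected genes per
#' subgenome, the summed-TPM shares, and the top-N compositions. Shares are
#' also reported as percentages rounded to one decimal, the form used in
#' output tables.
#'
#' @param tpm gene x sample TPM matrix.
#' @param subgenomes named `"A"`/`"C"` vector.
#' @param meta optional sample metadata (see [read_metadata()]); adds
#'   condition-level rows computed on replicate-mean TPM.
#' @param n_list top-N list lengths; entries exceeding the gene count are
#'   dropped with a message.
#' @param detect_threshold TPM detection threshold (strict `>`).
#' @return data.frame, one row per sample/condition with `level` flagging
#'   `"sample"` or `"condition"` rows.
#' @export
subgenome_summary <- function(tpm, subgenomes, meta = NULL,
                              n_list = c(500, 1000, 1500, 5000),
                              detect_threshold = 1) {
  n_list <- n_list[n_list <= nrow(tpm)]
  one <- function(mat, level) {
    lab <- subgenome_of(mat, subgenomes)
    det <- detect_genes(mat, detect_threshold)
    share <- tpm_share(mat, subgenomes)
    out <- data.frame(
      sample_id = colnames(mat), level = level,
      detected_A = colSums(det[lab == "A", , drop = FALSE]),
      detected_C = colSums(det[lab == "C", , drop = FALSE]),
      tpm_share_A = share$share_A, tpm_share_C = share$share_C,
      pct_A = round(100 * share$share_A, 1),
      pct_C = round(100 * share$share_C, 1),
      row.names = NULL, stringsAsFactors = FALSE)
    if (length(n_list) > 0L) {
      top <- top_n_composition(mat, subgenomes, n_list)
      for (n in n_list) {
        sub <- top[top$n == n, ]
        out[[paste0("top", n, "_frac_A")]] <-
          sub$frac_A[match(out$sample_id, sub$sample_id)]
        out[[paste0("top", n, "_frac_C")]] <-
          sub$frac_C[match(out$sample_id, sub$sample_id)]
      }
    }
    out
  }
  res <- one(tpm, "sample")
  if (!is.null(meta)) {
    cond <- aggregate_replicates(tpm, meta)
    res <- rbind(res, one(cond, "condition"))
  }
  rownames(res) <- NULL
  res
}

# -- internal ---------------------------------------------------------------

subgenome_of <- function(tpm, subgenomes) {
  lab <- subgenomes[rownames(tpm)]
  if (anyNA(lab)) {
    stop("gene(s) without a subgenome label, e.g. ",
         rownames(tpm)[which(is.na(lab))[1L]])
  }
  unname(lab)
}
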