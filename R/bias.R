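#' Bias classification thresholds
#'
#' Defaults follow the strong/low convention used for homoeolog bias
#' heat maps: strong bias at |log2(A/C)| >= 2 (a four-fold difference),
#' low bias at |log2(A/C)| <= 0.1, a 0.01-TPM pseudocount on both sides of
#' the ratio, and a 1-TPM detection threshold defining the pair universe.
#'
#' @param strong strong-bias boundary on the log2 scale (> low).
#' @param low low-bias boundary on the log2 scale (> 0).
#' @param pseudocount TPM added to numerator and denominator (> 0).
#' @param detect_threshold a pair enters a condition's universe iff
#'   `max(TPM_A, TPM_C)` strictly exceeds this value.
#' @return object of class `bias_thresholds`.
#' @export
bias_thresholds <- function(strong = 2, low = 0.1, pseudocount = 0.01,
                            detect_threshold = 1) {
  stopifnot(is.numeric(strong), is.numeric(low), strong > low, low > 0,
            pseudocount > 0, detect_threshold >= 0)
  structure(list(strong = strong, low = low, pseudocount = pseudocount,
                 detect_threshold = detect_threshold),
            class = "bias_thresholds")
}

#' Average replicate samples into condition profiles
#'
#' Condition TPM is the gene-wise arithmetic mean over the replicates of
#' each (subregion, stage). Condition labels follow the stage-prefix
#' convention (`ov`, `g`, `h`, `mg` + subregion, e.g. `ovCPT`); unknown
#' stages fall back to `tolower(stage)` + subregion.
#'
#' @param tpm gene x sample TPM matrix.
#' @param meta sample metadata with `sample_id`, `subregion`, `stage`,
#'   `replicate` covering every column of `tpm`.
#' @return gene x condition matrix with a `conditions` attribute
#'   (data.frame: `condition`, `subregion`, `stage`, `n_replicates`).
#' @export
aggregate_replicates <- function(tpm, meta) {
  missing <- setdiff(colnames(tpm), meta$sample_id)
  if (length(missing) > 0L) {
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(tpm), meta$sample_id), ]
  cond <- condition_label(meta$stage, meta$subregion)
  info <- unique(data.frame(condition = cond, subregion = meta$subregion,
                            stage = meta$stage, stringsAsFactors = FALSE))
  stage_rank <- match(info$stage, c("OV", "GLOB", "HEART", "MG"))
  stage_rank[is.na(stage_rank)] <- 99L
  info <- info[order(stage_rank, info$subregion), ]
  out <- vapply(info$condition, function(cl) {
    cols <- which(cond == cl)
    if (length(cols) == 0L) stop("condition with zero samples: ", cl)
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  info$n_replicates <- vapply(info$condition,
                              function(cl) sum(cond == cl), integer(1))
  rownames(info) <- NULL
  structure(out, conditions = info)
}

#' @rdname aggregate_replicates
#' @param stage,subregion character vectors.
#' @export
condition_label <- function(stage, subregion) {
  prefix <- c(OV = "ov", GLOB = "g", HEART = "h", MG = "mg")[stage]
  prefix[is.na(prefix)] <- tolower(stage[is.na(prefix)])
  paste0(prefix, subregion)
}

#' Per-pair log2(A/C) homoeolog bias matrix
#'
#' The core statistic: for each homoeolog pair and condition,
#' \deqn{v = \log_2\frac{TPM_A + \epsilon}{TPM_C + \epsilon}}
#' with pseudocount \eqn{\epsilon} from `thresholds`. A cell is
#' `UNDETECTED` when neither homoeolog exceeds the detection threshold
#' (`max(TPM_A, TPM_C) <= detect_threshold`); undetected values are stored
#' as `NA` and excluded from tallies and clustering. Remaining cells are
#' classified by [classify_bias()].
#'
#' Pairs with either member absent from the matrix are dropped (counted in
#' a message), per the documented unmatched-annotation policy.
#'
#' @param expr gene x condition (or gene x sample) TPM matrix.
#' @param pairs pair table (`pair_id`, `gene_A`, `gene_C`).
#' @param thresholds a [bias_thresholds()] object.
#' @return object of class `bias_matrix`: list with `values` and `classes`
#'   (pair x condition matrices), `pairs`, `thresholds`, `n_dropped`, and
#'   the condition info carried over from [aggregate_replicates()] (if any).
#' @examples
#' expr <- matrix(c(40, 10), 1, 2, dimnames = list("gA", c("c1", "c2")))
#' expr <- rbind(expr, gC = c(10, 40))
#' pb <- pair_bias(expr, data.frame(pair_id = "p1", gene_A = "gA", gene_C = "gC"))
#' pb$values
#' @export
pair_bias <- function(expr, pairs, thresholds = bias_thresholds()) {
  stopifnot(inherits(thresholds, "bias_thresholds"))
  present <- pairs$gene_A %in% rownames(expr) & pairs$gene_C %in% rownames(expr)
  n_dropped <- sum(!present)
  if (n_dropped > 0L) {
    message(n_dropped, " pair(s) with member(s) absent from the matrix ",
            "excluded from the bias universe")
  }
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no pair has both members in the matrix")
  A <- expr[pairs$gene_A, , drop = FALSE]
  C <- expr[pairs$gene_C, , drop = FALSE]
  eps <- thresholds$pseudocount
  detected <- pmax(A, C) > thresholds$detect_threshold
  values <- log2((A + eps) / (C + eps))
  values[!detected] <- NA_real_
  classes <- matrix(classify_bias(values, thresholds),
                    nrow = nrow(values), ncol = ncol(values))
  classes[!detected] <- "UNDETECTED"
  dimnames(values) <- dimnames(classes) <- list(pairs$pair_id, colnames(expr))
  structure(list(values = values, classes = classes, pairs = pairs,
                 thresholds = thresholds, n_dropped = n_dropped,
                 conditions = attr(expr, "conditions")),
            class = "bias_matrix")
}

#' @export
print.bias_matrix <- function(x, ...) {
  cat("bias_matrix:", nrow(x$values), "pairs x", ncol(x$values),
      "conditions\n")
  tab <- table(factor(x$classes, levels = bias_classes()))
  print(tab)
  invisible(x)
}

bias_classes <- function() {
  c("A_BIAS", "C_BIAS", "LOW_BIAS", "INTERMEDIATE", "UNDETECTED")
}

#' Classify log2(A/C) bias values
#'
#' Inclusive boundaries: `A_BIAS` iff v >= strong; `C_BIAS` iff
#' v <= -strong; `LOW_BIAS` iff -low <= v <= low; everything else in
#' between is `INTERMEDIATE`. Every finite value receives exactly one
#' class; non-finite values yield `NA`.
#'
#' @param values numeric vector or matrix of log2 ratios.
#' @param thresholds a [bias_thresholds()] object.
#' @return character vector of class labels (same length as `values`).
#' @export
classify_bias <- function(values, thresholds = bias_thresholds()) {
  v <- as.numeric(values)
  out <- rep(NA_character_, length(v))
  fin <- is.finite(v)
  out[fin & v >= thresholds$strong] <- "A_BIAS"
  out[fin & v <= -thresholds$strong] <- "C_BIAS"
  low <- fin & abs(v) <= thresholds$low
  out[low] <- "LOW_BIAS"
  out[fin & is.na(out)] <- "INTERMEDIATE"
  out
}

#' Per-condition bias class tallies
#'
#' Counts of each class among the pairs in each condition's universe
#' (cells not `UNDETECTED`), plus percentages of strongly biased
#' (`A_BIAS` + `C_BIAS`) and low-bias pairs. The four class counts always
#' sum to `n_universe`; percentages are `NA` when the universe is empty.
#'
#' @param bias a `bias_matrix`.
#' @return data.frame, one row per condition.
#' @export
bias_tally <- function(bias) {
  stopifnot(inherits(bias, "bias_matrix"))
  conds <- colnames(bias$classes)
  rows <- lapply(conds, function(cl) {
    cls <- bias$classes[, cl]
    n <- c(A_BIAS = sum(cls == "A_BIAS"), C_BIAS = sum(cls == "C_BIAS"),
           LOW_BIAS = sum(cls == "LOW_BIAS"),
           INTERMEDIATE = sum(cls == "INTERMEDIATE"))
    universe <- sum(n)
    data.frame(condition = cl,
               n_A_bias = n[["A_BIAS"]], n_C_bias = n[["C_BIAS"]],
               n_low_bias = n[["LOW_BIAS"]],
               n_intermediate = n[["INTERMEDIATE"]],
               n_universe = universe,
               pct_strong = if (universe > 0)
                 round(100 * (n[["A_BIAS"]] + n[["C_BIAS"]]) / universe, 1)
               else NA_real_,
               pct_low = if (universe > 0)
                 round(100 * n[["LOW_BIAS"]] / universe, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bias values and classes for a named pair subset
#'
#' Long-format report of log2(A/C) values and class labels for selected
#' pairs (e.g. a storage-protein gene family) across all conditions.
#'
#' @param bias a `bias_matrix`.
#' @param pair_ids character vector of pair ids (must all exist).
#' @return data.frame: `pair_id`, `gene_A`, `gene_C`, `condition`,
#'   `log2_ratio`, `class`.
#' @export
flag_gene_family <- function(bias, pair_ids) {
  stopifnot(inherits(bias, "bias_matrix"))
  unknown <- setdiff(pair_ids, rownames(bias$values))
  if (length(unknown) > 0L) {
    stop("unknown pair_id(s): ", paste(unknown, collapse = ", "))
  }
  conds <- colnames(bias$values)
  idx <- match(pair_ids, bias$pairs$pair_id)
  data.frame(
    pair_id = rep(pair_ids, times = length(conds)),
    gene_A = rep(bias$pairs$gene_A[idx], times = length(conds)),
    gene_C = rep(bias$pairs$gene_C[idx], times = length(conds)),
    condition = rep(conds, each = length(pair_ids)),
    log2_ratio = as.vector(bias$values[pair_ids, conds, drop = FALSE]),
    class = as.vector(bias$classes[pair_ids, conds, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict a bias matrix to a condition subset
#'
#' @param bias a `bias_matrix`.
#' @param conditions condition labels to keep (must exist).
#' @return a `bias_matrix` over the selected columns.
#' @export
subset_bias <- function(bias, conditions) {
  stopifnot(inherits(bias, "bias_matrix"))
  unknown <- setdiff(conditions, colnames(bias$values))
  if (length(unknown) > 0L) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  }
  bias$values <- bias$values[, conditions, drop = FALSE]
  bias$classes <- bias$classes[, conditions, drop = FALSE]
  if (!is.null(bias$conditions)) {
    bias$conditions <- bias$conditions[bias$conditions$condition %in% conditions, ]
  }
  bias
}
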