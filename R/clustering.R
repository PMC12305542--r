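#' Clustering configuration
#'
#' Euclidean distance with complete linkage by default; `average` and
#' `ward` (ward.D2) are available. `k_top` is the number of top-level
#' groups, `k_sub` a named list mapping top-level cluster labels to
#' sub-cluster counts, and `min_cluster_size` the reporting cutoff
#' (clusters with fewer members are kept but flagged out of reports).
#'
#' @param distance distance metric; only `"euclidean"` is supported.
#' @param linkage one of `"complete"`, `"average"`, `"ward"`.
#' @param k_top positive integer >= 2.
#' @param k_sub named list, e.g. `list("1" = 5, "2" = 6)`.
#' @param min_cluster_size reporting cutoff (default 60).
#' @return object of class `clustering_config`.
#' @export
clustering_config <- function(distance = "euclidean", linkage = "complete",
                              k_top = 9, k_sub = list(),
                              min_cluster_size = 60) {
  distance <- match.arg(distance, "euclidean")
  linkage <- match.arg(linkage, c("complete", "average", "ward"))
  stopifnot(k_top >= 2, min_cluster_size >= 0)
  if (length(k_sub) > 0L && is.null(names(k_sub))) {
    stop("k_sub must be a named list of cluster -> k")
  }
  structure(list(distance = distance, linkage = linkage, k_top = k_top,
                 k_sub = k_sub, min_cluster_size = min_cluster_size),
            class = "clustering_config")
}

hclust_method <- function(linkage) {
  c(complete = "complete", average = "average", ward = "ward.D2")[[linkage]]
}

# Complete-case rows: any UNDETECTED (NA) cell excludes the pair from the
# Euclidean distance computation (logged via message).
complete_bias_rows <- function(bias) {
  keep <- rowSums(!is.finite(bias$values)) == 0L
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with undetected cells excluded from clustering")
  }
  bias$values[keep, , drop = FALSE]
}

#' Agglomerative dendrogram over conditions
#'
#' Clusters the condition columns of a bias matrix (Euclidean distance on
#' complete-case pair rows, configurable linkage) and returns the tree.
#'
#' @param bias a `bias_matrix`.
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return `hclust` object; leaf order is in `$order`/`$labels`.
#' @export
condition_dendrogram <- function(bias, linkage = "complete") {
  vals <- complete_bias_rows(bias)
  if (ncol(vals) < 2L) stop("need >= 2 conditions to build a dendrogram")
  if (nrow(vals) == 0L) stop("no complete-case pairs available")
  stats::hclust(stats::dist(t(vals), method = "euclidean"),
                method = hclust_method(linkage))
}

#' Write a dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path output path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cut the pair dendrogram into k top-level clusters
#'
#' Rows with any undetected cell are excluded (complete-case). Cluster
#' labels are re-assigned by decreasing cluster size (ties broken by the
#' original dendrogram label), 1-based, for stable reporting.
#'
#' @param bias a `bias_matrix`.
#' @param k number of clusters (2 <= k <= number of complete rows, or 1).
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return data.frame of class `cluster_assignment`: `pair_id`,
#'   `top_cluster`, `sub_cluster` (`NA` until [subcluster()]),
#'   `included_in_report` (all `TRUE` until [filter_small()]).
#' @export
kcut_rows <- function(bias, k, linkage = "complete") {
  vals <- complete_bias_rows(bias)
  if (k > nrow(vals)) {
    stop("k (", k, ") exceeds the number of complete-case pairs (",
         nrow(vals), ")")
  }
  hc <- stats::hclust(stats::dist(vals, method = "euclidean"),
                      method = hclust_method(linkage))
  raw <- stats::cutree(hc, k = k)
  out <- data.frame(pair_id = rownames(vals),
                    top_cluster = relabel_by_size(raw),
                    sub_cluster = NA_integer_,
                    included_in_report = TRUE,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  attr(out, "linkage") <- linkage
  out
}

#' Recursively sub-cluster selected top-level clusters
#'
#' Each targeted cluster's rows are re-clustered independently with the
#' same distance/linkage; untouched clusters keep `sub_cluster = NA`.
#' Sub-labels are again size-ordered within their parent. A targeted
#' cluster whose rows are all identical is split arbitrarily and flagged
#' with a warning (degenerate input).
#'
#' @param bias a `bias_matrix`.
#' @param assignment result of [kcut_rows()].
#' @param k_sub named list mapping top-cluster label to its k, e.g.
#'   `list("1" = 5, "2" = 6)`.
#' @return updated `cluster_assignment`.
#' @export
subcluster <- function(bias, assignment, k_sub) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  linkage <- attr(assignment, "linkage") %||% "complete"
  for (cl in names(k_sub)) {
    k <- k_sub[[cl]]
    idx <- which(assignment$top_cluster == as.integer(cl))
    if (length(idx) == 0L) stop("no such top-level cluster: ", cl)
    if (k > length(idx)) {
      stop("k_sub (", k, ") exceeds the size of cluster ", cl,
           " (", length(idx), ")")
    }
    vals <- bias$values[assignment$pair_id[idx], , drop = FALSE]
    if (k == 1L) {
      assignment$sub_cluster[idx] <- 1L
      next
    }
    d <- stats::dist(vals, method = "euclidean")
    if (max(d) == 0) {
      warning("cluster ", cl, " has identical rows; sub-split is degenerate")
    }
    hc <- stats::hclust(d, method = hclust_method(linkage))
    assignment$sub_cluster[idx] <- relabel_by_size(stats::cutree(hc, k = k))
  }
  assignment
}

#' Flag clusters below the reporting size cutoff
#'
#' Reporting units are sub-clusters where assigned, otherwise top-level
#' clusters. Units with fewer than `min_size` members get
#' `included_in_report = FALSE`; membership itself is never deleted.
#'
#' @param assignment a `cluster_assignment`.
#' @param min_size strict cutoff ("fewer than"; default 60, so size 60 is
#'   included and size 59 is not).
#' @return updated `cluster_assignment`.
#' @export
filter_small <- function(assignment, min_size = 60) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  unit <- ifelse(is.na(assignment$sub_cluster),
                 paste0("t", assignment$top_cluster),
                 paste0("t", assignment$top_cluster, ".s", assignment$sub_cluster))
  sizes <- table(unit)
  assignment$included_in_report <- as.vector(sizes[unit] >= min_size)
  assignment
}

#' Tabulate cluster sizes
#'
#' @param assignment a `cluster_assignment`.
#' @return data.frame: `top_cluster`, `sub_cluster`, `size`,
#'   `included_in_report`.
#' @export
cluster_sizes <- function(assignment) {
  key <- paste(assignment$top_cluster, assignment$sub_cluster, sep = "\r")
  agg <- !duplicated(key)
  out <- data.frame(top_cluster = assignment$top_cluster[agg],
                    sub_cluster = assignment$sub_cluster[agg],
                    size = as.vector(table(key)[key[agg]]),
                    included_in_report = assignment$included_in_report[agg],
                    stringsAsFactors = FALSE)
  out[order(out$top_cluster, out$sub_cluster, na.last = FALSE), , drop = FALSE]
}

# -- internal ---------------------------------------------------------------

# 1-based labels by decreasing cluster size; ties by original label.
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  unname(map[as.character(labels)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
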