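#' Read a gene-by-sample expression table
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Works for raw counts and for
#' precomputed TPM alike. Per-gene effective lengths (in bp), needed for TPM
#' normalization, may be supplied either as a column of the same file (named
#' `length_col`) or as a separate two-column file (`lengths_path`).
#'
#' The delimiter is auto-detected between TAB and comma; pass `delimiter`
#' to override. Parsing is locale-independent (decimal point, never comma).
#'
#' @param path file path.
#' @param delimiter optional explicit field separator (`"\t"` or `","`).
#' @param length_col name of an optional in-file length column (default
#'   `"length"`); it is removed from the returned matrix.
#' @param lengths_path optional two-column (gene, length) side file.
#' @return list with `counts` (numeric matrix, genes x samples) and `lengths`
#'   (named numeric vector, or `NULL` when no lengths were supplied).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tlength\ts1\ts2", "g1\t1000\t10\t0", "g2\t2000\t10\t5"), f)
#' x <- read_counts(f)
#' dim(x$counts)
#' @export
read_counts <- function(path, delimiter = NULL, length_col = "length",
                        lengths_path = NULL) {
  df <- read_delim_auto(path, delimiter)
  if (ncol(df) < 2L) {
    stop("expression table '", path, "' needs a gene column plus >=1 sample column")
  }
  gene_ids <- df[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0L) {
    stop("duplicated gene ID(s) in '", path, "': ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]

  lengths <- NULL
  if (length_col %in% colnames(body)) {
    lengths <- as_numeric_checked(body[[length_col]], gene_ids, length_col, path)
    names(lengths) <- gene_ids
    body <- body[, setdiff(colnames(body), length_col), drop = FALSE]
  }
  if (!is.null(lengths_path)) {
    ldf <- read_delim_auto(lengths_path, delimiter)
    lengths <- as_numeric_checked(ldf[[2L]], ldf[[1L]], colnames(ldf)[2L], lengths_path)
    names(lengths) <- ldf[[1L]]
  }

  mat <- matrix(NA_real_, nrow = length(gene_ids), ncol = ncol(body),
                dimnames = list(gene_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    mat[, j] <- as_numeric_checked(body[[j]], gene_ids, colnames(body)[j], path)
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("negative value at gene '", rownames(mat)[neg[1L, 1L]],
         "', sample '", colnames(mat)[neg[1L, 2L]], "' in '", path, "'")
  }
  list(counts = mat, lengths = lengths)
}

#' Read a gene-to-subgenome assignment table
#'
#' Two-column delimited text (gene id, subgenome label). Labels must be
#' `"A"` or `"C"`.
#'
#' @param path file path.
#' @param delimiter optional explicit separator.
#' @return named character vector of `"A"`/`"C"` labels.
#' @export
read_subgenomes <- function(path, delimiter = NULL) {
  df <- read_delim_auto(path, delimiter)
  if (ncol(df) < 2L) stop("subgenome table '", path, "' needs two columns")
  labels <- toupper(trimws(df[[2L]]))
  bad <- !labels %in% c("A", "C")
  if (any(bad)) {
    stop("invalid subgenome label(s) in '", path, "': ",
         paste(unique(utils::head(df[[2L]][bad], 5L)), collapse = ", "),
         " (expected A or C)")
  }
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(dup) > 0L) {
    stop("gene(s) with multiple subgenome labels: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  stats::setNames(labels, df[[1L]])
}

#' Read and validate a homoeolog-pair table
#'
#' Accepts two-column (gene_A, gene_C) or three-column (pair_id, gene_A,
#' gene_C) delimited text. Every pair is checked against the subgenome map:
#' pairs whose members share a subgenome are rejected; pairs listed in
#' C-then-A order are swapped (with a warning) so that `gene_A` always
#' carries the A label. Genes appearing in more than one pair are rejected
#' unless `allow_multi = TRUE`.
#'
#' @param path file path.
#' @param subgenomes named `"A"`/`"C"` vector as from [read_subgenomes()].
#' @param delimiter optional explicit separator.
#' @param allow_multi allow a gene to appear in multiple pairs.
#' @param gene_universe optional character vector (e.g. matrix rownames);
#'   pairs with members outside it are kept but counted in a warning. They
#'   are excluded from the bias universe later, by [pair_bias()].
#' @return data.frame with columns `pair_id`, `gene_A`, `gene_C`.
#' @export
read_pairs <- function(path, subgenomes, delimiter = NULL, allow_multi = FALSE,
                       gene_universe = NULL) {
  df <- read_delim_auto(path, delimiter)
  if (ncol(df) == 2L) {
    pairs <- data.frame(pair_id = sprintf("pair_%05d", seq_len(nrow(df))),
                        gene_A = df[[1L]], gene_C = df[[2L]],
                        stringsAsFactors = FALSE)
  } else if (ncol(df) >= 3L) {
    pairs <- data.frame(pair_id = df[[1L]], gene_A = df[[2L]], gene_C = df[[3L]],
                        stringsAsFactors = FALSE)
  } else {
    stop("pair table '", path, "' needs 2 or 3 columns")
  }
  validate_pairs(pairs, subgenomes, allow_multi = allow_multi,
                 gene_universe = gene_universe)
}

#' @rdname read_pairs
#' @param pairs a data.frame with columns `pair_id`, `gene_A`, `gene_C`
#'   (validated in place; used by [read_pairs()] and by callers holding
#'   in-memory pair tables).
#' @export
validate_pairs <- function(pairs, subgenomes, allow_multi = FALSE,
                           gene_universe = NULL) {
  stopifnot(all(c("pair_id", "gene_A", "gene_C") %in% colnames(pairs)))
  if (anyDuplicated(pairs$pair_id)) {
    stop("duplicated pair_id(s): ",
         paste(utils::head(unique(pairs$pair_id[duplicated(pairs$pair_id)]), 5L),
               collapse = ", "))
  }
  same <- pairs$gene_A == pairs$gene_C
  if (any(same)) {
    stop("pair(s) with identical members: ",
         paste(utils::head(pairs$pair_id[same], 5L), collapse = ", "))
  }
  lab_A <- unname(subgenomes[pairs$gene_A])
  lab_C <- unname(subgenomes[pairs$gene_C])
  unknown <- is.na(lab_A) | is.na(lab_C)
  if (any(unknown)) {
    stop("pair member(s) missing from the subgenome map, e.g. pair ",
         pairs$pair_id[which(unknown)[1L]])
  }
  shared <- lab_A == lab_C
  if (any(shared)) {
    stop("pair(s) whose members share a subgenome (same subgenome): ",
         paste(utils::head(pairs$pair_id[shared], 5L), collapse = ", "))
  }
  swapped <- lab_A == "C"
  if (any(swapped)) {
    warning(sum(swapped), " pair(s) listed C-then-A were swapped to A-then-C")
    tmp <- pairs$gene_A[swapped]
    pairs$gene_A[swapped] <- pairs$gene_C[swapped]
    pairs$gene_C[swapped] <- tmp
  }
  if (!allow_multi) {
    genes <- c(pairs$gene_A, pairs$gene_C)
    dup <- unique(genes[duplicated(genes)])
    if (length(dup) > 0L) {
      stop("gene(s) appearing in multiple pairs (set allow_multi = TRUE to keep): ",
           paste(utils::head(dup, 10L), collapse = ", "))
    }
  }
  if (!is.null(gene_universe)) {
    absent <- !(pairs$gene_A %in% gene_universe & pairs$gene_C %in% gene_universe)
    if (any(absent)) {
      warning(sum(absent), " pair(s) reference gene(s) absent from the ",
              "expression matrix; they are excluded from the bias universe")
    }
  }
  rownames(pairs) <- NULL
  pairs
}

#' Read GMT-style annotation sets
#'
#' Standard GMT dialect: `term_id TAB term_name TAB gene1 TAB gene2 ...`.
#' Duplicate term ids are merged by union (with a warning); an empty file
#' yields an empty collection (with a warning).
#'
#' @param path file path.
#' @return named list of unique gene-id vectors, one per term, with a
#'   `term_names` attribute (named character vector of display names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("GMT file '", path, "' is empty")
    return(structure(list(), term_names = character(0)))
  }
  sets <- list()
  term_names <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i, " of '", path,
           "': fewer than 3 tab-separated fields")
    }
    id <- fields[1L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop("GMT parse error at line ", i, " of '", path, "': empty gene set")
    }
    if (id %in% names(sets)) {
      warning("duplicate term id '", id, "' in '", path, "': sets merged by union")
      sets[[id]] <- unique(c(sets[[id]], genes))
    } else {
      sets[[id]] <- genes
      term_names[id] <- fields[2L]
    }
  }
  structure(sets, term_names = term_names)
}

#' Read sample metadata
#'
#' Delimited text with header `sample_id,subregion,stage,replicate`.
#' `(subregion, stage, replicate)` triples must be unique.
#'
#' @param path file path.
#' @param delimiter optional explicit separator.
#' @return data.frame with the four columns above.
#' @export
read_metadata <- function(path, delimiter = NULL) {
  df <- read_delim_auto(path, delimiter)
  need <- c("sample_id", "subregion", "stage", "replicate")
  if (!all(need %in% colnames(df))) {
    stop("metadata '", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$replicate <- as_numeric_checked(df$replicate, df$sample_id, "replicate", path)
  if (any(df$replicate <= 0 | df$replicate != round(df$replicate))) {
    stop("replicate numbers must be positive integers in '", path, "'")
  }
  key <- paste(df$subregion, df$stage, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (subregion, stage, replicate) triple(s) in '", path, "'")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id(s) in '", path, "'")
  df
}

#' Write a matrix or data.frame as TSV
#'
#' Numeric values are written with 15 significant digits so a write/read
#' round trip is bit-exact for integers and accurate to >=12 significant
#' digits for reals.
#'
#' @param x matrix (rownames become the first column) or data.frame.
#' @param path output path.
#' @param id_col name of the identifier column used for matrix rownames.
#' @export
write_tsv <- function(x, path, id_col = "gene_id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_col
    x <- df
  }
  old <- options(digits = 15, scipen = 0)
  on.exit(options(old))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Captures the package version, seed, configuration snapshot, input-file
#' MD5 checksums and per-stage row counts, so a run can be reproduced and
#' audited.
#'
#' @param path output path (JSON).
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (checksummed).
#' @param seed integer seed used for any randomness (or `NA`).
#' @param stage_rows named list/vector of per-stage row counts.
#' @export
write_manifest <- function(path, config = list(), inputs = character(0),
                           seed = NA_integer_, stage_rows = list()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "homeobias",
    version = as.character(utils::packageVersion("homeobias")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stage_rows = stage_rows
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# -- internal ---------------------------------------------------------------

# TAB/comma auto-detection on the header line; explicit delimiter wins.
read_delim_auto <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  utils::read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "\"", comment.char = "", strip.white = TRUE)
}

# Converts character to numeric; on failure names the offending row/column.
as_numeric_checked <- function(x, row_ids, col_id, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & !(x %in% c("NA", "")))
  if (length(bad) > 0L) {
    stop("non-numeric value '", x[bad[1L]], "' at row '", row_ids[bad[1L]],
         "', column '", col_id, "' in '", path, "'")
  }
  out
}
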