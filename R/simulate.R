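#' Simulation configuration
#'
#' Defines the synthetic homoeolog expression dataset the package is tested
#' against: a multi-subregion x multi-stage dissection design with
#' replicates, a global C-subgenome expression share, discrete per-pair
#' bias classes, and a mature-embryo transcriptome contraction in which a
#' handful of storage genes absorb most of the transcript pool.
#'
#' Defaults: 2,000 homoeolog pairs plus 500 unpaired genes per subgenome
#' (5,000 genes), 26 conditions (seed-coat subregions ISC/OSC/CZSC/CPT at
#' OV/GLOB/HEART/MG, endosperm/embryo subregions MCE/PEN/CZE/EP at
#' GLOB/HEART, and COT/ROOT at MG), 3 replicates, C share 0.55, class
#' probabilities A 0.05 / C 0.065 / low 0.08 / intermediate 0.805 (11.5%
#' strongly biased), strong effect 3 on the log2 scale, negative-binomial
#' dispersion 0.02 and 5e6 expected counts per library.
#'
#' @param n_pairs number of homoeolog pairs.
#' @param n_singletons_A,n_singletons_C unpaired genes per subgenome.
#' @param conditions data.frame with `subregion` and `stage`.
#' @param replicates replicates per condition.
#' @param global_c_share expected C fraction of total expression.
#' @param class_probs named probabilities for `A_BIAS`, `C_BIAS`,
#'   `LOW_BIAS`, `INTERMEDIATE` (sum to 1).
#' @param strong_effect_log2 mean |log2 ratio| of the strong classes
#'   (>= 2).
#' @param strong_effect_sd spread of the strong-class log2 ratios.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (var = mu + phi mu^2).
#' @param library_size expected total counts per sample.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of per-pair
#'   expression on the TPM scale.
#' @param condition_sdlog log-normal spread of gene-level condition
#'   effects.
#' @param mature_embryo list with `fraction_expressed`,
#'   `storage_gene_count`, `storage_share` controlling the mature-embryo
#'   contraction.
#' @param mature_embryo_subregions subregions (at stage MG) subject to the
#'   contraction.
#' @param condition_switches optional list of
#'   `list(pairs =, conditions =, class =)` overrides planting
#'   condition-specific bias classes.
#' @param n_background_terms random annotation terms in the generated GMT.
#' @param seed integer seed governing all draws.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 2000,
                              n_singletons_A = 500,
                              n_singletons_C = 500,
                              conditions = default_conditions(),
                              replicates = 3,
                              global_c_share = 0.55,
                              class_probs = c(A_BIAS = 0.05, C_BIAS = 0.065,
                                              LOW_BIAS = 0.08,
                                              INTERMEDIATE = 0.805),
                              strong_effect_log2 = 3,
                              strong_effect_sd = 0.3,
                              nb_dispersion = 0.02,
                              library_size = 5e6,
                              baseline_meanlog = log(20),
                              baseline_sdlog = 1.2,
                              condition_sdlog = 0.2,
                              mature_embryo = list(fraction_expressed = 0.3,
                                                   storage_gene_count = 20,
                                                   storage_share = 0.6),
                              mature_embryo_subregions = c("EP", "COT", "ROOT"),
                              condition_switches = NULL,
                              n_background_terms = 30,
                              seed = 1) {
  stopifnot(n_pairs >= 1, replicates >= 1,
            all(c("subregion", "stage") %in% colnames(conditions)))
  if (!setequal(names(class_probs),
                c("A_BIAS", "C_BIAS", "LOW_BIAS", "INTERMEDIATE"))) {
    stop("class_probs must name A_BIAS, C_BIAS, LOW_BIAS, INTERMEDIATE")
  }
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (any(class_probs < 0 | class_probs > 1)) {
    stop("class_probs must lie in [0, 1]")
  }
  if (global_c_share <= 0 || global_c_share >= 1) {
    stop("global_c_share must lie in (0, 1)")
  }
  if (strong_effect_log2 < 2) stop("strong_effect_log2 must be >= 2")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (mature_embryo$storage_share >= 1 || mature_embryo$storage_share < 0) {
    stop("infeasible config: storage_share must lie in [0, 1)")
  }
  if (mature_embryo$fraction_expressed <= 0 ||
      mature_embryo$fraction_expressed > 1) {
    stop("fraction_expressed must lie in (0, 1]")
  }
  cfg <- list(n_pairs = n_pairs, n_singletons_A = n_singletons_A,
              n_singletons_C = n_singletons_C, conditions = conditions,
              replicates = replicates, global_c_share = global_c_share,
              class_probs = class_probs,
              strong_effect_log2 = strong_effect_log2,
              strong_effect_sd = strong_effect_sd,
              nb_dispersion = nb_dispersion, library_size = library_size,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              condition_sdlog = condition_sdlog,
              mature_embryo = mature_embryo,
              mature_embryo_subregions = mature_embryo_subregions,
              condition_switches = condition_switches,
              n_background_terms = n_background_terms,
              seed = seed)
  structure(cfg, class = "simulation_config")
}

#' Default simulated dissection design
#'
#' @return data.frame of (subregion, stage) combinations: four seed-coat
#'   subregions across all four stages, four endosperm/embryo subregions at
#'   GLOB and HEART, and the two mature-embryo subregions at MG.
#' @export
default_conditions <- function() {
  maternal <- expand.grid(subregion = c("ISC", "OSC", "CZSC", "CPT"),
                          stage = c("OV", "GLOB", "HEART", "MG"),
                          stringsAsFactors = FALSE)
  filial <- expand.grid(subregion = c("MCE", "PEN", "CZE", "EP"),
                        stage = c("GLOB", "HEART"),
                        stringsAsFactors = FALSE)
  embryo <- data.frame(subregion = c("COT", "ROOT"), stage = "MG",
                       stringsAsFactors = FALSE)
  rbind(maternal, filial, embryo)
}

#' Simulate a homoeolog expression dataset with known ground truth
#'
#' Counts are drawn negative-binomially around condition-specific expected
#' expression. Each pair receives a log-normal baseline and a bias class;
#' the A/C split of the pair's total follows the class's log2 ratio
#' (strong classes centred at +/- `strong_effect_log2`, `LOW_BIAS` at 0,
#' `INTERMEDIATE` uniform in +/-(0.1, 2)). Unpaired C-subgenome genes are
#' scaled so the expected global C share matches `global_c_share` without
#' distorting pair ratios. Mature-embryo conditions express only a
#' fraction of genes, with designated storage pairs absorbing a fixed
#' share of the transcript pool. Gene lengths are uniform in 500-5000 bp.
#' All draws come from the seeded generator, so identical configs yield
#' identical outputs.
#'
#' @param config a [simulation_config()].
#' @return list of class `homeobias_sim`: `counts`, `lengths`,
#'   `subgenomes`, `pairs`, `metadata`, `gmt`, `truth`, `config`. `truth`
#'   records per-pair base classes, the per-pair-per-condition class
#'   matrix and log2 ratios, planted cluster labels, per-condition expected
#'   C shares, storage pair ids and planted annotation terms.
#' @export
simulate_homoeologs <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  np <- config$n_pairs
  conds <- condition_label(config$conditions$stage, config$conditions$subregion)
  nc <- length(conds)

  pairs <- data.frame(pair_id = sprintf("pair_%05d", seq_len(np)),
                      gene_A = sprintf("GA%05d", seq_len(np)),
                      gene_C = sprintf("GC%05d", seq_len(np)),
                      stringsAsFactors = FALSE)
  singles_A <- if (config$n_singletons_A > 0)
    sprintf("SA%05d", seq_len(config$n_singletons_A)) else character(0)
  singles_C <- if (config$n_singletons_C > 0)
    sprintf("SC%05d", seq_len(config$n_singletons_C)) else character(0)
  genes <- c(pairs$gene_A, pairs$gene_C, singles_A, singles_C)
  subgenomes <- stats::setNames(
    c(rep("A", np), rep("C", np),
      rep("A", length(singles_A)), rep("C", length(singles_C))), genes)

  # per-pair bias class and log2 ratio; optionally overridden per condition
  base_class <- sample(names(config$class_probs), np, replace = TRUE,
                       prob = config$class_probs)
  draw_d <- function(cls) {
    n <- length(cls)
    d <- numeric(n)
    s <- config$strong_effect_log2
    d[cls == "A_BIAS"] <- stats::rnorm(sum(cls == "A_BIAS"), s,
                                       config$strong_effect_sd)
    d[cls == "C_BIAS"] <- stats::rnorm(sum(cls == "C_BIAS"), -s,
                                       config$strong_effect_sd)
    im <- cls == "INTERMEDIATE"
    d[im] <- sample(c(-1, 1), sum(im), replace = TRUE) *
      stats::runif(sum(im), 0.1, 2)
    d
  }
  base_d <- draw_d(base_class)
  class_mat <- matrix(base_class, np, nc, dimnames = list(pairs$pair_id, conds))
  d_mat <- matrix(base_d, np, nc, dimnames = list(pairs$pair_id, conds))
  for (sw in config$condition_switches) {
    pi <- match(sw$pairs, pairs$pair_id)
    ci <- match(sw$conditions, conds)
    if (anyNA(pi) || anyNA(ci)) stop("condition_switches reference unknown ids")
    class_mat[pi, ci] <- sw$class
    d_mat[pi, ci] <- matrix(draw_d(rep(sw$class, length(pi) * length(ci))),
                            length(pi), length(ci))
  }

  # expected expression on the (relative) TPM scale
  b_pair <- stats::rlnorm(np, config$baseline_meanlog, config$baseline_sdlog)
  noise_pair <- matrix(stats::rlnorm(np * nc, 0, config$condition_sdlog), np, nc)
  total <- b_pair * noise_pair
  w <- 2^d_mat / (1 + 2^d_mat)
  mean_A <- total * w
  mean_C <- total * (1 - w)
  mean_SA <- stats::rlnorm(length(singles_A), config$baseline_meanlog,
                           config$baseline_sdlog) *
    matrix(stats::rlnorm(length(singles_A) * nc, 0, config$condition_sdlog),
           length(singles_A), nc)
  mean_SC <- stats::rlnorm(length(singles_C), config$baseline_meanlog,
                           config$baseline_sdlog) *
    matrix(stats::rlnorm(length(singles_C) * nc, 0, config$condition_sdlog),
           length(singles_C), nc)

  # calibrate unpaired C genes so the expected global C share hits target
  t_share <- config$global_c_share
  A_tot <- sum(mean_A) + sum(mean_SA)
  C_pair <- sum(mean_C)
  C_single <- sum(mean_SC)
  if (C_single <= 0) stop("need C-subgenome singletons to calibrate the C share")
  g <- (t_share * A_tot - (1 - t_share) * C_pair) / ((1 - t_share) * C_single)
  if (g <= 0) {
    stop("infeasible config: cannot reach global_c_share = ", t_share,
         " with these class probabilities and singleton counts")
  }
  mean_SC <- mean_SC * g

  M <- rbind(mean_A, mean_C, mean_SA, mean_SC)
  rownames(M) <- genes
  colnames(M) <- conds

  # mature-embryo contraction: expression masking + storage-gene absorption
  contracted <- which(config$conditions$stage == "MG" &
                        config$conditions$subregion %in%
                        config$mature_embryo_subregions)
  storage_pairs <- character(0)
  if (length(contracted) > 0L) {
    me <- config$mature_embryo
    storage_idx <- sort(sample.int(np, min(me$storage_gene_count, np)))
    storage_pairs <- pairs$pair_id[storage_idx]
    storage_genes <- c(pairs$gene_A[storage_idx], pairs$gene_C[storage_idx])
    for (ci in contracted) {
      expressed <- stats::runif(length(genes)) < me$fraction_expressed
      expressed[match(storage_genes, genes)] <- TRUE
      M[!expressed, ci] <- 0
      s_sum <- sum(M[storage_genes, ci])
      o_sum <- sum(M[, ci]) - s_sum
      if (s_sum > 0 && o_sum > 0 && me$storage_share > 0) {
        M[storage_genes, ci] <- M[storage_genes, ci] *
          (me$storage_share / (1 - me$storage_share)) * (o_sum / s_sum)
      }
    }
  }

  lengths <- stats::setNames(stats::runif(length(genes), 500, 5000), genes)

  metadata <- data.frame(
    sample_id = paste0(rep(conds, each = config$replicates), "_r",
                       rep(seq_len(config$replicates), times = nc)),
    subregion = rep(config$conditions$subregion, each = config$replicates),
    stage = rep(config$conditions$stage, each = config$replicates),
    replicate = rep(seq_len(config$replicates), times = nc),
    stringsAsFactors = FALSE)

  counts <- matrix(0L, length(genes), nrow(metadata),
                   dimnames = list(genes, metadata$sample_id))
  size <- 1 / config$nb_dispersion
  for (j in seq_len(nrow(metadata))) {
    ci <- match(condition_label(metadata$stage[j], metadata$subregion[j]), conds)
    wgt <- M[, ci] * lengths
    mu <- config$library_size * wgt / sum(wgt)
    counts[, j] <- stats::rnbinom(length(genes), mu = mu, size = size)
  }

  gmt <- build_planted_gmt(pairs, base_class, genes, config$n_background_terms)

  condition_c_share <- apply(M, 2L, function(m) {
    sum(m[subgenomes[genes] == "C"]) / sum(m)
  })

  truth <- list(pair_class = stats::setNames(base_class, pairs$pair_id),
                class_matrix = class_mat,
                log2_ratio = d_mat,
                cluster_labels = stats::setNames(base_class, pairs$pair_id),
                condition_c_share = condition_c_share,
                contracted_conditions = conds[contracted],
                storage_pairs = storage_pairs,
                planted_terms = attr(gmt, "planted_terms"))

  structure(list(counts = counts, lengths = lengths, subgenomes = subgenomes,
                 pairs = pairs, metadata = metadata, gmt = gmt,
                 truth = truth, config = config),
            class = "homeobias_sim")
}

# Planted terms cover subsets of same-class pairs (both homoeologs
# annotated), so class-recovering clusters are enriched for them;
# background terms are random gene subsets.
build_planted_gmt <- function(pairs, base_class, genes, n_background) {
  sets <- list()
  term_names <- character(0)
  planted <- character(0)
  for (cls in c("A_BIAS", "C_BIAS", "LOW_BIAS")) {
    members <- which(base_class == cls)
    if (length(members) < 10L) next
    for (j in 1:2) {
      take <- sample(members, max(5L, min(length(members) %/% 2L, 60L)))
      id <- sprintf("PT_%s_%d", substr(cls, 1, 1), j)
      sets[[id]] <- c(pairs$gene_A[take], pairs$gene_C[take])
      term_names[id] <- paste0("planted ", tolower(cls), " set ", j)
      planted[id] <- cls
    }
  }
  for (j in seq_len(n_background)) {
    id <- sprintf("BG_%04d", j)
    sets[[id]] <- sample(genes, sample(20:80, 1L))
    term_names[id] <- paste0("background set ", j)
  }
  structure(sets, term_names = term_names, planted_terms = planted)
}

#' Write a simulated dataset as an on-disk input bundle
#'
#' Emits `counts.tsv` (with a `length` column), `subgenomes.tsv`,
#' `pairs.tsv`, `metadata.tsv`, `annotations.gmt` and `truth_classes.tsv`
#' into `dir`, in the formats the readers in this package expect.
#'
#' @param sim a `homeobias_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "homeobias_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cdf <- data.frame(gene_id = rownames(sim$counts),
                    length = unname(sim$lengths[rownames(sim$counts)]),
                    sim$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(gene_id = names(sim$subgenomes),
                       subgenome = unname(sim$subgenomes),
                       stringsAsFactors = FALSE),
            file.path(dir, "subgenomes.tsv"))
  write_tsv(sim$pairs, file.path(dir, "pairs.tsv"))
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  gmt_lines <- vapply(names(sim$gmt), function(id) {
    paste(c(id, attr(sim$gmt, "term_names")[id], sim$gmt[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, file.path(dir, "annotations.gmt"))
  write_tsv(data.frame(pair_id = names(sim$truth$pair_class),
                       class = unname(sim$truth$pair_class),
                       log2_ratio = unname(rowMeans(sim$truth$log2_ratio)),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_classes.tsv"))
  invisible(dir)
}

#' Ground-truth recovery metrics
#'
#' Compares pipeline outputs against the simulator's recorded truth:
#' a class confusion matrix and per-cell strong-class recall over the
#' detected universe; the pair-level strong-bias fraction estimated from
#' each pair's across-condition median log2 ratio (robust to
#' condition-specific extremes such as the mature-embryo contraction)
#' versus the planted fraction; adjusted Rand index of a cluster
#' assignment against the
#' planted labels; and per-condition C-share errors.
#'
#' @param truth the `truth` element of a `homeobias_sim`.
#' @param bias optional `bias_matrix` computed from the simulated data.
#' @param assignment optional `cluster_assignment`.
#' @param c_share optional named per-condition estimated C shares.
#' @return list with (depending on inputs) `confusion`, `strong_recall`,
#'   `strong_fraction_est`, `strong_fraction_planted`, `ari`,
#'   `c_share_max_error`.
#' @export
recovery_report <- function(truth, bias = NULL, assignment = NULL,
                            c_share = NULL) {
  out <- list()
  if (!is.null(bias)) {
    pids <- rownames(bias$values)
    if (!all(pids %in% rownames(truth$class_matrix))) {
      stop("mismatched pair sets between bias matrix and ground truth")
    }
    conds <- intersect(colnames(bias$values), colnames(truth$class_matrix))
    called <- bias$classes[pids, conds, drop = FALSE]
    planted <- truth$class_matrix[pids, conds, drop = FALSE]
    universe <- called != "UNDETECTED"
    out$confusion <- table(truth = planted[universe],
                           called = called[universe])
    strong <- universe & (planted == "A_BIAS" | planted == "C_BIAS")
    out$strong_recall <- if (any(strong))
      mean(called[strong] == planted[strong]) else NA_real_
    med_ratio <- apply(bias$values[pids, conds, drop = FALSE], 1L,
                       stats::median, na.rm = TRUE)
    est_class <- classify_bias(med_ratio, bias$thresholds)
    out$strong_fraction_est <-
      mean(est_class %in% c("A_BIAS", "C_BIAS"), na.rm = TRUE)
    out$strong_fraction_planted <-
      mean(truth$pair_class[pids] %in% c("A_BIAS", "C_BIAS"))
    out$n_pairs <- length(pids)
  }
  if (!is.null(assignment)) {
    lab <- truth$cluster_labels[assignment$pair_id]
    if (anyNA(lab)) stop("mismatched pair sets between assignment and truth")
    out$ari <- mclust::adjustedRandIndex(assignment$top_cluster, lab)
  }
  if (!is.null(c_share)) {
    conds <- intersect(names(c_share), names(truth$condition_c_share))
    if (length(conds) == 0L) stop("no shared conditions for C-share comparison")
    out$c_share_max_error <-
      max(abs(c_share[conds] - truth$condition_c_share[conds]))
  }
  out
}
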