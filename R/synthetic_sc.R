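#' Configuration for synthetic scRNA-seq UMI counts
#'
#' Defines a negative-binomial count simulator with planted cluster structure:
#' cluster-specific ligand/receptor programs (a gene up-regulated by a fold
#' factor in designated source or target clusters), condition-dependent
#' circadian genes (day/night fold change), mitochondrial genes, and planted
#' low-quality cells (low-UMI, high-mito, doublets) for exercising QC.
#'
#' Counts are drawn gene-by-gene as NB(mean = modulated base mean,
#' size = dispersion), where `size` is the usual R parameterization
#' (variance = mu + mu^2/size). The seed fully determines the output.
#'
#' @param n_clusters number of cell clusters.
#' @param cells_per_cluster cells per cluster (before planted bad cells).
#' @param n_genes number of genes.
#' @param base_mean expected UMI per cell per gene; scalar or length `n_genes`.
#' @param dispersion NB size parameter; scalar (shared across genes) or
#'   length `n_genes`.
#' @param axis_programs list of lists with fields `ligand`, `receptor`
#'   (gene indices or names like "g12"), `source_clusters`, `target_clusters`
#'   (1-based cluster ids), `fold_up` (> 1), and optionally `conditions`
#'   (condition labels in which the program is active; default all).
#' @param circadian_genes list of lists with fields `gene` and `fold` (> 0):
#'   the gene's mean is multiplied by `fold` in the first condition
#'   (circadian day) relative to the others.
#' @param condition_fractions named numeric vector of condition label ->
#'   fraction of cells; must sum to 1.
#' @param mito_gene_indices integer indices of genes renamed with an `mt-`
#'   prefix and counted as mitochondrial.
#' @param mito_base_fraction expected mitochondrial share of a healthy cell's
#'   transcriptome (mito gene means are scaled to this share).
#' @param planted_bad_cells named integer vector with any of `low_umi`,
#'   `high_mito`, `doublet`.
#' @param seed integer seed.
#' @return A list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_clusters = 8,
                          cells_per_cluster = 250,
                          n_genes = 500,
                          base_mean = 1,
                          dispersion = 2,
                          axis_programs = list(),
                          circadian_genes = list(),
                          condition_fractions = c(CT7.5 = 0.5, CT15.5 = 0.5),
                          mito_gene_indices = integer(),
                          mito_base_fraction = 0.05,
                          planted_bad_cells = c(low_umi = 0L, high_mito = 0L,
                                                doublet = 0L),
                          seed = 1L) {
  if (n_clusters < 1 || cells_per_cluster < 1 || n_genes < 1)
    stop("configuration error: dimensions must be positive")
  if (abs(sum(condition_fractions) - 1) > 1e-8)
    stop("condition fractions must sum to 1")
  if (is.null(names(condition_fractions)))
    stop("condition_fractions must be named")
  base_mean <- rep_len(base_mean, n_genes)
  dispersion <- rep_len(dispersion, n_genes)
  if (any(base_mean <= 0) || any(dispersion <= 0))
    stop("base_mean and dispersion must be positive")
  for (p in axis_programs)
    if (is.null(p$fold_up) || p$fold_up <= 0) stop("fold parameters must be > 0")
  for (g in circadian_genes)
    if (is.null(g$fold) || g$fold <= 0) stop("fold parameters must be > 0")
  bad <- c(low_umi = 0L, high_mito = 0L, doublet = 0L)
  bad[names(planted_bad_cells)] <- as.integer(planted_bad_cells)
  structure(list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
                 n_genes = n_genes, base_mean = base_mean,
                 dispersion = dispersion, axis_programs = axis_programs,
                 circadian_genes = circadian_genes,
                 condition_fractions = condition_fractions,
                 mito_gene_indices = as.integer(mito_gene_indices),
                 mito_base_fraction = mito_base_fraction,
                 planted_bad_cells = bad, seed = as.integer(seed)),
            class = "sc_sim_config")
}

.resolve_gene <- function(g, gene_names_) {
  if (is.character(g)) {
    i <- match(g, gene_names_)
    if (is.na(i)) stop("unknown gene in program: ", g)
    return(i)
  }
  as.integer(g)
}

#' Simulate a UMI count matrix with known ground truth
#'
#' Draws NB-distributed UMI counts per the configuration: each cell belongs to
#' a cluster and a condition; axis programs multiply the ligand mean in source
#' clusters and the receptor mean in target clusters by `fold_up`; circadian
#' genes are scaled by `fold` in the first condition. Planted bad cells are
#' appended: low-UMI cells (means scaled to ~2% library size), high-mito cells
#' (~25% expected mitochondrial share) and doublets (sums of two random good
#' cells' counts).
#'
#' @param cfg an [sc_sim_config].
#' @return A list with `matrix` (a [chrono_counts] whose `cell_meta` has
#'   `condition` and `run` columns) and `truth` (a data.frame per cell:
#'   `barcode`, `cluster` (1-based; NA for planted bad cells), `condition`,
#'   `bad_type`), plus `de_genes` (character vector of truly condition-DE
#'   genes), `mean_matrix` (gene x cluster matrix of day-condition expected
#'   means) and `mito_genes`.
#' @export
simulate_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_names_ <- sprintf("g%04d", seq_len(G))
  if (length(cfg$mito_gene_indices))
    gene_names_[cfg$mito_gene_indices] <-
      sprintf("mt-%04d", cfg$mito_gene_indices)

  n_cells <- cfg$n_clusters * cfg$cells_per_cluster
  cluster <- rep(seq_len(cfg$n_clusters), each = cfg$cells_per_cluster)
  conds <- names(cfg$condition_fractions)
  condition <- sample(conds, n_cells, replace = TRUE,
                      prob = cfg$condition_fractions)

  base <- cfg$base_mean
  # mito genes get means such that their expected share is mito_base_fraction
  if (length(cfg$mito_gene_indices)) {
    mi <- cfg$mito_gene_indices
    tot_other <- sum(base[-mi])
    f <- cfg$mito_base_fraction
    base[mi] <- f * tot_other / ((1 - f) * length(mi))
  }

  # gene x (cluster, condition) expected means
  mean_arr <- array(rep(base, times = cfg$n_clusters * length(conds)),
                    dim = c(G, cfg$n_clusters, length(conds)),
                    dimnames = list(gene_names_, NULL, conds))
  for (p in cfg$axis_programs) {
    li <- .resolve_gene(p$ligand, gene_names_)
    ri <- .resolve_gene(p$receptor, gene_names_)
    on <- if (is.null(p$conditions)) conds else p$conditions
    for (cc in on) {
      mean_arr[li, p$source_clusters, cc] <- base[li] * p$fold_up
      mean_arr[ri, p$target_clusters, cc] <- base[ri] * p$fold_up
    }
  }
  de_genes <- character()
  for (g in cfg$circadian_genes) {
    gi <- .resolve_gene(g$gene, gene_names_)
    mean_arr[gi, , conds[1]] <- mean_arr[gi, , conds[1]] * g$fold
    if (g$fold != 1) de_genes <- c(de_genes, gene_names_[gi])
  }

  cond_idx <- match(condition, conds)
  counts <- matrix(0L, G, n_cells)
  for (k in seq_len(cfg$n_clusters)) {
    for (ci in seq_along(conds)) {
      sel <- which(cluster == k & cond_idx == ci)
      if (!length(sel)) next
      mu <- mean_arr[, k, ci]
      counts[, sel] <- matrix(
        stats::rnbinom(G * length(sel), mu = mu,
                       size = cfg$dispersion),
        nrow = G)
    }
  }

  bad_type <- rep(NA_character_, n_cells)
  bad <- cfg$planted_bad_cells
  extra <- list()
  extra_cond <- character(); extra_bad <- character()
  if (bad["low_umi"] > 0) {
    mu <- base * 0.02
    extra <- c(extra, list(matrix(stats::rnbinom(G * bad["low_umi"], mu = mu,
                                                 size = cfg$dispersion), nrow = G)))
    extra_cond <- c(extra_cond, sample(conds, bad["low_umi"], TRUE,
                                       cfg$condition_fractions))
    extra_bad <- c(extra_bad, rep("low_umi", bad["low_umi"]))
  }
  if (bad["high_mito"] > 0) {
    mu <- base
    if (length(cfg$mito_gene_indices)) {
      mi <- cfg$mito_gene_indices
      f <- 0.25
      mu[mi] <- f * sum(mu[-mi]) / ((1 - f) * length(mi))
    }
    extra <- c(extra, list(matrix(stats::rnbinom(G * bad["high_mito"], mu = mu,
                                                 size = cfg$dispersion), nrow = G)))
    extra_cond <- c(extra_cond, sample(conds, bad["high_mito"], TRUE,
                                       cfg$condition_fractions))
    extra_bad <- c(extra_bad, rep("high_mito", bad["high_mito"]))
  }
  if (bad["doublet"] > 0) {
    i1 <- sample(n_cells, bad["doublet"], replace = TRUE)
    i2 <- sample(n_cells, bad["doublet"], replace = TRUE)
    extra <- c(extra, list(counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]))
    extra_cond <- c(extra_cond, condition[i1])
    extra_bad <- c(extra_bad, rep("doublet", bad["doublet"]))
  }
  if (length(extra)) {
    counts <- cbind(counts, do.call(cbind, extra))
    condition <- c(condition, extra_cond)
    cluster <- c(cluster, rep(NA_integer_, length(extra_bad)))
    bad_type <- c(bad_type, extra_bad)
  }

  bcs <- sprintf("cell%05d", seq_len(ncol(counts)))
  meta <- data.frame(condition = condition,
                     run = paste0("run_", cond_idx_to_run(condition)),
                     stringsAsFactors = FALSE)
  m <- chrono_counts(Matrix::Matrix(counts, sparse = TRUE),
                     gene_names_, bcs, meta)
  truth <- data.frame(barcode = bcs, cluster = cluster, condition = condition,
                      bad_type = bad_type, stringsAsFactors = FALSE)
  list(matrix = m, truth = truth, de_genes = unique(de_genes),
       mean_matrix = mean_arr[, , 1, drop = TRUE],
       mito_genes = gene_names_[cfg$mito_gene_indices])
}

# one synthetic sequencing run per condition label
cond_idx_to_run <- function(condition) as.integer(factor(condition))
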