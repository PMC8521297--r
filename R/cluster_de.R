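#' Cluster cells on PCA of log-normalized expression
#'
#' Reduces the log-normalized matrix to its top principal components (genes
#' centered and unit-scaled) and clusters cells either by k-means or by a
#' graph-based method (shared nearest-neighbour graph, walktrap community
#' detection cut at `k` communities). Both are deterministic for a fixed seed.
#'
#' @param norm a `chrono_norm` object from [normalize_counts()].
#' @param k number of clusters (>= 1; >= 2 for k-means).
#' @param method `"kmeans"` or `"graph"`.
#' @param seed integer seed.
#' @param n_pcs number of principal components (capped at the data rank).
#' @param knn neighbours for the graph method.
#' @return A list of class `cluster_assignment`: `labels` (integer 1..k per
#'   cell, named by barcode), `k`, `method`, `seed`.
#' @export
cluster_cells <- function(norm, k, method = c("kmeans", "graph"), seed = 1L,
                          n_pcs = 50, knn = 15) {
  stopifnot(inherits(norm, "chrono_norm"))
  method <- match.arg(method)
  n_cells <- ncol(norm$values)
  if (k > n_cells) stop("k exceeds the number of cells")
  if (method == "kmeans" && k < 2) stop("k-means requires k >= 2")
  set.seed(seed)

  x <- t(as.matrix(norm$values))          # cells x genes
  keep <- apply(x, 2, stats::sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), n_cells - 1)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  if (k == 1) {
    labels <- rep(1L, n_cells)
  } else if (method == "kmeans") {
    labels <- stats::kmeans(pcs, centers = k, nstart = 10,
                            iter.max = 100)$cluster
  } else {
    knn <- min(knn, n_cells - 1)
    d <- as.matrix(stats::dist(pcs))
    diag(d) <- Inf
    adj <- matrix(0, n_cells, n_cells)
    for (i in seq_len(n_cells)) {
      nb <- order(d[i, ])[seq_len(knn)]
      adj[i, nb] <- 1
    }
    adj <- pmax(adj, t(adj))               # mutualize: undirected kNN graph
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    wt <- igraph::cluster_walktrap(g)
    labels <- tryCatch(igraph::cut_at(wt, no = k),
                       error = function(e) igraph::membership(wt))
  }
  labels <- as.integer(factor(labels))     # contiguous 1..k
  names(labels) <- colnames(norm$values)
  structure(list(labels = labels, k = max(labels), method = method,
                 seed = as.integer(seed)),
            class = "cluster_assignment")
}

#' Condition purity ("coverage") of clusters
#'
#' For each cluster, reports the majority condition and the percentage of the
#' cluster's cells carrying it — the cluster-coverage statistic used to show
#' near-perfect day/night segregation of pooled cells.
#'
#' @param assign a `cluster_assignment`.
#' @param conditions per-cell condition labels aligned to the assignment.
#' @return data.frame: `cluster`, `n_cells`, `majority_condition`,
#'   `purity_pct`.
#' @export
condition_coverage <- function(assign, conditions) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (length(conditions) != length(assign$labels))
    stop("conditions must align with cells")
  out <- lapply(sort(unique(assign$labels)), function(cl) {
    cc <- conditions[assign$labels == cl]
    tab <- sort(table(cc), decreasing = TRUE)
    data.frame(cluster = cl, n_cells = length(cc),
               majority_condition = names(tab)[1],
               purity_pct = 100 * tab[[1]] / length(cc))
  })
  do.call(rbind, out)
}

# Per-gene method-of-moments dispersion (var = mu + phi mu^2) on size-factor
# normalized counts, shrunk toward the mean dispersion with the
# Hausser-Strimmer / sSeq-style weight
#   delta = [ sum (phi_g - phi_bar)^2 / (G-1) ] / [ sum (phi_g - xi)^2 / (G-2) ]
# and xi = mean(phi). With this xi, delta -> (G-2)/(G-1): near-complete
# pooling, appropriate when genes share a dispersion; per-gene signal enters
# through xi.
.estimate_dispersion <- function(q) {
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  phi <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  G <- length(phi)
  xi <- mean(phi)
  if (G < 3 || sum((phi - xi)^2) == 0) return(rep(xi, G))
  delta <- (sum((phi - xi)^2) / (G - 1)) / (sum((phi - xi)^2) / (G - 2))
  delta <- min(1, max(0, delta))
  delta * xi + (1 - delta) * phi
}

#' Negative-binomial exact test between two cell groups
#'
#' Per-gene two-sided exact test for a difference in mean expression between
#' groups of cells, conditioned on the total count:
#' \enumerate{
#'   \item cell size factors = total UMIs / median total UMIs;
#'   \item per-gene dispersion by method of moments on size-factor-normalized
#'     counts, shrunk toward the mean dispersion (sSeq-style);
#'   \item normalized counts rounded to integers; with group sums
#'     \eqn{Y_A, Y_B} and common fitted mean, the two-sided p-value sums the
#'     probabilities of all splits of the conditioned total \eqn{T = Y_A +
#'     Y_B} that are as or less likely than the observed one, where
#'     \eqn{Y_A \sim NB(n_A \hat\mu, n_A/\phi)} and analogously for B
#'     (Poisson when \eqn{\phi = 0});
#'   \item Benjamini-Hochberg adjustment across genes;
#'   \item `log2fc = log2((mean_a + 1)/(mean_b + 1))` on size-factor-normalized
#'     means (positive = up in group A).
#' }
#' A gene with zero counts in both groups gets p = 1 and log2fc = 0.
#'
#' @param m a [chrono_counts] object.
#' @param cells_a,cells_b disjoint, non-empty cell selections (barcodes or
#'   indices).
#' @param dispersion optional fixed dispersion phi (scalar or per gene),
#'   bypassing estimation; phi = 0 means Poisson.
#' @param size_factors optional per-cell size factors (for the cells in
#'   `c(cells_a, cells_b)`, in that order) overriding the total-count
#'   factors. They are renormalized to median 1, so p-values are invariant
#'   to multiplying all size factors by a constant.
#' @return data.frame: `gene`, `log2fc`, `p_value`, `p_adj`, `mean_a`,
#'   `mean_b`, `dispersion`.
#' @export
nb_exact_test <- function(m, cells_a, cells_b, dispersion = NULL,
                          size_factors = NULL) {
  stopifnot(inherits(m, "chrono_counts"))
  bcs <- barcodes(m)
  ia <- if (is.character(cells_a)) match(cells_a, bcs) else as.integer(cells_a)
  ib <- if (is.character(cells_b)) match(cells_b, bcs) else as.integer(cells_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell selection")
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")

  counts <- m$counts[, c(ia, ib), drop = FALSE]
  grp_a <- seq_along(ia)
  grp_b <- length(ia) + seq_along(ib)
  if (is.null(size_factors)) {
    totals <- Matrix::colSums(counts)
    sf <- totals / stats::median(totals)
  } else {
    if (length(size_factors) != ncol(counts))
      stop("size_factors must cover the selected cells")
    sf <- size_factors / stats::median(size_factors)
  }
  if (any(sf <= 0)) stop("cells with zero totals; filter first")
  q <- as.matrix(counts %*% Matrix::Diagonal(x = 1 / sf))

  phi <- if (is.null(dispersion)) .estimate_dispersion(q)
         else rep_len(dispersion, nrow(q))

  qa <- round(q[, grp_a, drop = FALSE])
  qb <- round(q[, grp_b, drop = FALSE])
  ya <- rowSums(qa); yb <- rowSums(qb)
  na <- length(grp_a); nb <- length(grp_b)
  G <- nrow(q)
  p <- numeric(G)
  for (g in seq_len(G)) {
    p[g] <- .exact_nb_p(ya[g], yb[g], na, nb, phi[g])
  }
  mean_a <- rowMeans(q[, grp_a, drop = FALSE])
  mean_b <- rowMeans(q[, grp_b, drop = FALSE])
  log2fc <- ifelse(ya + yb == 0, 0, log2((mean_a + 1) / (mean_b + 1)))
  data.frame(gene = gene_names(m), log2fc = log2fc, p_value = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             mean_a = mean_a, mean_b = mean_b, dispersion = phi,
             row.names = NULL, stringsAsFactors = FALSE)
}

# exact conditional two-sided p for one gene; sums probabilities of splits of
# the total as or less likely than the observed split
.exact_nb_p <- function(ya, yb, na, nb, phi) {
  tot <- ya + yb
  if (tot == 0) return(1)
  mu <- tot / (na + nb)
  a <- 0:tot
  if (phi <= 0) {
    pa <- stats::dpois(a, na * mu)
    pb <- stats::dpois(tot - a, nb * mu)
  } else {
    pa <- stats::dnbinom(a, mu = na * mu, size = na / phi)
    pb <- stats::dnbinom(tot - a, mu = nb * mu, size = nb / phi)
  }
  pr <- pa * pb
  denom <- sum(pr)
  if (denom == 0) return(1)
  obs <- pr[ya + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / denom)
}

#' Top marker genes per cluster
#'
#' Runs the one-vs-rest NB exact test for each cluster and ranks significantly
#' up-regulated genes (BH-adjusted p < `alpha`, positive fold change) by
#' decreasing log2 fold change; ties broken by adjusted p, then gene name.
#' Clusters with fewer than 2 cells are skipped with a warning.
#'
#' @param m a [chrono_counts] object.
#' @param assign a `cluster_assignment` aligned with `m`.
#' @param n_top markers to report per cluster (fewer if fewer pass).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return Named list (one element per cluster) of data.frames as from
#'   [nb_exact_test()], at most `n_top` rows each.
#' @export
top_markers <- function(m, assign, n_top = 5, alpha = 0.05) {
  stopifnot(inherits(assign, "cluster_assignment"), n_top >= 1)
  out <- list()
  for (cl in sort(unique(assign$labels))) {
    in_cl <- which(assign$labels == cl)
    if (length(in_cl) < 2) {
      warning("cluster ", cl, " has fewer than 2 cells; skipped")
      next
    }
    de <- nb_exact_test(m, in_cl, setdiff(seq_along(assign$labels), in_cl))
    de <- de[de$p_adj < alpha & de$log2fc > 0, , drop = FALSE]
    de <- de[order(-de$log2fc, de$p_adj, de$gene), , drop = FALSE]
    out[[as.character(cl)]] <- utils::head(de, n_top)
  }
  out
}
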