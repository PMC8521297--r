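#' Define a ligand-receptor signalling axis
#'
#' @param name axis label, e.g. `"Prok2-ProkR2"`.
#' @param ligand_gene,receptor_gene gene names; both must be present in the
#'   matrices the axis is evaluated on.
#' @return A list of class `axis_spec`.
#' @export
axis_spec <- function(name, ligand_gene, receptor_gene) {
  structure(list(name = name, ligand_gene = ligand_gene,
                 receptor_gene = receptor_gene),
            class = "axis_spec")
}

#' Default neuropeptide signalling axes
#'
#' The four SCN ligand-receptor pairs analysed throughout: Prok2-ProkR2,
#' Vip-Vipr2, Avp-Avpr1a and Grp-Grpr.
#' @return List of [axis_spec] objects.
#' @export
default_axes <- function() {
  list(axis_spec("Prok2-ProkR2", "Prok2", "Prokr2"),
       axis_spec("Vip-Vipr2", "Vip", "Vipr2"),
       axis_spec("Avp-Avpr1a", "Avp", "Avpr1a"),
       axis_spec("Grp-Grpr", "Grp", "Grpr"))
}

#' Cells positively expressing a gene
#'
#' Two positivity rules: `"nonzero"` (raw count >= 1) or
#' `"range_fraction"`, which calls a cell positive when its expression
#' exceeds `min + q * (max - min)` of the gene's overall expression range —
#' the rule used for highlighting high-expresser cells (q = 0.9 gives the
#' ">90% of the overall expression range" sets).
#'
#' @param m a [chrono_counts] (rule `"nonzero"`) or an expression source for
#'   the range rule: raw counts are used for both by default; supply `values`
#'   to apply the range rule to normalized expression.
#' @param gene gene name.
#' @param rule `"nonzero"` or `"range_fraction"`.
#' @param q range fraction threshold for `"range_fraction"` (default 0.9).
#' @param values optional numeric vector of per-cell expression overriding the
#'   raw counts for the range rule.
#' @return Character vector of barcodes of positive cells.
#' @export
positive_cells <- function(m, gene, rule = c("nonzero", "range_fraction"),
                           q = 0.9, values = NULL) {
  stopifnot(inherits(m, "chrono_counts"))
  rule <- match.arg(rule)
  if (!gene %in% gene_names(m)) stop("gene not present: ", gene)
  x <- if (is.null(values)) as.numeric(m$counts[gene, ]) else values
  if (length(x) != ncol(m$counts)) stop("values must align with cells")
  pos <- if (rule == "nonzero") {
    x >= 1
  } else {
    thr <- min(x) + q * (max(x) - min(x))
    if (max(x) == min(x)) rep(FALSE, length(x)) else x > thr
  }
  barcodes(m)[pos]
}

#' Pairwise overlap summary of positive-cell sets
#'
#' For named cell sets, reports each set's size and, for each ordered pair,
#' the intersection size and the directional overlap percentages (what share
#' of A is also in B and vice versa) — the quantities behind co-expression
#' Venn diagrams.
#'
#' @param sets named list (>= 2) of character vectors of cell barcodes.
#' @return List with `sizes` (named integer vector) and `pairs` (data.frame:
#'   `set_a`, `set_b`, `n_a`, `n_b`, `n_intersect`, `pct_a_in_b`,
#'   `pct_b_in_a`). Percentages involving an empty set are 0 (with a warning).
#' @export
overlap_summary <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  sizes <- vapply(sets, length, integer(1))
  if (any(sizes == 0)) warning("empty set(s): percentages defined as 0")
  nm <- names(sets)
  cmb <- utils::combn(length(sets), 2)
  pairs <- apply(cmb, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    ni <- length(intersect(a, b))
    data.frame(set_a = nm[ij[1]], set_b = nm[ij[2]],
               n_a = length(a), n_b = length(b), n_intersect = ni,
               pct_a_in_b = if (length(a)) 100 * ni / length(a) else 0,
               pct_b_in_a = if (length(b)) 100 * ni / length(b) else 0,
               stringsAsFactors = FALSE)
  })
  list(sizes = sizes, pairs = do.call(rbind, pairs))
}

#' Share of a set within the union of two sets
#'
#' Convenience for ligand-share statements of the form "77% (683/886)": the
#' percentage of the two sets' union occupied by the first set.
#'
#' @param set_a,set_b character vectors of cell identifiers, or integers
#'   giving the set size and the union size directly.
#' @return Percentage in \[0, 100\].
#' @export
union_share_pct <- function(set_a, set_b) {
  if (is.numeric(set_a) && length(set_a) == 1 &&
      is.numeric(set_b) && length(set_b) == 1) {
    return(100 * set_a / set_b)
  }
  u <- union(set_a, set_b)
  100 * length(unique(set_a)) / length(u)
}

#' Per-cluster mean raw expression of a gene
#'
#' The "average cellular count": arithmetic mean of raw UMI counts over the
#' cells of each cluster (set `use = "normalized"` with a `chrono_norm` to
#' average log-normalized values instead).
#'
#' @param m a [chrono_counts] object.
#' @param assign a `cluster_assignment` aligned with `m`.
#' @param gene gene name.
#' @return Named numeric vector of cluster means (names = cluster ids).
#' @export
cluster_mean_expression <- function(m, assign, gene) {
  stopifnot(inherits(m, "chrono_counts"), inherits(assign, "cluster_assignment"))
  if (!gene %in% gene_names(m)) stop("gene not present: ", gene)
  if (length(assign$labels) != ncol(m$counts))
    stop("assignment must align with cells")
  x <- as.numeric(m$counts[gene, ])
  cl <- sort(unique(assign$labels))
  sizes <- table(factor(assign$labels, levels = cl))
  if (any(sizes == 0)) stop("empty cluster")
  out <- vapply(cl, function(k) mean(x[assign$labels == k]), numeric(1))
  names(out) <- cl
  out
}

#' Outer-product edge weights of a signalling axis
#'
#' The inferred strength of signalling from cluster i to cluster j is the
#' product of the mean ligand count in i and the mean receptor count in j:
#' `W_raw[i, j] = mL[i] * mR[j]` (rank-1; diagonal = autocrine edges).
#'
#' @param means_ligand,means_receptor per-cluster mean expression vectors in
#'   the same cluster order.
#' @return k x k non-negative matrix.
#' @export
edge_weights <- function(means_ligand, means_receptor) {
  if (length(means_ligand) != length(means_receptor))
    stop("ligand and receptor mean vectors must align")
  if (any(means_ligand < 0) || any(means_receptor < 0))
    stop("means must be non-negative")
  W <- outer(means_ligand, means_receptor)
  if (!is.null(names(means_ligand)))
    dimnames(W) <- list(names(means_ligand), names(means_receptor))
  W
}

#' Min-max scale edge-weight matrices
#'
#' Scales raw weights to \[0, 1\]. Mode `"axis_joint_minmax"` (default) uses
#' the minimum and maximum over all supplied matrices jointly — required for
#' day/night sigma values of one axis to be comparable. Mode
#' `"per_matrix_minmax"` scales each matrix by its own range. A constant
#' matrix scales to all zeros with a warning.
#'
#' @param ... one or more raw weight matrices (or a single list of them).
#' @param mode `"axis_joint_minmax"` or `"per_matrix_minmax"`.
#' @return A scaled matrix, or a list of them when several were supplied.
#' @export
scale_weights <- function(..., mode = c("axis_joint_minmax",
                                        "per_matrix_minmax")) {
  mode <- match.arg(mode)
  Ws <- list(...)
  if (length(Ws) == 1 && is.list(Ws[[1]]) && !is.matrix(Ws[[1]]))
    Ws <- Ws[[1]]
  if (!length(Ws)) stop("need at least one matrix")
  scale1 <- function(W, lo, hi) {
    if (hi == lo) {
      warning("constant weight matrix: scaled to zeros")
      return(W * 0)
    }
    (W - lo) / (hi - lo)
  }
  out <- if (mode == "axis_joint_minmax") {
    lo <- min(vapply(Ws, min, numeric(1)))
    hi <- max(vapply(Ws, max, numeric(1)))
    lapply(Ws, scale1, lo = lo, hi = hi)
  } else {
    lapply(Ws, function(W) scale1(W, min(W), max(W)))
  }
  if (length(out) == 1) out[[1]] else out
}

#' Assemble an axis network for one condition
#'
#' Computes cluster means for the ligand and receptor, the raw outer-product
#' weight matrix, and source-cluster flags. Scaled weights and sigma are
#' filled in by [compare_networks()] (or by scaling a single network against
#' itself).
#'
#' @param m a [chrono_counts] for one condition.
#' @param assign a `cluster_assignment` aligned with `m`.
#' @param axis an [axis_spec].
#' @param condition condition label stored on the network.
#' @param source_factor enrichment factor for source calls (see
#'   [identify_source_clusters()]).
#' @param alpha marker-significance level for source calls.
#' @return A list of class `axis_network`: `axis`, `condition`, `clusters`,
#'   `means_ligand`, `means_receptor`, `W_raw`, `W_scaled` (NULL until
#'   scaled), `sigma` (sum of scaled weights, NULL until scaled),
#'   `source_flags`.
#' @export
axis_network <- function(m, assign, axis, condition = NA_character_,
                         source_factor = 2, alpha = 0.05) {
  stopifnot(inherits(axis, "axis_spec"))
  mL <- cluster_mean_expression(m, assign, axis$ligand_gene)
  mR <- cluster_mean_expression(m, assign, axis$receptor_gene)
  W <- edge_weights(mL, mR)
  src <- identify_source_clusters(mL, m = m, assign = assign,
                                  gene = axis$ligand_gene,
                                  factor = source_factor, alpha = alpha)
  structure(list(axis = axis$name, condition = condition,
                 clusters = names(mL), means_ligand = mL, means_receptor = mR,
                 W_raw = W, W_scaled = NULL, sigma = NULL,
                 source_flags = src),
            class = "axis_network")
}

#' Network connectivity sigma
#'
#' The sum of all edge weights of an axis network — the overall degree of
#' connectivity. Computed on scaled weights when available (the reported
#' sigma), else on raw weights.
#'
#' @param net an `axis_network`, or a bare weight matrix.
#' @return Scalar sigma.
#' @export
network_sigma <- function(net) {
  if (is.matrix(net)) return(sum(net))
  stopifnot(inherits(net, "axis_network"))
  if (!is.null(net$W_scaled)) sum(net$W_scaled) else sum(net$W_raw)
}

#' Flag ligand-enriched source clusters
#'
#' A cluster is a source ("distributor") node when its mean ligand expression
#' exceeds `factor` times the grand mean across clusters and, when a count
#' matrix is supplied, the ligand is a significant one-vs-rest marker of the
#' cluster (BH-adjusted p < `alpha`).
#'
#' @param means_ligand per-cluster mean ligand expression.
#' @param m,assign,gene optional count matrix, assignment and ligand gene for
#'   the marker-significance requirement.
#' @param factor enrichment multiple over the grand mean (default 2).
#' @param alpha marker significance level.
#' @return Named logical vector per cluster.
#' @export
identify_source_clusters <- function(means_ligand, m = NULL, assign = NULL,
                                     gene = NULL, factor = 2, alpha = 0.05) {
  grand <- mean(means_ligand)
  flags <- if (grand == 0) rep(FALSE, length(means_ligand))
           else means_ligand > factor * grand
  if (!is.null(m) && !is.null(assign) && !is.null(gene) && any(flags)) {
    for (k in which(flags)) {
      cl <- sort(unique(assign$labels))[k]
      in_cl <- which(assign$labels == cl)
      if (length(in_cl) < 2 || length(in_cl) == length(assign$labels)) next
      de <- nb_exact_test(m, in_cl, setdiff(seq_along(assign$labels), in_cl))
      row <- de[de$gene == gene, ]
      flags[k] <- nrow(row) == 1 && row$p_adj < alpha && row$log2fc > 0
    }
  }
  names(flags) <- names(means_ligand)
  flags
}

#' Compare day and night networks of one axis
#'
#' Jointly min-max scales the two raw weight matrices, computes per-edge
#' differences (day - night) and the sigma values and their ratio, and flags
#' the axis as "disassembled" at night when sigma_night < theta * sigma_day.
#'
#' @param day,night `axis_network` objects over the same clusters (or a
#'   mapping via `cluster_map`: named vector night cluster -> day cluster).
#' @param theta disassembly threshold on the sigma ratio (default 0.25).
#' @param mode scaling mode passed to [scale_weights()].
#' @param cluster_map optional reordering of the night network's clusters.
#' @return List: `day`, `night` (networks with `W_scaled`/`sigma` filled),
#'   `delta` (day - night scaled weights), `sigma_day`, `sigma_night`,
#'   `sigma_ratio` (night/day; 0 when both are 0), `disassembled_at_night`.
#' @export
compare_networks <- function(day, night, theta = 0.25,
                             mode = "axis_joint_minmax", cluster_map = NULL) {
  stopifnot(inherits(day, "axis_network"), inherits(night, "axis_network"))
  Wn <- night$W_raw
  if (!is.null(cluster_map)) {
    ord <- match(day$clusters, cluster_map[night$clusters])
    if (anyNA(ord)) stop("cluster_map does not cover the day clusters")
    Wn <- Wn[ord, ord, drop = FALSE]
  }
  if (!all(dim(day$W_raw) == dim(Wn)))
    stop("incompatible cluster sets; supply cluster_map")
  sc <- scale_weights(day$W_raw, Wn, mode = mode)
  day$W_scaled <- sc[[1]]; night$W_scaled <- sc[[2]]
  day$sigma <- sum(sc[[1]]); night$sigma <- sum(sc[[2]])
  ratio <- if (day$sigma == 0) {
    if (night$sigma == 0) 0 else Inf
  } else night$sigma / day$sigma
  list(day = day, night = night, delta = sc[[1]] - sc[[2]],
       sigma_day = day$sigma, sigma_night = night$sigma,
       sigma_ratio = ratio,
       disassembled_at_night = night$sigma < theta * day$sigma)
}

#' Export an axis network
#'
#' Writes a network as GraphML (via igraph) and/or as a JSON edge list with
#' fields source, target, weight_raw, weight_scaled, axis, condition.
#'
#' @param net an `axis_network`.
#' @param graphml,json output paths (either may be `NULL` to skip).
#' @return Invisibly, the edge-list data.frame.
#' @export
export_network <- function(net, graphml = NULL, json = NULL) {
  stopifnot(inherits(net, "axis_network"))
  k <- length(net$clusters)
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  edges <- data.frame(source = net$clusters[idx$i],
                      target = net$clusters[idx$j],
                      weight_raw = net$W_raw[cbind(idx$i, idx$j)],
                      weight_scaled = if (is.null(net$W_scaled)) NA_real_
                                      else net$W_scaled[cbind(idx$i, idx$j)],
                      axis = net$axis, condition = net$condition,
                      stringsAsFactors = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      edges[edges$weight_raw > 0, c("source", "target", "weight_raw")],
      directed = TRUE,
      vertices = data.frame(name = net$clusters,
                            source_node = unname(net$source_flags)))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(json))
    jsonlite::write_json(edges, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(edges)
}
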