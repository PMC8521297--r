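# shared fixture builders for the test suite

# tiny count container from a dense matrix (genes x cells)
mk_counts <- function(mat, genes = NULL, cells = NULL, condition = NULL) {
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("cell%02d", seq_len(ncol(mat)))
  meta <- if (is.null(condition)) NULL else data.frame(condition = condition)
  chrono_counts(Matrix::Matrix(mat, sparse = TRUE), genes, cells, meta)
}

# cluster assignment from a plain label vector
mk_assign <- function(labels) {
  structure(list(labels = as.integer(labels),
                 k = length(unique(labels)),
                 method = "kmeans", seed = 1L),
            class = "cluster_assignment")
}

# adjusted Rand index oracle (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}
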