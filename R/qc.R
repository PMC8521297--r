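#' Per-cell quality-control metrics
#'
#' Computes, on raw counts, the total UMI count, the number of detected genes
#' and the percentage of the transcriptome of mitochondrial origin for each
#' cell. A cell with zero total counts has `pct_mito` defined as 0 (it is
#' removed by the minimum-total filter anyway).
#'
#' @param m a [chrono_counts] object.
#' @param mito_genes character vector of mitochondrial gene names, or `NULL`
#'   to use all genes whose name starts with `"mt-"` (case-insensitive).
#' @return data.frame with one row per cell: `barcode`, `total_umis`,
#'   `n_genes_detected`, `pct_mito`.
#' @export
compute_qc_metrics <- function(m, mito_genes = NULL) {
  stopifnot(inherits(m, "chrono_counts"))
  gn <- gene_names(m)
  if (is.null(mito_genes)) {
    mito_genes <- gn[grepl("^mt-", gn, ignore.case = TRUE)]
  } else {
    bad <- setdiff(mito_genes, gn)
    if (length(bad))
      stop("unknown mitochondrial gene name(s): ", paste(bad, collapse = ", "))
  }
  total <- Matrix::colSums(m$counts)
  ngene <- Matrix::colSums(m$counts > 0)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(m$counts[gn %in% mito_genes, , drop = FALSE])
  } else rep(0, ncol(m$counts))
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(barcode = barcodes(m), total_umis = as.integer(total),
             n_genes_detected = as.integer(ngene), pct_mito = pct,
             stringsAsFactors = FALSE)
}

#' Default QC thresholds
#'
#' Cells are retained with at least 200 total UMIs, fewer than 10,000 total
#' UMIs, less than 10% mitochondrial content and at least 100 detected genes;
#' genes are retained when expressed in at least 3 cells; cells outside 3
#' median absolute deviations (on any of the three metrics, two-sided) are
#' additionally removed as potential multiplets.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(min_total = 200, max_total = 10000, max_pct_mito = 10,
       min_genes_per_cell = 100, min_cells_per_gene = 3, n_mads = 3)
}

# two-sided MAD outlier flag; inert when MAD == 0
.mad_outlier <- function(x, n_mads) {
  md <- stats::median(x)
  s <- stats::mad(x)  # 1.4826 * median(|x - median|)
  if (s == 0) return(rep(FALSE, length(x)))
  abs(x - md) > n_mads * s
}

#' Filter cells and genes by QC thresholds
#'
#' Application order: (1) genes expressed in fewer than `min_cells_per_gene`
#' cells are dropped; (2) hard cell thresholds (minimum/maximum total UMIs,
#' maximum mitochondrial percentage, minimum detected genes); (3) potential
#' multiplets removed as cells outside `n_mads` median absolute deviations
#' (two-sided, scaled by the consistency constant 1.4826) on any of total
#' UMIs, detected genes or mitochondrial percentage, recomputed on the cells
#' surviving step 2. A MAD of zero makes that metric's rule inert.
#'
#' @param m a [chrono_counts] object.
#' @param qc output of [compute_qc_metrics()] aligned to `m`; recomputed when
#'   `NULL`.
#' @param thresholds list as from [qc_thresholds()] (partial lists are merged
#'   over the defaults).
#' @param mito_genes passed to [compute_qc_metrics()] when `qc` is `NULL`.
#' @return A list: `matrix` (filtered [chrono_counts]), `cell_report`
#'   (data.frame: barcode, metrics, `kept`, `reasons` — semicolon-separated
#'   removal reasons among `min_total`, `max_total`, `max_pct_mito`,
#'   `min_genes`, `mad_outlier`), `genes_kept` (logical per input gene).
#' @export
filter_cells_and_genes <- function(m, qc = NULL, thresholds = qc_thresholds(),
                                   mito_genes = NULL) {
  stopifnot(inherits(m, "chrono_counts"))
  th <- utils::modifyList(qc_thresholds(), as.list(thresholds))
  if (is.null(qc)) qc <- compute_qc_metrics(m, mito_genes)
  if (nrow(qc) != ncol(m$counts) || !identical(qc$barcode, barcodes(m)))
    stop("qc metrics are not aligned with the count matrix")

  genes_kept <- Matrix::rowSums(m$counts > 0) >= th$min_cells_per_gene

  reasons <- vector("list", nrow(qc))
  add_reason <- function(flag, label) {
    for (i in which(flag)) reasons[[i]] <<- c(reasons[[i]], label)
  }
  add_reason(qc$total_umis < th$min_total, "min_total")
  add_reason(qc$total_umis >= th$max_total, "max_total")
  add_reason(qc$pct_mito >= th$max_pct_mito, "max_pct_mito")
  add_reason(qc$n_genes_detected < th$min_genes_per_cell, "min_genes")
  pass_hard <- lengths(reasons) == 0

  if (any(pass_hard)) {
    sub <- qc[pass_hard, ]
    out <- .mad_outlier(sub$total_umis, th$n_mads) |
      .mad_outlier(sub$n_genes_detected, th$n_mads) |
      .mad_outlier(sub$pct_mito, th$n_mads)
    flag <- rep(FALSE, nrow(qc))
    flag[pass_hard] <- out
    add_reason(flag, "mad_outlier")
  }

  kept <- lengths(reasons) == 0
  if (!any(kept)) stop("all cells removed by QC filters")
  report <- cbind(qc,
                  kept = kept,
                  reasons = vapply(reasons, function(r)
                    paste(r, collapse = ";"), character(1)))
  filtered <- m[genes_kept, kept]
  list(matrix = filtered, cell_report = report, genes_kept = genes_kept)
}

#' Library-size normalization with log transform
#'
#' Scales each cell to a common library size and applies a natural log with a
#' pseudocount of 1: `value = ln(1 + count * scale_factor / cell_total)`.
#' Per cell, `sum(exp(value) - 1) == scale_factor` (up to float tolerance).
#'
#' @param m a [chrono_counts] object; all cells must have positive totals.
#' @param scale_factor target library size (default 10,000 UMIs per cell).
#' @return A list of class `chrono_norm`: `values` (sparse gene x cell matrix
#'   of log-normalized expression), `scale_factor`, `pseudocount` (1),
#'   `cell_meta`.
#' @export
normalize_counts <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "chrono_counts"))
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0))
    stop(sum(totals == 0), " cell(s) with zero total counts; filter first")
  v <- m$counts
  # column-wise scaling on the dgCMatrix slots
  v@x <- log1p(v@x * scale_factor / rep.int(totals, diff(v@p)))
  structure(list(values = v, scale_factor = scale_factor, pseudocount = 1,
                 cell_meta = m$cell_meta),
            class = "chrono_norm")
}

#' @export
print.chrono_norm <- function(x, ...) {
  cat(sprintf("chrono_norm: %d genes x %d cells, scale factor %g, ln(1+x)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Write a per-cell QC report CSV
#' @param report `cell_report` from [filter_cells_and_genes()].
#' @param path output CSV path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
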