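#' Construct a UMI count matrix container
#'
#' Bundles a sparse gene x cell matrix of UMI counts with gene names, cell
#' barcodes and per-cell metadata (condition label, run id, ...). This is the
#' input type of the QC, normalization, clustering, differential-expression
#' and signalling-topology functions.
#'
#' @param counts gene x cell matrix of non-negative integer counts; coerced to
#'   [Matrix::dgCMatrix-class].
#' @param gene_names character vector of unique gene symbols (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param cell_meta data.frame with one row per cell; typically includes a
#'   `condition` column (e.g. `"CT7.5"` / `"CT15.5"`). May be `NULL`.
#'
#' @return An object of class `chrono_counts`: a list with elements `counts`
#'   (dgCMatrix with dimnames), and `cell_meta` (data.frame or NULL).
#' @export
chrono_counts <- function(counts, gene_names = rownames(counts),
                          barcodes = colnames(counts), cell_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count matrix must have at least one gene and one cell")
  if (is.null(gene_names) || is.null(barcodes))
    stop("gene names and barcodes are required")
  if (length(gene_names) != nrow(counts))
    stop("length(gene_names) != number of rows")
  if (length(barcodes) != ncol(counts))
    stop("length(barcodes) != number of columns")
  if (anyDuplicated(gene_names))
    stop("duplicate gene names: ",
         paste(utils::head(unique(gene_names[duplicated(gene_names)]), 5), collapse = ", "))
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ",
         paste(utils::head(unique(barcodes[duplicated(barcodes)]), 5), collapse = ", "))
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != ncol(counts))
      stop("cell_meta must have one row per cell")
    rownames(cell_meta) <- barcodes
  }
  dimnames(counts) <- list(as.character(gene_names), as.character(barcodes))
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "chrono_counts")
}

#' @export
print.chrono_counts <- function(x, ...) {
  cat(sprintf("chrono_counts: %d genes x %d cells (%.2f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (!is.null(x$cell_meta))
    cat("cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.chrono_counts <- function(x) dim(x$counts)

#' Gene names of a count container
#' @param x a `chrono_counts` object.
#' @return Character vector of gene names.
#' @export
gene_names <- function(x) rownames(x$counts)

#' Cell barcodes of a count container
#' @param x a `chrono_counts` object.
#' @return Character vector of barcodes.
#' @export
barcodes <- function(x) colnames(x$counts)

#' Subset a count container by genes and/or cells
#' @param x a `chrono_counts` object.
#' @param i gene index (integer, logical, or character).
#' @param j cell index (integer, logical, or character).
#' @param ... ignored.
#' @export
`[.chrono_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  meta <- x$cell_meta
  if (!is.null(meta)) meta <- meta[colnames(counts), , drop = FALSE]
  chrono_counts(counts, rownames(counts), colnames(counts), meta)
}

#' Read a 10x-style MTX triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`
#' (plain or gzipped) from a directory into a [chrono_counts] container.
#' 1-based MatrixMarket indices are handled by the reader; features files with
#' two or more columns use the second column (symbol) as the gene name, falling
#' back to the first when symbols are duplicated.
#'
#' @param dir directory containing the triplet.
#' @param cell_meta optional data.frame of per-cell metadata (one row per
#'   barcode, in file order).
#' @return A [chrono_counts] object.
#' @export
read_mtx_triplet <- function(dir, cell_meta = NULL) {
  pick <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop("none of ", paste(cands, collapse = "/"), " found in ", dir)
  }
  mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- pick(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("malformed MatrixMarket file '", mtx,
                                         "': ", conditionMessage(e)))
  ft <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  bcs <- readLines(bc)
  bcs <- bcs[nzchar(bcs)]
  if (nrow(ft) != nrow(m))
    stop("dimension mismatch: ", nrow(ft), " features vs ", nrow(m), " matrix rows")
  if (length(bcs) != ncol(m))
    stop("dimension mismatch: ", length(bcs), " barcodes vs ", ncol(m), " matrix columns")
  gn <- if (ncol(ft) >= 2 && !anyDuplicated(ft[[2]])) ft[[2]] else ft[[1]]
  chrono_counts(m, gn, bcs, cell_meta)
}

#' Write a count container as an MTX triplet
#'
#' Writes `matrix.mtx` (1-based MatrixMarket indices), `features.tsv`
#' (gene id and symbol columns, identical here) and `barcodes.tsv`.
#'
#' @param x a [chrono_counts] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(x, dir) {
  stopifnot(inherits(x, "chrono_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = gene_names(x), symbol = gene_names(x)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(barcodes(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
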