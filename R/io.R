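# Readers and writers for the standard formats: MatrixMarket counts with
# gene/cell TSV sidecars, dense CSV/TSV, label and covariate TSVs, and the
# results JSON + TSV pair.

#' Read a genes x cells count matrix
#'
#' For `format = "mtx"`, expects `genes.tsv` and `barcodes.tsv` sidecars
#' next to the matrix file (first column used as ids; 1-based MatrixMarket
#' coordinates with rows = genes). For dense `csv`/`tsv`, the header row
#' holds cell ids and the first column gene ids; `transpose = TRUE` reads a
#' cells x genes layout (never auto-detected: a silent orientation guess
#' corrupts the cell-to-gene ratio).
#'
#' @param path Path to the matrix file.
#' @param format `"mtx"`, `"csv"` or `"tsv"` (default: from the extension).
#' @param transpose Dense input has cells as rows (default FALSE).
#' @return List of class `count_matrix`: integer `values` (genes x cells
#'   with dimnames), `gene_ids`, `cell_ids`.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_phiclust("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      mtx = "mtx", csv = "csv", tsv = "tsv",
      stop_phiclust("cannot infer format from extension; pass `format`")
    )
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes_f <- file.path(dir, "genes.tsv")
    cells_f <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_f) || !file.exists(cells_f)) {
      stop_phiclust("mtx input needs genes.tsv and barcodes.tsv sidecars in ", dir)
    }
    gene_ids <- utils::read.delim(genes_f, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    cell_ids <- utils::read.delim(cells_f, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (length(gene_ids) != nrow(m)) {
      stop_phiclust("genes.tsv has ", length(gene_ids), " ids but the matrix has ",
                    nrow(m), " rows")
    }
    if (length(cell_ids) != ncol(m)) {
      stop_phiclust("barcodes.tsv has ", length(cell_ids), " ids but the matrix has ",
                    ncol(m), " columns")
    }
  } else {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (transpose) m <- t(m)
    gene_ids <- rownames(m)
    cell_ids <- colnames(m)
  }
  validate_count_matrix(m, gene_ids, cell_ids)
}

validate_count_matrix <- function(m, gene_ids, cell_ids) {
  if (anyDuplicated(gene_ids)) stop_phiclust("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop_phiclust("duplicate cell ids")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_phiclust("negative count at gene ", neg[1, 1], ", cell ", neg[1, 2])
  }
  if (any(!is.finite(m))) stop_phiclust("non-finite entries in counts")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, cell_ids)
  structure(list(values = m, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' Read a cell_id / cluster label table (TSV)
#' @param path TSV with columns `cell_id`, `cluster`.
#' @return A tibble.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(df))) {
    stop_phiclust("labels TSV needs cell_id and cluster columns")
  }
  tibble::as_tibble(df)
}

#' Read a per-cell covariate table (TSV)
#' @param path TSV with a `cell_id` column plus numeric covariates.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) {
    stop_phiclust("covariates TSV needs a cell_id column")
  }
  tibble::as_tibble(df)
}

#' Write / read phiclust results
#'
#' `write_phiclust_results()` writes a JSON document (one record per
#' cluster, with nested component records) plus a flat TSV summary next to
#' it; `read_phiclust_results()` reads the JSON back. Numbers are written
#' at full precision, so the round trip is bit-exact.
#'
#' @param fit A `phiclust_fit` (or the list returned by the reader).
#' @param path Output path of the JSON file (the TSV gets extension .tsv).
#' @return The JSON path, invisibly; the reader returns a list with
#'   `clusters` and `components` tibbles.
#' @export
write_phiclust_results <- function(fit, path) {
  clusters <- tibble::as_tibble(fit$clusters)
  components <- tibble::as_tibble(fit$components)
  if (nrow(components) && "per_covariate" %in% names(components)) {
    components$per_covariate <- NULL
  }
  recs <- purrr::map(seq_len(nrow(clusters)), function(i) {
    row <- as.list(clusters[i, ])
    row$components <- components[
      components$cluster_id == clusters$cluster_id[i],
      setdiff(names(components), "cluster_id"),
      drop = FALSE
    ]
    row
  })
  jsonlite::write_json(list(clusters = recs), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  tsv_path <- sub("\\.json$", ".tsv", path)
  if (identical(tsv_path, path)) tsv_path <- paste0(path, ".tsv")
  utils::write.table(clusters, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phiclust_results
#' @export
read_phiclust_results <- function(path) {
  doc <- jsonlite::read_json(path)
  comp_cols <- c("index", "gamma", "gamma_corrected", "theta", "phi",
                 "phi_gene", "sw_p", "sw_p_adj", "adj_r2")
  int_cols <- c("n_cells", "n_genes", "n_significant", "index")
  fix_types <- function(df) {
    for (nm in names(df)) {
      if (nm %in% int_cols) {
        df[[nm]] <- as.integer(df[[nm]])
      } else if (is.numeric(df[[nm]])) {
        df[[nm]] <- as.numeric(df[[nm]])
      }
    }
    df
  }
  clusters <- purrr::map(doc$clusters, function(r) {
    fix_types(tibble::as_tibble(r[setdiff(names(r), "components")]))
  })
  components <- purrr::map(doc$clusters, function(r) {
    rows <- r$components
    if (!length(rows)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(cluster_id = r$cluster_id),
      fix_types(dplyr::bind_rows(purrr::map(rows, tibble::as_tibble)))
    )
  })
  list(
    clusters = dplyr::bind_rows(clusters),
    components = dplyr::bind_rows(components)
  )
}

#' Write a count matrix with MatrixMarket sidecars
#' @param counts A `count_matrix` or genes x cells matrix.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m) %||% paste0("gene", seq_len(nrow(m))),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(m) %||% paste0("cell", seq_len(ncol(m))),
             file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
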