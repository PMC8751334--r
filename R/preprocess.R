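# Preprocessing: raw counts -> doubly standardized matrix whose noise bulk
# matches the MP law. Order matters: normalize + log1p, drop degenerate
# genes, then standardize gene-wise and finally cell-wise. The cell-wise
# step makes every column exactly mean 0, variance 1 (population sd), so
# the squared Frobenius norm equals genes x cells, the convention under
# which the scaled spectrum has MP edges 1 +/- sqrt(c). Double
# standardization also drives the transcriptome mode (the expression trend
# shared by all cells) to a singular value near 0.

#' Library-size normalization and log transform
#'
#' Scales every cell to a common target total (the median of the per-cell
#' totals by default, or a fixed constant), then applies `log(1 + x)`.
#'
#' @param counts Non-negative numeric matrix, genes x cells.
#' @param scale `"median"` or `"fixed"`.
#' @param target Target total when `scale = "fixed"`.
#' @return Numeric matrix of log-normalized expression, same dimnames.
#' @export
normalize_log <- function(counts, scale = c("median", "fixed"), target = 1e4) {
  scale <- match.arg(scale)
  if (any(counts < 0)) stop_phiclust("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0] %||% which(totals == 0)
    stop_phiclust("cell(s) with zero total counts: ",
                  paste(utils::head(bad, 5), collapse = ", "))
  }
  tgt <- if (scale == "median") stats::median(totals) else target
  log1p(sweep(counts, 2, totals / tgt, `/`))
}

#' Drop genes without variance
#'
#' Gene-wise standardization is undefined for constant genes; this removes
#' them (and nothing else -- there is no expression floor, all informative
#' genes stay in the analysis).
#'
#' @param x Numeric matrix, genes x cells.
#' @return List with `values` (filtered matrix) and `dropped` (gene ids or
#'   row indices removed).
#' @export
filter_degenerate <- function(x) {
  v <- rowVars_pop(x)
  keep <- v > 0
  dropped <- rownames(x)[!keep] %||% which(!keep)
  out <- x[keep, , drop = FALSE]
  if (nrow(out) < 10 || ncol(out) < 10) {
    stop_phiclust("fewer than 10 genes or 10 cells remain after filtering")
  }
  list(values = out, dropped = if (any(!keep)) dropped else character(0))
}

rowVars_pop <- function(x) rowMeans(x^2) - rowMeans(x)^2

#' Double standardization (gene-wise, then cell-wise)
#'
#' Step 1 centers and scales every gene to mean 0, variance 1 across cells;
#' step 2 repeats this per cell across genes. Population (1/n) standard
#' deviations are used throughout so columns end with exactly unit
#' variance. Gene rows are only approximately standardized after step 2;
#' the cell-wise step is last because the MP convention requires exact
#' column standardization.
#'
#' @param x Numeric matrix, genes x cells, no constant gene rows
#'   (see [filter_degenerate()]).
#' @return Standardized matrix of the same shape.
#' @export
standardize_expression <- function(x) {
  rm_ <- rowMeans(x)
  rs <- sqrt(rowVars_pop(x))
  if (any(rs == 0)) stop_phiclust("constant gene row; run filter_degenerate() first")
  x <- (x - rm_) / rs
  cm <- colMeans(x)
  cs <- sqrt(colMeans(x^2) - cm^2)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0] %||% which(cs == 0)
    stop_phiclust("constant cell column after gene-wise step: ",
                  paste(utils::head(bad, 5), collapse = ", "))
  }
  sweep(sweep(x, 2, cm, `-`), 2, cs, `/`)
}

#' Full preprocessing pipeline for raw counts
#'
#' [normalize_log()], [filter_degenerate()], [standardize_expression()] in
#' sequence.
#'
#' @inheritParams normalize_log
#' @return List with `values` (processed matrix) and `dropped` genes.
#' @export
preprocess_counts <- function(counts, scale = c("median", "fixed"), target = 1e4) {
  f <- filter_degenerate(normalize_log(counts, scale, target))
  list(values = standardize_expression(f$values), dropped = f$dropped)
}

#' Assemble per-cell nuisance covariates
#'
#' Builds the standard confounder table used in the regression step:
#' `log_total_counts = log(1 + raw column total)`; for each named gene set,
#' the per-cell mean of normalized expression over the set (gene sets named
#' `cycle*` or `stress*` are additionally z-scored across cells, since only
#' their relative variation is meaningful). Gene sets that match no gene
#' are skipped with a warning. User extras are passed through.
#'
#' @param counts Raw counts matrix, genes x cells.
#' @param normalized Log-normalized matrix from [normalize_log()] (same cells).
#' @param gene_sets Named list of character vectors of gene ids. Defaults to
#'   mitochondrial (`^MT-`) and ribosomal (`^RPL|^RPS`) genes found in
#'   `rownames(counts)`, yielding `mito_fraction` / `ribo_fraction`.
#' @param extras Optional data frame with a `cell_id` column and extra
#'   numeric covariates; every `cell_id` must be a column of `counts`.
#' @return A tibble with `cell_id` and one numeric column per covariate.
#' @export
build_covariates <- function(counts, normalized = normalize_log(counts),
                             gene_sets = default_gene_sets(counts),
                             extras = NULL) {
  cell_ids <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  out <- tibble::tibble(
    cell_id = cell_ids,
    log_total_counts = unname(log1p(colSums(counts)))
  )
  for (nm in names(gene_sets)) {
    hits <- intersect(gene_sets[[nm]], rownames(normalized))
    if (!length(hits)) {
      warning("gene set '", nm, "' matches no genes; covariate skipped",
              call. = FALSE)
      next
    }
    score <- unname(colMeans(normalized[hits, , drop = FALSE]))
    if (grepl("^(cycle|stress)", nm)) {
      s <- stats::sd(score)
      score <- if (s > 0) (score - mean(score)) / s else score * 0
    }
    out[[nm]] <- score
  }
  if (!is.null(extras)) {
    if (!"cell_id" %in% names(extras)) stop_phiclust("`extras` needs a cell_id column")
    unknown <- setdiff(extras$cell_id, cell_ids)
    if (length(unknown)) {
      stop_phiclust("extras contain unknown cell ids: ",
                    paste(utils::head(unknown, 5), collapse = ", "))
    }
    out <- dplyr::left_join(out, extras, by = "cell_id")
  }
  out
}

#' @rdname build_covariates
#' @export
default_gene_sets <- function(counts) {
  g <- rownames(counts) %||% character(0)
  sets <- list(
    mito_fraction = grep("^MT-", g, value = TRUE),
    ribo_fraction = grep("^RPL|^RPS", g, value = TRUE)
  )
  sets[vapply(sets, length, 1L) > 0]
}
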