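# Tabular I/O: cell tables, core tables, clinical tables, expression
# matrices.  All formats are delimited text (comma default, tab accepted)
# or MatrixMarket triplets with plain-text name sidecars.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a per-cell intensity table
#'
#' Expects a delimited file with header and columns `cell_id`, `patient_id`,
#' `core_id`, `panel_id`, plus one intensity column per configured marker of
#' every panel that appears in `panel_id`. Unknown columns are preserved.
#'
#' @param path file path (comma- or tab-delimited, auto-detected).
#' @param config a [sia_config()] providing panel definitions.
#' @return `data.frame` of cell records, intensities as non-negative reals.
#' @export
read_cell_table <- function(path, config = sia_config()) {
  cells <- read_delim_table(path)
  stop_missing_cols(cells, c("cell_id", "patient_id", "core_id", "panel_id"),
                    "cell table")
  used_panels <- intersect(names(config$panels), unique(cells$panel_id))
  unknown <- setdiff(unique(cells$panel_id), names(config$panels))
  if (length(unknown)) {
    stop(sprintf("cell table references unconfigured panel(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (p in used_panels) {
    markers <- config$panels[[p]]
    stop_missing_cols(cells, markers, sprintf("cell table (panel '%s')", p))
    rows <- which(cells$panel_id == p)
    for (m in markers) {
      v <- cells[[m]][rows]
      bad <- rows[which(!is.na(v) & v < 0)]
      if (length(bad)) {
        stop(sprintf("negative intensity for marker '%s' at row %d",
                     m, bad[1]), call. = FALSE)
      }
    }
  }
  cells
}

#' Read a TMA core / tile metadata table
#'
#' Requires columns `core_id`, `patient_id`, `region` (one of `centre`,
#' `margin`, `bulk`) and `area_mm2` (> 0).
#'
#' @param path file path.
#' @return `data.frame` of core records.
#' @export
read_core_table <- function(path) {
  cores <- read_delim_table(path)
  stop_missing_cols(cores, c("core_id", "patient_id", "region", "area_mm2"),
                    "core table")
  bad_region <- setdiff(unique(cores$region), c("centre", "margin", "bulk"))
  if (length(bad_region)) {
    stop(sprintf("unknown region label(s): %s",
                 paste(bad_region, collapse = ", ")), call. = FALSE)
  }
  if (any(cores$area_mm2 <= 0)) stop("core area must be > 0", call. = FALSE)
  cores
}

#' Read a patient clinical table
#'
#' Requires `patient_id` and at least one of the endpoint pairs
#' (`os_time`, `os_event`) / (`rfs_time`, `rfs_event`); covariate columns
#' (`t_stage`, `n_stage`, `age_group`, `sex`, `msi`) are optional.
#'
#' @param path file path.
#' @return `data.frame` of survival records.
#' @export
read_clinical_table <- function(path) {
  clin <- read_delim_table(path)
  stop_missing_cols(clin, "patient_id", "clinical table")
  has_os <- all(c("os_time", "os_event") %in% names(clin))
  has_rfs <- all(c("rfs_time", "rfs_event") %in% names(clin))
  if (!has_os && !has_rfs) {
    stop("clinical table needs os_time/os_event and/or rfs_time/rfs_event",
         call. = FALSE)
  }
  for (col in intersect(c("os_time", "rfs_time"), names(clin))) {
    if (any(clin[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative survival time in column '%s'", col),
           call. = FALSE)
    }
  }
  clin
}

#' Read a gene expression matrix
#'
#' Dense layout: genes in rows, samples/cells in columns, first column gene
#' symbols. MTX layout: MatrixMarket coordinate file plus sidecar files
#' listing row (gene) and column (cell) names, one per line.
#'
#' Gene symbols are trimmed and matched case-insensitively; duplicate
#' symbols are collapsed by summation with a logged warning.
#'
#' @param path matrix file path.
#' @param layout `"dense"` or `"mtx"`.
#' @param genes_path,cells_path sidecar name files (mtx layout only;
#'   default `<path>.genes.txt` / `<path>.cells.txt`).
#' @return numeric matrix (dense) or `dgCMatrix` (mtx), genes in rows.
#' @export
read_expression_matrix <- function(path, layout = c("dense", "mtx"),
                                   genes_path = NULL, cells_path = NULL) {
  layout <- match.arg(layout)
  if (layout == "dense") {
    df <- read_delim_table(path)
    genes <- trimws(as.character(df[[1]]))
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
  } else {
    mat <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    genes_path <- genes_path %||% paste0(path, ".genes.txt")
    cells_path <- cells_path %||% paste0(path, ".cells.txt")
    rownames(mat) <- trimws(readLines(genes_path))
    colnames(mat) <- trimws(readLines(cells_path))
  }
  collapse_duplicate_genes(mat)
}

collapse_duplicate_genes <- function(mat) {
  key <- toupper(trimws(rownames(mat)))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    sia_log("collapsing %d duplicated gene symbol(s) by summation: %s",
            length(dup), paste(utils::head(dup, 5), collapse = ", "))
    first <- !duplicated(key)
    groups <- factor(key, levels = key[first])
    agg <- Matrix::sparse.model.matrix(~ 0 + groups)
    out <- Matrix::crossprod(agg, mat)
    rownames(out) <- rownames(mat)[first]
    if (is.matrix(mat)) out <- as.matrix(out)
    return(out)
  }
  mat
}

# Case-insensitive gene lookup; errors at scoring time, naming the gene.
gene_row <- function(mat, gene) {
  idx <- match(toupper(trimws(gene)), toupper(trimws(rownames(mat))))
  if (is.na(idx)) {
    stop(sprintf("gene '%s' not present in expression matrix", gene),
         call. = FALSE)
  }
  as.numeric(mat[idx, ])
}

#' Write a table as delimited text at full numeric precision
#'
#' Doubles are serialised with 17 significant digits so that a write/read
#' round trip reproduces values exactly.
#'
#' @param df data frame.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_table_precise <- function(df, path, delim = ",") {
  utils::write.table(format_full_precision(df), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dense expression matrix as delimited text
#'
#' @param mat numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.matrix(mat),
                   check.names = FALSE)
  write_table_precise(df, path)
}
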