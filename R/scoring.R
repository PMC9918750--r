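# SIA and Immunoscore-like metrics from densities, and their RNA
# surrogates from bulk and single-cell expression.

#' Signature of Immune Activation (SIA)
#'
#' SIA = CD8 density / (CD8 density + CD68+CD163+ macrophage density),
#' a value in \[0, 1\] balancing anti-tumoural cytotoxic T cells against
#' tumour-supportive M2-like macrophages. When both densities are zero the
#' score is undefined (NA) and should be excluded downstream.
#'
#' @param cd8_density,m2_density non-negative cell densities (cells/mm^2);
#'   vectorised.
#' @return numeric vector of SIA values in \[0, 1\], NA where undefined.
#' @export
compute_sia <- function(cd8_density, m2_density) {
  if (any(cd8_density < 0, na.rm = TRUE) || any(m2_density < 0, na.rm = TRUE)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  total <- cd8_density + m2_density
  n_undef <- sum(!is.na(total) & total == 0)
  if (n_undef > 0) {
    sia_log("SIA undefined for %d patient(s) with no CD8+ and no M2 cells",
            n_undef)
  }
  ifelse(!is.na(total) & total == 0, NA_real_, cd8_density / total)
}

#' Immunoscore-like mean-percentile metric
#'
#' Each density channel (CD3 and CD8, in tumour centre and invasive margin,
#' or in the bulk region) is percentile-ranked within the cohort
#' (percentile = 100 * rank / n over non-missing values, average ranks for
#' ties). A patient's score is the mean of their available percentiles —
#' four channels when complete, three when one region is missing, two in
#' bulk mode — and is categorised Low (<= 25), Intermediate (25-70] or
#' High (> 70).
#'
#' @param marker_densities long data frame with columns `patient_id`,
#'   `region`, `marker`, `density` (the `marker_densities` element of
#'   [compute_densities()]).
#' @param config a [sia_config()]; `is_region_mode` selects
#'   centre+margin (channels CD3/CD8 x centre/margin) or bulk
#'   (channels CD3/CD8 pooled over all cores).
#' @return data frame: `patient_id`, `n_channels`, `is_percentile`,
#'   `is_category`.
#' @export
compute_is <- function(marker_densities, config = sia_config()) {
  if (config$is_region_mode == "centre_margin") {
    channels <- expand.grid(marker = c("CD3", "CD8"),
                            region = c("centre", "margin"),
                            stringsAsFactors = FALSE)
  } else {
    channels <- data.frame(marker = c("CD3", "CD8"), region = "all",
                           stringsAsFactors = FALSE)
  }
  patients <- unique(marker_densities$patient_id)
  if (length(patients) < 3L) {
    stop("Immunoscore needs a cohort of at least 3 patients", call. = FALSE)
  }
  pct <- matrix(NA_real_, length(patients), nrow(channels),
                dimnames = list(patients, NULL))
  for (k in seq_len(nrow(channels))) {
    d <- marker_densities[marker_densities$marker == channels$marker[k] &
                          marker_densities$region == channels$region[k], ]
    v <- d$density[match(patients, d$patient_id)]
    n_ok <- sum(!is.na(v))
    if (n_ok > 0) {
      pct[, k] <- 100 * rank(v, ties.method = "average",
                             na.last = "keep") / n_ok
    }
  }
  n_channels <- rowSums(!is.na(pct))
  is_pct <- rowMeans(pct, na.rm = TRUE)
  is_pct[n_channels == 0] <- NA_real_
  if (any(n_channels == 0)) {
    sia_log("Immunoscore undefined for %d patient(s) with no channel data",
            sum(n_channels == 0))
  }
  b <- config$is_bounds
  cat_lab <- ifelse(is.na(is_pct), NA_character_,
                    ifelse(is_pct <= b[1], "Low",
                           ifelse(is_pct <= b[2], "Intermediate", "High")))
  data.frame(patient_id = patients, n_channels = n_channels,
             is_percentile = unname(is_pct),
             is_category = factor(cat_lab,
                                  levels = c("Low", "Intermediate", "High")),
             row.names = NULL, stringsAsFactors = FALSE)
}

ensure_linear <- function(mat) {
  if (identical(attr(mat, "scale"), "log2")) {
    mat <- 2^mat
    attr(mat, "scale") <- "linear"
  }
  mat
}

#' Bulk RNA surrogate of SIA: the CD8A / C1Q ratio
#'
#' Per sample, score = CD8A expression / C1Q subunit expression (linear
#' scale; a matrix with attribute `scale = "log2"` is exponentiated first).
#' When sample metadata carry a `timepoint`, only pre-therapy samples are
#' scored; patients with several samples get the mean of their sample
#' scores. A zero denominator with positive CD8A yields +Inf (ranked top);
#' 0/0 is undefined (NA).
#'
#' @param mat expression matrix, genes in rows.
#' @param denominator one of `"C1QA"`, `"C1QB"`, `"C1QC"`.
#' @param sample_info optional data frame with `sample_id` (matching matrix
#'   columns) and optional `patient_id`, `timepoint` columns.
#' @param pre_label timepoint label(s) identifying pre-therapy samples.
#' @return data frame keyed by patient (or sample when no metadata):
#'   `id`, `sia_rna`, `n_samples`.
#' @export
rna_sia <- function(mat, denominator = c("C1QA", "C1QB", "C1QC"),
                    sample_info = NULL, pre_label = "pre") {
  denominator <- match.arg(denominator)
  mat <- ensure_linear(mat)
  num <- gene_row(mat, "CD8A")
  den <- gene_row(mat, denominator)
  score <- ifelse(num == 0 & den == 0, NA_real_, num / den)
  ids <- colnames(mat) %||% as.character(seq_along(score))
  if (is.null(sample_info)) {
    return(data.frame(id = ids, sia_rna = score, n_samples = 1L,
                      stringsAsFactors = FALSE))
  }
  info <- sample_info[match(ids, sample_info$sample_id), , drop = FALSE]
  keep <- rep(TRUE, length(score))
  if (!is.null(info$timepoint)) {
    keep <- info$timepoint %in% pre_label
    sia_log("pre-therapy filter kept %d of %d samples", sum(keep),
            length(keep))
  }
  score <- score[keep]
  pid <- if (is.null(info$patient_id)) ids[keep] else info$patient_id[keep]
  agg <- tapply(score, pid, mean)
  n <- tapply(score, pid, length)
  data.frame(id = names(agg), sia_rna = unname(agg),
             n_samples = as.integer(n[names(agg)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bulk RNA Immunoscore-like metric: mean of CD8A and CD3E
#'
#' @param mat expression matrix, genes in rows (linear scale; log2 input
#'   is exponentiated first).
#' @return data frame: `id`, `is_like` = (CD8A + CD3E) / 2 per sample.
#' @export
rna_is_like <- function(mat) {
  mat <- ensure_linear(mat)
  score <- (gene_row(mat, "CD8A") + gene_row(mat, "CD3E")) / 2
  data.frame(id = colnames(mat) %||% as.character(seq_along(score)),
             is_like = score, stringsAsFactors = FALSE)
}

#' Single-cell quality-control filter
#'
#' Keeps cells with at least `min_genes` detected genes (count > 0) and a
#' mitochondrial count fraction at most `mito_ceiling`. Mitochondrial genes
#' are identified by symbol prefix. If no mitochondrial gene is present the
#' mitochondrial filter is skipped with a warning.
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param config a [sia_config()] (fields `min_genes`, `mito_ceiling`,
#'   `mito_prefix`).
#' @return list: `counts` (filtered), `keep` (logical per input cell),
#'   `report` (data frame of removal counts per criterion).
#' @export
sc_qc_filter <- function(counts, config = sia_config()) {
  detected <- Matrix::colSums(counts > 0)
  keep_genes <- detected >= config$min_genes
  mito <- startsWith(rownames(counts), config$mito_prefix)
  if (!any(mito)) {
    warning("no mitochondrial genes found (prefix '", config$mito_prefix,
            "'); mitochondrial filter skipped")
    keep_mito <- rep(TRUE, ncol(counts))
    mito_frac <- rep(NA_real_, ncol(counts))
  } else {
    total <- Matrix::colSums(counts)
    mito_frac <- ifelse(total == 0, 0,
                        Matrix::colSums(counts[mito, , drop = FALSE]) / total)
    keep_mito <- mito_frac <= config$mito_ceiling
  }
  keep <- keep_genes & keep_mito
  report <- data.frame(
    criterion = c(sprintf("detected genes < %d", config$min_genes),
                  sprintf("mitochondrial fraction > %g", config$mito_ceiling),
                  "kept"),
    n = c(sum(!keep_genes), sum(keep_genes & !keep_mito), sum(keep)))
  sia_log("single-cell QC kept %d / %d cells", sum(keep), ncol(counts))
  list(counts = counts[, keep, drop = FALSE], keep = keep, report = report)
}

#' Single-cell SIA from marker-positive cell counts
#'
#' Per patient (or lesion), counts cells positive for CD8A and cells
#' positive for both genes of the chosen M2-macrophage definition, then
#' SIA = n_CD8 / (n_CD8 + n_M2); undefined (NA) when both counts are zero.
#' Positivity is expression strictly greater than the configured threshold
#' (default 0, i.e. any nonzero count).
#'
#' @param counts QC-filtered genes x cells count matrix.
#' @param cell_info data frame aligned with matrix columns, with a
#'   `patient_id` column (any extra columns such as `response` are carried
#'   through the per-patient output).
#' @param m2_definition one of `"CD68&CD163"`, `"CD68&C1QA"`,
#'   `"CD68&C1QB"`, `"CD68&C1QC"`.
#' @param config a [sia_config()] (`sc_positivity_threshold`).
#' @return data frame: `patient_id`, `n_cd8`, `n_m2`, `sia`, plus any
#'   patient-constant metadata columns of `cell_info`.
#' @export
sc_sia <- function(counts, cell_info,
                   m2_definition = c("CD68&CD163", "CD68&C1QA",
                                     "CD68&C1QB", "CD68&C1QC"),
                   config = sia_config()) {
  m2_definition <- match.arg(m2_definition)
  if (ncol(counts) != nrow(cell_info)) {
    stop("cell_info must have one row per matrix column", call. = FALSE)
  }
  thr <- config$sc_positivity_threshold
  pair <- strsplit(m2_definition, "&", fixed = TRUE)[[1]]
  cd8_pos <- gene_row(counts, "CD8A") > thr
  m2_pos <- gene_row(counts, pair[1]) > thr & gene_row(counts, pair[2]) > thr
  pid <- cell_info$patient_id
  patients <- unique(pid)
  n_cd8 <- as.integer(tapply(cd8_pos, factor(pid, patients), sum))
  n_m2 <- as.integer(tapply(m2_pos, factor(pid, patients), sum))
  out <- data.frame(patient_id = patients, n_cd8 = n_cd8, n_m2 = n_m2,
                    sia = compute_sia(as.numeric(n_cd8), as.numeric(n_m2)),
                    stringsAsFactors = FALSE)
  # carry patient-constant metadata (e.g. response labels)
  for (col in setdiff(names(cell_info), c("patient_id", "cell_id"))) {
    per_pat <- tapply(cell_info[[col]], factor(pid, patients),
                      function(x) if (length(unique(x)) == 1L) x[1] else NA)
    out[[col]] <- unname(unlist(per_pat))
  }
  out
}
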