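#' Default antibody panels
#'
#' The two multiplex IHC panels: a lymphocyte panel (CD4, CD8, CD20, FoxP3,
#' CD45RO, pan-cytokeratin) and an NK/macrophage panel (CD56, NKp46, CD3,
#' CD68, CD163, pan-cytokeratin).
#'
#' @return Named list of character vectors, one per panel.
#' @export
default_panels <- function() {
  list(
    lymphocyte    = c("CD4", "CD8", "CD20", "FoxP3", "CD45RO", "CK"),
    nk_macrophage = c("CD56", "NKp46", "CD3", "CD68", "CD163", "CK")
  )
}

#' Run configuration for the scoring pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' All stochastic operations accept a seed so that a fixed configuration
#' reproduces bit-for-bit.
#'
#' @param panels named list mapping panel id to ordered marker names.
#' @param rules classification rule table, see [default_rule_table()].
#' @param tercile_cuts two strictly increasing percentiles in (0, 100) used
#'   to stratify scores into low/intermediate/high (default 33.3, 66.6).
#' @param is_bounds two strictly increasing Immunoscore category bounds in
#'   (0, 100); Low is below the first, High above the second (default 25, 70).
#' @param is_region_mode `"centre_margin"` (CD3/CD8 in tumour centre and
#'   invasive margin, up to four channels) or `"bulk"` (two channels).
#' @param sc_positivity_threshold single-cell expression above this count
#'   marks a cell positive for a gene (default 0, i.e. any nonzero count).
#' @param min_genes minimum detected genes per cell for single-cell QC
#'   (default 250; some droplet data sets warrant 100).
#' @param mito_ceiling maximum mitochondrial count fraction per cell,
#'   interpreted as a fraction (default 0.05 = 5%). A literal 0.05% rule can
#'   be requested by passing 0.0005.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @param bootstrap_replicates bootstrap resamples for AUC distributions.
#' @param ks_iterations iterations of the tile-resampling representativeness
#'   test.
#' @param alpha significance level (default 0.05).
#' @param cutoff_window quantile window searched by optimal-cutoff
#'   dichotomisation (default c(0.10, 0.90)).
#' @param error_min_priors `"empirical"` (reference-set proportions) or
#'   `"equal"` class priors in the threshold misclassification functional.
#' @param seed optional integer seed applied by stochastic operations.
#'
#' @return A validated list of class `sia_config`.
#' @export
sia_config <- function(panels = default_panels(),
                       rules = default_rule_table(),
                       tercile_cuts = c(33.3, 66.6),
                       is_bounds = c(25, 70),
                       is_region_mode = c("centre_margin", "bulk"),
                       sc_positivity_threshold = 0,
                       min_genes = 250,
                       mito_ceiling = 0.05,
                       mito_prefix = "MT-",
                       bootstrap_replicates = 1000,
                       ks_iterations = 1000,
                       alpha = 0.05,
                       cutoff_window = c(0.10, 0.90),
                       error_min_priors = c("empirical", "equal"),
                       seed = NULL) {
  is_region_mode <- match.arg(is_region_mode)
  error_min_priors <- match.arg(error_min_priors)
  stopifnot(
    length(tercile_cuts) == 2, all(tercile_cuts > 0), all(tercile_cuts < 100),
    tercile_cuts[1] < tercile_cuts[2],
    length(is_bounds) == 2, all(is_bounds > 0), all(is_bounds < 100),
    is_bounds[1] < is_bounds[2],
    min_genes >= 0, mito_ceiling >= 0, mito_ceiling <= 1,
    bootstrap_replicates >= 1, ks_iterations >= 1,
    alpha > 0, alpha < 1,
    length(cutoff_window) == 2, cutoff_window[1] >= 0, cutoff_window[2] <= 1,
    cutoff_window[1] <= cutoff_window[2]
  )
  cfg <- list(
    panels = panels, rules = rules,
    tercile_cuts = tercile_cuts, is_bounds = is_bounds,
    is_region_mode = is_region_mode,
    sc_positivity_threshold = sc_positivity_threshold,
    min_genes = min_genes, mito_ceiling = mito_ceiling,
    mito_prefix = mito_prefix,
    bootstrap_replicates = bootstrap_replicates,
    ks_iterations = ks_iterations, alpha = alpha,
    cutoff_window = cutoff_window,
    error_min_priors = error_min_priors,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sia_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Fields absent from the file keep their [sia_config()] defaults. The rule
#' table, if given, must be a list of records with fields `panel`,
#' `positive`, `negative`, `class`.
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file
#'   (used by the command-line interface for flag overrides).
#' @return A `sia_config` object.
#' @export
read_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$rules)) {
    raw$rules <- do.call(rbind, lapply(raw$rules, function(r) {
      data.frame(panel = r$panel,
                 positive = paste(r$positive, collapse = ","),
                 negative = paste(r$negative %||% character(), collapse = ","),
                 class = r$class)
    }))
  }
  known <- intersect(names(raw), names(formals(sia_config)))
  do.call(sia_config, raw[known])
}
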