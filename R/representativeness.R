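# In-silico TMA resampling: does a single random tile per whole-slide
# section represent the slide-wide marker density distribution?

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical
#' cumulative distribution functions; the p-value is exact for small
#' tie-free samples and asymptotic otherwise (ties are tolerated with the
#' asymptotic approximation).
#'
#' @param a,b non-empty numeric samples.
#' @return list: `d`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(d = unname(kt$statistic), p = min(1, unname(kt$p.value)))
}

#' Tile-resampling representativeness test
#'
#' Per iteration, one tile is drawn at random from each whole-slide
#' section, forming a small in-silico TMA cohort; for each marker the
#' cohort's densities are compared with the remaining tiles by a
#' two-sample Kolmogorov-Smirnov test, and the iteration is significant
#' if p < alpha. The fraction of significant iterations per marker over
#' `n_iter` repeats estimates how often single-tile sampling misrepresents
#' the slides; under exchangeable tiles it approaches alpha.
#'
#' The default comparison pools the remaining tiles of all slides into one
#' reference sample (one KS test per marker per iteration). The
#' `"per_slide"` variant tests the cohort against each slide's own
#' remaining tiles and flags the iteration if any slide's
#' Bonferroni-adjusted p falls below alpha.
#'
#' @param tiles tile grid data frame (see [simulate_tile_grid()]):
#'   `slide_id`, `tile_id`, density columns.
#' @param markers density columns to test (default: every column other
#'   than `slide_id`, `tile_id`, `area_mm2`).
#' @param n_iter iterations (default 1000).
#' @param alpha significance level (default 0.05, strict `p < alpha`).
#' @param comparison `"pooled"` (default) or `"per_slide"`.
#' @param seed optional integer seed.
#' @return data frame: `marker`, `fraction_significant`, `n_iter`,
#'   `alpha`, `comparison`; attribute `selections` holds the matrix of
#'   selected tile ids (iterations x slides).
#' @export
representativeness_test <- function(tiles, markers = NULL, n_iter = 1000,
                                    alpha = 0.05,
                                    comparison = c("pooled", "per_slide"),
                                    seed = NULL) {
  comparison <- match.arg(comparison)
  set_seed_if(seed)
  markers <- markers %||% setdiff(names(tiles),
                                  c("slide_id", "tile_id", "area_mm2"))
  missing <- setdiff(markers, names(tiles))
  if (length(missing)) {
    stop(sprintf("marker(s) absent from tile grid: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  slides <- unique(tiles$slide_id)
  if (length(slides) < 2L) stop("need at least 2 slides", call. = FALSE)
  idx_by_slide <- split(seq_len(nrow(tiles)), tiles$slide_id)[slides]
  if (any(lengths(idx_by_slide) < 2L)) {
    stop("every slide needs at least 2 tiles", call. = FALSE)
  }
  n_sig <- stats::setNames(numeric(length(markers)), markers)
  selections <- matrix(NA_character_, n_iter, length(slides),
                       dimnames = list(NULL, slides))
  for (it in seq_len(n_iter)) {
    picked <- vapply(idx_by_slide, function(ix) ix[sample.int(length(ix), 1)],
                     integer(1))
    selections[it, ] <- tiles$tile_id[picked]
    rest <- setdiff(seq_len(nrow(tiles)), picked)
    for (m in markers) {
      if (comparison == "pooled") {
        p <- ks_two_sample(tiles[[m]][picked], tiles[[m]][rest])$p
      } else {
        ps <- vapply(seq_along(slides), function(s) {
          own_rest <- setdiff(idx_by_slide[[s]], picked[s])
          ks_two_sample(tiles[[m]][picked], tiles[[m]][own_rest])$p
        }, numeric(1))
        p <- min(stats::p.adjust(ps, method = "bonferroni"))
      }
      if (p < alpha) n_sig[m] <- n_sig[m] + 1
    }
  }
  out <- data.frame(marker = markers,
                    fraction_significant = unname(n_sig) / n_iter,
                    n_iter = n_iter, alpha = alpha, comparison = comparison,
                    stringsAsFactors = FALSE)
  attr(out, "selections") <- selections
  out
}
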