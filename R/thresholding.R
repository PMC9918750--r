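# Marker positivity thresholds from labelled positive/negative reference
# cells.  Non-overlapping references get the midpoint rule; overlapping
# references get the intensity minimising the KDE-based overall
# classification error.

#' Gaussian kernel density estimate on a fixed grid
#'
#' Bandwidth is Silverman's rule of thumb (`stats::bw.nrd0`), the automatic
#' default of `stats::density()`. The estimate is evaluated on a 512-point
#' grid spanning `[min - 3h, max + 3h]` and integrates to 1 (trapezoid rule)
#' within 1e-3.
#'
#' @param values numeric intensities with at least 2 distinct values.
#' @param n_grid grid size (default 512).
#' @return list with elements `x`, `y`, `bw`.
#' @export
estimate_density <- function(values, n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L) {
    stop("density estimation needs at least 2 distinct values",
         call. = FALSE)
  }
  h <- stats::bw.nrd0(values)
  d <- stats::density(values, bw = h, n = n_grid,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  list(x = d$x, y = d$y, bw = h)
}

#' Determine a marker positivity threshold from reference cells
#'
#' If the positive and negative reference intensities do not overlap the
#' threshold is the midpoint between the highest negative and the lowest
#' positive intensity (`rule = "midpoint"`). If they overlap, the threshold
#' minimises the overall classification error
#' \deqn{err(t) = \pi_{neg} \int_t^\infty \hat f_{neg} +
#'               \pi_{pos} \int_{-\infty}^t \hat f_{pos}}
#' over the union of the two KDE grids (`rule = "error_min"`); ties go to
#' the smallest t. Class priors default to the empirical reference-set
#' proportions. A cell is called positive iff its intensity is strictly
#' greater than the threshold; FPR/TPR/FNR/TNR are computed empirically on
#' the reference cells at the returned threshold.
#'
#' @param pos_ref,neg_ref intensities of reference cells labelled positive
#'   / negative; both non-empty.
#' @param priors `"empirical"` or `"equal"` class priors for the error
#'   functional.
#' @param marker optional marker name carried into the result.
#' @return list of class `sia_threshold`: `marker`, `threshold`, `rule`,
#'   `fpr`, `tpr`, `fnr`, `tnr`, `error`, `n_pos_ref`, `n_neg_ref`.
#' @export
determine_threshold <- function(pos_ref, neg_ref,
                                priors = c("empirical", "equal"),
                                marker = NA_character_) {
  priors <- match.arg(priors)
  pos_ref <- pos_ref[!is.na(pos_ref)]
  neg_ref <- neg_ref[!is.na(neg_ref)]
  if (!length(pos_ref) || !length(neg_ref)) {
    stop("both reference sets must be non-empty", call. = FALSE)
  }
  if (length(pos_ref) == length(neg_ref) &&
      all(sort(pos_ref) == sort(neg_ref))) {
    warning("positive and negative reference sets are identical; ",
            "falling back to the error-minimisation rule")
  }

  if (max(neg_ref) < min(pos_ref)) {
    t_star <- (max(neg_ref) + min(pos_ref)) / 2
    rule <- "midpoint"
  } else {
    t_star <- error_min_threshold(pos_ref, neg_ref, priors)
    rule <- "error_min"
  }

  fpr <- mean(neg_ref > t_star)
  tpr <- mean(pos_ref > t_star)
  if (rule == "error_min" && fpr >= tpr) {
    warning(sprintf(paste0("threshold for '%s': FPR %.2f >= TPR %.2f on ",
                           "the reference cells - inverted or ",
                           "uninformative marker"),
                    marker, fpr, tpr))
  }
  if (priors == "empirical") {
    w_pos <- length(pos_ref) / (length(pos_ref) + length(neg_ref))
  } else {
    w_pos <- 0.5
  }
  res <- list(marker = marker, threshold = t_star, rule = rule,
              fpr = fpr, tpr = tpr, fnr = 1 - tpr, tnr = 1 - fpr,
              error = (1 - w_pos) * fpr + w_pos * (1 - tpr),
              n_pos_ref = length(pos_ref), n_neg_ref = length(neg_ref))
  class(res) <- "sia_threshold"
  res
}

# Exact CDF of the Gaussian KDE fitted to x with bandwidth h: the mixture
# of kernel CDFs, evaluated without numerical integration.
kde_cdf <- function(t, x, h) {
  vapply(t, function(t0) mean(stats::pnorm(t0, mean = x, sd = h)),
         numeric(1))
}

# KDE misclassification functional minimised over the union grid of the
# two density estimates, restricted to the observed intensity range (a
# threshold outside the data degenerates to an all-positive or
# all-negative call).
error_min_threshold <- function(pos_ref, neg_ref, priors = "empirical") {
  f_pos <- estimate_density(pos_ref)
  f_neg <- estimate_density(neg_ref)
  lo <- min(pos_ref, neg_ref); hi <- max(pos_ref, neg_ref)
  grid <- sort(unique(c(f_pos$x, f_neg$x, lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  if (priors == "empirical") {
    w_pos <- length(pos_ref) / (length(pos_ref) + length(neg_ref))
  } else {
    w_pos <- 0.5
  }
  err <- (1 - w_pos) * (1 - kde_cdf(grid, neg_ref, f_neg$bw)) +
    w_pos * kde_cdf(grid, pos_ref, f_pos$bw)
  grid[which.min(err)]   # which.min returns the first (smallest t) on ties
}

#' Determine thresholds for every marker of a reference table
#'
#' @param ref data frame with columns `marker`, `intensity`, `label`
#'   (`"pos"` / `"neg"`).
#' @param priors see [determine_threshold()].
#' @return data frame, one row per marker, with threshold, rule and error
#'   rates.
#' @export
determine_thresholds <- function(ref, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  stop_missing_cols(ref, c("marker", "intensity", "label"),
                    "reference table")
  rows <- lapply(split(ref, ref$marker), function(d) {
    r <- determine_threshold(d$intensity[d$label == "pos"],
                             d$intensity[d$label == "neg"],
                             priors = priors, marker = d$marker[1])
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply marker thresholds to a cell table
#'
#' Adds one logical column `pos_<marker>` per thresholded marker; a cell is
#' positive iff its intensity is strictly greater than the threshold
#' (intensity exactly equal to the threshold is negative). Idempotent.
#'
#' @param cells cell table (see [read_cell_table()]).
#' @param thresholds data frame from [determine_thresholds()] or a named
#'   numeric vector of thresholds.
#' @param config a [sia_config()]; every configured marker of each panel
#'   present in `cells` must have a threshold.
#' @return `cells` with positivity flag columns added.
#' @export
apply_thresholds <- function(cells, thresholds, config = sia_config()) {
  if (is.data.frame(thresholds)) {
    thr <- stats::setNames(thresholds$threshold, thresholds$marker)
  } else {
    thr <- thresholds
  }
  used_panels <- intersect(names(config$panels), unique(cells$panel_id))
  needed <- unique(unlist(config$panels[used_panels]))
  missing <- setdiff(needed, names(thr))
  if (length(missing)) {
    stop(sprintf("no threshold for marker(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (m in needed) {
    flag <- rep(NA, nrow(cells))
    for (p in used_panels) {
      if (m %in% config$panels[[p]]) {
        rows <- cells$panel_id == p
        flag[rows] <- cells[[m]][rows] > thr[[m]]
      }
    }
    cells[[paste0("pos_", m)]] <- flag
  }
  cells
}
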