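# Cell classification by marker-combination rules and area-normalised
# density computation.

#' Default immune cell classification rule table
#'
#' An ordered rule table (first matching rule wins) covering the two
#' default panels. Pan-cytokeratin positive cells are labelled `tumour`
#' and excluded from immune densities. The table defines 15 immune cell
#' classes; the published supplementary class definitions are not
#' reproduced verbatim anywhere, so this default is a documented
#' reconstruction from the panel marker combinations and is fully
#' configurable.
#'
#' @return data frame with columns `panel`, `positive`, `negative`,
#'   `class` (marker lists comma-separated).
#' @export
default_rule_table <- function() {
  r <- function(panel, positive, negative, class) {
    data.frame(panel = panel, positive = positive, negative = negative,
               class = class, stringsAsFactors = FALSE)
  }
  rbind(
    r("lymphocyte", "CK", "", "tumour"),
    r("lymphocyte", "CD8,FoxP3", "CK", "CD8+FoxP3+ regulatory T cell"),
    r("lymphocyte", "CD8,CD45RO", "CK", "CD8+CD45RO+ memory cytotoxic T cell"),
    r("lymphocyte", "CD8", "CK", "CD8+ cytotoxic T cell"),
    r("lymphocyte", "CD4,FoxP3", "CK", "CD4+FoxP3+ regulatory T cell"),
    r("lymphocyte", "CD4,CD45RO", "CK", "CD4+CD45RO+ memory helper T cell"),
    r("lymphocyte", "CD4", "CK", "CD4+ helper T cell"),
    r("lymphocyte", "CD20", "CK", "CD20+ B cell"),
    r("lymphocyte", "FoxP3", "CK", "FoxP3+ regulatory T cell"),
    r("lymphocyte", "CD45RO", "CK", "CD45RO+ memory lymphocyte"),
    r("nk_macrophage", "CK", "", "tumour"),
    r("nk_macrophage", "CD3,CD56", "CK", "CD3+CD56+ NKT-like cell"),
    r("nk_macrophage", "CD56", "CD3,CK", "NK cell"),
    r("nk_macrophage", "NKp46", "CD3,CK", "NK cell"),
    r("nk_macrophage", "CD68,CD163", "CK", "CD68+CD163+ macrophage"),
    r("nk_macrophage", "CD68", "CD163,CK", "CD68+CD163- macrophage"),
    r("nk_macrophage", "CD163", "CD68,CK", "CD68-CD163+ cell"),
    r("nk_macrophage", "CD3", "CK", "CD3+ T cell")
  )
}

split_markers <- function(x) {
  x <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  x[nzchar(x)]
}

#' Classify positivity-flagged cells into immune classes
#'
#' Applies the ordered rule table within each panel: the first rule whose
#' required-positive markers are all flagged positive and required-negative
#' markers all flagged negative assigns the class. Cells matching no rule
#' are labelled `"unclassified"`.
#'
#' @param cells cell table with `pos_<marker>` flags
#'   (see [apply_thresholds()]).
#' @param rules rule table (default [default_rule_table()]).
#' @param config a [sia_config()].
#' @return `cells` with a `class_label` column.
#' @export
classify_cells <- function(cells, rules = NULL, config = sia_config()) {
  rules <- rules %||% config$rules
  key <- paste(rules$panel, rules$positive, rules$negative)
  if (anyDuplicated(key)) {
    warning("rule table contains duplicated marker patterns; ",
            "the first occurrence wins")
  }
  label <- rep(NA_character_, nrow(cells))
  for (p in unique(rules$panel)) {
    in_panel <- cells$panel_id == p
    if (!any(in_panel)) next
    panel_markers <- config$panels[[p]]
    for (i in which(rules$panel == p)) {
      pos <- split_markers(rules$positive[i])
      neg <- split_markers(rules$negative[i])
      bad <- setdiff(c(pos, neg), panel_markers)
      if (length(bad)) {
        stop(sprintf("rule '%s' references marker(s) absent from panel '%s': %s",
                     rules$class[i], p, paste(bad, collapse = ", ")),
             call. = FALSE)
      }
      match_i <- in_panel & is.na(label)
      for (m in pos) match_i <- match_i & cells[[paste0("pos_", m)]]
      for (m in neg) match_i <- match_i & !cells[[paste0("pos_", m)]]
      label[match_i] <- rules$class[i]
    }
  }
  label[is.na(label)] <- "unclassified"
  cells$class_label <- label
  cells
}

#' Compute per-patient, area-normalised cell densities
#'
#' Densities pool all of a patient's cores: density = total cell count
#' across cores / total tissue area, never a mean of per-core densities.
#' Region-stratified densities pool within region. Class densities cover
#' every class of the rule table; marker densities count non-tumour cells
#' flagged positive for each marker (the inputs to SIA and the
#' Immunoscore). Cells with a TRUE `excluded` column (necrosis/debris
#' curation) are dropped before counting.
#'
#' @param cells classified cell table (see [classify_cells()]).
#' @param cores core table (see [read_core_table()]); every `core_id` in
#'   `cells` must be present.
#' @param config a [sia_config()].
#' @return list with data frames `class_densities` and `marker_densities`
#'   (columns `patient_id`, `region` — `"all"` pools every region —,
#'   `class`/`marker`, `n_cells`, `area_mm2`, `density`).
#' @export
compute_densities <- function(cells, cores, config = sia_config()) {
  if (nrow(cells) && is.null(cells$class_label)) {
    stop("cells carry no class_label; run classify_cells() first",
         call. = FALSE)
  }
  unknown <- setdiff(unique(cells$core_id), cores$core_id)
  if (length(unknown)) {
    stop(sprintf("cell(s) reference unknown core(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(cells$excluded)) cells <- cells[!cells$excluded, , drop = FALSE]
  cells$region <- cores$region[match(cells$core_id, cores$core_id)]

  area_of <- function(core_subset) {
    stats::aggregate(area_mm2 ~ patient_id, core_subset, sum)
  }
  dens_one <- function(cell_subset, value_col, region_label, cores_used) {
    areas <- area_of(cores_used)
    values <- unique(value_col$value)
    if (!length(values)) {
      return(data.frame(patient_id = character(), value = character(),
                        n_cells = integer(), area_mm2 = numeric(),
                        region = character(), density = numeric(),
                        stringsAsFactors = FALSE))
    }
    grid <- expand.grid(patient_id = areas$patient_id, value = values,
                        stringsAsFactors = FALSE)
    cnt <- table(factor(value_col$patient_id, levels = areas$patient_id),
                 factor(value_col$value, levels = values))
    grid$n_cells <- as.vector(cnt[cbind(match(grid$patient_id, areas$patient_id),
                                        match(grid$value, values))])
    grid$area_mm2 <- areas$area_mm2[match(grid$patient_id, areas$patient_id)]
    grid$region <- region_label
    grid$density <- grid$n_cells / grid$area_mm2
    grid
  }

  regions <- c("all", unique(cores$region))
  class_rows <- list(); marker_rows <- list()
  immune <- cells[cells$class_label != "tumour", , drop = FALSE]
  markers <- unique(unlist(config$panels))
  markers <- setdiff(markers, "CK")
  for (rg in regions) {
    cores_rg <- if (rg == "all") cores else cores[cores$region == rg, , drop = FALSE]
    if (!nrow(cores_rg)) next
    cells_rg <- cells[cells$core_id %in% cores_rg$core_id, , drop = FALSE]
    immune_rg <- immune[immune$core_id %in% cores_rg$core_id, , drop = FALSE]
    class_rows[[rg]] <- dens_one(
      cells_rg,
      data.frame(patient_id = cells_rg$patient_id,
                 value = cells_rg$class_label, stringsAsFactors = FALSE),
      rg, cores_rg)
    per_marker <- lapply(markers, function(m) {
      col <- paste0("pos_", m)
      if (is.null(immune_rg[[col]])) return(NULL)
      hit <- immune_rg[!is.na(immune_rg[[col]]) & immune_rg[[col]], ,
                       drop = FALSE]
      d <- dens_one(hit,
                    data.frame(patient_id = hit$patient_id,
                               value = rep(m, nrow(hit)),
                               stringsAsFactors = FALSE),
                    rg, cores_rg)
      if (!nrow(d)) {   # no positive cell anywhere: emit zero rows
        areas <- area_of(cores_rg)
        d <- data.frame(patient_id = areas$patient_id, value = m,
                        n_cells = 0L, area_mm2 = areas$area_mm2,
                        region = rg, density = 0)
      }
      d
    })
    marker_rows[[rg]] <- do.call(rbind, per_marker)
  }
  class_densities <- do.call(rbind, class_rows)
  names(class_densities)[names(class_densities) == "value"] <- "class"
  marker_densities <- do.call(rbind, marker_rows)
  names(marker_densities)[names(marker_densities) == "value"] <- "marker"
  rownames(class_densities) <- rownames(marker_densities) <- NULL
  list(class_densities = class_densities,
       marker_densities = marker_densities)
}

#' Co-expression summary for a marker pair
#'
#' Counts cells positive for only the first marker, only the second, or
#' both, and reports the fraction of each single-positive compartment that
#' is double-positive (e.g. the share of CD68+ macrophages that co-express
#' CD163).
#'
#' @param cells cell table with positivity flags for both markers.
#' @param marker_a,marker_b marker names.
#' @return list: `a_only`, `b_only`, `both`, `neither`, `frac_a_double`
#'   (both / all a-positive), `frac_b_double`.
#' @export
coexpression_summary <- function(cells, marker_a, marker_b) {
  a <- cells[[paste0("pos_", marker_a)]]
  b <- cells[[paste0("pos_", marker_b)]]
  if (is.null(a) || is.null(b)) {
    stop("both markers must carry positivity flags", call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  both <- sum(a & b); a_only <- sum(a & !b); b_only <- sum(!a & b)
  list(a_only = a_only, b_only = b_only, both = both,
       neither = sum(!a & !b),
       frac_a_double = if (a_only + both > 0) both / (a_only + both) else 0,
       frac_b_double = if (b_only + both > 0) both / (b_only + both) else 0)
}

#' Stratify per-patient scores into terciles (with median-split fallback)
#'
#' Cut points are the linearly interpolated empirical percentiles (default
#' 33.3 and 66.6); ties go to the lower stratum (value <= cut). When the
#' two cut points coincide, or when a single value is shared by at least a
#' third of the patients (as happens when many patients sit at the maximum
#' possible score), the stratification switches to a median split
#' (low: value <= median, high: value > median) and logs the switch.
#' Missing scores are excluded and returned as NA.
#'
#' @param values per-patient scores.
#' @param cuts two percentiles in (0, 100).
#' @return factor with levels `low`/`intermediate`/`high` (tercile mode) or
#'   `low`/`high` (median mode); attribute `method` records which rule was
#'   applied and `cutpoints` the cut values.
#' @export
categorize_tercile <- function(values, cuts = c(33.3, 66.6)) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 3L) {
    stop("tercile stratification needs at least 3 non-missing values",
         call. = FALSE)
  }
  if (length(unique(v)) == 1L) {
    stop("all values identical: no informative split", call. = FALSE)
  }
  c12 <- unname(stats::quantile(v, cuts / 100, type = 7))
  modal_share <- max(table(v)) / length(v)
  if (c12[1] == c12[2] || modal_share >= 1 / 3) {
    med <- stats::median(v)
    sia_log(paste0("tercile cuts degenerate or a single value covers ",
                   "%.0f%% of patients; switching to median split at %g"),
            100 * modal_share, med)
    out <- rep(NA_character_, length(values))
    out[ok] <- ifelse(v <= med, "low", "high")
    f <- factor(out, levels = c("low", "high"))
    attr(f, "method") <- "median"
    attr(f, "cutpoints") <- med
    return(f)
  }
  out <- rep(NA_character_, length(values))
  out[ok] <- ifelse(v <= c12[1], "low",
                    ifelse(v <= c12[2], "intermediate", "high"))
  f <- factor(out, levels = c("low", "intermediate", "high"))
  attr(f, "method") <- "tercile"
  attr(f, "cutpoints") <- c12
  f
}
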