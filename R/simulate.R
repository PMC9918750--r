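# Synthetic-data generators: cell tables with ground-truth positivity,
# TMA cores, survival under tercile hazard ratios, bulk and single-cell
# expression, and whole-slide tile grids.  Every generator is a pure
# function of (spec, seed).

#' Simulation specification
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' one to four cores per patient with a mean analysed tissue area of
#' 1.84 mm^2; log-normal marker intensity mixtures with ground-truth
#' positivity; exponential survival whose hazard depends on the SIA
#' tercile (overall survival hazard ratios 0.65 intermediate / 0.43 high
#' vs low, recurrence-free 0.65 / 0.46); bulk expression in which CD8A and
#' CD3E track CD8+ density and C1QA-C track CD68+CD163+ macrophage
#' density; and negative-binomial single-cell libraries with
#' class-specific marker means.
#'
#' @param n_patients number of patients.
#' @param cores_per_patient cores per patient, in 1-4.
#' @param region_mode `"centre_margin"` (cores alternate tumour centre and
#'   invasive margin) or `"bulk"`.
#' @param core_area tissue area per core in mm^2 (default 1.84, a typical
#'   cohort mean).
#' @param class_densities named mean densities (cells/mm^2) per cell
#'   class; defaults cover both default panels.
#' @param patient_sdlog log-normal sd of per-patient, per-class density
#'   multipliers (inter-patient heterogeneity; default 0.6).
#' @param intensity_neg_meanlog,intensity_separation,intensity_sdlog
#'   log-normal intensity mixture: negative component log-mean, separation
#'   of the positive component's log-mean above it, and common log-sd.
#'   Separation around 6 sd gives essentially separable mixtures; smaller
#'   values create overlap.
#' @param baseline_rate_os,baseline_rate_rfs exponential baseline hazards
#'   (events per time unit, for the low-SIA stratum).
#' @param hr_os,hr_rfs named hazard ratios vs the low stratum.
#' @param horizon administrative censoring horizon (time units).
#' @param dropout_rate independent exponential dropout rate.
#' @param expr_noise_sdlog log-normal multiplicative noise linking bulk
#'   expression to density (0 = noiseless).
#' @param n_decoys density-independent decoy genes in bulk matrices.
#' @param cells_per_patient,sc_effect_size,sc_base_cd8,sc_base_m2,
#'   nb_size,marker_mean,decoy_mean,n_sc_decoys,mito_frac_mean,
#'   high_mito_rate,low_quality_rate single-cell library model: cells per
#'   patient; multiplier applied to the responder CD8:M2 cell-count odds;
#'   baseline class fractions; negative-binomial size; marker / decoy gene
#'   mean counts; decoy gene number; typical mitochondrial count fraction;
#'   rates of simulated high-mitochondrial and low-library-quality cells.
#' @param seed integer seed.
#' @return validated list of class `sia_sim_spec`.
#' @export
sia_sim_spec <- function(n_patients = 100,
                         cores_per_patient = 2,
                         region_mode = c("centre_margin", "bulk"),
                         core_area = 1.84,
                         class_densities = default_class_densities(),
                         patient_sdlog = 0.6,
                         intensity_neg_meanlog = 0,
                         intensity_separation = 2.5,
                         intensity_sdlog = 0.35,
                         baseline_rate_os = 0.08,
                         baseline_rate_rfs = 0.10,
                         hr_os = c(intermediate = 0.65, high = 0.43),
                         hr_rfs = c(intermediate = 0.65, high = 0.46),
                         horizon = 15,
                         dropout_rate = 0.02,
                         expr_noise_sdlog = 0.3,
                         n_decoys = 50,
                         cells_per_patient = 200,
                         sc_effect_size = 3,
                         sc_base_cd8 = 0.15,
                         sc_base_m2 = 0.15,
                         nb_size = 2,
                         marker_mean = 8,
                         decoy_mean = 5,
                         n_sc_decoys = 300,
                         mito_frac_mean = 0.02,
                         high_mito_rate = 0.03,
                         low_quality_rate = 0.05,
                         seed = 1L) {
  region_mode <- match.arg(region_mode)
  stopifnot(
    n_patients >= 1, cores_per_patient >= 1, cores_per_patient <= 4,
    core_area > 0, all(class_densities >= 0), patient_sdlog >= 0,
    intensity_separation >= 0, intensity_sdlog > 0,
    baseline_rate_os > 0, baseline_rate_rfs > 0,
    all(hr_os > 0), all(hr_rfs > 0), horizon >= 0, dropout_rate >= 0,
    expr_noise_sdlog >= 0, sc_effect_size > 0,
    sc_base_cd8 > 0, sc_base_m2 > 0, sc_base_cd8 + sc_base_m2 < 1
  )
  spec <- as.list(environment())
  class(spec) <- "sia_sim_spec"
  spec
}

#' Default mean class densities (cells/mm^2) for simulation
#' @return named numeric vector over the default rule table's classes.
#' @export
default_class_densities <- function() {
  c("tumour" = 800,
    "CD8+FoxP3+ regulatory T cell" = 5,
    "CD8+CD45RO+ memory cytotoxic T cell" = 60,
    "CD8+ cytotoxic T cell" = 140,
    "CD4+FoxP3+ regulatory T cell" = 40,
    "CD4+CD45RO+ memory helper T cell" = 80,
    "CD4+ helper T cell" = 150,
    "CD20+ B cell" = 60,
    "FoxP3+ regulatory T cell" = 10,
    "CD45RO+ memory lymphocyte" = 30,
    "CD3+CD56+ NKT-like cell" = 15,
    "NK cell" = 25,
    "CD68+CD163+ macrophage" = 60,
    "CD68+CD163- macrophage" = 180,
    "CD68-CD163+ cell" = 45,
    "CD3+ T cell" = 250)
}

# Map each class to its panel and true marker-positivity pattern: the
# union of required-positive markers over all rules defining the class
# (so an NK cell reachable as CD56+CD3- or NKp46+CD3- is simulated
# CD56+NKp46+), everything else negative.
class_patterns <- function(config = sia_config()) {
  rules <- config$rules
  classes <- unique(rules$class)
  lapply(stats::setNames(classes, classes), function(cl) {
    own <- rules[rules$class == cl, , drop = FALSE]
    panel <- own$panel[1]
    markers <- config$panels[[panel]]
    pos <- unique(unlist(lapply(own$positive, split_markers)))
    list(panel = panel, positive = pos,
         pattern = stats::setNames(markers %in% pos, markers))
  })
}

#' Simulate a per-cell intensity table with ground truth
#'
#' Per core and class, cell counts are Poisson with mean
#' density x multiplier x area, where the per-patient multiplier is
#' log-normal (inter-patient heterogeneity). Each cell draws per-marker
#' intensities from its class's true positive or negative log-normal
#' mixture component. The truth tables record every cell's class and true
#' positivity and each patient's realised CD8+ / M2 densities and SIA.
#'
#' @param spec a [sia_sim_spec()].
#' @param config a [sia_config()] (panels and rule table).
#' @return list: `cells` (intensity table), `cores`, `cell_truth`
#'   (`cell_id`, `true_class`, `true_<marker>` flags), `patient_truth`
#'   (`patient_id`, realised `cd8_density`, `m2_density`, `sia` plus the
#'   per-class expected densities).
#' @export
simulate_cell_table <- function(spec = sia_sim_spec(),
                                config = sia_config()) {
  set_seed_if(spec$seed)
  patterns <- class_patterns(config)
  classes <- intersect(names(spec$class_densities), names(patterns))
  pats <- sprintf("P%04d", seq_len(spec$n_patients))

  cores <- do.call(rbind, lapply(seq_along(pats), function(i) {
    k <- spec$cores_per_patient
    region <- if (spec$region_mode == "centre_margin") {
      rep(c("centre", "margin"), length.out = k)
    } else rep("bulk", k)
    data.frame(core_id = sprintf("%s_C%d", pats[i], seq_len(k)),
               patient_id = pats[i], region = region,
               area_mm2 = spec$core_area, stringsAsFactors = FALSE)
  }))

  mult <- matrix(stats::rlnorm(length(pats) * length(classes),
                               -spec$patient_sdlog^2 / 2, spec$patient_sdlog),
                 nrow = length(pats),
                 dimnames = list(pats, classes))

  cell_rows <- vector("list", nrow(cores))
  truth_rows <- vector("list", nrow(cores))
  all_markers <- unique(unlist(config$panels))
  mu_pos <- spec$intensity_neg_meanlog + spec$intensity_separation
  cell_counter <- 0L
  for (ci in seq_len(nrow(cores))) {
    pid <- cores$patient_id[ci]
    n_by_class <- stats::rpois(
      length(classes),
      spec$class_densities[classes] * mult[pid, classes] * cores$area_mm2[ci])
    n_tot <- sum(n_by_class)
    if (n_tot == 0L) next
    cls <- rep(classes, n_by_class)
    ids <- sprintf("cell%08d", cell_counter + seq_len(n_tot))
    cell_counter <- cell_counter + n_tot
    panel <- vapply(patterns[cls], `[[`, "", "panel")
    intens <- matrix(NA_real_, n_tot, length(all_markers),
                     dimnames = list(NULL, all_markers))
    truth <- matrix(NA, n_tot, length(all_markers),
                    dimnames = list(NULL, all_markers))
    for (cl in unique(cls)) {
      rows <- which(cls == cl)
      pat <- patterns[[cl]]
      for (m in names(pat$pattern)) {
        mu <- if (pat$pattern[[m]]) mu_pos else spec$intensity_neg_meanlog
        intens[rows, m] <- stats::rlnorm(length(rows), mu,
                                         spec$intensity_sdlog)
        truth[rows, m] <- pat$pattern[[m]]
      }
    }
    cell_rows[[ci]] <- data.frame(
      cell_id = ids, patient_id = pid, core_id = cores$core_id[ci],
      panel_id = panel, intens, check.names = FALSE,
      stringsAsFactors = FALSE)
    colnames(truth) <- paste0("true_", all_markers)
    truth_rows[[ci]] <- data.frame(cell_id = ids, true_class = cls, truth,
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  cell_truth <- do.call(rbind, truth_rows)
  if (is.null(cells)) {   # all densities zero
    cells <- data.frame(cell_id = character(), patient_id = character(),
                        core_id = character(), panel_id = character())
    cell_truth <- data.frame(cell_id = character(),
                             true_class = character())
  }

  patient_truth <- realized_patient_truth(cells, cell_truth, cores, pats)
  expected <- t(spec$class_densities[classes] * t(mult))
  colnames(expected) <- paste0("expected_", classes)
  patient_truth <- cbind(patient_truth,
                         as.data.frame(expected)[patient_truth$patient_id, ,
                                                 drop = FALSE])
  rownames(patient_truth) <- NULL
  list(cells = cells, cores = cores, cell_truth = cell_truth,
       patient_truth = patient_truth)
}

realized_patient_truth <- function(cells, cell_truth, cores, pats) {
  area <- tapply(cores$area_mm2, factor(cores$patient_id, pats), sum)
  if (nrow(cells)) {
    stopifnot(identical(cells$cell_id, cell_truth$cell_id))
    not_tumour <- cell_truth$true_class != "tumour"
    cd8 <- !is.na(cell_truth$true_CD8) & cell_truth$true_CD8 & not_tumour
    f <- factor(cells$patient_id, pats)
    n_cd8 <- tapply(cd8, f, sum)
    n_m2 <- tapply(cell_truth$true_class == "CD68+CD163+ macrophage", f, sum)
    n_cd8[is.na(n_cd8)] <- 0; n_m2[is.na(n_m2)] <- 0
  } else {
    n_cd8 <- n_m2 <- stats::setNames(rep(0, length(pats)), pats)
  }
  cd8_density <- as.numeric(n_cd8) / as.numeric(area)
  m2_density <- as.numeric(n_m2) / as.numeric(area)
  data.frame(patient_id = pats, total_area = as.numeric(area),
             cd8_density = cd8_density, m2_density = m2_density,
             sia = compute_sia(cd8_density, m2_density),
             stringsAsFactors = FALSE)
}

#' Simulate survival records under SIA-stratum hazard ratios
#'
#' Event times are exponential with rate = baseline x HR(stratum); the
#' observed time is the minimum of the event time, an independent
#' exponential dropout time and the administrative horizon. OS and RFS are
#' generated independently with their own baselines and hazard ratios.
#' Patients with an undefined stratum are excluded with a log entry.
#'
#' @param profiles data frame with `patient_id` and `sia_stratum` (factor;
#'   level `low` is the reference).
#' @param spec a [sia_sim_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return data frame: `patient_id`, `sia_stratum`, `os_time`, `os_event`,
#'   `rfs_time`, `rfs_event`.
#' @export
simulate_survival <- function(profiles, spec = sia_sim_spec(),
                              seed = NULL) {
  set_seed_if(seed %||% spec$seed)
  ok <- !is.na(profiles$sia_stratum)
  if (any(!ok)) {
    sia_log("excluding %d patient(s) with undefined SIA stratum", sum(!ok))
  }
  profiles <- profiles[ok, , drop = FALSE]
  n <- nrow(profiles)
  stratum <- as.character(profiles$sia_stratum)
  hr_of <- function(hr) {
    h <- c(low = 1, hr)
    unname(h[stratum])
  }
  draw <- function(base, hr) {
    t_event <- stats::rexp(n, base * hr)
    t_drop <- if (spec$dropout_rate > 0) {
      stats::rexp(n, spec$dropout_rate)
    } else rep(Inf, n)
    t_cens <- pmin(t_drop, spec$horizon)
    list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  }
  os <- draw(spec$baseline_rate_os, hr_of(spec$hr_os))
  rfs <- draw(spec$baseline_rate_rfs, hr_of(spec$hr_rfs))
  data.frame(patient_id = profiles$patient_id,
             sia_stratum = profiles$sia_stratum,
             os_time = os$time, os_event = os$event,
             rfs_time = rfs$time, rfs_event = rfs$event,
             stringsAsFactors = FALSE)
}

#' Simulate a bulk expression matrix linked to immune densities
#'
#' CD8A and CD3E are proportional to each patient's CD8+ density and
#' C1QA/B/C to the CD68+CD163+ macrophage density, each multiplied by
#' log-normal noise; decoy genes are density-independent.
#'
#' @param profiles data frame with `patient_id`, `cd8_density`,
#'   `m2_density` (e.g. the `patient_truth` of [simulate_cell_table()]).
#' @param spec a [sia_sim_spec()] (`expr_noise_sdlog`, `n_decoys`).
#' @param seed optional seed overriding `spec$seed`.
#' @return numeric matrix, genes x samples (sample names = patient ids).
#' @export
simulate_bulk_expression <- function(profiles, spec = sia_sim_spec(),
                                     seed = NULL) {
  set_seed_if(seed %||% spec$seed)
  n <- nrow(profiles)
  noise <- function() stats::rlnorm(n, 0, spec$expr_noise_sdlog)
  mat <- rbind(
    CD8A = profiles$cd8_density * noise(),
    CD3E = 1.5 * profiles$cd8_density * noise(),
    C1QA = profiles$m2_density * noise(),
    C1QB = 0.8 * profiles$m2_density * noise(),
    C1QC = 1.2 * profiles$m2_density * noise())
  decoys <- matrix(stats::rlnorm(spec$n_decoys * n, 3, 1), spec$n_decoys, n)
  rownames(decoys) <- sprintf("DECOY%03d", seq_len(spec$n_decoys))
  mat <- rbind(mat, decoys)
  colnames(mat) <- profiles$patient_id
  mat
}

#' Simulate a single-cell expression matrix with cell labels
#'
#' Cells belong to CD8 T, M2 macrophage or other classes; responders get a
#' CD8:M2 cell-count odds multiplied by `sc_effect_size` relative to
#' non-responders (effect size 1 = null). Marker genes (CD8A/CD3E for CD8
#' cells; CD68/CD163/C1QA-C for M2 cells) have negative-binomial counts in
#' their class and zero elsewhere; decoy and mitochondrial genes are
#' class-independent. A configurable fraction of cells is generated with
#' collapsed library complexity (few detected genes) or high mitochondrial
#' fraction, to exercise the QC filter.
#'
#' @param spec a [sia_sim_spec()].
#' @param n_patients number of patients (default 48).
#' @param response_labels per-patient labels (default half
#'   `"responder"` / half `"non-responder"`).
#' @param seed optional seed overriding `spec$seed`.
#' @return list: `counts` (sparse genes x cells), `cell_info`
#'   (`cell_id`, `patient_id`, `response`, `true_class`,
#'   `is_low_quality`, `is_high_mito`).
#' @export
simulate_single_cell <- function(spec = sia_sim_spec(), n_patients = 48,
                                 response_labels = NULL, seed = NULL) {
  set_seed_if(seed %||% spec$seed)
  response_labels <- response_labels %||%
    rep(c("responder", "non-responder"), length.out = n_patients)
  stopifnot(length(response_labels) == n_patients)
  pats <- sprintf("SC%03d", seq_len(n_patients))

  frac_tot <- spec$sc_base_cd8 + spec$sc_base_m2
  class_probs <- function(resp) {
    odds <- spec$sc_base_cd8 / spec$sc_base_m2
    if (resp == "responder") odds <- odds * spec$sc_effect_size
    m2 <- frac_tot / (1 + odds)
    c(cd8 = frac_tot - m2, m2 = m2, other = 1 - frac_tot)
  }

  n_cells <- n_patients * spec$cells_per_patient
  genes <- c("CD8A", "CD3E", "CD68", "CD163", "C1QA", "C1QB", "C1QC",
             "MT-CO1", "MT-ND1",
             sprintf("SCDECOY%04d", seq_len(spec$n_sc_decoys)))
  counts <- matrix(0, length(genes), n_cells, dimnames = list(genes, NULL))

  cls <- character(n_cells); pid <- character(n_cells)
  resp <- character(n_cells)
  for (i in seq_len(n_patients)) {
    idx <- (i - 1) * spec$cells_per_patient + seq_len(spec$cells_per_patient)
    pid[idx] <- pats[i]
    resp[idx] <- response_labels[i]
    cls[idx] <- sample(c("cd8", "m2", "other"), length(idx), replace = TRUE,
                       prob = class_probs(response_labels[i]))
  }

  nb <- function(k, mu) stats::rnbinom(k, size = spec$nb_size, mu = mu)
  i_cd8 <- which(cls == "cd8"); i_m2 <- which(cls == "m2")
  for (g in c("CD8A", "CD3E")) counts[g, i_cd8] <- nb(length(i_cd8),
                                                      spec$marker_mean)
  for (g in c("CD68", "CD163", "C1QA", "C1QB", "C1QC")) {
    counts[g, i_m2] <- nb(length(i_m2), spec$marker_mean)
  }
  decoy_rows <- grep("^SCDECOY", genes)
  counts[decoy_rows, ] <- nb(length(decoy_rows) * n_cells, spec$decoy_mean)

  expected_total <- spec$n_sc_decoys * spec$decoy_mean
  mito_mu <- spec$mito_frac_mean * expected_total /
    (1 - spec$mito_frac_mean) / 2
  mito_rows <- grep("^MT-", genes)
  counts[mito_rows, ] <- nb(length(mito_rows) * n_cells, mito_mu)

  is_high_mito <- stats::runif(n_cells) < spec$high_mito_rate
  if (any(is_high_mito)) {   # mitochondrial fraction ~ 0.3
    hi_mu <- 0.3 * expected_total / 0.7 / 2
    counts[mito_rows, is_high_mito] <-
      nb(length(mito_rows) * sum(is_high_mito), hi_mu)
  }
  is_low_quality <- stats::runif(n_cells) < spec$low_quality_rate
  if (any(is_low_quality)) {  # collapse library to ~10 detected genes
    for (j in which(is_low_quality)) {
      keep <- sample(decoy_rows, 10)
      zero <- setdiff(seq_len(length(genes)), keep)
      counts[zero, j] <- 0
      counts[keep, j] <- pmax(counts[keep, j], 1)
    }
  }
  colnames(counts) <- sprintf("cell%06d", seq_len(n_cells))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       cell_info = data.frame(cell_id = colnames(counts), patient_id = pid,
                              response = resp, true_class = cls,
                              is_low_quality = is_low_quality,
                              is_high_mito = is_high_mito,
                              stringsAsFactors = FALSE))
}

#' Simulate whole-slide tile grids
#'
#' Each slide is a grid of tiles with per-marker cell densities. In
#' homogeneous mode all tiles of a slide share one log-normal density law
#' per marker (exchangeable tiles, the null of the representativeness
#' test); in gradient mode the mean density increases linearly across the
#' global tile index by `fold_change`, so consecutive slides sit at
#' increasing density levels - the slide-to-slide heterogeneity that makes
#' single-tile sampling unrepresentative of individual slides.
#'
#' @param n_slides number of whole-slide sections (default 8).
#' @param tiles_per_slide tiles per slide: a scalar, a vector per slide, or
#'   NULL to sample 13-93 tiles per slide.
#' @param heterogeneity `"homogeneous"` or `"gradient"`.
#' @param markers marker names for the density columns.
#' @param base_density named (or scalar) mean density per marker.
#' @param fold_change gradient fold change across a slide.
#' @param noise_sdlog log-normal tile-to-tile noise.
#' @param tile_area tile area in mm^2 (default 1.86 x 1.39 mm).
#' @param seed integer seed.
#' @return data frame: `slide_id`, `tile_id`, `area_mm2`, one density
#'   column per marker.
#' @export
simulate_tile_grid <- function(n_slides = 8, tiles_per_slide = 40,
                               heterogeneity = c("homogeneous", "gradient"),
                               markers = c("CD8", "CD68_CD163neg",
                                           "CD68_CD163pos", "CD68neg_CD163"),
                               base_density = 100, fold_change = 10,
                               noise_sdlog = 0.25,
                               tile_area = 1.86 * 1.39, seed = NULL) {
  heterogeneity <- match.arg(heterogeneity)
  set_seed_if(seed)
  if (is.null(tiles_per_slide)) {
    tiles_per_slide <- sample(13:93, n_slides, replace = TRUE)
  }
  tiles_per_slide <- rep(tiles_per_slide, length.out = n_slides)
  if (any(tiles_per_slide < 2)) {
    stop("each slide needs at least 2 tiles", call. = FALSE)
  }
  base <- rep(base_density, length.out = length(markers))
  names(base) <- markers
  n_total <- sum(tiles_per_slide)
  offsets <- c(0, cumsum(tiles_per_slide))
  rows <- lapply(seq_len(n_slides), function(s) {
    k <- tiles_per_slide[s]
    d <- data.frame(slide_id = sprintf("WSS%02d", s),
                    tile_id = sprintf("WSS%02d_T%03d", s, seq_len(k)),
                    area_mm2 = tile_area, stringsAsFactors = FALSE)
    grad <- if (heterogeneity == "gradient") {
      # linear in the global tile index, so slides sit at different
      # levels of the gradient (slide-to-slide heterogeneity)
      gi <- offsets[s] + seq_len(k)
      1 + (fold_change - 1) * (gi - 1) / (n_total - 1)
    } else rep(1, k)
    for (m in markers) {
      d[[m]] <- base[[m]] * grad * stats::rlnorm(k, -noise_sdlog^2 / 2,
                                                 noise_sdlog)
    }
    d
  })
  do.call(rbind, rows)
}
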