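# Shared fixtures and independent oracles, all built in code at test time.

options(siascore.verbose = FALSE)

# Reference table (marker, intensity, label) from a simulation's truth.
reference_from_sim <- function(sim, config = sia_config()) {
  do.call(rbind, lapply(unique(unlist(config$panels)), function(m) {
    tm <- sim$cell_truth[[paste0("true_", m)]]
    ok <- !is.na(tm)
    data.frame(marker = m, intensity = sim$cells[[m]][ok],
               label = ifelse(tm[ok], "pos", "neg"),
               stringsAsFactors = FALSE)
  }))
}

# Tiny hand-built cell table on the NK/macrophage panel with explicit
# positivity flags (no thresholding involved).
flagged_cells <- function(flags) {
  # flags: data.frame with logical columns named after markers
  markers <- c("CD56", "NKp46", "CD3", "CD68", "CD163", "CK")
  n <- nrow(flags)
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      patient_id = "P1", core_id = "P1_C1",
                      panel_id = "nk_macrophage",
                      stringsAsFactors = FALSE)
  for (m in markers) {
    cells[[m]] <- 1
    cells[[paste0("pos_", m)]] <- if (m %in% names(flags)) flags[[m]] else FALSE
  }
  cells
}

one_core <- function(patient = "P1", core = "P1_C1", area = 1,
                     region = "bulk") {
  data.frame(core_id = core, patient_id = patient, region = region,
             area_mm2 = area, stringsAsFactors = FALSE)
}

# Independent brute-force minimiser of the KDE misclassification
# functional: scans n_scan evenly spaced thresholds over the pooled data
# range, computing the Gaussian-KDE tail masses directly as mixtures of
# kernel CDFs (no shared code with the implementation path).
brute_force_threshold <- function(pos, neg, n_scan = 10000) {
  h_p <- stats::bw.nrd0(pos); h_n <- stats::bw.nrd0(neg)
  w_pos <- length(pos) / (length(pos) + length(neg))
  ts <- seq(min(c(pos, neg)), max(c(pos, neg)), length.out = n_scan)
  errs <- vapply(ts, function(t0) {
    pos_below <- sum(stats::pnorm(t0, pos, h_p)) / length(pos)
    neg_above <- sum(stats::pnorm(t0, neg, h_n,
                                  lower.tail = FALSE)) / length(neg)
    w_pos * pos_below + (1 - w_pos) * neg_above
  }, numeric(1))
  list(threshold = ts[which.min(errs)], errors = errs, ts = ts)
}

# Independent Newton-Raphson maximiser of the Efron partial likelihood
# for a single binary covariate with no ties (times distinct).
newton_cox_binary <- function(time, event, x, tol = 1e-10) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  stopifnot(!anyDuplicated(time[event == 1]))
  beta <- 0
  for (it in 1:50) {
    eta <- exp(beta * x)
    U <- 0; I <- 0
    for (i in which(event == 1)) {
      at_risk <- seq_along(time) >= i
      s0 <- sum(eta[at_risk])
      s1 <- sum((x * eta)[at_risk])
      s2 <- sum((x^2 * eta)[at_risk])
      U <- U + x[i] - s1 / s0
      I <- I + s2 / s0 - (s1 / s0)^2
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Exhaustive concordant-pair tAUC at time t (no censoring).
pair_count_tauc <- function(score, time, t0) {
  cases <- which(time <= t0); controls <- which(time > t0)
  mean(outer(score[cases], score[controls], ">") +
         0.5 * outer(score[cases], score[controls], "=="))
}

# Empirical-CDF scan oracle for the two-sample KS statistic.
ecdf_scan_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}
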