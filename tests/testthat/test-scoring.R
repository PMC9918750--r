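test_that("SIA boundary behaviour and monotonicity", {
  expect_equal(compute_sia(100, 100), 0.5)
  expect_equal(compute_sia(0, 50), 0)
  expect_equal(compute_sia(50, 0), 1)
  expect_true(is.na(compute_sia(0, 0)))
  expect_error(compute_sia(-1, 5), "non-negative")
  # strictly increasing in CD8 at fixed M2; decreasing in M2 at fixed CD8
  cd8 <- seq(1, 100, length.out = 20)
  expect_true(all(diff(compute_sia(cd8, 50)) > 0))
  expect_true(all(diff(compute_sia(50, cd8)) < 0))
})

test_that("Immunoscore percentiles match a rank-then-average oracle", {
  dens <- expand.grid(patient_id = sprintf("P%d", 1:5),
                      region = c("centre", "margin"),
                      marker = c("CD3", "CD8"), stringsAsFactors = FALSE)
  set.seed(5)
  dens$density <- c(10, 20, 30, 40, 50,   # CD3 centre
                    5, 4, 3, 2, 1,        # CD3 margin
                    100, 90, 80, 70, 60,  # CD8 centre
                    11, 22, 33, 44, 55)   # CD8 margin
  is_df <- compute_is(dens)
  oracle <- sapply(1:5, function(i) {
    mean(c(100 * rank(dens$density[1:5])[i] / 5,
           100 * rank(dens$density[6:10])[i] / 5,
           100 * rank(dens$density[11:15])[i] / 5,
           100 * rank(dens$density[16:20])[i] / 5))
  })
  expect_equal(is_df$is_percentile[match(sprintf("P%d", 1:5),
                                         is_df$patient_id)], oracle)
  expect_true(all(is_df$n_channels == 4))
})

test_that("a cohort-maximal patient scores 100 and the 25 boundary is Low", {
  dens <- expand.grid(patient_id = sprintf("P%d", 1:4),
                      region = c("centre", "margin"),
                      marker = c("CD3", "CD8"), stringsAsFactors = FALSE)
  dens$density <- rep(c(1, 2, 3, 10), 4)  # P4 maximal in every channel
  is_df <- compute_is(dens)
  p4 <- is_df[is_df$patient_id == "P4", ]
  expect_equal(p4$is_percentile, 100)
  expect_identical(as.character(p4$is_category), "High")
  p1 <- is_df[is_df$patient_id == "P1", ]
  expect_equal(p1$is_percentile, 25)      # rank 1 of 4 in all channels
  expect_identical(as.character(p1$is_category), "Low")
})

test_that("Immunoscore uses the available channels in incomplete cases", {
  dens <- expand.grid(patient_id = sprintf("P%d", 1:4),
                      region = c("centre", "margin"),
                      marker = c("CD3", "CD8"), stringsAsFactors = FALSE)
  dens$density <- seq_len(16)
  dens <- dens[!(dens$patient_id == "P2" & dens$region == "margin"), ]
  is_df <- compute_is(dens)
  expect_equal(is_df$n_channels[is_df$patient_id == "P2"], 2)
  expect_equal(is_df$n_channels[is_df$patient_id == "P1"], 4)
  expect_false(any(is.na(is_df$is_percentile)))
})

test_that("IS depends only on ranks of each density channel", {
  dens <- expand.grid(patient_id = sprintf("P%d", 1:6),
                      region = c("centre", "margin"),
                      marker = c("CD3", "CD8"), stringsAsFactors = FALSE)
  set.seed(8)
  dens$density <- runif(nrow(dens), 1, 100)
  base <- compute_is(dens)
  warped <- dens
  warped$density <- exp(warped$density / 20)   # strictly increasing map
  expect_equal(compute_is(warped)$is_percentile, base$is_percentile)
})

test_that("bulk RNA SIA: ratio, duplicate averaging and filters", {
  mat <- rbind(CD8A = c(10, 8, 20, 0), C1QA = c(5, 2, 5, 0),
               C1QB = c(2, 2, 2, 2), C1QC = c(1, 1, 1, 1),
               CD3E = c(6, 6, 6, 6))
  colnames(mat) <- paste0("S", 1:4)
  r <- rna_sia(mat)
  expect_equal(r$sia_rna[1], 2.0)
  expect_true(is.na(r$sia_rna[4]))   # 0/0 undefined

  # one patient with two pre-therapy samples scoring 2.0 and 4.0 -> 3.0
  info <- data.frame(sample_id = paste0("S", 1:4),
                     patient_id = c("A", "A", "B", "C"),
                     timepoint = c("pre", "pre", "pre", "post"))
  r2 <- rna_sia(mat, sample_info = info)
  expect_equal(r2$sia_rna[r2$id == "A"], 3.0)
  expect_equal(r2$n_samples[r2$id == "A"], 2L)
  expect_false("C" %in% r2$id)       # post-therapy sample filtered out

  # ratio of two genes is invariant under library-size rescaling
  mat2 <- mat %*% diag(c(10, 0.5, 2, 7))
  colnames(mat2) <- colnames(mat)
  expect_equal(rna_sia(mat2)$sia_rna, r$sia_rna)

  expect_error(rna_sia(mat[-1, , drop = FALSE]), "CD8A")
  # log2-scaled input is exponentiated before scoring
  lmat <- log2(mat + 1e-9)
  attr(lmat, "scale") <- "log2"
  expect_equal(rna_sia(lmat)$sia_rna[1:3], r$sia_rna[1:3], tolerance = 1e-6)
})

test_that("IS-like bulk metric is the CD8A/CD3E mean", {
  mat <- rbind(CD8A = c(4, 7), CD3E = c(6, 7))
  colnames(mat) <- c("S1", "S2")
  r <- rna_is_like(mat)
  expect_equal(r$is_like, c(5, 7))
  mat["CD8A", 1] <- 5
  expect_gt(rna_is_like(mat)$is_like[1], 5)   # monotone in CD8A
})

test_that("single-cell QC thresholds are boundary-inclusive", {
  n_genes <- 300
  genes <- c(sprintf("G%03d", seq_len(n_genes - 1)), "MT-CO1")
  counts <- matrix(1, n_genes, 4, dimnames = list(genes, paste0("c", 1:4)))
  counts[250:299, 1] <- 0          # cell 1: 250 detected genes
  counts[249:299, 2] <- 0          # cell 2: 249 detected genes
  counts["MT-CO1", 3] <- 17        # cell 3: mito frac 17/316 > 0.05
  counts["MT-CO1", 4] <- 0         # cell 4: mito frac 0
  qc <- sc_qc_filter(counts, sia_config(min_genes = 250))
  expect_identical(unname(qc$keep), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(qc$report$n[1], 1)  # one cell under the gene floor
  expect_equal(qc$report$n[2], 1)  # one cell over the mito ceiling

  qc100 <- sc_qc_filter(counts[, 2, drop = FALSE],
                        sia_config(min_genes = 100))
  expect_true(qc100$keep)          # 249 >= 100

  no_mito <- counts[seq_len(n_genes - 1), , drop = FALSE]
  expect_warning(sc_qc_filter(no_mito, sia_config(min_genes = 10)),
                 "mitochondrial")
})

test_that("single-cell SIA counts marker-positive cells per patient", {
  genes <- c("CD8A", "CD68", "CD163", "C1QA", "C1QB", "C1QC")
  counts <- matrix(0, length(genes), 40,
                   dimnames = list(genes, sprintf("c%02d", 1:40)))
  counts["CD8A", 1:30] <- 3
  counts["CD68", 31:40] <- 2; counts["CD163", 31:40] <- 1
  info <- data.frame(patient_id = rep("P1", 40))
  r <- sc_sia(counts, info)
  expect_equal(r$sia, 0.75)        # 30 / (30 + 10)

  counts["CD68", 31:40] <- 0; counts["CD163", 31:40] <- 0
  expect_equal(sc_sia(counts, info)$sia, 1.0)
  expect_error(sc_sia(counts[-1, , drop = FALSE], info), "CD8A")
})

test_that("single-cell SIA recovers the class-count ground truth", {
  sc <- simulate_single_cell(sia_sim_spec(seed = 19,
                                          cells_per_patient = 300),
                             n_patients = 10)
  qc <- sc_qc_filter(sc$counts, sia_config())
  info <- sc$cell_info[qc$keep, ]
  est <- sc_sia(qc$counts, info, "CD68&CD163")
  truth <- sapply(split(info$true_class, info$patient_id), function(cl) {
    n_cd8 <- sum(cl == "cd8"); n_m2 <- sum(cl == "m2")
    n_cd8 / (n_cd8 + n_m2)
  })
  expect_lt(max(abs(est$sia - truth[est$patient_id])), 0.05)
})

test_that("single-cell SIA separates simulated therapy responders", {
  sc <- simulate_single_cell(sia_sim_spec(seed = 77,
                                          cells_per_patient = 200),
                             n_patients = 48)   # 24 vs 24 patients
  qc <- sc_qc_filter(sc$counts, sia_config())
  est <- sc_sia(qc$counts, sc$cell_info[qc$keep, ], "CD68&CD163")
  grp <- factor(est$response, levels = c("non-responder", "responder"))
  r <- suppressWarnings(responder_tests(est$sia, grp, boot_n = 100))
  expect_gt(r$auc, 0.9)          # large effect by construction
  expect_lt(r$p_mw, 0.001)

  # at effect size 1 the groups are exchangeable
  sc0 <- simulate_single_cell(sia_sim_spec(seed = 78, sc_effect_size = 1,
                                           cells_per_patient = 200),
                              n_patients = 48)
  qc0 <- sc_qc_filter(sc0$counts, sia_config())
  est0 <- sc_sia(qc0$counts, sc0$cell_info[qc0$keep, ], "CD68&CD163")
  grp0 <- factor(est0$response, levels = c("non-responder", "responder"))
  r0 <- suppressWarnings(responder_tests(est0$sia, grp0, boot_n = 100))
  expect_gt(r0$p_mw, 0.05)
  expect_lt(abs(r0$auc - 0.5), 0.15)
})
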