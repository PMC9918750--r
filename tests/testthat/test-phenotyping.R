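test_that("marker combinations map to the expected classes", {
  cells <- flagged_cells(data.frame(
    CD68  = c(TRUE,  FALSE, FALSE, TRUE,  FALSE),
    CD163 = c(TRUE,  FALSE, FALSE, FALSE, TRUE),
    CK    = c(FALSE, FALSE, TRUE,  FALSE, FALSE)))
  out <- classify_cells(cells)
  expect_identical(out$class_label,
                   c("CD68+CD163+ macrophage", "unclassified", "tumour",
                     "CD68+CD163- macrophage", "CD68-CD163+ cell"))
})

test_that("rule order and rule validation behave as documented", {
  rules <- rbind(default_rule_table(),
                 data.frame(panel = "nk_macrophage", positive = "CD68,CD163",
                            negative = "CK", class = "shadow class"))
  cells <- flagged_cells(data.frame(CD68 = TRUE, CD163 = TRUE))
  expect_warning(out <- classify_cells(cells, rules), "duplicated")
  expect_identical(out$class_label, "CD68+CD163+ macrophage")  # first wins

  bad <- data.frame(panel = "nk_macrophage", positive = "CD99",
                    negative = "", class = "ghost")
  expect_error(classify_cells(cells, bad), "CD99")
})

test_that("densities pool counts and areas, never per-core means", {
  # two cores: 1 mm2 with 10 CD8 cells, 3 mm2 with none -> 10/4 = 2.5
  cores <- rbind(one_core("P1", "C1", 1), one_core("P1", "C2", 3))
  cells <- do.call(rbind, replicate(10, flagged_cells(
    data.frame(CD68 = TRUE, CD163 = FALSE)), simplify = FALSE))
  cells$cell_id <- sprintf("c%03d", seq_len(nrow(cells)))
  cells$core_id <- "C1"
  cells <- classify_cells(cells)
  dens <- compute_densities(cells, cores)
  m1 <- dens$class_densities
  row <- m1[m1$class == "CD68+CD163- macrophage" & m1$region == "all", ]
  expect_equal(row$density, 2.5)
  expect_equal(row$area_mm2, 4)

  # single core arithmetic: 50 cells on 2 mm2 -> 25 / mm2
  cores2 <- one_core("P1", "C1", 2)
  cells2 <- do.call(rbind, replicate(50, flagged_cells(
    data.frame(CD68 = TRUE)), simplify = FALSE))
  cells2$cell_id <- sprintf("c%03d", seq_len(nrow(cells2)))
  cells2$core_id <- "C1"
  d2 <- compute_densities(classify_cells(cells2), cores2)
  r2 <- d2$marker_densities
  expect_equal(r2[r2$marker == "CD68" & r2$region == "all", "density"], 25)

  # a class with no cells has density zero, and unknown cores are caught
  r0 <- m1[m1$class == "NK cell" & m1$region == "all", ]
  expect_true(nrow(r0) == 0 ||
                all(r0$density == 0))  # absent class contributes nothing
  cells$core_id[1] <- "C9"
  expect_error(compute_densities(cells, cores), "unknown core")
})

test_that("densities are invariant to cell and core order", {
  sim <- simulate_cell_table(sia_sim_spec(n_patients = 4, seed = 17))
  cells <- classify_cells(apply_thresholds(
    sim$cells, determine_thresholds(reference_from_sim(sim))))
  d1 <- compute_densities(cells, sim$cores)
  set.seed(1)
  perm <- sample(nrow(cells))
  d2 <- compute_densities(cells[perm, ], sim$cores[sample(nrow(sim$cores)), ])
  key <- function(d) d[order(d$patient_id, d$region, d$class), ]
  expect_equal(key(d1$class_densities), key(d2$class_densities),
               ignore_attr = TRUE)
})

test_that("excluded debris cells are dropped before counting", {
  cells <- flagged_cells(data.frame(CD68 = c(TRUE, TRUE)))
  cells$cell_id <- c("c1", "c2")
  cells$excluded <- c(FALSE, TRUE)
  d <- compute_densities(classify_cells(cells), one_core(area = 1))
  md <- d$marker_densities
  expect_equal(md[md$marker == "CD68" & md$region == "all", "density"], 1)
})

test_that("co-expression fractions reproduce the Venn arithmetic", {
  counts <- c(a_only = 9.0e5, b_only = 1.9e5, both = 4.4e4)
  flags <- data.frame(
    CD68  = rep(c(TRUE, FALSE, TRUE), counts),
    CD163 = rep(c(FALSE, TRUE, TRUE), counts))
  cells <- flagged_cells(flags)
  cx <- coexpression_summary(cells, "CD68", "CD163")
  expect_equal(cx$both, 44000)
  expect_equal(round(100 * cx$frac_a_double), 5)    # 4.66% -> 5%
  none <- coexpression_summary(
    flagged_cells(data.frame(CD68 = c(TRUE, FALSE), CD163 = c(FALSE, TRUE))),
    "CD68", "CD163")
  expect_equal(c(none$frac_a_double, none$frac_b_double), c(0, 0))
  all_double <- coexpression_summary(
    flagged_cells(data.frame(CD68 = TRUE, CD163 = TRUE)), "CD68", "CD163")
  expect_equal(c(all_double$frac_a_double, all_double$frac_b_double), c(1, 1))
})

test_that("tercile stratification and its median-split fallback", {
  s <- categorize_tercile(1:9)
  expect_equal(as.vector(table(s)), c(3, 3, 3))
  expect_identical(attr(s, "method"), "tercile")

  # 41% of patients at the maximum score triggers the median split
  v <- c(runif(59, 0, 0.9), rep(1, 41))
  s2 <- categorize_tercile(v)
  expect_identical(attr(s2, "method"), "median")
  expect_setequal(levels(s2), c("low", "high"))

  expect_error(categorize_tercile(rep(2, 10)), "identical")
  expect_error(categorize_tercile(c(1, 2)), "at least 3")

  # values equal to a cut point go to the lower stratum
  s3 <- categorize_tercile(c(1, 2, 3, 3, 4, 7, 8, 9, 10))
  expect_equal(unname(attr(s3, "cutpoints")[1]), 3)
  expect_identical(as.character(s3)[3:4], c("low", "low"))
})
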