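make_metrics <- function(foci, cal = toy_calibration(), id = 1) {
  summarize_nucleus(NULL, foci, calibration = cal, nucleus_id = id)
}

test_that("per-nucleus counts, biases and fractions follow their formulas", {
  cal <- toy_calibration()
  foci <- rbind(
    toy_focus("TelG", "halo", intensity = rep(10000, 10), z = 1:10),
    toy_focus("CEN", "core", intensity = rep(5000, 4), z = 1:4)
  )
  m <- make_metrics(foci, cal)
  expect_equal(m$halo_count_G, 10)
  expect_equal(m$halo_count_C, 0)
  expect_equal(m$number_bias_pct, 100 * (10 - 0) / mean(c(10, 0)))  # +200%
  expect_equal(m$number_bias_pct, 200)

  # equal halo and core content -> 50% extrachromosomal
  foci2 <- rbind(
    toy_focus("TelG", "halo", intensity = rep(20000, 5), z = 1:5),
    toy_focus("TelG", "core", intensity = rep(10000, 10), z = 1:10)
  )
  m2 <- make_metrics(foci2, cal)
  expect_equal(m2$ectr_fraction_G, 50)

  # diploid G1 core: 92 telomere foci per strand over 46 centromeres
  foci3 <- rbind(
    toy_focus("TelG", "core", intensity = rep(15000, 92), z = seq_len(92)),
    toy_focus("TelC", "core", intensity = rep(15000, 92), z = seq_len(92)),
    toy_focus("CEN", "core", intensity = rep(5000, 46), z = seq_len(46))
  )
  m3 <- make_metrics(foci3, cal)
  expect_equal(m3$tel_cen_ratio_G, 2.0)
  expect_equal(m3$tel_cen_ratio_C, 2.0)
})

test_that("strand swap negates biases and preserves colocalization", {
  cal <- toy_calibration()
  set.seed(91)
  g <- toy_focus("TelG", "halo", intensity = runif(12, 2000, 60000),
                 z = runif(12, 1, 7), y = runif(12, 1, 24),
                 x = runif(12, 1, 24))
  c <- toy_focus("TelC", "halo", intensity = runif(7, 2000, 60000),
                 z = runif(7, 1, 7), y = runif(7, 1, 24),
                 x = runif(7, 1, 24))
  m <- make_metrics(rbind(g, c), cal)
  swapped <- rbind(g, c)
  swapped$channel <- ifelse(swapped$channel == "TelG", "TelC", "TelG")
  ms <- make_metrics(swapped, cal)
  expect_equal(ms$number_bias_pct, -m$number_bias_pct)
  expect_equal(ms$content_bias_pct, -m$content_bias_pct)
  expect_equal(ms$coloc_fraction_halo, m$coloc_fraction_halo)
  expect_equal(ms$halo_count_G, m$halo_count_C)
  expect_equal(ms$halo_content_kb_G, m$halo_content_kb_C)
})

test_that("content conservation: compartment sums equal the channel total", {
  cal <- toy_calibration()
  set.seed(92)
  foci <- rbind(
    toy_focus("TelG", "halo", intensity = runif(8, 1000, 90000), z = 1:8),
    toy_focus("TelG", "core", intensity = runif(5, 1000, 90000), z = 1:5)
  )
  m <- make_metrics(foci, cal)
  f <- apply_detection_threshold(foci, cal)
  total <- sum(f$estimated_bp[f$passes_threshold]) / 1000
  expect_equal(m$halo_content_kb_G + m$core_content_kb_G, total)
})

test_that("ectr fraction is invariant under global intensity rescaling", {
  set.seed(93)
  ints_halo <- runif(6, 5000, 50000)
  ints_core <- runif(9, 5000, 50000)
  frac_at <- function(scale) {
    cal <- toy_calibration(mean_810 = 810 * scale)
    foci <- rbind(
      toy_focus("TelG", "halo", intensity = ints_halo * scale, z = 1:6),
      toy_focus("TelG", "core", intensity = ints_core * scale, z = 1:9))
    make_metrics(foci, cal)$ectr_fraction_G
  }
  expect_equal(frac_at(1), frac_at(3.7), tolerance = 1e-12)
})

test_that("cell-cycle bins follow the modal-count cut-offs", {
  expect_equal(assign_cell_cycle_bin(46, 46), "G1")
  expect_equal(assign_cell_cycle_bin(92, 46), "G2")
  expect_equal(assign_cell_cycle_bin(69, 46), "S")
  expect_equal(assign_cell_cycle_bin(c(40, 58, 81, 92), 46),
               c("G1", "S", "G2", "G2"))
  expect_error(assign_cell_cycle_bin(0, 46), "> 0")
  expect_error(assign_cell_cycle_bin(46, 0), "modal")
  expect_equal(modal_centromere_count(c(46, 46, 45, 92, 46, 92)), 46)
})

test_that("length statistics match closed forms", {
  s <- length_distribution_stats(c(10, 10, 10))
  expect_equal(s$mean_kb, 10)
  expect_equal(s$median_kb, 10)
  expect_equal(s$mean_median_ratio, 1.0)
  expect_equal(s$pct_below_50, 100)
  expect_equal(s$pct_above_200, 0)

  # exponential control: mean/median = 1/log(2)
  set.seed(94)
  x <- rexp(1e5, rate = 1 / 30)
  s2 <- length_distribution_stats(x)
  expect_lt(abs(s2$mean_median_ratio - 1 / log(2)), 0.01 / log(2))

  s3 <- length_distribution_stats(numeric(0))
  expect_true(is.na(s3$mean_kb) && is.na(s3$median_kb))
})

test_that("group comparison behaves like a Welch t-test should", {
  a <- c(10, 12, 11, 13, 10.5)
  r_same <- compare_groups(a, a)
  expect_equal(r_same$t_statistic, 0)
  expect_equal(r_same$p_value, 1)

  set.seed(95)
  ok <- vapply(1:5, function(i) {
    x <- rnorm(60, 100, 10); y <- rnorm(60, 200, 10)
    compare_groups(x, y)$p_value < 1e-6
  }, logical(1))
  expect_true(all(ok))

  x <- rnorm(20, 5, 2); y <- rnorm(20, 7, 3)
  r1 <- compare_groups(x, y); r2 <- compare_groups(y, x)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("content regression recovers exact and null relations", {
  cen <- c(46, 50, 60, 70, 80, 92)
  metrics <- data.frame(centromere_count_core = cen,
                        halo_content_kb_G = 6 * cen,
                        halo_content_kb_C = 4 * cen)
  r <- regress_content_vs_centromeres(metrics)
  expect_equal(r$slope, 10, tolerance = 1e-9)
  expect_equal(r$ci_low, r$ci_high, tolerance = 1e-6)

  set.seed(96)
  cover <- vapply(1:40, function(i) {
    m <- data.frame(centromere_count_core = sample(cen, 30, replace = TRUE),
                    halo_content_kb_G = sample(600 + rnorm(30, 0, 100)),
                    halo_content_kb_C = 0)
    ci <- regress_content_vs_centromeres(m)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)  # ~95% nominal coverage under the null

  expect_error(regress_content_vs_centromeres(
    data.frame(centromere_count_core = c(46, 46, 46),
               halo_content_kb_G = 1:3, halo_content_kb_C = 0)),
    "constant")
})

test_that("cell-cycle fold changes recover generator-style contrasts", {
  mk <- function(bin, count, medlen, n) {
    data.frame(cell_cycle_bin = bin,
               halo_count_G = count, halo_count_C = count,
               length_median_kb_all = medlen)[rep(1, n), ]
  }
  metrics <- rbind(mk("G1", 20, 12, 10), mk("G2", 60, 12, 10))
  fc <- cell_cycle_fold_changes(metrics)
  expect_equal(fc$count_fold_g2_g1, 3)
  expect_equal(fc$median_length_fold_g2_g1, 1)

  same <- rbind(mk("G1", 30, 15, 5), mk("G2", 30, 15, 5))
  fc2 <- cell_cycle_fold_changes(same)
  expect_equal(fc2$count_fold_g2_g1, 1)
  expect_equal(fc2$median_length_fold_g2_g1, 1)

  expect_warning(fc3 <- cell_cycle_fold_changes(mk("G1", 30, 15, 5)),
                 "empty")
  expect_true(is.na(fc3$count_fold_g2_g1))
})

test_that("asynchronous populations recover the configured G2/G1 folds", {
  preset <- cell_line_preset("fold3", 40, 40, ectr_count_dispersion = 1e6,
                             g2_count_fold = 3, g2_length_fold = 1)
  pops_g1 <- sample_ectr_population(preset, 60, seed = 97, phase = "G1")
  pops_g2 <- sample_ectr_population(preset, 60, seed = 98, phase = "G2")
  n1 <- mean(vapply(pops_g1, nrow, integer(1)))
  n2 <- mean(vapply(pops_g2, nrow, integer(1)))
  expect_gt(n2 / n1, 2.5)
  expect_lt(n2 / n1, 3.5)
  l1 <- median(unlist(lapply(pops_g1, function(p) p$repeat_length_bp)))
  l2 <- median(unlist(lapply(pops_g2, function(p) p$repeat_length_bp)))
  expect_gt(l2 / l1, 0.95)
  expect_lt(l2 / l1, 1.05)
})

test_that("group summaries report median and interquartile range", {
  metrics <- data.frame(nucleus_id = 1:5, halo_count_G = c(1, 2, 3, 4, 100))
  gs <- group_summary(metrics, label = "demo")
  row <- gs[gs$metric == "halo_count_G", ]
  expect_equal(row$median, 3)
  expect_equal(row$iqr_low, 2)
  expect_equal(row$iqr_high, 4)
  expect_true(row$iqr_low <= row$median && row$median <= row$iqr_high)
})
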