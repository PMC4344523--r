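test_that("zero-rate presets give empty ECTR populations", {
  p <- cell_line_preset("null", 0, 0)
  pops <- sample_ectr_population(p, 5, seed = 1)
  expect_true(all(vapply(pops, nrow, integer(1)) == 0L))
})

test_that("sampled ECTR counts and lengths match the configured laws", {
  preset <- get_preset("GM847")
  n <- 10000L
  pops <- sample_ectr_population(preset, n, seed = 11)
  g_counts <- vapply(pops, function(p) sum(p$strand == "G"), numeric(1))
  c_counts <- vapply(pops, function(p) sum(p$strand == "C"), numeric(1))

  # thinned negative binomial: Var(G) = p^2 Var(N) + p(1-p) E[N]
  mu_t <- preset$ectr_count_mean_G + preset$ectr_count_mean_C
  p_g <- preset$ectr_count_mean_G / mu_t
  var_n <- mu_t + mu_t^2 / preset$ectr_count_dispersion
  var_g <- p_g^2 * var_n + p_g * (1 - p_g) * mu_t
  se_g <- sqrt(var_g / n)
  expect_lt(abs(mean(g_counts) - preset$ectr_count_mean_G), 3 * se_g)
  var_c <- (1 - p_g)^2 * var_n + p_g * (1 - p_g) * mu_t
  expect_lt(abs(mean(c_counts) - preset$ectr_count_mean_C),
            3 * sqrt(var_c / n))

  # empirical variance consistent with the over-dispersed law (not Poisson)
  expect_gt(var(g_counts), 5 * mean(g_counts))
  expect_lt(abs(var(g_counts) / var_g - 1), 0.2)

  lengths <- unlist(lapply(pops, function(p) p$repeat_length_bp))
  ratio <- mean(lengths) / median(lengths)
  expect_gte(ratio, 2.0)
  expect_lte(ratio, 2.5)
  expect_gt(mean(lengths), median(lengths))
})

test_that("length skew is reproducible across seeds", {
  preset <- get_preset("VA13")
  ratios <- vapply(c(21, 22), function(s) {
    lens <- unlist(lapply(sample_ectr_population(preset, 1500, seed = s),
                          function(p) p$repeat_length_bp))
    mean(lens) / median(lens)
  }, numeric(1))
  expect_lt(abs(ratios[1] / ratios[2] - 1), 0.05)
})

test_that("nucleus truth has the expected chromosomal entries per phase", {
  preset <- get_preset("GM847")
  cfg <- small_config()
  pop <- data.frame(strand = character(0), repeat_length_bp = numeric(0))
  g1 <- do.call(build_nucleus_truth,
                c(list(preset, pop, "G1", cfg, seed = 3),
                  small_truth_args()))
  expect_equal(nrow(g1$centromere_positions_um), 46L)
  expect_equal(sum(g1$molecules$compartment_truth == "core"), 92L)
  g2 <- do.call(build_nucleus_truth,
                c(list(preset, pop, "G2", cfg, seed = 3),
                  small_truth_args()))
  expect_equal(nrow(g2$centromere_positions_um), 92L)
  expect_equal(sum(g2$molecules$compartment_truth == "core"), 184L)
})

test_that("halo molecules are placed outside the core, inside the field", {
  preset <- cell_line_preset("dense", 500, 500)
  cfg <- sim_config()
  pop <- sample_ectr_population(preset, 1, seed = 5)[[1]]
  expect_gt(nrow(pop), 300)
  truth <- build_nucleus_truth(preset, pop, "G1", cfg, seed = 6)
  halo <- truth$molecules[truth$molecules$compartment_truth == "halo", ]
  ctr <- truth$core_center_um
  r_xy <- sqrt((halo$y_um - ctr["y"])^2 + (halo$x_um - ctr["x"])^2)
  expect_true(all(r_xy > truth$core_radius_um))
  ext <- field_extent_um(cfg)
  expect_true(all(halo$z_um > 0 & halo$z_um < ext["z"]))
  expect_true(all(halo$y_um > 0 & halo$y_um < ext["y"]))
  expect_true(all(halo$x_um > 0 & halo$x_um < ext["x"]))
})

test_that("rendering conserves molecule flux and is linear in length", {
  cfg <- small_config()
  ext <- field_extent_um(cfg)
  mol <- molecule_frame("G", 810, ext["z"] / 2, ext["y"] / 2, ext["x"] / 2)
  truth <- make_truth(mol, cfg)
  stack <- render_stack(truth, cfg, noise = FALSE)
  sig <- sum(get_channel(stack, "TelG")) -
    length(get_channel(stack, "TelG")) *
      (cfg$background_level + cfg$camera_offset)
  expect_lt(abs(sig / (cfg$photons_per_bp * 810) - 1), 0.001)

  mol2 <- molecule_frame(c("G", "G"), c(810, 1620),
                         rep(ext["z"] / 2, 2), c(6, 6), c(3.5, 8))
  stack2 <- render_stack(make_truth(mol2, cfg), cfg, noise = FALSE)
  arr <- get_channel(stack2, "TelG") - cfg$background_level -
    cfg$camera_offset
  # split the field between the two sources
  half <- round(dim(arr)[3] / 2)
  s1 <- sum(arr[, , 1:half]); s2 <- sum(arr[, , (half + 1):dim(arr)[3]])
  expect_lt(abs(s2 / s1 - 2), 0.01)
})

test_that("an empty field renders pure background plus offset", {
  cfg <- small_config()
  truth <- make_truth(molecule_frame(character(0), numeric(0),
                                     numeric(0), numeric(0), numeric(0)),
                      cfg)
  stack <- render_stack(truth, cfg, noise = TRUE, seed = 9)
  m <- mean(get_channel(stack, "TelG"))
  expect_lt(abs(m - (cfg$background_level + cfg$camera_offset)), 0.5)
})

test_that("rendering is bit-identical for identical seed and config", {
  cfg <- small_config()
  preset <- get_preset("U2OS")
  pop <- sample_ectr_population(preset, 1, seed = 4)[[1]]
  truth <- do.call(build_nucleus_truth,
                   c(list(preset, pop, "G1", cfg, seed = 5),
                     small_truth_args()))
  s1 <- render_stack(truth, cfg, seed = 42)
  s2 <- render_stack(truth, cfg, seed = 42)
  expect_identical(s1$voxels, s2$voxels)
})

test_that("calibration slides carry the insert lengths of the standards", {
  cfg <- small_config()
  s135 <- simulate_calibration_slide(135, 12, cfg, seed = 7, noise = FALSE)
  expect_true(all(s135$truth$molecules$repeat_length_bp == 810))
  expect_true(all(s135$truth$molecules$strand == "duplex"))
  s270 <- simulate_calibration_slide(270, 12, cfg, seed = 7, noise = FALSE)
  expect_true(all(s270$truth$molecules$repeat_length_bp == 1620))
  # duplex foci emit equally in both telomere channels
  telg <- sum(get_channel(s135$stack, "TelG"))
  telc <- sum(get_channel(s135$stack, "TelC"))
  expect_equal(telg, telc, tolerance = 1e-10)

  empty <- simulate_calibration_slide(135, 0, cfg, seed = 8)
  expect_equal(nrow(empty$truth$molecules), 0L)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(sim_config(bit_depth = 10), "bit_depth")
  expect_error(cell_line_preset("bad", NA, 5), "finite")
  expect_error(cell_line_preset("bad", 5, 5, chromosome_count = 45),
               "even")
  expect_error(simulate_calibration_slide(0, 5), "insert_repeats")
  cfg <- small_config()
  expect_error(
    simulate_calibration_slide(135, 5000, cfg, seed = 1,
                               min_separation_um = 3),
    "overlap")
})
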