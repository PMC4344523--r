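test_that("well-separated molecules are each detected at their position", {
  cfg <- small_config()
  set.seed(41)
  pos <- separated_positions(5, cfg, min_dist = 2.5)
  bp <- c(2000, 5000, 10000, 20000, 40000)
  mol <- molecule_frame(rep("G", 5), bp, pos[, "z"], pos[, "y"], pos[, "x"])
  stack <- render_stack(make_truth(mol, cfg), cfg, noise = FALSE)
  f <- detect_foci(stack, "TelG")
  expect_equal(nrow(f), 5L)
  # match each detection to its truth molecule
  for (i in seq_len(5)) {
    dd <- sqrt((f$z_um - pos[i, "z"])^2 + (f$y_um - pos[i, "y"])^2 +
               (f$x_um - pos[i, "x"])^2)
    j <- which.min(dd)
    expect_lt(dd[j], 0.2)  # within one voxel
    expect_lt(abs(f$integrated_intensity[j] /
                  (cfg$photons_per_bp * bp[i]) - 1), 0.01)
  }
  # intensity increases with true length
  ord <- order(f$integrated_intensity)
  expect_equal(f$integrated_intensity[ord],
               sort(f$integrated_intensity))
  expect_true(all(diff(sort(f$integrated_intensity)) > 0))
})

test_that("two molecules below the resolution limit merge into one focus", {
  cfg <- small_config()
  ext <- field_extent_um(cfg)
  mol <- molecule_frame(c("G", "G"), c(4000, 4000),
                        rep(ext["z"] / 2, 2),
                        ext["y"] / 2 + c(0, 0.1), rep(ext["x"] / 2, 2))
  stack <- render_stack(make_truth(mol, cfg), cfg, noise = FALSE)
  f <- detect_foci(stack, "TelG")
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$integrated_intensity / (cfg$photons_per_bp * 8000) - 1),
            0.01)
})

test_that("a pure-noise field yields no foci passing the 810-bp threshold", {
  cfg <- small_config()
  cal <- toy_calibration()
  hits <- vapply(1:20, function(s) {
    stack <- render_stack(make_truth(molecule_frame(character(0),
                                                    numeric(0), numeric(0),
                                                    numeric(0), numeric(0)),
                                     cfg), cfg, seed = 100 + s)
    f <- detect_foci(stack, "TelG")
    f <- apply_detection_threshold(f, cal)
    sum(f$passes_threshold)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("threshold uses the at-least rule and fills estimated lengths", {
  cal <- toy_calibration(mean_810 = 810)
  f <- toy_focus("TelG", "halo", intensity = c(809.99, 810, 810.01))
  f <- apply_detection_threshold(f, cal)
  expect_equal(f$passes_threshold, c(FALSE, TRUE, TRUE))
  expect_equal(f$estimated_bp, c(809.99, 810, 810.01), tolerance = 1e-9)
  cen <- apply_detection_threshold(toy_focus("CEN", "core", 5), cal)
  expect_true(cen$passes_threshold)
  expect_error(apply_detection_threshold(f, NULL), "calibration")
})

test_that("simulated 810-bp molecules pass a mean-centered threshold about half the time", {
  cfg <- small_config()
  set.seed(55)
  stacks_foci <- lapply(1:6, function(s) {
    pos <- separated_positions(10, cfg, min_dist = 2.2)
    mol <- molecule_frame(rep("G", 10), rep(810, 10),
                          pos[, "z"], pos[, "y"], pos[, "x"])
    stack <- render_stack(make_truth(mol, cfg), cfg, seed = 300 + s)
    detect_foci(stack, "TelG")
  })
  ii <- unlist(lapply(stacks_foci, function(f) f$integrated_intensity))
  pass <- mean(ii >= mean(ii))
  expect_gt(pass, 0.35)
  expect_lt(pass, 0.65)
})

test_that("simulated 1620-bp molecules essentially always pass the 810-bp cut", {
  cfg <- small_config()
  set.seed(56)
  ii <- unlist(lapply(1:6, function(s) {
    pos <- separated_positions(10, cfg, min_dist = 2.2)
    mol <- molecule_frame(rep("G", 10), rep(1620, 10),
                          pos[, "z"], pos[, "y"], pos[, "x"])
    stack <- render_stack(make_truth(mol, cfg), cfg, seed = 400 + s)
    detect_foci(stack, "TelG")$integrated_intensity
  }))
  expect_gt(mean(ii >= 810 * cfg$photons_per_bp), 0.99)
})

test_that("colocalization pairing is exact for coincident foci and symmetric", {
  g <- toy_focus("TelG", "halo", intensity = rep(1000, 4),
                 z = c(2, 2, 3, 3), y = c(3, 6, 9, 2), x = c(3, 6, 9, 4))
  c <- g; c$channel <- "TelC"
  res <- pair_colocalized(g, c, 0.3)
  expect_equal(res$fraction, 1.0)
  expect_equal(nrow(res$pairs), 4L)

  # symmetry: swapping inputs yields the same pair set
  c2 <- toy_focus("TelC", "halo", intensity = rep(1000, 3),
                  z = c(2, 2.05, 3), y = c(3, 6, 9), x = c(3, 6.1, 9))
  r1 <- pair_colocalized(g, c2, 0.3)
  r2 <- pair_colocalized(c2, g, 0.3)
  expect_equal(nrow(r1$pairs), nrow(r2$pairs))
  expect_equal(sort(r1$pairs$centroid_distance_um),
               sort(r2$pairs$centroid_distance_um))

  empty <- pair_colocalized(g, g[0, ], 0.3)
  expect_equal(empty$fraction, 0)
  expect_equal(nrow(empty$pairs), 0L)
  expect_error(pair_colocalized(g, c, -1), "max_distance_um")
})

test_that("each focus joins at most one pair, ties resolved by distance", {
  g <- toy_focus("TelG", "halo", intensity = rep(1, 2),
                 z = c(2, 2), y = c(5, 5.25), x = c(5, 5))
  c <- toy_focus("TelC", "halo", intensity = 1, z = 2, y = 5.1, x = 5)
  res <- pair_colocalized(g, c, 0.3)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$g_id, 1L)  # 0.10 beats 0.15
  expect_equal(res$fraction, 1 / mean(c(2, 1)))
})

test_that("independently placed G and C foci rarely colocalize by chance", {
  set.seed(77)
  n <- 126
  mk <- function(channel, n) toy_focus(channel, "halo", rep(1, n),
                                       z = runif(n, 2, 6),
                                       y = runif(n, 1, 24),
                                       x = runif(n, 1, 24))
  fr <- vapply(1:5, function(i) {
    pair_colocalized(mk("TelG", 126), mk("TelC", 95), 0.3)$fraction
  }, numeric(1))
  expect_lt(mean(fr), 0.15)
})

test_that("chance strand-mixing probability follows exact enumeration", {
  expect_equal(chance_mixed_focus_probability(1, 0.5), 0)
  expect_equal(chance_mixed_focus_probability(2, 0.5), 0.5)
  # enumeration oracle for k = 3: all 2^3 equiprobable strand assignments
  assignments <- expand.grid(rep(list(c("G", "C")), 3))
  mixed <- mean(apply(assignments, 1, function(a) {
    length(unique(a)) == 2
  }))
  expect_equal(chance_mixed_focus_probability(3, 0.5), mixed)
  # minimized over k >= 2 at k = 2
  ks <- 2:12
  expect_equal(min(chance_mixed_focus_probability(ks, 0.5)),
               chance_mixed_focus_probability(2, 0.5))
  expect_error(chance_mixed_focus_probability(0, 0.5), "k_molecules")
  expect_error(chance_mixed_focus_probability(2, 1.5), "p_g")
})
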