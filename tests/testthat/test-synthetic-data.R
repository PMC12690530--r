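test_that("panel generation is deterministic and respects the design", {
  des <- group_design(c("ctrl", "case"), c(4, 4), pseudoreplicates_per_animal = 3)
  str <- two_block_structure(5)
  p1 <- generate_cytokine_panel(des, str, seed = 42)
  p2 <- generate_cytokine_panel(des, str, seed = 42)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_cytokine_panel(des, str, seed = 43)
  expect_false(identical(p1$C01, p3$C01))

  expect_equal(nrow(p1), 8 * 3)  # one row per (animal, pseudo-replicate)
  expect_equal(sort(unique(p1$group)), c("case", "ctrl"))
  expect_equal(max(p1$replicate), 3L)
  # zero missing rate: nothing flagged, all concentrations positive
  vals <- as.matrix(p1[sprintf("C%02d", 1:10)])
  expect_false(anyNA(vals))
  expect_true(all(vals > 0))
})

test_that("planted missingness is left-censored at the requested rate", {
  des <- group_design(c("a", "b"), c(10, 10), pseudoreplicates_per_animal = 1)
  str <- two_block_structure(5, missing_rate = 0.25)
  p <- generate_cytokine_panel(des, str, seed = 7)
  vals <- as.matrix(p[sprintf("C%02d", 1:10)])
  frac <- colMeans(is.na(vals))
  expect_true(all(abs(frac - 0.25) <= 0.05))
  # censored entries sit below every detected value of the same cytokine
  gt <- attr(p, "ground_truth")
  expect_true(nrow(gt$flagged) > 0)
  for (j in seq_len(ncol(vals))) {
    truth_j <- exp(gt$animal_log_means[rep(1:20, each = 1), j])
    flagged_j <- is.na(vals[, j])
    if (any(flagged_j)) {
      expect_lt(max(truth_j[flagged_j]), max(truth_j[!flagged_j]))
    }
  }
})

test_that("planted block correlation separates within from between blocks", {
  # large-n simulation: empirical mean within-block |r| exceeds
  # between-block |r| by at least 0.5 at the strong-contrast setting
  des <- group_design(c("g1", "g2"), c(30, 30), pseudoreplicates_per_animal = 1)
  str <- two_block_structure(8, within = 0.9, between = 0, noise_sd = 0.2)
  p <- collapse_pseudoreplicates(generate_cytokine_panel(des, str, seed = 11))
  r <- correlation_matrix(p, "g1")$r
  blocks <- attr(generate_cytokine_panel(des, str, seed = 11), "ground_truth")$block_of
  same <- outer(blocks, blocks, "==") & upper.tri(r)
  diff_b <- outer(blocks, blocks, "!=") & upper.tri(r)
  expect_gt(mean(abs(r[same])) - mean(abs(r[diff_b])), 0.5)
})

test_that("generator rejects invalid designs and structures", {
  expect_error(group_design(c("a", "a"), c(3, 3)), class = "ivdnet_bad_design")
  expect_error(group_design(c("a", "b"), c(1, 3)), class = "ivdnet_bad_design")
  expect_error(group_design("only_one", 3), class = "ivdnet_bad_design")
  expect_error(
    correlation_structure(list(c("x", "y"), c("y", "z"))),
    class = "ivdnet_bad_structure"
  )
  expect_error(
    correlation_structure(list(c("x", "y")), within_block_r = 0.5,
                          between_block_r = 0.7),
    class = "ivdnet_bad_argument"
  )
  expect_error(
    correlation_structure(list(c("x", "y")),
                          upregulated = list(g = c(x = -2))),
    class = "ivdnet_bad_structure"
  )
})

test_that("disc phantoms are deterministic with exact ground-truth masks", {
  spec <- small_phantom_spec(noise_sd = 2)
  ph1 <- generate_disc_volume(spec, seed = 5)
  ph2 <- generate_disc_volume(spec, seed = 5)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_true(all(ph1$masks$np <= ph1$masks$disc))

  # ground-truth NPVF within 2% of the analytic solid-volume ratio
  v_np <- 4 / 3 * pi * prod(spec$np_geometry$semiaxes)
  v_disc <- pi * prod(spec$disc_geometry$radius) *
    (2 * spec$disc_geometry$half_height)
  npvf_truth <- sum(ph1$masks$np) / sum(ph1$masks$disc)
  expect_equal(npvf_truth, v_np / v_disc, tolerance = 0.02)

  # uniform intensity: ground-truth NI/DI from the masks is exactly 1
  uniform <- disc_volume(array(100, spec$grid_shape), spec$voxel_size)
  m <- morphometry_metrics(uniform, ph1$masks)
  expect_equal(m$nidi, 1)

  expect_error(
    disc_phantom_spec(np_geometry = list(center = c(36.5, 36.5, 36.5),
                                         semiaxes = c(40, 10, 10))),
    class = "ivdnet_bad_phantom"
  )
})

test_that("loading traces follow the protocol closed form", {
  proto <- loading_protocol(frequency = 1, n_cycles = 20, sample_rate = 100,
                            phase_delta = 0, noise_sd = 0)
  tr <- generate_loading_trace(proto, seed = 1)
  expect_equal(nrow(tr), 2000)
  # elastic case: force is an affine function of displacement
  fit <- lm(force_N ~ displacement_um, data = tr)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(unname(coef(fit)[2]), proto$stiffness, tolerance = 1e-9)

  tr2 <- generate_loading_trace(proto, seed = 1)
  expect_identical(tr$force_N, tr2$force_N)
  expect_error(loading_protocol(sample_rate = 5), class = "ivdnet_bad_protocol")
})

test_that("GTT series are emitted in stated order at fixed times", {
  s <- generate_gtt_series(200, c(400, 400, 300))
  expect_equal(s$time_h, c(0, 0.5, 1.0, 1.5))
  expect_equal(s$glucose_mg_dl, c(200, 400, 400, 300))
  expect_equal(generate_gtt_series(100, c(100, 100, 100))$glucose_mg_dl,
               rep(100, 4))
  s1 <- generate_gtt_series(200, c(400, 400, 300), noise_sd = 10, seed = 3)
  s2 <- generate_gtt_series(200, c(400, 400, 300), noise_sd = 10, seed = 3)
  expect_identical(s1, s2)
  expect_error(generate_gtt_series(200, c(400, 400)), class = "ivdnet_bad_gtt")
})
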