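make_panel <- function(df) {
  tibble::as_tibble(df)
}

test_that("pseudo-replicate collapse takes the median of detected values", {
  panel <- make_panel(data.frame(
    animal_id = c("a1", "a1", "a2", "a2", "a2"),
    group = "g",
    replicate = c(1L, 2L, 1L, 2L, 3L),
    CK1 = c(1, 3, 2, NA, 4),
    CK2 = c(5, NA, NA, NA, NA)
  ))
  out <- collapse_pseudoreplicates(panel)
  expect_equal(nrow(out), 2)
  expect_equal(out$CK1[out$animal_id == "a1"], 2)   # median of two
  expect_equal(out$CK1[out$animal_id == "a2"], 3)   # median over detected only
  expect_equal(out$CK2[out$animal_id == "a1"], 5)   # single replicate unchanged
  expect_true(is.na(out$CK2[out$animal_id == "a2"]))  # all replicates flagged

  # idempotence: collapsing a collapsed panel is the identity
  again <- collapse_pseudoreplicates(out)
  expect_equal(as.data.frame(again), as.data.frame(out))
})

test_that("missingness filter excludes strictly above the threshold", {
  n <- 18
  panel <- make_panel(data.frame(
    animal_id = sprintf("a%02d", 1:n), group = "g", replicate = 1L,
    none = runif(n) + 1,
    five_of_18 = c(rep(NA, 5), runif(n - 5) + 1),     # 27.8% > 25% -> out
    exactly_25pct = c(rep(NA, 4.5 * 0), runif(n) + 1) # placeholder, replaced below
  ))
  # exactly 25% flagged: 4.5 of 18 is impossible, use 16 animals for the
  # boundary case instead
  panel16 <- make_panel(data.frame(
    animal_id = sprintf("a%02d", 1:16), group = "g", replicate = 1L,
    boundary = c(rep(NA, 4), runif(12) + 1)  # exactly 25%
  ))
  res <- filter_missingness(panel[c("animal_id", "group", "replicate",
                                    "none", "five_of_18")])
  expect_equal(res$excluded$cytokine, "five_of_18")
  expect_true("none" %in% names(res$panel))
  expect_false("five_of_18" %in% names(res$panel))

  res16 <- filter_missingness(panel16)
  expect_equal(nrow(res16$excluded), 0)  # retained: exclusion needs > 25%
})

test_that("welch_test matches the closed form and the reference implementation", {
  w <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3))  # = -3.674
  expect_equal(w$t, -3.674, tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.0214, tolerance = 1e-2)

  # cross-check against stats::t.test over random samples
  withr::with_seed(99, {
    for (i in 1:25) {
      a <- rlnorm(sample(3:10, 1), 4, 0.5)
      b <- rlnorm(sample(3:10, 1), 4.2, 0.8)
      ref <- t.test(a, b)
      w <- welch_test(a, b)
      expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(w$p, ref$p.value, tolerance = 1e-10)
      # antisymmetry: swapping arguments negates t, preserves df and p
      ws <- welch_test(b, a)
      expect_equal(ws$t, -w$t)
      expect_equal(ws$df, w$df)
      expect_equal(ws$p, w$p)
    }
  })
})

test_that("welch_test handles identity, large shifts and degenerate input", {
  x <- c(1, 2, 3)
  w <- welch_test(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  big <- welch_test(x, x + 1000)
  expect_lt(big$p, 1e-6)
  deg <- welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  deg2 <- welch_test(c(2, 2, 2), c(3, 3, 3))
  expect_true(deg2$degenerate)
  expect_equal(deg2$p, 0)
  expect_error(welch_test(1, c(1, 2)), class = "ivdnet_too_few_values")
})

test_that("differential screen flags only upregulated significant cytokines", {
  des <- group_design(c("case", "ctrl"), c(9, 3), pseudoreplicates_per_animal = 2)
  str <- independent_structure(
    10, noise_sd = 0.2,
    upregulated = list(case = c(C01 = 3, C02 = 1 / 3))
  )
  panel <- collapse_pseudoreplicates(generate_cytokine_panel(des, str, seed = 21))
  scr <- differential_screen(panel, "case", "ctrl")
  expect_true(scr$upregulated[scr$cytokine == "C01"])
  # C02 is strongly DOWN: significant but never flagged (one-direction rule)
  row2 <- scr[scr$cytokine == "C02", ]
  expect_lt(row2$mean_case, row2$mean_control)
  expect_false(row2$upregulated)
  expect_equal(scr$cytokine[1], "C01")  # sorted by p
  expect_error(differential_screen(panel, "case", "nope"),
               class = "ivdnet_unknown_group")
})

test_that("fold changes divide by the control mean and are scale invariant", {
  panel <- make_panel(data.frame(
    animal_id = c("c1", "c2", "c3", "m1", "m2"),
    group = c("ctrl", "ctrl", "ctrl", "model", "model"),
    replicate = 1L,
    CK = c(1, 2, 3, 4, 6)
  ))
  fc <- fold_change_analysis(panel, "model", "ctrl")
  expect_equal(fc$fc, c(2, 3))  # control mean 2, cases 4 and 6

  at_mean <- panel
  at_mean$CK[4] <- 2
  expect_equal(fold_change_analysis(at_mean, "model", "ctrl")$fc[1], 1)

  scaled <- panel
  scaled$CK <- scaled$CK * 37.5
  expect_equal(fold_change_analysis(scaled, "model", "ctrl")$fc, fc$fc)

  zero_ctrl <- panel
  zero_ctrl$CK[1:3] <- NA
  expect_error(fold_change_analysis(zero_ctrl, "model", "ctrl"),
               class = "ivdnet_bad_control_mean")
})

test_that("fold-change comparison detects planted between-model differences", {
  fc1 <- tibble::tibble(model = "m1", animal_id = sprintf("a%d", 1:6),
                        cytokine = "CK", fc = c(1.0, 1.1, 0.9, 1.05, 0.95, 1.0))
  fc_same <- fc1
  fc_same$model <- "m2"
  same <- compare_fold_changes(fc1, fc_same)
  expect_equal(same$p, 1)
  expect_true(is.na(same$higher_model))

  fc2 <- fc1
  fc2$model <- "m2"
  fc2$fc <- fc1$fc * 2
  diff <- compare_fold_changes(fc1, fc2)
  expect_lt(diff$p, 0.01)
  expect_equal(diff$higher_model, "m2")

  fc3 <- fc2
  fc3$cytokine <- "OTHER"
  expect_error(compare_fold_changes(fc1, fc3, cytokines = "OTHER"),
               class = "ivdnet_unknown_cytokine")
})
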