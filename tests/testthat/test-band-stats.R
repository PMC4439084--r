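test_that("per-bin t matches the pooled closed form and t.test", {
  # worked 4-vs-4 example: A = {0,0,1,1}, B = {2,2,3,3} at one bin
  a_vals <- c(0, 0, 1, 1)
  b_vals <- c(2, 2, 3, 3)
  ga <- lapply(seq_len(4), function(i)
    new_modspec(c(a_vals[i], 5), cell_id = sprintf("a%d", i)))
  gb <- lapply(seq_len(4), function(i)
    new_modspec(c(b_vals[i], 5), cell_id = sprintf("b%d", i)))
  sm <- compare_groups(ga, gb, alpha = 0.05)
  # hand evaluation: sp2 = 1/3, t = -2 / sqrt((1/3)(1/2)) = -sqrt(24), df = 6
  expect_equal(sm$t_values[1], -sqrt(24), tolerance = 1e-10)
  expect_equal(sm$p_values[1], 2 * pt(-sqrt(24), 6), tolerance = 1e-12)
  tt <- t.test(a_vals, b_vals, var.equal = TRUE)
  expect_equal(sm$t_values[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(sm$p_values[1], tt$p.value, tolerance = 1e-12)
  # constant bin: zero variance, equal means -> t = 0, p = 1
  expect_identical(sm$t_values[2], 0)
  expect_identical(sm$p_values[2], 1)
})

test_that("Welch option reproduces stats::t.test without pooling", {
  set.seed(4)
  ga <- noise_spectra(5, 3, "a")
  gb <- lapply(noise_spectra(7, 3, "b"), function(s) {
    s$values <- 2 * s$values + 1; s
  })
  sm <- compare_groups(ga, gb, welch = TRUE)
  for (j in 1:3) {
    tt <- t.test(sapply(ga, function(s) s$values[j]),
                 sapply(gb, function(s) s$values[j]))
    expect_equal(sm$t_values[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(sm$p_values[j], tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give t = 0 everywhere and an empty mask", {
  set.seed(1)
  g <- noise_spectra(6, 40)
  sm <- compare_groups(g[1:3], lapply(g[1:3], function(s) {
    s$cell_id <- paste0("copy_", s$cell_id); s
  }))
  expect_true(all(sm$t_values == 0))
  expect_false(any(sm$mask))

  one <- lapply(1:3, function(i) new_modspec(c(i, i), cell_id = paste0("x", i)))
  two <- lapply(1:3, function(i) new_modspec(c(i, i), cell_id = paste0("y", i)))
  sm2 <- compare_groups(one, two)
  expect_identical(sm2$t_values, c(0, 0))
  expect_identical(sm2$p_values, c(1, 1))
})

test_that("comparison is antisymmetric in the group order", {
  set.seed(2)
  ga <- noise_spectra(5, 30, "a")
  gb <- noise_spectra(6, 30, "b")
  ab <- compare_groups(ga, gb)
  ba <- compare_groups(gb, ga)
  expect_equal(ab$p_values, ba$p_values, tolerance = 1e-14)
  expect_equal(ab$t_values, -ba$t_values, tolerance = 1e-14)
})

test_that("null calibration holds on independent-noise fixtures", {
  set.seed(3)
  ga <- noise_spectra(30, 2000, "a")
  gb <- noise_spectra(30, 2000, "b")
  sm <- compare_groups(ga, gb, alpha = 0.05)
  frac <- mean(sm$mask)
  # binomial 3-sigma band around 0.05 over 2000 independent bins
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_identical(sum(compare_groups(ga, gb, alpha = 1e-7)$mask), 0L)
})

test_that("group size and axis mismatches are rejected", {
  g <- noise_spectra(3, 10)
  expect_error(compare_groups(g[1], g[2:3]), "at least 2")
  shifted <- lapply(g, function(s) { s$axis <- s$axis + 1; s })
  expect_error(compare_groups(g, shifted), "axis")
})

test_that("significant regions are maximal runs of at least min_run bins", {
  mk <- function(mask) {
    structure(list(axis = seq_along(mask), t_values = numeric(length(mask)),
                   p_values = ifelse(mask, 1e-9, 1), alpha = 1e-7,
                   mask = mask, df = 2, n_a = 2, n_b = 2),
              class = "significance_map")
  }
  expect_identical(nrow(significant_regions(mk(rep(FALSE, 5)), 1)), 0L)
  r <- significant_regions(mk(c(FALSE, TRUE, TRUE, TRUE, FALSE)), 2)
  expect_identical(nrow(r), 1L)
  expect_equal(r$start, 2)
  expect_equal(r$end, 4)
  expect_identical(r$n_bins, 3L)
  expect_identical(nrow(significant_regions(mk(c(TRUE, FALSE, TRUE)), 2)), 0L)
})

test_that("bands differing between classes cover the differing peak only", {
  acq <- acquisition_config(n_bins = 600)
  base <- c(1305, 1450, 1660)
  bg <- background_model(scale = 10)
  backbone <- lapply(base, raman_peak, width = 8, amplitude = 1)
  # class A adds one modest band at 1007; keeping it small limits the
  # norm-coupling of the shared bands so only 1007 should light up
  ma <- cell_class_model("A", c(backbone, list(raman_peak(1007, 8, 0.3))),
                         background = bg, amplitude_cv = 0.05,
                         noise_sigma = 0.02)
  mb <- cell_class_model("B", backbone, background = bg,
                         amplitude_cv = 0.05, noise_sigma = 0.02)
  ds <- generate_dataset(list(ma, mb), 20, default_donors(1), acq, seed = 8)
  sp <- extract_dataset(ds)
  labs <- vapply(sp, `[[`, character(1), "class_label")
  sm <- compare_groups(sp[labs == "A"], sp[labs == "B"])
  reg <- significant_regions(sm, 3)
  expect_gt(nrow(reg), 0)
  # every region sits in the neighbourhood of the differing 1007 band
  expect_true(all(reg$start > 1007 - 40 & reg$end < 1007 + 40))
})
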