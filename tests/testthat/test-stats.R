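test_that("comparative-Cq fold induction reproduces worked examples", {
  cq <- example_cq_table()
  res <- fold_induction(cq, "NDM29", "GAPDH", "Mock")
  expect_equal(res$fold[res$group == "Mock"], 1)
  expect_equal(res$ddcq[res$group == "S1.1"], -2)
  expect_equal(res$fold[res$group == "S1.1"], 4)
  # all Cq equal across groups -> fold 1
  cq0 <- cq; cq0$cq <- c(24, 20, 24, 20)
  expect_equal(fold_induction(cq0, "NDM29", "GAPDH", "Mock")$fold,
               c(1, 1))
  # treated target one cycle higher, refs equal -> fold 0.5
  cq1 <- cq; cq1$cq <- c(24, 20, 25, 20)
  expect_equal(
    fold_induction(cq1, "NDM29", "GAPDH", "Mock")$fold[2], 0.5)
})

test_that("fold induction averages replicates and is shift invariant", {
  set.seed(8)
  cq <- rbind(example_cq_table(), example_cq_table())  # technical replicates
  cq$cq <- cq$cq + rnorm(nrow(cq), 0, 0.05)
  base <- fold_induction(cq, "NDM29", "GAPDH", "Mock")
  shifted <- cq; shifted$cq <- shifted$cq + 5.37
  res2 <- fold_induction(shifted, "NDM29", "GAPDH", "Mock")
  expect_lt(abs(res2$fold[2] - base$fold[2]), 1e-12)
  expect_error(fold_induction(cq, "DNMT1", "GAPDH", "Mock"), "not present")
  expect_error(fold_induction(cq, "NDM29", "GAPDH", "sham"), "control group")
})

test_that("plate normalization gives percent of control with blank correction", {
  plate <- data.frame(gene = c("FASL", "GAPDH", "FASL", "GAPDH"),
                      group = c("control", "control", "treated", "treated"),
                      lum = c(1000, 1000, 550, 1000))
  res <- plate_normalize(plate, blank = 100)
  tr <- res[res$group == "treated", ]
  expect_equal(tr$percent_of_control, 50)
  expect_equal(tr$percent_change, -50)
  # treated identical to control -> 100%
  plate2 <- plate; plate2$lum <- c(1000, 1000, 1000, 1000)
  expect_equal(
    plate_normalize(plate2, 100)$percent_of_control, c(100, 100))
  # invariance under rescaling all luminescence (blank rescaled too)
  plate3 <- plate; plate3$lum <- plate$lum * 3.5
  res3 <- plate_normalize(plate3, blank = 350)
  expect_equal(res3$percent_of_control, res$percent_of_control,
               tolerance = 1e-12)
  expect_error(plate_normalize(plate, blank = 1000), "exceed the blank")
})

test_that("compare_groups matches the textbook pooled-t closed form", {
  a <- c(1.1, 2.4, 3.0, 2.2, 1.7)
  b <- c(2.9, 3.8, 3.3, 4.4, 3.6, 4.0)
  cmp <- compare_groups(a, b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p_ref <- 2 * pt(-abs(t_ref), na + nb - 2)
  expect_lt(abs(cmp$t - t_ref), 1e-10)
  expect_lt(abs(cmp$p - p_ref), 1e-10)
  expect_equal(cmp$df, na + nb - 2)
  # identical groups: t = 0, p = 1, no stars
  cmp0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)
  expect_equal(cmp0$stars, "")
  # strong shift: ***
  expect_equal(compare_groups(c(1, 2, 3), c(11, 12, 13))$stars, "***")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  # Welch variant exists and differs when variances differ
  a2 <- c(1, 2, 3, 4); b2 <- c(10, 30, 50, 80)
  expect_false(isTRUE(all.equal(compare_groups(a2, b2)$p,
                                compare_groups(a2, b2, welch = TRUE)$p)))
})

test_that("significance stars use the <= boundary convention", {
  expect_equal(significance_stars(0.05), "*")
  expect_equal(significance_stars(0.010000), "**")
  expect_equal(significance_stars(0.001), "***")
  expect_equal(significance_stars(0.0011), "**")
  expect_equal(significance_stars(0.051), "")
  expect_error(significance_stars(1.2))
})

test_that("morphometry_contrasts compares each parameter between two groups", {
  set.seed(30)
  mor <- data.frame(
    group = rep(c("Mock", "S1.1"), each = 12),
    volume_um3 = c(rnorm(12, 638, 50), rnorm(12, 486, 50)),
    elongation = c(rnorm(12, 1.34, 0.1), rnorm(12, 1.86, 0.1)),
    compactness = c(rnorm(12, 0.0080, 5e-4), rnorm(12, 0.0086, 5e-4)),
    chromatin_density = c(rnorm(12, 0.254, 0.02), rnorm(12, 0.319, 0.02)))
  ct <- morphometry_contrasts(mor)
  expect_equal(nrow(ct), 4L)
  expect_true(all(ct$p <= 0.05))
  expect_true(all((ct$mean_a > ct$mean_b) ==
                    c(TRUE, FALSE, FALSE, FALSE)))
  expect_error(morphometry_contrasts(mor[mor$group == "Mock", ]),
               "exactly 2 groups")
})
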