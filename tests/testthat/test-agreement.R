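test_that("ICC is 1 for perfect agreement and separates the two models", {
  x <- cbind(c(4, 7, 2, 9, 5), c(4, 7, 2, 9, 5))
  expect_equal(icc(x, "two_way_random_2_1")$icc, 1)
  expect_equal(icc(x, "two_way_mixed_3_1")$icc, 1)

  # constant offset: consistency stays perfect, absolute agreement drops
  y <- cbind(c(4, 7, 2, 9, 5), c(4, 7, 2, 9, 5) + 3)
  expect_equal(icc(y, "two_way_mixed_3_1")$icc, 1)
  expect_lt(icc(y, "two_way_random_2_1")$icc, 1)

  # all ratings identical: degenerate, warn
  expect_warning(z <- icc(matrix(5, 4, 2), "two_way_mixed_3_1"),
                 "zero total variance")
  expect_equal(z$icc, 1)
})

test_that("ICC matches an explicit ANOVA sum-of-squares oracle", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(5:10, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, mean = 10, sd = 2), n, k) +
      rnorm(n, sd = 3)  # subject effect
    for (model in c("two_way_random_2_1", "two_way_mixed_3_1")) {
      expect_equal(icc(x, model)$icc, brute_icc(x, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("ICC point estimates and CIs match an independent implementation", {
  # frozen reference values computed with pingouin.intraclass_corr
  fixA <- matrix(c(9.1, 9.3, 8.8,
                   6.2, 6.0, 6.5,
                   7.7, 8.1, 7.5,
                   5.0, 5.4, 5.1,
                   8.4, 8.2, 8.6,
                   4.9, 5.2, 4.6), 6, 3, byrow = TRUE)
  a21 <- icc(fixA, "two_way_random_2_1")
  a31 <- icc(fixA, "two_way_mixed_3_1")
  expect_equal(a21$icc, 0.978656441052, tolerance = 1e-10)
  expect_equal(a31$icc, 0.978125677923, tolerance = 1e-10)
  expect_equal(round(c(a21$ci_low, a21$ci_high), 2), c(0.92, 1))
  expect_equal(round(c(a31$ci_low, a31$ci_high), 2), c(0.91, 1))

  fixB <- fixA; fixB[, 3] <- fixB[, 3] + 1.5
  b21 <- icc(fixB, "two_way_random_2_1")
  b31 <- icc(fixB, "two_way_mixed_3_1")
  expect_equal(b21$icc, 0.809533784188, tolerance = 1e-10)
  expect_equal(b31$icc, 0.978125677923, tolerance = 1e-10)
  expect_equal(round(c(b21$ci_low, b21$ci_high), 2), c(0.13, 0.97))
})

test_that("ICC(3,1) is offset invariant; ICC(2,1) strictly decreases", {
  set.seed(23)
  subj <- rnorm(6, 10, 3)
  x <- cbind(subj + rnorm(6, sd = 0.3), subj + rnorm(6, sd = 0.3))
  xoff <- x; xoff[, 2] <- xoff[, 2] + 2
  expect_equal(icc(xoff, "two_way_mixed_3_1")$icc,
               icc(x, "two_way_mixed_3_1")$icc, tolerance = 1e-12)
  expect_lt(icc(xoff, "two_way_random_2_1")$icc,
            icc(x, "two_way_random_2_1")$icc)
})

test_that("interpretation bands assign boundaries to the lower band", {
  expect_equal(icc_interpret(c(0.49, 0.50, 0.75, 0.76, 0.90, 0.91)),
               c("poor", "moderate", "moderate", "good", "good", "excellent"))
})

test_that("Bland-Altman reproduces hand-computed statistics", {
  # identical pairs
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # differences {+1, -1, +1, -1}: bias 0, sample SD = 2/sqrt(3)
  a <- c(5, 5, 5, 5); b <- a - c(1, -1, 1, -1)
  # d is exactly linear in the pair means here, so lm warns of a perfect fit
  ba <- suppressWarnings(bland_altman(a, b))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * 2 / sqrt(3), tolerance = 1e-12)

  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman invariants: antisymmetry and LoA width", {
  set.seed(31)
  for (rep in 1:5) {
    a <- rnorm(20, 10, 3); b <- a + rnorm(20, 0.2, 0.8)
    ab <- bland_altman(a, b); ba <- bland_altman(b, a)
    expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
    expect_equal(ab$loa_high - ab$loa_low, 2 * 1.96 * ab$sd_diff,
                 tolerance = 1e-12)
    expect_lte(ab$loa_low, ab$bias)
    expect_lte(ab$bias, ab$loa_high)
  }
})

test_that("proportional bias slope detects a trend in the differences", {
  set.seed(37)
  m <- seq(1, 20, length.out = 40)
  a <- m + 0.2 * m + rnorm(40, sd = 0.1)  # difference grows with the mean
  ba <- bland_altman(a, m)
  expect_lt(ba$proportional_bias_p, 0.001)
  expect_gt(ba$proportional_bias_slope, 0.1)
})

test_that("Dice coefficient counts overlap correctly", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  # two 10x10 squares overlapping in a 10x5 strip
  c2 <- matrix(FALSE, 20, 20); c2[1:10, 6:15] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(a, c2), dice(c2, a))
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shape mismatch")
  expect_warning(d0 <- dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)),
                 "empty")
  expect_equal(d0, 1)
})

test_that("grouped errors reflect injected per-group noise", {
  sch <- fdi_schema()
  posterior <- sch$fdi_code[sch$tooth_type %in% default_tooth_selection()]
  set.seed(41)
  ids <- sprintf("img%02d", 1:30)
  ref <- dplyr::bind_rows(lapply(ids, function(id)
    make_records(id, posterior, rnorm(length(posterior), 0, 4), sch)))

  # identical records: zero MAE, unit ICC
  g0 <- grouped_errors(ref, ref, "tooth_type")
  expect_equal(g0$mae, rep(0, 5))
  expect_equal(g0$icc, rep(1, 5))

  # constant offset shows up as the MAE in every group
  off <- ref; off$angle_deg <- off$angle_deg + 0.5
  g1 <- grouped_errors(off, ref, "arch")
  expect_equal(g1$mae, rep(0.5, 2), tolerance = 1e-12)

  # per-group noise SDs order the group MAEs
  sds <- c("canine" = 0.1, "first premolar" = 0.3, "second premolar" = 0.6,
           "first molar" = 1.2, "second molar" = 2.4)
  noisy <- ref
  noisy$angle_deg <- ref$angle_deg + rnorm(nrow(ref), 0,
                                           sds[ref$tooth_type])
  g2 <- grouped_errors(noisy, ref, "tooth_type")
  expect_equal(g2$group[order(g2$mae)], names(sort(sds)))
})

test_that("repeat sensitivity summarizes absolute differences", {
  sch <- fdi_schema()
  fdis <- c("13", "14", "15", "16")
  r1 <- make_records("p1", fdis, c(10, 10, 10, 10), sch)
  r2 <- make_records("p1", fdis, c(10.5, 11.5, 12.5, 13.5), sch)
  s <- repeat_sensitivity(r2, r1)  # diffs 0.5, 1.5, 2.5, 3.5
  expect_equal(s$mean_abs_diff, 2)
  expect_equal(s$max_abs_diff, 3.5)
  expect_equal(s$frac_gt_1deg, 0.75)
  expect_equal(s$frac_gt_2deg, 0.5)
  expect_equal(s$n_teeth, 4L)

  s0 <- repeat_sensitivity(r1, r1)
  expect_equal(s0$mean_abs_diff, 0)
  expect_equal(s0$max_abs_diff, 0)

  # ordering invariant on random inputs
  set.seed(43)
  for (rep in 1:5) {
    ra <- make_records("p", fdis, rnorm(4, 0, 5), sch)
    rb <- make_records("p", fdis, rnorm(4, 0, 5), sch)
    ss <- repeat_sensitivity(ra, rb)
    expect_lte(ss$mean_abs_diff, ss$p95_abs_diff)
    expect_lte(ss$p95_abs_diff, ss$max_abs_diff)
    expect_lte(ss$frac_gt_2deg, ss$frac_gt_1deg)
  }

  expect_error(suppressMessages(
    repeat_sensitivity(make_records("a", "13", 1, sch),
                       make_records("b", "13", 1, sch))),
    "no matched")
})

test_that("exclusion accounting balances the screening ledger", {
  scr <- example_screening_counts()
  expect_equal(nrow(scr$exclusions), 9L)
  expect_equal(exclusion_accounting(scr$collected, scr$exclusions), 214L)
  expect_equal(exclusion_accounting(100, numeric(0)), 100L)
  expect_error(exclusion_accounting(10, c(6, 6)), "exceed")
  expect_error(exclusion_accounting(10, c(-1, 2)), "non-negative")
})
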