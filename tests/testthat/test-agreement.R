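test_that("coefficient of variation uses the sample SD in percent", {
  expect_equal(cov_pct(c(1, 3)), 100 * sqrt(2) / 2)
  expect_equal(round(cov_pct(c(1, 3)), 2), 70.71)
  expect_equal(cov_pct(rep(5.5, 8)), 0)
  v <- vector_with_moments(64.69, 7.76)
  expect_equal(mean(v), 64.69)
  expect_equal(sd(v), 7.76)
  expect_equal(round(cov_pct(v), 2), 12.00)
  expect_error(cov_pct(3), "two values")
  expect_error(cov_pct(c(-1, 1)), "mean is zero")
})

test_that("overlap coefficients match set-arithmetic oracles and each other", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_blob_mask(); b <- random_blob_mask()
    expect_equal(dsc(a, b), oracle_dsc(a, b))
    expect_equal(jaccard(a, b), oracle_jaccard(a, b))
    expect_equal(dsc(a, b), dsc_from_jaccard(jaccard(a, b)),
                 tolerance = 1e-12)
  }
  m <- random_blob_mask()
  expect_equal(dsc(m, m), 1)
  expect_equal(jaccard(m, m), 1)
  expect_equal(round(dsc_from_jaccard(0.42), 2), 0.59)
  e <- voi_mask(array(FALSE, c(4, 4, 4)), test_spacing, allow_empty = TRUE)
  expect_warning(expect_equal(dsc(e, e), 1), "empty")
  expect_error(dsc_from_jaccard(1.2), "0, 1")
})

test_that("surface distances are exact on hand-computable geometry", {
  m1 <- array(FALSE, c(5, 5, 7)); m1[3, 3, 2] <- TRUE
  m2 <- array(FALSE, c(5, 5, 7)); m2[3, 3, 5] <- TRUE
  a <- voi_mask(m1, c(2.03135, 2.03135, 3))
  b <- voi_mask(m2, c(2.03135, 2.03135, 3))
  expect_equal(hausdorff_mm(a, b), 9)     # three 3-mm slices apart
  expect_equal(masd_mm(a, b), 9)
  expect_equal(hausdorff_mm(a, a), 0)
  expect_equal(masd_mm(b, b), 0)
  expect_error(hausdorff_mm(a, voi_mask(array(FALSE, c(5, 5, 7)),
                                        c(2.03135, 2.03135, 3),
                                        allow_empty = TRUE)),
               "empty")
})

test_that("surface distances equal the exhaustive all-pairs oracle", {
  set.seed(123)
  for (i in 1:10) {
    a <- random_blob_mask(c(8, 9, 7)); b <- random_blob_mask(c(8, 9, 7))
    o <- oracle_hd_masd(a, b)
    expect_equal(hausdorff_mm(a, b), o$hd, tolerance = 1e-9)
    expect_equal(masd_mm(a, b), o$masd, tolerance = 1e-9)
    # symmetry and the HD >= MASD ordering
    expect_equal(hausdorff_mm(b, a), hausdorff_mm(a, b))
    expect_equal(masd_mm(b, a), masd_mm(a, b))
    expect_gte(hausdorff_mm(a, b), masd_mm(a, b))
  }
})

test_that("ICC(2,1) reproduces independent fixtures to high precision", {
  # classic 6 x 4 reliability example
  x <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  r <- icc21(x)
  expect_equal(r$estimate, 0.289763779528, tolerance = 1e-11)
  expect_equal(r$ci_low, 0.018786513375, tolerance = 1e-9)
  expect_equal(r$ci_high, 0.761084369649, tolerance = 1e-9)
  expect_equal(r$estimate, oracle_icc21(x), tolerance = 1e-12)
  # 5 x 3 volumes-like matrix: estimate equals the mean-squares formula
  y <- matrix(c(10.1, 10.6, 10.3,
                14.2, 14.9, 14.0,
                9.8, 10.1, 10.4,
                12.3, 12.9, 12.5,
                11.1, 11.7, 11.3), nrow = 5, byrow = TRUE)
  ry <- icc21(y)
  expect_equal(ry$estimate, oracle_icc21(y), tolerance = 1e-12)
  expect_equal(ry$estimate, 0.964729207972, tolerance = 1e-11)
  expect_equal(ry$ci_low, 0.751316245654, tolerance = 1e-9)
  expect_equal(ry$ci_high, 0.996190087770, tolerance = 1e-9)
  ms <- anova_mean_squares(y)
  expect_equal(ms$ms_rows, 9.292666666667, tolerance = 1e-10)
  expect_equal(ms$ms_cols, 0.372666666667, tolerance = 1e-10)
  expect_equal(ms$ms_error, 0.047666666667, tolerance = 1e-10)
})

test_that("ICC limits and invariances behave as absolute agreement demands", {
  # identical raters, varying subjects: perfect reliability
  base <- c(3, 7, 9, 12, 20)
  perfect <- cbind(base, base, base)
  expect_equal(icc21(perfect)$estimate, 1)
  # adding a constant to every cell changes nothing
  y <- matrix(c(10.1, 10.6, 10.3, 14.2, 14.9, 14.0, 9.8, 10.1, 10.4,
                12.3, 12.9, 12.5, 11.1, 11.7, 11.3), nrow = 5, byrow = TRUE)
  expect_equal(icc21(y + 100)$estimate, icc21(y)$estimate,
               tolerance = 1e-9)
  # per-rater constant shifts reduce absolute agreement
  shifted <- sweep(perfect, 2, c(0, 2, 4), "+")
  expect_lt(icc21(shifted)$estimate, 1)
  expect_lt(icc21(sweep(y, 2, c(0, 3, 6), "+"))$estimate,
            icc21(y)$estimate)
  # degenerate inputs
  expect_warning(rz <- icc21(matrix(5, 4, 3)), "zero total variance")
  expect_equal(rz$estimate, 1)
  expect_error(icc21(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)), "incomplete")
  expect_error(ratings_matrix(matrix(1:3, 3, 1)), "at least 2")
})

test_that("CI interpretation labels follow the reliability bands", {
  expect_equal(fetagree:::koo_li_label(0.63, 0.97), "moderate to excellent")
  expect_equal(fetagree:::koo_li_label(0.44, 0.93), "poor to excellent")
  expect_equal(fetagree:::koo_li_label(0.91, 0.99), "excellent")
  expect_equal(fetagree:::koo_li_label(0.3, 0.45), "poor")
  expect_equal(fetagree:::koo_li_label(0.76, 0.89), "good")
})

test_that("median/range summaries and pairwise tables have the right shape", {
  s <- summarize_values(c(4, 1, 3, 2))
  expect_equal(s$median, 2.5)        # even count: mean of central pair
  expect_equal(s$range, c(1, 4))
  set.seed(11)
  masks <- replicate(3, random_blob_mask(), simplify = FALSE)
  tab <- build_pairwise_table(list(caseA = masks))
  expect_equal(nrow(tab), 3)         # k(k-1)/2 for k = 3
  expect_named(tab, c("case_id", "rater_a", "rater_b", "dsc", "jaccard",
                      "hd_mm", "masd_mm"))
  summ <- summarize_pairwise(tab)
  expect_equal(nrow(summ), 4)        # one row per metric for one case
  i <- which(summ$metric == "dsc")
  expect_equal(summ$mean[i], mean(tab$dsc))
  expect_equal(summ$cov_pct[i], 100 * sd(tab$dsc) / mean(tab$dsc))
})
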