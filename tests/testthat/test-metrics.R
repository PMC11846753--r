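# Aggregation, group/site comparison and the statistical tests.

test_that("patient aggregation pools slice points correctly", {
  mk_field <- function(values_by_slice) {
    purrr::imap_dfr(values_by_slice, function(v, i) {
      tibble::tibble(
        slice_index = rep(i - 1L, 2 * length(v)),
        point_index = rep(seq_along(v), 2),
        time_point = rep(c("maxP", "minP"), each = length(v)),
        pws_kpa = rep(v, 2), pwsn = rep(v / 1000, 2),
        fss_dyn_cm2 = c(v, v / 2),
        erosion = FALSE
      )
    })
  }
  morph <- tibble::tibble(mean_plaque_burden = 0.5, area_stenosis = 0.6,
                          min_cap_thickness_um = 100, mean_cap_thickness_um = 300,
                          mean_lumen_area_mm2 = 5)

  f_const <- mk_field(list(rep(7, 10)))
  row <- aggregate_patient(f_const, morph)
  expect_equal(row$max_pws_kpa, 7)
  expect_equal(row$mean_pws_kpa, 7)
  expect_equal(row$min_fss_dyn_cm2, 7)

  f2 <- mk_field(list(1:100, 101:200))
  row2 <- aggregate_patient(f2, morph)
  expect_equal(row2$max_pws_kpa, 200)
  expect_equal(row2$mean_pws_kpa, 100.5)
  expect_equal(row2$max_fss_dyn_cm2, 200)
  # dFSS is pointwise FSS(maxP) - FSS(minP) = v / 2
  expect_equal(row2$max_dfss_dyn_cm2, 100)
  expect_equal(row2$mean_dfss_dyn_cm2, 50.25)

  f_bad <- f2[f2$slice_index != 1L | f2$point_index != 5L, ]
  expect_error(aggregate_patient(f_bad, morph), "missing points")
})

test_that("a field matching a printed patient row reproduces it", {
  # reconstruct a field whose pooled aggregates equal the P1 row
  target <- c(max_pws = 396.8, mean_pws = 122.6, max_pwsn = 0.3724,
              mean_pwsn = 0.1149, max_fss = 166.97, mean_fss = 63.84,
              min_fss = 9.53)
  n <- 100
  spread <- function(mx, mn, mean, n) {
    v <- seq(mn, mx, length.out = n)
    v + (mean - mean(v)) * (1 - seq(0, 1, length.out = n))^0 # shift preserving ends
  }
  # simple construction: two extremes plus a constant filler hitting the mean
  vals <- function(mx, mn, mean) c(mx, mn, rep((mean * n - mx - mn) / (n - 2), n - 2))
  pws <- vals(target["max_pws"], 10, target["mean_pws"])
  pwsn <- vals(target["max_pwsn"], 0.01, target["mean_pwsn"])
  fss <- vals(target["max_fss"], target["min_fss"], target["mean_fss"])
  field <- tibble::tibble(
    slice_index = 0L, point_index = rep(1:n, 2),
    time_point = rep(c("maxP", "minP"), each = n),
    pws_kpa = rep(pws, 2), pwsn = rep(pwsn, 2), fss_dyn_cm2 = rep(fss, 2),
    erosion = FALSE
  )
  morph <- tibble::tibble(mean_plaque_burden = 0.388, area_stenosis = 0.691,
                          min_cap_thickness_um = 56, mean_cap_thickness_um = 125,
                          mean_lumen_area_mm2 = 5)
  row <- aggregate_patient(field, morph, patient_id = "P1", label = "erosion")
  expect_equal(row$max_pws_kpa, 396.8)
  expect_equal(row$mean_pws_kpa, 122.6, tolerance = 1e-12)
  expect_equal(row$max_pwsn, 0.3724)
  expect_equal(row$mean_pwsn, 0.1149, tolerance = 1e-12)
  expect_equal(row$max_fss_dyn_cm2, 166.97)
  expect_equal(row$mean_fss_dyn_cm2, 63.84, tolerance = 1e-12)
  expect_equal(row$min_fss_dyn_cm2, 9.53)
})

test_that("relative differences match the printed comparisons", {
  expect_equal(relative_difference(127.96, 72.69), 76.04, tolerance = 0.005)
  expect_equal(relative_difference(5, 5), 0)
  expect_equal(relative_difference(83.2, 107.8), -22.82, tolerance = 0.05)
  expect_error(relative_difference(1, 0), "zero denominator")
})

test_that("group summary computes n-1 SDs and flags degenerate groups", {
  t6 <- load_fixture("table6_biomech")
  gs <- group_summary(t6, "max_fss_dyn_cm2")
  expect_equal(gs$eroded_mean, 127.96, tolerance = 0.005)
  expect_equal(gs$eroded_sd, 35.77, tolerance = 0.005)
  expect_equal(gs$non_eroded_mean, 72.69, tolerance = 0.005)
  # the exact rank-sum p reproduces the printed group-comparison values
  expect_lt(abs(gs$p_value - 0.0207), 0.00005)
  gs2 <- group_summary(t6, "mean_pws_kpa")
  expect_lt(abs(gs2$p_value - 0.0281), 0.00005)

  two <- tibble::tibble(label = c("erosion", "no_erosion"), v = c(1, 2))
  gs2 <- group_summary(two, "v")
  expect_true(gs2$sd_undefined)
  expect_true(is.na(gs2$eroded_sd))

  same <- tibble::tibble(label = rep(c("erosion", "no_erosion"), each = 2),
                         v = c(3, 3, 4, 4))
  expect_equal(group_summary(same, "v")$eroded_sd, 0)

  expect_error(group_summary(tibble::tibble(label = "erosion", v = 1), "v"),
               "non-empty")
})

test_that("site comparison partitions points and errors on degenerate masks", {
  pts <- tibble::tibble(
    patient_id = "E1", quantity = "fss",
    value = c(10, 20, 30, 1, 2, 3),
    erosion = rep(c(TRUE, FALSE), each = 3)
  )
  sc <- site_compare(pts)
  expect_equal(sc$with_erosion[sc$stat == "mean"], 20)
  expect_equal(sc$without_erosion[sc$stat == "max"], 3)
  expect_equal(sc$difference_pct[sc$stat == "min"], relative_difference(10, 1))

  all_er <- dplyr::mutate(pts, erosion = TRUE)
  expect_error(site_compare(all_er), "no non-erosion")
  none <- dplyr::mutate(pts, erosion = FALSE)
  expect_error(site_compare(none), "no erosion-labeled")
})

test_that("exact signed-rank and rank-sum tests match enumeration oracles", {
  # all 8 paired differences with the same sign: p = 2 / 2^8
  t7 <- load_fixture("table7_site_fss")
  minfss <- t7[t7$stat == "min", ]
  res <- wilcoxon_test(minfss$with_erosion, minfss$without_erosion, paired = TRUE)
  expect_identical(res$p_value, 2 / 256)
  expect_true(res$exact)

  # enumeration oracle: all 2^8 sign patterns of the observed ranks
  d <- minfss$with_erosion - minfss$without_erosion
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  w_null <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  p_oracle <- min(1, 2 * min(mean(w_null <= w_obs), mean(w_null >= w_obs)))
  expect_identical(res$p_value, p_oracle)

  # identical groups
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value, 1)
  expect_equal(wilcoxon_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)

  # complete separation, unpaired 8 vs 8: p = 2 / C(16, 8)
  res2 <- wilcoxon_test(101:108, 1:8)
  expect_equal(res2$p_value, 2 / choose(16, 8))

  # agreement with the reference implementation on tie-free data
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, 0.5)
    expect_equal(wilcoxon_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    xp <- rnorm(8); yp <- rnorm(8, 0.3)
    expect_equal(wilcoxon_test(xp, yp, paired = TRUE)$p_value,
                 stats::wilcox.test(xp, yp, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  expect_error(wilcoxon_test(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("site-table summaries reproduce the printed fixture statistics", {
  t7 <- load_fixture("table7_site_fss")
  mean_fss <- summarize_site_table(t7[t7$stat == "mean", ])
  expect_equal(mean_fss$with_mean, 71.52, tolerance = 0.005)
  expect_equal(mean_fss$without_mean, 48.11, tolerance = 0.005)
  expect_equal(mean_fss$relative_difference_pct, 48.6, tolerance = 0.1)

  t8 <- load_fixture("table8_site_pws")
  maxpws <- summarize_site_table(t8[t8$quantity == "max_pws_kpa", ])
  expect_equal(maxpws$with_mean, 131.7, tolerance = 0.05)
  expect_equal(maxpws$without_mean, 243.0, tolerance = 0.05)
  expect_identical(maxpws$p_value_paired, 2 / 256)
})

test_that("the KS normality test is calibrated and has power", {
  # calibration: standard-normal draws rarely rejected
  rejections <- vapply(1:40, function(s) {
    set.seed(s)
    normality_test(rnorm(1000))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05)

  # power: heavy tails detected
  set.seed(1)
  expect_lt(normality_test(rt(1000, df = 1))$p_value, 0.05)

  expect_error(normality_test(c(1, 2)), "n >= 3")
  expect_error(normality_test(rep(1, 10)), "constant")
})
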