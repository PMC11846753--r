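# Synthetic cohort generator: determinism, distributional recovery,
# contour construction targets.

test_that("cohorts are bit-identical under the same seed", {
  cfg <- cohort_config(n_eroded = 20, n_non_eroded = 20, seed = 7)
  expect_identical(generate_predictor_cohort(cfg), generate_predictor_cohort(cfg))
  cfg2 <- cohort_config(n_eroded = 20, n_non_eroded = 20, seed = 8)
  expect_false(identical(generate_predictor_cohort(cfg),
                         generate_predictor_cohort(cfg2)))
})

# mean of a normal truncated to [lower, upper]
truncnorm_mean <- function(mu, sd, lower, upper) {
  if (sd == 0) return(mu)
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

test_that("group means recover the configured (truncation-corrected) values", {
  cfg <- cohort_config(n_eroded = 500, n_non_eroded = 500, seed = 11)
  coh <- generate_predictor_cohort(cfg)
  gp <- cfg$group_params
  er <- coh[coh$label == "erosion", ]
  ne <- coh[coh$label == "no_erosion", ]
  for (j in seq_len(nrow(gp))) {
    v <- gp$predictor[j]
    for (grp in list(list(d = er, mu = gp$eroded_mean[j], sd = gp$eroded_sd[j]),
                     list(d = ne, mu = gp$non_eroded_mean[j], sd = gp$non_eroded_sd[j]))) {
      m_target <- truncnorm_mean(grp$mu, grp$sd, gp$lower[j], gp$upper[j])
      se <- grp$sd / sqrt(nrow(grp$d))
      expect_lt(abs(mean(grp$d[[v]]) - m_target), 3.5 * se)
    }
  }
  # the eroded max FSS mean is within 5% of its configured 127.96
  expect_equal(mean(er$max_fss_dyn_cm2), 127.96, tolerance = 0.05)
})

test_that("a null cohort has no group differences beyond noise", {
  cfg <- cohort_config(n_eroded = 200, n_non_eroded = 200, seed = 3,
                       effect_scale = 0)
  coh <- generate_predictor_cohort(cfg)
  gp <- cfg$group_params
  for (j in seq_len(nrow(gp))) {
    v <- gp$predictor[j]
    xe <- coh[[v]][coh$label == "erosion"]
    xn <- coh[[v]][coh$label == "no_erosion"]
    pooled_se <- sqrt(var(xe) / length(xe) + var(xn) / length(xn))
    expect_lt(abs(mean(xe) - mean(xn)), 3.5 * pooled_se)
  }
})

test_that("the correlation knob induces the requested dependence", {
  p <- nrow(default_group_params())
  R <- diag(p)
  R[1, 2] <- R[2, 1] <- 0.9
  cfg <- cohort_config(n_eroded = 400, n_non_eroded = 0, seed = 5, correlation = R)
  coh <- generate_predictor_cohort(cfg)
  expect_gt(cor(coh$max_pws_kpa, coh$mean_pws_kpa), 0.75)
  expect_lt(abs(cor(coh$max_pws_kpa, coh$max_pwsn)), 0.2)
})

test_that("configuration errors are caught", {
  gp <- default_group_params()
  gp$eroded_mean[1] <- NaN
  expect_error(cohort_config(group_params = gp), "non-finite")
  expect_error(cohort_config(effect_scale = -1))
})

test_that("contour patients hit their stenosis target and label invariants", {
  for (st in c(0.3, 0.654)) {
    p <- generate_contour_patient("erosion", seed = 2, n_slices = 8,
                                  stenosis_target = st)
    expect_equal(stenosis_by_area(p$geometry), st, tolerance = 0.02)
  }

  p_no <- generate_contour_patient("no_erosion", seed = 4, n_slices = 6,
                                   stenosis_target = 0.4)
  masks <- lapply(p_no$geometry$slices, function(s) s$erosion_mask)
  expect_identical(sum(unlist(masks)), 0L)
  expect_true(all(vapply(p_no$geometry$slices, function(s) is.null(s$thrombus), logical(1))))

  p_er <- generate_contour_patient("erosion", seed = 4, n_slices = 6,
                                   stenosis_target = 0.4)
  has_thr <- vapply(p_er$geometry$slices, function(s) !is.null(s$thrombus), logical(1))
  expect_true(any(has_thr))
  sl <- p_er$geometry$slices[[which(has_thr)[1]]]
  expect_gt(sum(sl$erosion_mask), 0)
  # erosion-labeled points form a contiguous angular sector
  idx <- which(sl$erosion_mask)
  gaps <- diff(idx)
  expect_lte(sum(gaps > 1), 1)  # at most one wrap-around break
  # thrombus straddles the lumen line (points inside and outside)
  thr_in <- point_in_polygon(sl$thrombus$x, sl$thrombus$y, sl$lumen)
  expect_true(any(thr_in) && any(!thr_in))
  # lumen strictly inside the outer boundary on every slice
  for (s in p_er$geometry$slices) {
    expect_true(all(point_in_polygon(s$lumen$x, s$lumen$y, s$outer)))
  }

  expect_error(generate_contour_patient("erosion", stenosis_target = 0.99),
               "unreachable")
})

test_that("contour patients are reproducible and serialize through JSON", {
  p1 <- generate_contour_patient("erosion", seed = 9, n_slices = 5)
  p2 <- generate_contour_patient("erosion", seed = 9, n_slices = 5)
  expect_equal(p1$geometry$slices[[3]]$lumen, p2$geometry$slices[[3]]$lumen)

  tmp <- withr::local_tempfile(fileext = ".json")
  write_patient_json(p1, tmp)
  back <- read_patient_json(tmp)
  expect_identical(back$label, "erosion")
  expect_equal(length(back$geometry$slices), 5L)
  expect_equal(back$geometry$slices[[3]]$lumen$x, p1$geometry$slices[[3]]$lumen$x,
               tolerance = 1e-12)
  expect_identical(back$geometry$slices[[p1$lesion_slice + 1]]$erosion_mask,
                   p1$geometry$slices[[p1$lesion_slice + 1]]$erosion_mask)
})
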