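# Contour processing and morphology metrics.

test_that("polygon areas match the fan-triangulation oracle", {
  expect_equal(polygon_area(circle_polygon(1, 100)), pi, tolerance = 1e-3)
  sq <- polygon_xy(c(0, 2, 2, 0), c(0, 0, 2, 2))
  expect_identical(polygon_area(sq), 4)
  for (s in 1:5) {
    p <- star_polygon(seed = s)
    expect_equal(polygon_area(p), fan_triangulation_area(p), tolerance = 1e-9)
  }
  bowtie <- polygon_xy(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(polygon_area(bowtie, check = TRUE), "self-intersecting")
})

test_that("four-quarter resampling is symmetric, quarter-exact and idempotent", {
  rs <- resample_four_quarter(circle_polygon(1, 720), 100)
  r <- sqrt(rs$x^2 + rs$y^2)
  expect_lt(max(abs(r - 1)), 1e-4)
  ang <- atan2(rs$y, rs$x) %% (2 * pi)
  gaps <- diff(sort(ang))
  expect_lt(max(abs(gaps - 2 * pi / 100)), 1e-3)
  # point 1 on the +x axis
  expect_lt(abs(rs$y[1]), 1e-9)
  expect_gt(rs$x[1], 0)

  ell <- ellipse_polygon(2, 1, 720)
  re <- resample_four_quarter(ell, 100)
  # 25 points per quarter (quadrant of the centered ellipse)
  quadrant <- findInterval(atan2(re$y, re$x) %% (2 * pi), c(0, pi / 2, pi, 3 * pi / 2))
  expect_identical(as.integer(table(quadrant)), rep(25L, 4))
  # total arc length preserved within 0.5% of the true ellipse perimeter
  perim_true <- 4 * 2 * pracma_ellipke_perimeter(2, 1)
  perim_rs <- sum(sqrt(diff(c(re$x, re$x[1]))^2 + diff(c(re$y, re$y[1]))^2))
  expect_equal(perim_rs, perim_true, tolerance = 0.005)

  re2 <- resample_four_quarter(re, 100)
  expect_lt(max(abs(re2$x - re$x), abs(re2$y - re$y)), 1e-9)
})


test_that("resampling preserves enclosed area for convex contours", {
  for (ab in list(c(1, 1), c(2, 1), c(3, 2))) {
    p <- ellipse_polygon(ab[1], ab[2], 720)
    rs <- resample_four_quarter(p, 100)
    expect_equal(polygon_area(rs), pi * ab[1] * ab[2], tolerance = 0.005)
  }
})

test_that("thrombus removal recovers the lumen and never shrinks it", {
  sl <- circular_slice(1.5, 2.5)
  expect_identical(remove_thrombus(sl), sl)

  # lumen with a 60-degree bite of depth 0.3; thrombus fills the bite
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  bite <- abs(((th - pi / 2) + pi) %% (2 * pi) - pi) < (30 * pi / 180)
  r <- rep(1.5, length(th))
  depth <- 0.3 * cos(((th - pi / 2) / (30 * pi / 180)) * (pi / 2))
  r[bite] <- 1.5 - depth[bite]
  lumen <- polygon_xy(r * cos(th), r * sin(th))
  thr_idx <- which(bite)
  thr <- polygon_xy(
    c(r[thr_idx] * cos(th[thr_idx]), rev(1.505 * cos(th[thr_idx]))),
    c(r[thr_idx] * sin(th[thr_idx]), rev(1.505 * sin(th[thr_idx])))
  )
  sl2 <- contour_slice(0, lumen, circle_polygon(2.5, 240), thrombus = thr,
                       validate = FALSE)
  rec <- remove_thrombus(sl2)
  expect_null(rec$thrombus)
  expect_equal(lumen_area(rec), pi * 1.5^2, tolerance = 0.01)
  expect_gte(lumen_area(rec), lumen_area(sl2))

  # a detached thrombus is dropped with a warning
  far <- circle_polygon(0.2, 60, center = c(0, 0))
  sl3 <- contour_slice(0, circle_polygon(1.5, 120), circle_polygon(2.5, 120),
                       thrombus = far, validate = FALSE)
  expect_warning(rec3 <- remove_thrombus(sl3), "not adjacent")
  expect_equal(rec3$lumen, sl3$lumen)
})

test_that("thrombus removal is area-monotone on eroded synthetic patients", {
  p <- generate_contour_patient("erosion", seed = 11, n_slices = 6,
                                stenosis_target = 0.5)
  pre <- vapply(p$geometry$slices, lumen_area, numeric(1))
  post <- vapply(lapply(p$geometry$slices, remove_thrombus), lumen_area, numeric(1))
  expect_true(all(post >= pre - 1e-9))
})

test_that("lipid trailing edge obeys the two-thirds rule", {
  th <- seq(-pi / 4, pi / 4, length.out = 40)
  lead <- tibble::tibble(x = 2.2 * cos(th), y = 2.2 * sin(th))
  sl <- contour_slice(0, circle_polygon(2, 160), circle_polygon(3.5, 160),
                      lipid = lead, validate = FALSE)
  out <- complete_lipid_trailing_edge(sl)
  lip <- out$lipid
  n_lead <- attr(lip, "leading_edge_n")
  trail_r <- sqrt(lip$x[-(1:n_lead)]^2 + lip$y[-(1:n_lead)]^2)
  expect_equal(trail_r, rep(2.2 + (2 / 3) * (3.5 - 2.2), length(trail_r)),
               tolerance = 1e-3)

  # coincident with the outer boundary -> empty lipid with warning
  lead_out <- tibble::tibble(x = 3.5 * cos(th), y = 3.5 * sin(th))
  sl2 <- contour_slice(0, circle_polygon(2, 160), circle_polygon(3.5, 160),
                       lipid = lead_out, validate = FALSE)
  expect_warning(out2 <- complete_lipid_trailing_edge(sl2), "coincides")
  expect_null(out2$lipid)

  # asymmetric wall: trailing edge strictly inside the outer boundary
  outer <- star_polygon(seed = 4, r0 = 3.5, amp = 0.3)
  sl3 <- contour_slice(0, circle_polygon(2, 160), outer, lipid = lead,
                       validate = FALSE)
  out3 <- complete_lipid_trailing_edge(sl3)
  lip3 <- out3$lipid
  n3 <- attr(lip3, "leading_edge_n")
  trail <- lip3[-(1:n3), ]
  r_tr <- sqrt(trail$x^2 + trail$y^2)
  th_tr <- atan2(trail$y, trail$x)
  r_out <- plaquemech:::polygon_radius_at(outer, th_tr, c(0, 0))
  expect_true(all(r_tr < r_out - 1e-6))
})

test_that("outer-boundary interpolation recovers constant, ramped and end arcs", {
  mk <- function(r, i) contour_slice(i, circle_polygon(0.6 * r, 120),
                                     circle_polygon(r, 120), validate = FALSE)
  arcs <- tibble::tibble(slice_index = 1L, theta_start = pi / 4, theta_end = 3 * pi / 4)

  # constant stack
  sl <- interpolate_outer_boundary(list(mk(3, 0), mk(3, 1), mk(3, 2)), arcs)
  r_rec <- sqrt(sl[[2]]$outer$x^2 + sl[[2]]$outer$y^2)
  expect_lt(max(abs(r_rec - 3)), 1e-9)

  # linear ramp: middle arc equals the neighbor mean
  sl2 <- interpolate_outer_boundary(list(mk(2.8, 0), mk(3.4, 1), mk(3.2, 2)), arcs)
  th <- atan2(sl2[[2]]$outer$y, sl2[[2]]$outer$x)
  in_arc <- plaquemech:::angle_in_arc(th, pi / 4, 3 * pi / 4)
  r_rec2 <- sqrt(sl2[[2]]$outer$x^2 + sl2[[2]]$outer$y^2)
  expect_lt(max(abs(r_rec2[in_arc] - 3)), 1e-9)        # mean of 2.8 and 3.2
  expect_lt(max(abs(r_rec2[!in_arc] - 3.4)), 1e-9)     # untouched elsewhere

  # end slice: copies its only neighbor
  arcs_end <- tibble::tibble(slice_index = 0L, theta_start = 0, theta_end = pi / 2)
  sl3 <- interpolate_outer_boundary(list(mk(2.8, 0), mk(3.4, 1)), arcs_end)
  th3 <- atan2(sl3[[1]]$outer$y, sl3[[1]]$outer$x)
  in3 <- plaquemech:::angle_in_arc(th3, 0, pi / 2)
  r3 <- sqrt(sl3[[1]]$outer$x^2 + sl3[[1]]$outer$y^2)
  expect_lt(max(abs(r3[in3] - 3.4)), 1e-9)
})

test_that("plaque burden and stenosis behave as area ratios", {
  sl <- circular_slice(sqrt(2 / pi), sqrt(4 / pi))
  expect_equal(plaque_burden(sl), 0.5, tolerance = 1e-6)

  geom <- uniform_geometry(4)
  expect_equal(stenosis_by_area(geom), 0, tolerance = 1e-12)

  slices <- list(circular_slice(sqrt(4 / pi), 2, index = 0),
                 circular_slice(sqrt(2 / pi), 2, index = 1))
  expect_equal(stenosis_by_area(vessel_geometry(slices)), 0.5, tolerance = 1e-6)

  # monotone: shrinking the lumen never decreases either metric
  for (f in c(0.9, 0.7, 0.5)) {
    small <- circular_slice(1.5 * f, 2.5)
    expect_gte(plaque_burden(small), plaque_burden(circular_slice(1.5, 2.5)) - 1e-12)
  }
})

test_that("cap thickness measures lumen-to-lipid distance along the ray", {
  sl <- circular_slice(2, 3.5, lipid_lead_r = 2.25)
  sl <- resample_slice(sl, 100)
  ct <- cap_thickness(sl)
  expect_identical(nrow(ct), 100L)
  expect_equal(ct$cap_thickness_mm, rep(0.25, 100), tolerance = 5e-3)
  expect_equal(attr(ct, "mean"), 0.25, tolerance = 5e-3)

  no_lipid <- circular_slice(2, 3.5)
  ct0 <- cap_thickness(no_lipid)
  expect_identical(nrow(ct0), 0L)
  expect_true(is.na(attr(ct0, "mean")))
})

test_that("preshrink finds the circumferential shrink within tolerance", {
  geom <- uniform_geometry(3)

  # zero pressure, no axial shrink: geometry unchanged
  out0 <- apply_preshrink(geom, pressure_kpa = 0, axial_shrink = 0)
  expect_identical(out0$circumferential_shrink, rep(0, 3))
  expect_equal(out0$slices[[1]]$lumen, geom$slices[[1]]$lumen)

  # analytic oracle: pressurized area = A0 (1 - s)^2 g(p); closed-form inverse
  gp <- 1.21
  oracle <- function(shrunk_slice, p, lz) lumen_area(shrunk_slice) * gp
  out <- apply_preshrink(geom, pressure_kpa = 10, axial_shrink = 0.05,
                         mechanics_oracle = oracle)
  s_true <- 1 - sqrt(1 / gp)
  expect_equal(out$circumferential_shrink, rep(s_true, 3), tolerance = 1e-3)

  # tube-based default oracle: residual within 0.5% on every slice
  geom10 <- uniform_geometry(5, r_in = 1.4, r_out = 2.2, n = 120)
  out2 <- apply_preshrink(geom10, pressure_kpa = 13.3)
  rec <- attr(out2, "preshrink_record")
  expect_true(all(rec$residual <= 0.005))
  expect_true(all(out2$circumferential_shrink > 0))
})
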