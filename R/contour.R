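# Cross-section containers and contour-processing operations:
# thrombus removal, lipid trailing-edge completion, outer-boundary
# interpolation from neighboring slices.

#' Construct a vessel cross-section slice
#'
#' A slice holds the closed contours segmented from one intravascular
#' imaging frame: the lumen, the outer boundary (external elastic
#' membrane), and optional lipid, calcification and thrombus polygons,
#' plus a per-lumen-point erosion mask.
#'
#' @param slice_index 0-based position of the slice along the centerline.
#' @param lumen,outer Closed polygon tibbles (mm), counterclockwise.
#' @param lipid,calcification,thrombus Optional polygon tibbles. `lipid`
#'   may also be an open leading-edge polyline to be completed with
#'   [complete_lipid_trailing_edge()].
#' @param erosion_mask Optional logical vector aligned with the lumen
#'   vertices marking erosion-labeled points.
#' @param validate Check polygon invariants (simplicity, containment).
#' @return An object of class `contour_slice`.
#' @export
contour_slice <- function(slice_index, lumen, outer, lipid = NULL,
                          calcification = NULL, thrombus = NULL,
                          erosion_mask = NULL, validate = TRUE) {
  lumen <- ensure_ccw(tibble::as_tibble(lumen))
  outer <- ensure_ccw(tibble::as_tibble(outer))
  if (validate) {
    if (!is_simple_polygon(lumen)) stop("lumen polygon is self-intersecting", call. = FALSE)
    if (!is_simple_polygon(outer)) stop("outer polygon is self-intersecting", call. = FALSE)
    if (polygon_area(lumen) >= polygon_area(outer)) {
      stop("lumen area must be smaller than outer-boundary area", call. = FALSE)
    }
  }
  if (!is.null(erosion_mask)) {
    stopifnot(is.logical(erosion_mask), length(erosion_mask) == nrow(lumen))
  }
  structure(
    list(
      slice_index = as.integer(slice_index),
      lumen = lumen, outer = outer,
      lipid = if (!is.null(lipid)) tibble::as_tibble(lipid) else NULL,
      calcification = if (!is.null(calcification)) tibble::as_tibble(calcification) else NULL,
      thrombus = if (!is.null(thrombus)) tibble::as_tibble(thrombus) else NULL,
      erosion_mask = erosion_mask
    ),
    class = "contour_slice"
  )
}

#' @export
print.contour_slice <- function(x, ...) {
  cat(sprintf(
    "<contour_slice %d> lumen %.2f mm^2, wall %.2f mm^2%s%s%s\n",
    x$slice_index, polygon_area(x$lumen), polygon_area(x$outer),
    if (!is.null(x$lipid)) ", lipid" else "",
    if (!is.null(x$thrombus)) ", thrombus" else "",
    if (!is.null(x$erosion_mask) && any(x$erosion_mask)) sprintf(", %d erosion pts", sum(x$erosion_mask)) else ""
  ))
  invisible(x)
}

#' Construct a vessel geometry (ordered slice stack)
#'
#' @param slices List of [contour_slice()] objects in proximal-to-distal
#'   order.
#' @param slice_spacing Spacing between slices along the centerline, cm
#'   (default 0.2, the imaging frame distance).
#' @param centerline Optional 3D polyline tibble (x, y, z in mm).
#' @param axial_shrink Axial shrink fraction applied to reach the
#'   zero-load state (default 0, set by [apply_preshrink()]).
#' @param circumferential_shrink Per-slice circumferential shrink
#'   fractions (default 0).
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(slices, slice_spacing = 0.2, centerline = NULL,
                            axial_shrink = 0, circumferential_shrink = NULL) {
  stopifnot(length(slices) >= 1, slice_spacing > 0)
  stopifnot(all(vapply(slices, inherits, logical(1), "contour_slice")))
  if (is.null(circumferential_shrink)) circumferential_shrink <- rep(0, length(slices))
  stopifnot(length(circumferential_shrink) == length(slices))
  if (any(axial_shrink < 0 | axial_shrink > 0.5) ||
      any(circumferential_shrink < 0 | circumferential_shrink > 0.5)) {
    stop("shrink fractions must lie in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(slices = slices, slice_spacing = slice_spacing, centerline = centerline,
         axial_shrink = axial_shrink, circumferential_shrink = circumferential_shrink),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> %d slices, spacing %.2f cm, axial shrink %.1f%%\n",
              length(x$slices), x$slice_spacing, 100 * x$axial_shrink))
  invisible(x)
}

#' Remove a thrombus and recover the pre-erosion lumen line
#'
#' White thrombi protrude into the lumen; the pre-erosion lumen is
#' recovered by taking, at each lumen vertex angle, the larger of the
#' segmented lumen radius and the far (wall-side) radius of the thrombus
#' footprint, then smoothing circumferentially. The erosion mask is kept
#' aligned with the (recovered) lumen points.
#'
#' @param slice A [contour_slice()].
#' @param smooth_window Circumferential smoothing window (vertices).
#' @return The slice with `thrombus = NULL` and the recovered lumen.
#' @export
remove_thrombus <- function(slice, smooth_window = 5) {
  stopifnot(inherits(slice, "contour_slice"))
  if (is.null(slice$thrombus)) return(slice)
  lumen <- slice$lumen
  thr <- slice$thrombus
  center <- polygon_centroid(lumen)

  # thrombus must touch or overlap the lumen contour (a polygon floating
  # in the lumen interior or detached in the wall is not adjacent)
  gap <- min_dist_to_polygon(thr, lumen)
  if (gap > 0.05) {
    warning("thrombus polygon is not adjacent to the lumen; dropped unchanged", call. = FALSE)
    slice$thrombus <- NULL
    return(slice)
  }

  dx <- lumen$x - center[1]; dy <- lumen$y - center[2]
  th <- atan2(dy, dx)
  r_lum <- sqrt(dx^2 + dy^2)
  r_new <- r_lum
  changed <- logical(length(th))
  for (i in seq_along(th)) {
    ts <- ray_polygon_intersections(center, c(cos(th[i]), sin(th[i])), thr)
    if (length(ts) >= 1) {
      r_far <- max(ts)
      if (r_far > r_new[i]) {
        r_new[i] <- r_far
        changed[i] <- TRUE
      }
    }
  }
  rec <- tibble::tibble(x = center[1] + r_new * cos(th), y = center[2] + r_new * sin(th))
  if (any(changed)) rec <- smooth_recovered(rec, changed, center, smooth_window)
  # smoothing must not shrink the lumen below the original contour
  r_s <- sqrt((rec$x - center[1])^2 + (rec$y - center[2])^2)
  r_s <- pmax(r_s, r_lum)
  rec <- tibble::tibble(x = center[1] + r_s * cos(th), y = center[2] + r_s * sin(th))
  slice$lumen <- rec
  slice$thrombus <- NULL
  slice
}

# moving-average smoothing restricted to a neighborhood of the recovered
# (changed) points, so untouched lumen stretches are preserved exactly
smooth_recovered <- function(poly, changed, center, window) {
  n <- nrow(poly)
  half <- (window - 1) / 2
  near <- changed
  for (o in seq_len(half)) {
    near <- near | changed[((seq_len(n) - 1 + o) %% n) + 1] |
      changed[((seq_len(n) - 1 - o) %% n) + 1]
  }
  sm <- smooth_contour(poly, window = window, center = center)
  out <- poly
  out[near, ] <- sm[near, ]
  out
}

#' Complete a lipid contour behind its leading edge
#'
#' The imaging signal attenuates behind the lipid leading edge, so the
#' trailing edge is constructed by assuming the lipid core occupies
#' two-thirds of the wall space behind the leading edge: along the outward
#' ray through each leading-edge point, the trailing point sits at
#' `leading + 2/3 * (outer - leading)`.
#'
#' @param slice A [contour_slice()] whose `lipid` field holds the
#'   leading-edge polyline (open, ordered).
#' @param fraction Fraction of the leading-edge-to-outer distance occupied
#'   by lipid (default 2/3).
#' @return The slice with `lipid` replaced by the closed lipid polygon.
#' @export
complete_lipid_trailing_edge <- function(slice, fraction = 2 / 3) {
  stopifnot(inherits(slice, "contour_slice"))
  if (is.null(slice$lipid)) stop("slice has no lipid leading edge", call. = FALSE)
  lead <- tibble::as_tibble(slice$lipid)
  outer <- slice$outer
  center <- polygon_centroid(slice$lumen)

  n <- nrow(lead)
  trail <- matrix(NA_real_, n, 2)
  zero_thickness <- TRUE
  for (i in seq_len(n)) {
    pt <- c(lead$x[i], lead$y[i])
    dir <- pt - center
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-12) stop("lipid leading-edge point at the slice center", call. = FALSE)
    dir <- dir / nd
    ts <- ray_polygon_intersections(center, dir, outer)
    if (length(ts) == 0) stop("lipid leading edge lies outside the wall ring", call. = FALSE)
    r_outer <- max(ts)
    d <- r_outer - nd
    # tolerate the chordal sag of a discretized outer contour; a leading
    # edge clearly beyond the wall ring is an error
    if (d < -0.05) stop("lipid leading edge lies outside the outer boundary", call. = FALSE)
    d <- max(0, d)
    if (d > 1e-6) zero_thickness <- FALSE
    trail[i, ] <- center + (nd + fraction * d) * dir
  }
  if (zero_thickness) {
    warning("lipid leading edge coincides with the outer boundary; empty lipid", call. = FALSE)
    slice$lipid <- NULL
    return(slice)
  }
  poly <- tibble::tibble(
    x = c(lead$x, rev(trail[, 1])),
    y = c(lead$y, rev(trail[, 2]))
  )
  slice$lipid <- poly
  attr(slice$lipid, "leading_edge_n") <- n
  slice
}

#' Fill missing outer-boundary arcs from neighboring slices
#'
#' Where the outer boundary cannot be detected on a slice, its per-angle
#' radius over the missing arc is linearly interpolated between the
#' nearest flanking slices that carry the sector (copied from the single
#' neighbor at the ends of the stack), assuming the outer boundary changes
#' continuously along the vessel.
#'
#' @param slices List of [contour_slice()] objects.
#' @param missing_arcs Tibble with columns `slice_index` (0-based),
#'   `theta_start`, `theta_end` (radians, counterclockwise arc from start
#'   to end about the slice's outer centroid).
#' @return The slice list with the affected arcs replaced.
#' @export
interpolate_outer_boundary <- function(slices, missing_arcs) {
  stopifnot(is.data.frame(missing_arcs),
            all(c("slice_index", "theta_start", "theta_end") %in% names(missing_arcs)))
  idx_of <- vapply(slices, function(s) s$slice_index, integer(1))
  for (row in seq_len(nrow(missing_arcs))) {
    si <- missing_arcs$slice_index[row]
    t0 <- missing_arcs$theta_start[row]
    t1 <- missing_arcs$theta_end[row]
    k <- match(si, idx_of)
    if (is.na(k)) stop(sprintf("no slice with index %d", si), call. = FALSE)
    target <- slices[[k]]
    center <- polygon_centroid(target$outer)
    th <- atan2(target$outer$y - center[2], target$outer$x - center[1])
    in_arc <- angle_in_arc(th, t0, t1)
    if (!any(in_arc)) next
    nbrs <- neighbor_slices(k, length(slices))
    prev_k <- nbrs$prev; next_k <- nbrs$nxt
    r_prev <- if (!is.na(prev_k)) polygon_radius_at(slices[[prev_k]]$outer, th[in_arc],
                                                    polygon_centroid(slices[[prev_k]]$outer)) else NULL
    r_next <- if (!is.na(next_k)) polygon_radius_at(slices[[next_k]]$outer, th[in_arc],
                                                    polygon_centroid(slices[[next_k]]$outer)) else NULL
    if (is.null(r_prev) && is.null(r_next)) {
      stop("no neighboring slice carries the missing sector", call. = FALSE)
    }
    r_fill <- if (is.null(r_prev)) r_next
      else if (is.null(r_next)) r_prev
      else (r_prev + r_next) / 2
    if (anyNA(r_fill)) stop("no neighboring slice carries the missing sector", call. = FALSE)
    target$outer$x[in_arc] <- center[1] + r_fill * cos(th[in_arc])
    target$outer$y[in_arc] <- center[2] + r_fill * sin(th[in_arc])
    if (!is_simple_polygon(target$outer)) {
      stop("interpolated outer boundary is not a simple polygon", call. = FALSE)
    }
    slices[[k]] <- target
  }
  slices
}

neighbor_slices <- function(k, n) {
  list(prev = if (k > 1) k - 1L else NA_integer_,
       nxt = if (k < n) k + 1L else NA_integer_)
}

angle_in_arc <- function(theta, t0, t1) {
  two_pi <- 2 * pi
  rel <- (theta - t0) %% two_pi
  span <- (t1 - t0) %% two_pi
  rel <= span + 1e-12
}

#' Resample a slice's lumen (and mask) to the canonical 100 points
#'
#' @param slice A [contour_slice()].
#' @param n_points Number of lumen points (default 100).
#' @return The slice with a resampled lumen and remapped erosion mask.
#' @export
resample_slice <- function(slice, n_points = 100) {
  stopifnot(inherits(slice, "contour_slice"))
  old_lumen <- slice$lumen
  mask <- slice$erosion_mask
  new_lumen <- resample_four_quarter(old_lumen, n_points = n_points)
  if (!is.null(mask) && any(mask)) {
    # carry the label to the nearest original vertex
    center <- attr(new_lumen, "fq_center")
    th_old <- atan2(old_lumen$y - center[2], old_lumen$x - center[1])
    th_new <- atan2(new_lumen$y - center[2], new_lumen$x - center[1])
    nearest <- vapply(th_new, function(t) {
      which.min(abs(atan2(sin(th_old - t), cos(th_old - t))))
    }, integer(1))
    slice$erosion_mask <- mask[nearest]
  } else if (!is.null(mask)) {
    slice$erosion_mask <- rep(FALSE, n_points)
  }
  slice$lumen <- new_lumen
  slice
}
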