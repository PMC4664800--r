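#' Shoelace area of a polygon
#'
#' Absolute area of the closed polygon defined by `vertices` in order, by
#' the shoelace (surveyor's) formula.  Vertex order may be clockwise or
#' counter-clockwise; the absolute value is returned so orientation cannot
#' flip the sign.
#'
#' @param vertices A matrix or data frame with two columns (x, y) and at
#'   least three rows.
#' @return Area in squared input units.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(as.data.frame(vertices))
  if (nrow(v) < 3L) {
    abort("A polygon needs at least 3 vertices.")
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Cervicomental contour area (uncalibrated)
#'
#' Quantifies anterior-neck fat deposition from the profile view.  The six
#' contour points (upper-right point 11 through bottom-left point 23 in the
#' default numbering) trace the chin-neck outline.  An axis-aligned
#' rectangle is spanned by point 23 (bottom-left; larger y under the image
#' convention) and point 11 (upper-right).  The closed polygon formed by
#' the contour, the rectangle's low side from point 23 to the bottom-right
#' corner, and its right side back up to point 11 is measured by shoelace
#' area and normalized by the rectangle area.  A straight-diagonal contour
#' gives exactly 0.5; the value decreases as the contour bulges toward the
#' bottom-right corner, i.e. as neck fat increases.
#'
#' Because the rectangle is axis-aligned in image coordinates, this
#' measurement assumes an upright head; unlike the width ratio and the
#' angle it is not invariant to image rotation (see the methods vignette).
#'
#' @param profile A profile [landmark_set()].
#' @param index_map A [landmark_index_map()].
#' @return A scalar ratio, 0.5 for the diagonal contour, 1 when the
#'   contour follows the rectangle's top and left sides.
#' @export
cervicomental_contour_area <- function(profile, index_map = landmark_index_map()) {
  stopifnot(landmark_view(profile) == "profile")
  xy <- as_xy_matrix(profile)
  p_ur <- xy[index_map$rect_upper_right, ]
  p_bl <- xy[index_map$rect_bottom_left, ]
  width <- abs(p_ur[1] - p_bl[1])
  height <- abs(p_ur[2] - p_bl[2])
  if (width < 1e-12 || height < 1e-12) {
    abort("Degenerate cervicomental rectangle: zero width or height.")
  }
  contour <- xy[index_map$cervicomental_contour, , drop = FALSE]
  corner_br <- c(p_ur[1], p_bl[2])
  inside <- contour[, 1] >= min(p_ur[1], p_bl[1]) - 1e-9 &
    contour[, 1] <= max(p_ur[1], p_bl[1]) + 1e-9 &
    contour[, 2] >= min(p_ur[2], p_bl[2]) - 1e-9 &
    contour[, 2] <= max(p_ur[2], p_bl[2]) + 1e-9
  if (!all(inside)) {
    warn("Cervicomental contour points fall outside the normalizing rectangle; value computed anyway.")
  }
  poly <- rbind(contour, corner_br)
  polygon_area(poly) / (width * height)
}

#' Face width ratio (uncalibrated)
#'
#' Midface width divided by interocular width, both as Euclidean distances
#' between the role-mapped frontal landmarks.  Being a ratio of distances
#' it needs no metric calibration and is invariant to translation,
#' rotation and uniform scaling of the image.
#'
#' @param frontal A frontal [landmark_set()].
#' @inheritParams cervicomental_contour_area
#' @return A positive scalar ratio.
#' @export
face_width_ratio <- function(frontal, index_map = landmark_index_map()) {
  stopifnot(landmark_view(frontal) == "frontal")
  xy <- as_xy_matrix(frontal)
  midface <- sqrt(sum((xy[index_map$midface_left, ] -
                         xy[index_map$midface_right, ])^2))
  interocular <- sqrt(sum((xy[index_map$interocular_left, ] -
                             xy[index_map$interocular_right, ])^2))
  if (interocular < 1e-12) {
    abort("Zero interocular distance: width ratio undefined.")
  }
  midface / interocular
}

#' Tragion-ramus-stomion angle
#'
#' The angle at the ramus (posterior mandible landmark) between the rays
#' towards the stomion (lip midpoint) and towards the tragion (upper
#' tragus of the ear), in degrees in \[0, 180\].  A proxy for mandibular
#' retraction.  The documented contract is the arccosine of the normalized
#' dot product; the implementation uses the numerically equivalent
#' two-argument arctangent of cross and dot products, which is stable for
#' nearly collinear configurations.
#'
#' @inheritParams cervicomental_contour_area
#' @param profile A profile [landmark_set()].
#' @return Angle in degrees.
#' @export
tragion_ramus_stomion_angle <- function(profile, index_map = landmark_index_map()) {
  stopifnot(landmark_view(profile) == "profile")
  xy <- as_xy_matrix(profile)
  v1 <- xy[index_map$stomion, ] - xy[index_map$ramus, ]
  v2 <- xy[index_map$tragion, ] - xy[index_map$ramus, ]
  if (sum(v1^2) < 1e-24 || sum(v2^2) < 1e-24) {
    abort("Coincident angle landmarks: angle undefined.")
  }
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  atan2(abs(cross), dot) * 180 / pi
}

#' The three-component craniofacial feature vector
#'
#' Stacks the cervicomental contour area, face width ratio and
#' tragion-ramus-stomion angle for one subject, in that fixed order.
#'
#' @param frontal A frontal [landmark_set()].
#' @param profile A profile [landmark_set()].
#' @inheritParams cervicomental_contour_area
#' @return A one-row tibble with columns `cervicomental`, `face_width`,
#'   `trs_angle`.
#' @export
craniofacial_vector <- function(frontal, profile, index_map = landmark_index_map()) {
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Craniofacial measurement '%s' failed: %s",
                    what, conditionMessage(e)))
    })
  }
  tibble(
    cervicomental = wrap("cervicomental", cervicomental_contour_area(profile, index_map)),
    face_width = wrap("face_width", face_width_ratio(frontal, index_map)),
    trs_angle = wrap("trs_angle", tragion_ramus_stomion_angle(profile, index_map))
  )
}

#' Craniofacial features for a whole cohort
#'
#' Computes the three uncalibrated measurements for every subject of a
#' synthetic cohort (see [generate_cohort()]) or for a directory of paired
#' PTS files.
#'
#' @param x An `osa_cohort`, or a directory containing
#'   `<subject_id>_frontal.pts` / `<subject_id>_profile.pts` pairs.
#' @param index_map A [landmark_index_map()].
#' @return A tibble with columns `subject_id`, `cervicomental`,
#'   `face_width`, `trs_angle`.
#' @export
craniofacial_features <- function(x, index_map = landmark_index_map()) {
  if (inherits(x, "osa_cohort")) {
    pairs <- x$landmarks
    ids <- names(pairs)
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    frontal_files <- sort(list.files(x, pattern = "_frontal\\.pts$", full.names = TRUE))
    ids <- sub("_frontal\\.pts$", "", basename(frontal_files))
    pairs <- lapply(ids, function(id) {
      list(frontal = read_pts(file.path(x, paste0(id, "_frontal.pts"))),
           profile = read_pts(file.path(x, paste0(id, "_profile.pts"))))
    })
    names(pairs) <- ids
  } else {
    abort("`x` must be an `osa_cohort` or a directory of PTS files.")
  }
  rows <- map(ids, function(id) {
    craniofacial_vector(pairs[[id]]$frontal, pairs[[id]]$profile, index_map)
  })
  bind_cols(tibble(subject_id = ids), bind_rows(rows))
}
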