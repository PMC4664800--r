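#' Landmark sets for frontal and profile facial views
#'
#' A landmark set is a tibble with columns `point` (1-based index), `x` and
#' `y` (pixel coordinates, image convention: origin top-left, y increasing
#' downward), carrying a `view` attribute.  The frontal view has exactly 52
#' points and the profile view exactly 24, matching the landmark grids used
#' for automatic facial annotation of 640x480 photographs.
#'
#' @param coords A two-column matrix or data frame of (x, y) pixel
#'   coordinates, ordered by point index.
#' @param view `"frontal"` (52 points) or `"profile"` (24 points).
#' @return A `landmark_set` tibble with columns `point`, `x`, `y`.
#' @examples
#' lm <- landmark_set(cbind(runif(24, 0, 640), runif(24, 0, 480)), "profile")
#' landmark_view(lm)
#' @export
landmark_set <- function(coords, view = c("frontal", "profile")) {
  view <- match.arg(view)
  coords <- as.matrix(as.data.frame(coords))
  if (ncol(coords) != 2L) {
    abort("`coords` must have exactly two columns (x, y).")
  }
  n_expected <- landmark_count(view)
  if (nrow(coords) != n_expected) {
    abort(sprintf("A %s landmark set must have exactly %d points, got %d.",
                  view, n_expected, nrow(coords)))
  }
  if (!all(is.finite(coords))) {
    abort("All landmark coordinates must be finite.")
  }
  out <- tibble(point = seq_len(nrow(coords)),
                x = as.numeric(coords[, 1]),
                y = as.numeric(coords[, 2]))
  attr(out, "view") <- view
  class(out) <- c("landmark_set", class(out))
  out
}

#' @rdname landmark_set
#' @param x A `landmark_set`.
#' @export
landmark_view <- function(x) {
  attr(x, "view") %||% abort("Not a landmark set: no `view` attribute.")
}

landmark_count <- function(view) {
  c(frontal = 52L, profile = 24L)[[view]]
}

as_xy_matrix <- function(landmarks) {
  cbind(landmarks$x, landmarks$y)
}

#' Role-to-index map for the craniofacial measurements
#'
#' Names the landmark indices entering each measurement.  Profile roles
#' follow the published point numbering: the cervicomental contour is traced
#' by points 11, 12, 20, 21, 22 and 23 (point 23 the bottom-left and point
#' 11 the upper-right corner of the normalizing rectangle), the
#' tragion-ramus-stomion angle uses points 19, 16 and 6.  The frontal
#' indices for the midface and interocular widths are not fixed by any
#' published numbering, so they are configurable here; the defaults refer to
#' the schematic template of [template_landmarks()] (widest jaw-outline
#' points and inner eye corners).
#'
#' @param cervicomental_contour Six profile indices tracing the
#'   cervicomental contour, upper-right first.
#' @param rect_upper_right,rect_bottom_left Profile indices of the
#'   normalizing rectangle corners.
#' @param ramus,stomion,tragion Profile indices of the angle landmarks.
#' @param midface_left,midface_right,interocular_left,interocular_right
#'   Frontal indices of the width landmarks.
#' @return A named list of indices with class `landmark_index_map`.
#' @export
landmark_index_map <- function(cervicomental_contour = c(11L, 12L, 20L, 21L, 22L, 23L),
                               rect_upper_right = 11L,
                               rect_bottom_left = 23L,
                               ramus = 16L,
                               stomion = 6L,
                               tragion = 19L,
                               midface_left = 3L,
                               midface_right = 15L,
                               interocular_left = 32L,
                               interocular_right = 33L) {
  map <- list(
    cervicomental_contour = as.integer(cervicomental_contour),
    rect_upper_right = as.integer(rect_upper_right),
    rect_bottom_left = as.integer(rect_bottom_left),
    ramus = as.integer(ramus),
    stomion = as.integer(stomion),
    tragion = as.integer(tragion),
    midface_left = as.integer(midface_left),
    midface_right = as.integer(midface_right),
    interocular_left = as.integer(interocular_left),
    interocular_right = as.integer(interocular_right)
  )
  if (length(map$cervicomental_contour) != 6L) {
    abort("`cervicomental_contour` must list exactly six point indices.")
  }
  profile_idx <- c(map$cervicomental_contour, map$rect_upper_right,
                   map$rect_bottom_left, map$ramus, map$stomion, map$tragion)
  if (any(profile_idx < 1L | profile_idx > 24L)) {
    abort("Profile role indices must lie in 1..24.")
  }
  frontal_idx <- c(map$midface_left, map$midface_right,
                   map$interocular_left, map$interocular_right)
  if (any(frontal_idx < 1L | frontal_idx > 52L)) {
    abort("Frontal role indices must lie in 1..52.")
  }
  if (length(unique(c(map$ramus, map$stomion, map$tragion))) != 3L) {
    abort("`ramus`, `stomion` and `tragion` must be three distinct points.")
  }
  structure(map, class = "landmark_index_map")
}

#' Read a PTS landmark file
#'
#' Parses the plain-text points dialect used for interchange of facial
#' landmark annotations: a `version: 1` line, an `n_points: N` line, then a
#' `{` line, N lines of `x y`, and a closing `}`.
#'
#' @param path Path to a `.pts` file.
#' @return A [landmark_set()]; the view is inferred from the point count
#'   (52 = frontal, 24 = profile).
#' @export
read_pts <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("PTS file does not exist: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse_fail <- function(line_no, msg) {
    abort(sprintf("Malformed PTS file %s (line %d): %s", path, line_no, msg))
  }
  if (length(lines) < 4L || !grepl("^version:\\s*1$", lines[1])) {
    parse_fail(1L, "expected header 'version: 1'")
  }
  m <- regmatches(lines[2], regexec("^n_points:\\s*([0-9]+)$", lines[2]))[[1]]
  if (length(m) != 2L) parse_fail(2L, "expected 'n_points: N'")
  n <- as.integer(m[2])
  if (lines[3] != "{") parse_fail(3L, "expected '{'")
  body <- lines[seq.int(4L, length.out = max(0L, length(lines) - 4L))]
  if (length(body) != n) {
    parse_fail(4L, sprintf("declared n_points: %d but found %d coordinate lines",
                           n, length(body)))
  }
  if (lines[length(lines)] != "}") parse_fail(length(lines), "expected closing '}'")
  coords <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals)) {
      parse_fail(3L + i, sprintf("non-numeric coordinate pair '%s'", body[i]))
    }
    coords[i, ] <- vals
  }
  view <- switch(as.character(n), "52" = "frontal", "24" = "profile",
                 parse_fail(2L, sprintf(
                   "point count %d matches neither view (frontal 52, profile 24)", n)))
  landmark_set(coords, view)
}

#' Write a PTS landmark file
#'
#' @param landmarks A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(landmarks, path) {
  if (nrow(landmarks) == 0L) {
    abort("Refusing to write an empty landmark set.")
  }
  landmark_view(landmarks)  # errors if not a landmark set
  lines <- c("version: 1",
             sprintf("n_points: %d", nrow(landmarks)),
             "{",
             sprintf("%.6f %.6f", landmarks$x, landmarks$y),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Validate a landmark set against the image frame and role geometry
#'
#' A reporting-only stand-in for the human supervision step of
#' semi-automatic landmarking: flags out-of-frame points, coincident
#' role-mapped points, and degenerate role geometry (a zero-width or
#' zero-height cervicomental rectangle).  Coordinates are never modified.
#'
#' @param landmarks A [landmark_set()].
#' @param frame Image frame as `c(width, height)` in pixels.
#' @param index_map A [landmark_index_map()].
#' @return A tibble of flags with columns `flag`, `point` (NA when the flag
#'   concerns a role rather than a single point) and `detail`.  Zero rows
#'   mean a clean set.
#' @export
validate_landmarks <- function(landmarks, frame = c(640, 480),
                               index_map = landmark_index_map()) {
  view <- landmark_view(landmarks)
  flags <- list()
  outside <- which(landmarks$x < 0 | landmarks$x >= frame[1] |
                     landmarks$y < 0 | landmarks$y >= frame[2])
  for (i in outside) {
    flags[[length(flags) + 1L]] <- tibble(
      flag = "point_outside_frame", point = i,
      detail = sprintf("(%.1f, %.1f) outside [0,%g)x[0,%g)",
                       landmarks$x[i], landmarks$y[i], frame[1], frame[2]))
  }
  role_idx <- if (view == "profile") {
    unique(c(index_map$cervicomental_contour, index_map$ramus,
             index_map$stomion, index_map$tragion))
  } else {
    unique(c(index_map$midface_left, index_map$midface_right,
             index_map$interocular_left, index_map$interocular_right))
  }
  pts <- as_xy_matrix(landmarks)[role_idx, , drop = FALSE]
  if (length(role_idx) > 1L) {
    d <- as.matrix(stats::dist(pts))
    dup <- which(upper.tri(d) & d < 1e-9, arr.ind = TRUE)
    for (k in seq_len(nrow(dup))) {
      flags[[length(flags) + 1L]] <- tibble(
        flag = "coincident_role_points", point = NA_integer_,
        detail = sprintf("points %d and %d coincide",
                         role_idx[dup[k, 1]], role_idx[dup[k, 2]]))
    }
  }
  if (view == "profile") {
    p_ur <- as_xy_matrix(landmarks)[index_map$rect_upper_right, ]
    p_bl <- as_xy_matrix(landmarks)[index_map$rect_bottom_left, ]
    if (abs(p_ur[1] - p_bl[1]) < 1e-9) {
      flags[[length(flags) + 1L]] <- tibble(
        flag = "zero_width_cervicomental_rectangle", point = NA_integer_,
        detail = "rectangle corner points share an x coordinate")
    }
    if (abs(p_ur[2] - p_bl[2]) < 1e-9) {
      flags[[length(flags) + 1L]] <- tibble(
        flag = "zero_height_cervicomental_rectangle", point = NA_integer_,
        detail = "rectangle corner points share a y coordinate")
    }
  }
  if (length(flags) == 0L) {
    tibble(flag = character(), point = integer(), detail = character())
  } else {
    bind_rows(flags)
  }
}

#' Schematic template landmark configurations
#'
#' Fixed, anatomically plausible landmark layouts inside a 640x480 frame:
#' a 52-point frontal grid (jaw outline, brows, eyes, nose, mouth) and a
#' 24-point profile set including the neck-area marks.  On the profile
#' template the cervicomental contour points (11, 12, 20-23) lie exactly on
#' the diagonal of the normalizing rectangle, so the template's
#' cervicomental contour area is 0.5 by construction.  These templates are
#' the deterministic base shapes that the synthetic cohort generator
#' perturbs.
#'
#' @param view `"frontal"` or `"profile"`.
#' @return A [landmark_set()].
#' @export
template_landmarks <- function(view = c("frontal", "profile")) {
  view <- match.arg(view)
  if (view == "profile") {
    coords <- matrix(NA_real_, 24L, 2L)
    coords[1, ] <- c(350, 80)    # forehead
    coords[2, ] <- c(395, 115)   # glabella
    coords[3, ] <- c(390, 140)   # nasion
    coords[4, ] <- c(430, 185)   # nose tip
    coords[5, ] <- c(410, 210)   # subnasale
    coords[6, ] <- c(415, 240)   # stomion
    coords[7, ] <- c(400, 265)   # labiomental sulcus
    coords[8, ] <- c(405, 290)   # pogonion
    coords[9, ] <- c(390, 315)   # menton
    coords[10, ] <- c(375, 325)  # gnathion underside
    # cervicomental contour, upper-right (11) to bottom-left (23), on the
    # rectangle diagonal
    diag_t <- seq(0, 1, length.out = 6)
    p11 <- c(370, 330); p23 <- c(250, 430)
    contour <- t(vapply(diag_t, function(t) p11 + t * (p23 - p11), numeric(2)))
    coords[11, ] <- contour[1, ]
    coords[12, ] <- contour[2, ]
    coords[20, ] <- contour[3, ]
    coords[21, ] <- contour[4, ]
    coords[22, ] <- contour[5, ]
    coords[23, ] <- contour[6, ]
    coords[13, ] <- c(240, 310)  # posterior neck
    coords[14, ] <- c(250, 190)  # occiput
    coords[15, ] <- c(295, 105)  # crown
    coords[16, ] <- c(310, 300)  # ramus
    coords[17, ] <- c(325, 260)  # below ear
    coords[18, ] <- c(352, 198)  # ear top
    coords[19, ] <- c(340, 225)  # tragion
    coords[24, ] <- c(420, 165)  # nasal bridge
    return(landmark_set(coords, "profile"))
  }
  coords <- matrix(NA_real_, 52L, 2L)
  # jaw/cheek outline 1..17 on an ellipse, left temple -> chin -> right temple
  phi <- (180 + (0:16) * 180 / 16) * pi / 180
  coords[1:17, 1] <- 320 + 110 * cos(phi)
  coords[1:17, 2] <- 250 - 150 * sin(phi)
  # brows 18..27
  coords[18:22, 1] <- seq(230, 300, length.out = 5)
  coords[18:22, 2] <- 160
  coords[23:27, 1] <- seq(340, 410, length.out = 5)
  coords[23:27, 2] <- 160
  # eyes 28..37, left outer -> inner (28..32), right inner -> outer (33..37)
  coords[28:32, 1] <- seq(250, 300, length.out = 5)
  coords[28:32, 2] <- c(200, 196, 194, 196, 200)
  coords[33:37, 1] <- seq(340, 390, length.out = 5)
  coords[33:37, 2] <- c(200, 196, 194, 196, 200)
  # nose 38..46
  coords[38:41, 1] <- 320
  coords[38:41, 2] <- seq(200, 260, length.out = 4)
  coords[42:46, 1] <- seq(290, 350, length.out = 5)
  coords[42:46, 2] <- c(272, 278, 280, 278, 272)
  # mouth 47..52
  coords[47:52, 1] <- c(285, 303, 320, 337, 355, 320)
  coords[47:52, 2] <- c(330, 322, 320, 322, 330, 342)
  landmark_set(coords, "frontal")
}

#' Plot a landmark set
#'
#' @param object A [landmark_set()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.landmark_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$point),
                       size = 2.5, nudge_y = -6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s landmark set", landmark_view(object)),
                  x = "x (px)", y = "y (px, image convention)")
}
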