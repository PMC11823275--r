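# Facial measurement layout: nine telespectroradiometer (TSR)-scale circular
# areas plus 32 contact-spectrophotometer (SPM) points and the map that
# averages SPM points into the nine areas.
#
# Side labels are the subject's anatomical sides: with a camera facing the
# subject, the subject's right appears on the image left (low column
# indices). The template is expressed in face-ellipse coordinates
# (u: horizontal offset / semi-width, positive toward image right = subject
# left; v: vertical offset / semi-height, positive downward) and scaled to a
# given cube size.

.tsr_template <- tibble::tribble(
  ~id, ~zone, ~side, ~u, ~v,
  1L, "forehead", "right", -0.45, -0.55,
  2L, "forehead", "center", 0.00, -0.62,
  3L, "forehead", "left", 0.45, -0.55,
  4L, "cheek", "right", -0.55, 0.08,
  5L, "nose", "center", 0.00, 0.02,
  6L, "cheek", "left", 0.55, 0.08,
  7L, "jawline", "right", -0.42, 0.52,
  8L, "jawline", "left", 0.42, 0.52,
  9L, "chin", "center", 0.00, 0.74
)

# Default SPM -> TSR grouping. The protocol specifies area 1 as the average
# of SPM points 1 and 5; the remaining groups follow the same surrounding-
# points scheme and are configurable. Every SPM id 1-32 appears exactly once.
.spm_groups_default <- list(
  `1` = c(1L, 5L), `2` = c(2L, 6L, 7L), `3` = c(3L, 8L),
  `4` = c(4L, 9L, 10L, 11L), `5` = c(12L, 13L, 14L),
  `6` = c(15L, 16L, 17L, 18L), `7` = c(19L, 20L, 21L, 22L),
  `8` = c(23L, 24L, 25L, 26L), `9` = c(27L, 28L, 29L, 30L, 31L, 32L)
)

#' Facial measurement layout
#'
#' Builds the nine-position facial layout (circular TSR-scale areas with
#' zone and anatomical-side labels), the 32 SPM point map, and the SPM-to-
#' area grouping, scaled to a cube of `dim = c(rows, cols)`. The side pairs
#' used for left-right comparison are (1,3) forehead, (4,6) cheek, and (7,8)
#' jawline, each ordered (right, left).
#'
#' @param dim Cube spatial size `c(rows, cols)`.
#' @param center Face-ellipse center `c(row, col)`; default places the face
#'   right of a left-margin reference patch.
#' @param semiaxes Face-ellipse semi-axes `c(rows, cols)` in pixels.
#' @param roi_radius Radius of the nine circular areas in pixels; the default
#'   scales the protocol's 100-pixel diameter to the face size.
#' @param spm_groups Named list mapping TSR area id (as character) to the SPM
#'   ids averaged into it; must cover every SPM id at least once.
#' @return An object of class `facial_layout`: a list with tibbles
#'   `tsr_positions`, `spm_points`, `spm_to_tsr`, plus the face geometry.
#' @export
facial_layout <- function(dim = c(192, 256), center = NULL, semiaxes = NULL,
                          roi_radius = NULL, spm_groups = .spm_groups_default) {
  nr <- dim[1]; nc <- dim[2]
  center <- center %||% c(nr * 0.52, nc * 0.56)
  semiaxes <- semiaxes %||% c(nr * 0.42, nc * 0.30)
  roi_radius <- roi_radius %||% max(3, round(0.16 * min(semiaxes)))

  tsr <- dplyr::mutate(.tsr_template,
    center_row = center[1] + .data$v * semiaxes[1],
    center_col = center[2] + .data$u * semiaxes[2],
    radius_px = roi_radius
  )

  spm_ids <- sort(unique(unlist(spm_groups)))
  if (!identical(spm_ids, 1:32)) {
    abort("`spm_groups` must cover every SPM id 1-32.")
  }
  if (!identical(sort(as.integer(names(spm_groups))), 1:9)) {
    abort("`spm_groups` must define all nine TSR areas.")
  }
  map <- tibble::tibble(
    tsr_id = rep(as.integer(names(spm_groups)), lengths(spm_groups)),
    spm_id = unlist(spm_groups, use.names = FALSE)
  )
  # place each group's SPM points on a small ring inside its TSR circle
  spm <- dplyr::group_by(map, .data$tsr_id)
  spm <- dplyr::mutate(spm, .k = dplyr::row_number(), .n = dplyr::n())
  spm <- dplyr::ungroup(spm)
  spm <- dplyr::left_join(spm, tsr[, c("id", "center_row", "center_col")],
                          by = c(tsr_id = "id"))
  ang <- 2 * pi * (spm$.k - 1) / spm$.n
  spm_points <- tibble::tibble(
    id = spm$spm_id,
    tsr_id = spm$tsr_id,
    center_row = spm$center_row + 0.45 * roi_radius * sin(ang),
    center_col = spm$center_col + 0.45 * roi_radius * cos(ang),
    radius_px = pmax(1, 0.22 * roi_radius)
  )
  spm_points <- dplyr::arrange(spm_points, .data$id)

  structure(list(tsr_positions = tsr, spm_points = spm_points,
                 spm_to_tsr = map, dim = c(nr, nc), center = center,
                 semiaxes = semiaxes,
                 side_pairs = list(c(1L, 3L), c(4L, 6L), c(7L, 8L))),
            class = "facial_layout")
}

#' @export
print.facial_layout <- function(x, ...) {
  cat(sprintf("<facial_layout: %d x %d px, 9 areas (radius %g px), 32 SPM points>\n",
              x$dim[1], x$dim[2], x$tsr_positions$radius_px[1]))
  invisible(x)
}

# Pixels whose integer centers fall inside a circle (center-in rule).
.circle_pixels <- function(center_row, center_col, radius, dim) {
  r0 <- max(1L, floor(center_row - radius)); r1 <- min(dim[1], ceiling(center_row + radius))
  c0 <- max(1L, floor(center_col - radius)); c1 <- min(dim[2], ceiling(center_col + radius))
  rows <- rep(r0:r1, times = c1 - c0 + 1L)
  cols <- rep(c0:c1, each = r1 - r0 + 1L)
  keep <- (rows - center_row)^2 + (cols - center_col)^2 <= radius^2
  list(rows = rows[keep], cols = cols[keep])
}

#' Write or read a layout as JSON
#'
#' @param layout A `facial_layout`.
#' @param path JSON file path.
#' @return `write_layout_json()` invisibly returns `path`;
#'   `read_layout_json()` returns a `facial_layout`.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "facial_layout"))
  obj <- list(tsr_positions = layout$tsr_positions,
              spm_points = layout$spm_points,
              spm_to_tsr = layout$spm_to_tsr,
              dim = layout$dim, center = layout$center,
              semiaxes = layout$semiaxes,
              side_convention = "anatomical; subject right = image left")
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- facial_layout(dim = obj$dim, center = obj$center,
                       semiaxes = obj$semiaxes)
  lay$tsr_positions <- tibble::as_tibble(obj$tsr_positions)
  lay$spm_points <- tibble::as_tibble(obj$spm_points)
  lay$spm_to_tsr <- tibble::as_tibble(obj$spm_to_tsr)
  lay
}
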