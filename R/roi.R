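# Nine-position facial ROI machinery: circular extraction, SPM point
# aggregation, left-right and between-group comparisons, normalized
# histograms, and device comparison tables.

#' Extract one circular facial region of interest
#'
#' Selects all pixels whose integer centers fall inside the position's
#' circle (center-in rule; a 50-pixel radius selects 7845 lattice points,
#' the "about 7500 spectra" scale of a 100-pixel-diameter area), and returns
#' per-pixel spectra and CIELAB values plus their means. The summary CIELAB
#' coordinate is the mean of the per-pixel Lab values by default
#' (`lab_stat = "mean_of_lab"`); the Lab of the mean spectrum is also
#' available (`"lab_of_mean"`), and both are always stored.
#'
#' @param cube Reflectance `hs_cube`.
#' @param layout A [facial_layout()].
#' @param position_id Area id 1-9.
#' @param illuminant,observer Colorimetric conditions (D65, 10-degree
#'   observer by default).
#' @param lab_stat Which summary convention `mean_lab` reports.
#' @param face_id Optional identifier carried into the summary.
#' @return An object of class `position_summary`: a list with `face_id`,
#'   `position_id`, `zone`, `side`, `n_pixels`, `mean_spectrum`
#'   (an `hs_spectrum`), `mean_lab` (named numeric), `lab_of_mean_spectrum`,
#'   `pixel_lab` (tibble: row, col, L, a, b), and `pixel_spectra` (matrix).
#' @export
extract_roi <- function(cube, layout, position_id,
                        illuminant = cie_d65(), observer = "cie10deg",
                        lab_stat = c("mean_of_lab", "lab_of_mean"),
                        face_id = NA_character_) {
  assert_cube(cube, "reflectance")
  lab_stat <- match.arg(lab_stat)
  stopifnot(inherits(layout, "facial_layout"))
  pos <- layout$tsr_positions[layout$tsr_positions$id == position_id, ]
  if (nrow(pos) != 1) abort(sprintf("Unknown position id %s.", position_id))
  d <- dim(cube$values)
  if (pos$center_row - pos$radius_px < 1 || pos$center_row + pos$radius_px > d[1] ||
      pos$center_col - pos$radius_px < 1 || pos$center_col + pos$radius_px > d[2]) {
    abort(sprintf("Position %d circle extends beyond the cube bounds.", position_id))
  }
  px <- .circle_pixels(pos$center_row, pos$center_col, pos$radius_px, d)
  mat <- cube_spectra_matrix(cube, px$rows, px$cols)
  pixel_lab <- cube_to_lab(cube, px$rows, px$cols, illuminant, observer)
  mean_spec <- spectrum(cube$wavelengths, colMeans(mat), "reflectance")
  lab_mean_px <- c(L = mean(pixel_lab$L), a = mean(pixel_lab$a), b = mean(pixel_lab$b))
  lab_of_mean <- lab_from_spectrum(mean_spec, illuminant, observer)
  structure(list(
    face_id = face_id, position_id = as.integer(position_id),
    zone = pos$zone, side = pos$side, n_pixels = length(px$rows),
    mean_spectrum = mean_spec,
    mean_lab = if (lab_stat == "mean_of_lab") lab_mean_px else lab_of_mean,
    mean_of_pixel_lab = lab_mean_px, lab_of_mean_spectrum = lab_of_mean,
    pixel_lab = pixel_lab, pixel_spectra = mat,
    provenance = list(observer = observer)
  ), class = "position_summary")
}

#' @export
print.position_summary <- function(x, ...) {
  cat(sprintf(
    "<position_summary: face %s, position %d (%s %s), %d px, Lab = (%.1f, %.1f, %.1f)>\n",
    x$face_id, x$position_id, x$side, x$zone, x$n_pixels,
    x$mean_lab["L"], x$mean_lab["a"], x$mean_lab["b"]))
  invisible(x)
}

#' Extract all nine positions of a face
#'
#' @inheritParams extract_roi
#' @return A named list of nine `position_summary` objects.
#' @export
extract_all_rois <- function(cube, layout, illuminant = cie_d65(),
                             observer = "cie10deg",
                             lab_stat = "mean_of_lab", face_id = NA_character_) {
  out <- purrr::map(1:9, function(p) {
    extract_roi(cube, layout, p, illuminant, observer, lab_stat, face_id)
  })
  names(out) <- paste0("P", 1:9)
  out
}

#' Tabulate position summaries
#'
#' @param summaries A list of `position_summary` objects.
#' @return A tibble with one row per summary: face_id, position_id, zone,
#'   side, n_pixels, L, a, b.
#' @export
summaries_to_tibble <- function(summaries) {
  purrr::map_dfr(summaries, function(s) {
    tibble::tibble(face_id = s$face_id, position_id = s$position_id,
                   zone = s$zone, side = s$side, n_pixels = s$n_pixels,
                   L = s$mean_lab["L"], a = s$mean_lab["a"], b = s$mean_lab["b"])
  })
}

#' Average the 32 contact-spectrophotometer points into the nine areas
#'
#' For each of the nine layout areas, the unweighted per-wavelength mean of
#' the SPM point spectra mapped to it (area 1 averages points 1 and 5, and
#' so on per the layout's grouping).
#'
#' @param spm_spectra List of 32 reflectance spectra on a common grid, named
#'   or ordered by SPM id.
#' @param layout A [facial_layout()].
#' @return A named list of nine spectra (`P1`-`P9`).
#' @export
combine_spm_points <- function(spm_spectra, layout) {
  stopifnot(inherits(layout, "facial_layout"))
  ids <- names(spm_spectra) %||% as.character(seq_along(spm_spectra))
  names(spm_spectra) <- ids
  need <- as.character(sort(unique(layout$spm_to_tsr$spm_id)))
  missing <- setdiff(need, ids)
  if (length(missing)) {
    abort(sprintf("Missing SPM spectra for point id(s) %s.",
                  paste(missing, collapse = ", ")))
  }
  ref <- spm_spectra[[1]]
  purrr::walk(spm_spectra, function(s) {
    assert_spectrum(s); assert_same_grid(ref, s)
  })
  out <- purrr::map(1:9, function(p) {
    members <- layout$spm_to_tsr$spm_id[layout$spm_to_tsr$tsr_id == p]
    vals <- rowMeans(vapply(as.character(members),
                            function(i) spm_spectra[[i]]$value,
                            numeric(nrow(ref))))
    spectrum(ref$wavelength, vals, "reflectance")
  })
  names(out) <- paste0("P", 1:9)
  out
}

#' Compare imaging-derived spectra with point-device spectra
#'
#' For one face and position: the RMSE and CIELAB delta E (D65, 10-degree
#' observer) between the imaging system's ROI mean spectrum and each
#' device's spectrum, all regridded to the common analysis grid
#' (400-700 nm, 10 nm).
#'
#' @param his A `position_summary` (or a reflectance `hs_spectrum`).
#' @param tsr,spm Device reflectance spectra (either may be NULL).
#' @param grid Common analysis grid.
#' @param illuminant,observer Colorimetric conditions.
#' @return A tibble with columns `device`, `rmse`, `delta_e_lab` (plus
#'   `face_id`, `position_id` when `his` is a summary).
#' @export
device_comparison <- function(his, tsr = NULL, spm = NULL,
                              grid = seq(400, 700, 10),
                              illuminant = cie_d65(), observer = "cie10deg") {
  if (inherits(his, "position_summary")) {
    his_spec <- his$mean_spectrum
    face_id <- his$face_id; position_id <- his$position_id
  } else {
    assert_spectrum(his, "his")
    his_spec <- his
    face_id <- NA_character_; position_id <- NA_integer_
  }
  his_g <- regrid_spectrum(his_spec, grid)
  lab_his <- lab_from_spectrum(his_g, illuminant, observer)
  one <- function(dev, s) {
    s_g <- regrid_spectrum(s, grid)
    tibble::tibble(
      face_id = face_id, position_id = position_id, device = dev,
      rmse = rmse_spectra(his_g, s_g),
      delta_e_lab = delta_e_lab(lab_his, lab_from_spectrum(s_g, illuminant, observer))
    )
  }
  out <- list()
  if (!is.null(tsr)) out <- c(out, list(one("TSR", tsr)))
  if (!is.null(spm)) out <- c(out, list(one("SPM", spm)))
  if (!length(out)) abort("Supply at least one device spectrum.")
  dplyr::bind_rows(out)
}

#' Aggregate device comparisons into a Table-III-shaped summary
#'
#' Mean and standard deviation of RMSE and delta E across faces, per
#' position and device, plus an `Average` row per device across positions.
#'
#' @param comparisons A tibble of rows from [device_comparison()].
#' @return A tibble of class `device_comparison_table`.
#' @export
device_comparison_table <- function(comparisons) {
  per_pos <- comparisons |>
    dplyr::group_by(.data$device, .data$position_id) |>
    dplyr::summarise(rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
                     delta_e_mean = mean(.data$delta_e_lab),
                     delta_e_sd = sd(.data$delta_e_lab),
                     n_faces = dplyr::n(), .groups = "drop")
  avg <- per_pos |>
    dplyr::group_by(.data$device) |>
    dplyr::summarise(position_id = NA_integer_,
                     rmse_sd = sd(.data$rmse_mean),
                     rmse_mean = mean(.data$rmse_mean),
                     delta_e_sd = sd(.data$delta_e_mean),
                     delta_e_mean = mean(.data$delta_e_mean),
                     n_faces = max(.data$n_faces), .groups = "drop")
  out <- dplyr::bind_rows(per_pos, avg)
  class(out) <- c("device_comparison_table", class(out))
  out
}

#' Left-right facial side comparison
#'
#' CIELAB differences between the anatomical side pairs (1,3) forehead,
#' (4,6) cheek, and (7,8) jawline, on the positions' summary Lab values,
#' plus the difference between the mean of the right-side positions
#' (1, 4, 7) and the mean of the left-side positions (3, 6, 8).
#'
#' @param summaries List of nine `position_summary` objects (P1-P9).
#' @return A tibble with columns `comparison`, `zone`, `delta_e_lab`,
#'   `delta_e_ab`.
#' @export
side_comparison <- function(summaries) {
  tab <- summaries_to_tibble(summaries)
  if (!all(1:9 %in% tab$position_id)) abort("All nine positions are required.")
  lab_of <- function(p) {
    r <- tab[tab$position_id == p, ]
    c(L = r$L, a = r$a, b = r$b)
  }
  pairs <- list(c(1L, 3L), c(4L, 6L), c(7L, 8L))
  rows <- purrr::map_dfr(pairs, function(pr) {
    tibble::tibble(
      comparison = sprintf("P%d vs P%d", pr[1], pr[2]),
      zone = tab$zone[tab$position_id == pr[1]],
      delta_e_lab = delta_e_lab(lab_of(pr[1]), lab_of(pr[2])),
      delta_e_ab = delta_e_ab(lab_of(pr[1]), lab_of(pr[2]))
    )
  })
  right <- colMeans(do.call(rbind, purrr::map(c(1L, 4L, 7L), lab_of)))
  left <- colMeans(do.call(rbind, purrr::map(c(3L, 6L, 8L), lab_of)))
  dplyr::bind_rows(rows, tibble::tibble(
    comparison = "right mean (1,4,7) vs left mean (3,6,8)", zone = "all",
    delta_e_lab = delta_e_lab(right, left), delta_e_ab = delta_e_ab(right, left)
  ))
}

#' Normalized frequency histogram of a CIELAB channel
#'
#' Histogram with bins of width `bin_width` centered on integer multiples of
#' the width, normalized so the modal bin has frequency 1. The peak location
#' is the center of the modal bin rounded to the nearest integer (ties break
#' to the lowest bin), matching how modal CIELAB coordinates are tabulated.
#'
#' @param values Numeric vector (one Lab channel over pixels).
#' @param bin_width Bin width in CIELAB units (default 1).
#' @return A list with `bins` (tibble: center, frequency) and `peak`
#'   (integer-rounded modal bin center).
#' @export
normalized_histogram <- function(values, bin_width = 1) {
  if (!length(values)) abort("`values` must be non-empty.")
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  centers_idx <- round(values / bin_width)
  lo <- min(centers_idx); hi <- max(centers_idx)
  counts <- tabulate(centers_idx - lo + 1L, nbins = hi - lo + 1L)
  centers <- (lo:hi) * bin_width
  keep <- counts > 0
  freq <- counts / max(counts)
  peak_center <- centers[which.max(counts)] # first maximum = lowest bin on ties
  list(bins = tibble::tibble(center = centers[keep], frequency = freq[keep]),
       peak = round(peak_center))
}

#' Per-group CIELAB statistics and between-group color difference
#'
#' Input is one row per (face, position) with the position's summary CIELAB
#' coordinate and the face's group label. Per group, means and standard
#' deviations of `L`, `a`, `b` are computed over all 9 x n_faces values.
#' The between-group difference is reported under both orders of averaging:
#' convention `"of_means"` is the delta E between the two group-mean Lab
#' coordinates; `"mean_of_pairs"` averages the delta E between per-face mean
#' Lab coordinates over all cross-group face pairs (the two conventions
#' differ whenever within-group spread is appreciable, so both are given).
#'
#' @param face_position_lab Tibble with columns `face_id`, `group`,
#'   `position_id`, `L`, `a`, `b`.
#' @return An object of class `skin_group_stats`: list with `per_group`,
#'   `between` tibbles.
#' @export
group_statistics <- function(face_position_lab) {
  req <- c("face_id", "group", "position_id", "L", "a", "b")
  if (!all(req %in% names(face_position_lab))) {
    abort(sprintf("`face_position_lab` needs columns %s.", paste(req, collapse = ", ")))
  }
  if (nrow(face_position_lab) == 0 || anyNA(face_position_lab$group)) {
    abort("Every row needs a non-missing group label, and groups must be non-empty.")
  }
  per_group <- face_position_lab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_faces = dplyr::n_distinct(.data$face_id),
                     dplyr::across(c("L", "a", "b"),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
  groups <- sort(unique(face_position_lab$group))
  between <- NULL
  if (length(groups) == 2) {
    gmean <- function(g) {
      d <- face_position_lab[face_position_lab$group == g, ]
      c(L = mean(d$L), a = mean(d$a), b = mean(d$b))
    }
    m1 <- gmean(groups[1]); m2 <- gmean(groups[2])
    face_means <- face_position_lab |>
      dplyr::group_by(.data$face_id, .data$group) |>
      dplyr::summarise(L = mean(.data$L), a = mean(.data$a), b = mean(.data$b),
                       .groups = "drop")
    f1 <- face_means[face_means$group == groups[1], ]
    f2 <- face_means[face_means$group == groups[2], ]
    pair_de <- outer(seq_len(nrow(f1)), seq_len(nrow(f2)),
                     Vectorize(function(i, j) {
                       delta_e_lab(c(f1$L[i], f1$a[i], f1$b[i]),
                                   c(f2$L[j], f2$a[j], f2$b[j]))
                     }))
    pair_de_ab <- outer(seq_len(nrow(f1)), seq_len(nrow(f2)),
                        Vectorize(function(i, j) {
                          delta_e_ab(c(f1$L[i], f1$a[i], f1$b[i]),
                                     c(f2$L[j], f2$a[j], f2$b[j]))
                        }))
    between <- tibble::tibble(
      convention = c("of_means", "mean_of_pairs"),
      delta_e_lab = c(delta_e_lab(m1, m2), mean(pair_de)),
      delta_e_ab = c(delta_e_ab(m1, m2), mean(pair_de_ab))
    )
  }
  structure(list(per_group = per_group, between = between,
                 n_rows = nrow(face_position_lab)),
            class = "skin_group_stats")
}

#' @export
print.skin_group_stats <- function(x, ...) {
  cat("Per-group CIELAB statistics (over faces x positions):\n")
  print(x$per_group)
  if (!is.null(x$between)) {
    cat("\nBetween-group color difference:\n")
    print(x$between)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.skin_group_stats <- function(x, ...) {
  x$per_group |>
    tidyr::pivot_longer(cols = -c("group", "n_faces"),
                        names_to = c("channel", "stat"), names_sep = "_") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
}

#' @exportS3Method generics::glance
glance.skin_group_stats <- function(x, ...) {
  if (is.null(x$between)) {
    return(tibble::tibble(n_groups = nrow(x$per_group), n_rows = x$n_rows))
  }
  tibble::tibble(
    n_groups = nrow(x$per_group), n_rows = x$n_rows,
    delta_e_lab_of_means = x$between$delta_e_lab[1],
    delta_e_lab_mean_of_pairs = x$between$delta_e_lab[2],
    delta_e_ab_of_means = x$between$delta_e_ab[1],
    delta_e_ab_mean_of_pairs = x$between$delta_e_ab[2]
  )
}

#' @exportS3Method generics::tidy
tidy.device_comparison_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.device_comparison_table <- function(x, ...) {
  avg <- x[is.na(x$position_id), ]
  tibble::tibble(device = avg$device, rmse = avg$rmse_mean,
                 delta_e_lab = avg$delta_e_mean)
}
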