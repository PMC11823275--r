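# End-to-end analysis pipeline over a synthetic cohort: generate, acquire,
# calibrate, extract the nine facial positions, and produce the group,
# side, color-volume and device-comparison summaries.

.config_defaults <- function() {
  list(
    n_faces = 29L, group_mix = 4 / 29, seed = 1L,
    dim = c(192L, 256L), wavelengths = seq(400, 720, 10),
    analysis_grid = seq(400, 700, 10),
    observer = "cie10deg", render_observer = "cie2deg",
    lab_stat = "mean_of_lab", histogram_bin_width = 1,
    noise = TRUE, het_amplitude = 0.15, melanin_asymmetry = 0,
    tsr_bias = 1, spm_bias = 1.08, device_noise_sd = 0,
    out_dir = NULL
  )
}

#' Analysis configuration
#'
#' Assembles and validates the pipeline configuration. Every field has a
#' recorded default; unknown fields are rejected before any computation.
#' The SPM bias default (1.08) reflects that diffuse-geometry contact
#' spectrophotometers read skin reflectance consistently higher than
#' radiance-geometry instruments.
#'
#' @param ... Named overrides of the defaults (see
#'   `hyperskin:::.config_defaults()` for the full list): `n_faces`,
#'   `group_mix`, `seed`, `dim`, `wavelengths`, `analysis_grid`, `observer`,
#'   `render_observer`, `lab_stat`, `histogram_bin_width`, `noise`,
#'   `het_amplitude`, `melanin_asymmetry`, `tsr_bias`, `spm_bias`,
#'   `device_noise_sd`, `out_dir`.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (cfg$n_faces < 1) abort("`n_faces` must be >= 1.")
  if (cfg$group_mix < 0 || cfg$group_mix > 1) abort("`group_mix` must be in [0, 1].")
  structure(cfg, class = "analysis_config")
}

#' Run the full cohort pipeline
#'
#' Generates a cohort of synthetic faces, renders and calibrates each face
#' (raw counts -> dark correction -> gray-reference radiance -> illuminant
#' field -> reflectance), extracts the nine facial positions, and computes:
#' per-group CIELAB statistics with the between-group color difference,
#' left-right side comparisons, discernible-color volume/area counts per
#' group and combined, normalized histograms of the side-pair channels, and
#' the device-comparison table against simulated TSR and SPM readings.
#' All randomness derives from `config$seed`; reruns with an identical
#' configuration reproduce identical numbers.
#'
#' @param config An [analysis_config()].
#' @return A list of class `skin_pipeline_report`: `config`, `faces`
#'   (tibble of face-position Lab values), `group_stats`, `side`,
#'   `volumes`, `device_table`, `histograms`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  illuminant <- cie_d65(config$wavelengths)
  scenes <- make_cohort(config$n_faces, config$group_mix, config$seed,
                        dim = config$dim, wavelengths = config$wavelengths,
                        het_amplitude = config$het_amplitude,
                        melanin_asymmetry = config$melanin_asymmetry)

  face_rows <- list()
  side_rows <- list()
  device_rows <- list()
  pixel_lab <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    face_id <- sprintf("face%02d", i)
    refl <- recover_reflectance(sc, noise = config$noise)
    rois <- extract_all_rois(refl, sc$layout, illuminant, config$observer,
                             config$lab_stat, face_id)
    tab <- summaries_to_tibble(rois)
    tab$group <- sc$group
    face_rows[[i]] <- tab
    s <- side_comparison(rois)
    s$face_id <- face_id; s$group <- sc$group
    side_rows[[i]] <- s
    pixel_lab[[i]] <- dplyr::bind_rows(purrr::map(rois, function(r) {
      cbind(r$pixel_lab, group = sc$group, position_id = r$position_id)
    }))
    # device comparison against simulated point readings
    spm_raw <- purrr::map(1:32, function(p) {
      simulate_device_readings(sc, "SPM", p, bias = config$spm_bias,
                               noise_sd = config$device_noise_sd)
    })
    names(spm_raw) <- as.character(1:32)
    spm9 <- combine_spm_points(spm_raw, sc$layout)
    dc <- purrr::map_dfr(1:9, function(p) {
      tsr <- simulate_device_readings(sc, "TSR", p, bias = config$tsr_bias,
                                      noise_sd = config$device_noise_sd)
      device_comparison(rois[[p]], tsr = tsr, spm = spm9[[p]],
                        grid = config$analysis_grid,
                        illuminant = illuminant, observer = config$observer)
    })
    device_rows[[i]] <- dc
  }

  faces <- dplyr::bind_rows(face_rows)
  px <- dplyr::bind_rows(pixel_lab)
  volumes <- dplyr::bind_rows(
    tibble::tibble(set = "all",
                   volume = count_discernible(px, "lab_volume"),
                   ab_area = count_discernible(px, "ab_area")),
    px |> dplyr::group_by(set = .data$group) |>
      dplyr::summarise(volume = count_discernible(dplyr::pick("L", "a", "b"), "lab_volume"),
                       ab_area = count_discernible(dplyr::pick("L", "a", "b"), "ab_area"),
                       .groups = "drop")
  )

  histograms <- purrr::map(c(L = "L", a = "a", b = "b"), function(ch) {
    px |>
      dplyr::group_by(.data$group, .data$position_id) |>
      dplyr::summarise(
        peak = normalized_histogram(.data[[ch]], config$histogram_bin_width)$peak,
        .groups = "drop")
  })

  structure(list(
    config = config,
    faces = faces,
    group_stats = group_statistics(faces),
    side = dplyr::bind_rows(side_rows),
    volumes = volumes,
    device_table = device_comparison_table(dplyr::bind_rows(device_rows)),
    histogram_peaks = histograms
  ), class = "skin_pipeline_report")
}

#' @export
print.skin_pipeline_report <- function(x, ...) {
  cat(sprintf("<skin_pipeline_report: %d faces, seed %d>\n\n",
              x$config$n_faces, x$config$seed))
  print(x$group_stats)
  cat("\nDiscernible-color volumes:\n")
  print(x$volumes)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' CSV tables (with a one-line `#` configuration comment) plus a JSON
#' summary; numeric CSV fields are written at 12 significant digits.
#'
#' @param report A `skin_pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "skin_pipeline_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  cfg_line <- sprintf("# seed=%d n_faces=%d group_mix=%.6f noise=%s",
                      cfg$seed, cfg$n_faces, cfg$group_mix, cfg$noise)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    writeLines(cfg_line, p)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          function(x) signif(x, 12)))
    suppressWarnings(utils::write.table(df, p, sep = ",", row.names = FALSE,
                                        append = TRUE, quote = FALSE))
    p
  }
  wr(report$faces, "face_position_lab.csv")
  wr(tibble::as_tibble(report$device_table), "device_comparison.csv")
  wr(report$side, "side_comparison.csv")
  wr(report$volumes, "color_volumes.csv")
  jsonlite::write_json(
    list(config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
         per_group = report$group_stats$per_group,
         between = report$group_stats$between,
         volumes = report$volumes),
    file.path(out_dir, "report.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
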