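# ENVI cube reader/writer. ENVI is the de facto hyperspectral interchange
# format: a flat binary file plus a plain-text .hdr with `samples` (cols),
# `lines` (rows), `bands`, `interleave` (bsq/bil/bip), `data type`, and a
# `wavelength = { ... }` list. Values are written as little-endian float32
# (data type 4). Stage, per-band exposure and metadata ride along in the
# header as custom fields.

#' Write a cube as an ENVI file pair
#'
#' @param cube An `hs_cube`.
#' @param path Path of the data file; the header is written at `<path>.hdr`.
#' @param interleave `"bsq"` (band sequential), `"bil"`, or `"bip"`.
#' @return Invisibly, `path`.
#' @export
write_envi_cube <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  assert_cube(cube)
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  # array index order is (row=line, col=sample, band)
  perm <- switch(interleave,
                 bsq = c(2, 1, 3), # sample fastest, then line, then band
                 bil = c(2, 3, 1), # sample, band, line
                 bip = c(3, 2, 1)) # band, sample, line
  vals <- aperm(cube$values, perm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  hdr <- c(
    "ENVI",
    "description = { hyperskin spectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = { %s }", paste(cube$wavelengths, collapse = ", ")),
    sprintf("stage = %s", cube$stage)
  )
  if (!is.null(cube$exposure)) {
    hdr <- c(hdr, sprintf("exposure = { %s }",
                          paste(cube$exposure, collapse = ", ")))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # join multi-line { ... } blocks onto one line
  repeat {
    new <- gsub("(\\{[^}]*?)\\n", "\\1 ", txt, perl = TRUE)
    if (identical(new, txt)) break
    txt <- new
  }
  fields <- list()
  # scan key = value pairs, where value may be a braced list spanning lines
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[tolower(key)]] <- val
  }
  fields
}

.parse_envi_list <- function(x) {
  as.numeric(strsplit(gsub("[{}]", "", x), ",")[[1]])
}

#' Read an ENVI cube
#'
#' @param path Path of the data file (a `<path>.hdr` header must exist, or
#'   pass the `.hdr` path itself).
#' @return An `hs_cube`.
#' @export
read_envi_cube <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  data_path <- sub("\\.hdr$", "", path)
  if (!file.exists(hdr_path)) abort(sprintf("Header %s not found.", hdr_path))
  if (!file.exists(data_path)) abort(sprintf("Data file %s not found.", data_path))
  f <- .parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(f))
  if (length(miss)) abort(sprintf("ENVI header is missing: %s.",
                                  paste(miss, collapse = ", ")))
  if (is.null(f$wavelength)) {
    abort("ENVI header has no `wavelength` field; the spectral axis is required.")
  }
  ns <- as.integer(f$samples); nl <- as.integer(f$lines); nb <- as.integer(f$bands)
  wl <- .parse_envi_list(f$wavelength)
  if (length(wl) != nb) {
    abort(sprintf("Header lists %d wavelengths but declares %d bands.",
                  length(wl), nb))
  }
  if (f$`data type` != "4") abort("Only float32 (data type 4) cubes are supported.")
  n <- ns * nl * nb
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(raw_vals) != n) {
    abort(sprintf("Data file holds %d values; header implies %d.",
                  length(raw_vals), n))
  }
  interleave <- tolower(trimws(f$interleave))
  dims <- switch(interleave,
                 bsq = c(ns, nl, nb), bil = c(ns, nb, nl), bip = c(nb, ns, nl),
                 abort(sprintf("Unknown interleave '%s'.", interleave)))
  arr <- array(raw_vals, dims)
  vals <- switch(interleave,
                 bsq = aperm(arr, c(2, 1, 3)),
                 bil = aperm(arr, c(3, 1, 2)),
                 bip = aperm(arr, c(3, 2, 1)))
  stage <- trimws(f$stage %||% "raw_counts")
  exposure <- if (!is.null(f$exposure)) .parse_envi_list(f$exposure) else NULL
  spectral_cube(vals, wl, stage, exposure = exposure,
                metadata = list(source = data_path))
}
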