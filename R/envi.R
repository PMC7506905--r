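#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' Reads the classic ENVI format: a plain-text `.hdr` describing dimensions,
#' data type, interleave and (optionally) the wavelength list, next to a raw
#' binary payload. BSQ, BIL and BIP interleaves and the common numeric data
#' types (8/16/32-bit integer, 32/64-bit float) are supported. All
#' intensities are converted to floating point on read.
#'
#' @param path path to the `.hdr` file, to the binary file, or their common
#'   stem (extension-free).
#' @param sample_id sample identifier for the returned cube; defaults to the
#'   file stem.
#' @param group_id augmentation-group id; defaults to `sample_id`.
#'
#' @return A [hyper_cube()] at stage `"raw"`, with wavelengths populated when
#'   the header carries a `wavelength` block.
#' @seealso [write_cube()]
#' @export
read_envi <- function(path, sample_id = NULL, group_id = NULL) {
  paths <- envi_paths(path)
  if (!file.exists(paths$hdr)) {
    abort(sprintf("ENVI header not found: '%s'.", paths$hdr),
          class = "hsal_error_format")
  }
  if (!file.exists(paths$bin)) {
    abort(sprintf("ENVI binary not found: '%s'.", paths$bin),
          class = "hsal_error_format")
  }
  hdr <- parse_envi_header(paths$hdr)
  required <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(required, names(hdr))
  if (length(missing) > 0) {
    abort(sprintf("ENVI header is missing field(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "hsal_error_format")
  }
  w <- as.integer(hdr[["samples"]])
  h <- as.integer(hdr[["lines"]])
  c <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  interleave <- tolower(trimws(hdr[["interleave"]]))
  if (!interleave %in% c("bsq", "bil", "bip")) {
    abort(sprintf("unsupported ENVI interleave '%s' (need bsq, bil or bip).",
                  interleave),
          class = "hsal_error_unsupported")
  }
  spec <- envi_dtype_spec(dtype)
  offset <- as.integer(hdr[["header offset"]] %||% "0")
  n <- as.double(w) * h * c
  expected_bytes <- offset + n * spec$size
  actual_bytes <- file.info(paths$bin)$size
  if (actual_bytes < expected_bytes) {
    abort(sprintf(
      "ENVI binary '%s' holds %.0f bytes but the header promises %.0f.",
      paths$bin, actual_bytes, expected_bytes
    ), class = "hsal_error_format")
  }
  endian <- if (identical(trimws(hdr[["byte order"]] %||% "0"), "1")) "big" else "little"
  con <- file(paths$bin, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", n = offset)
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  vals <- as.numeric(vals)
  pixels <- switch(interleave,
    # stream order (fastest first): bsq = sample,line,band; bil = sample,band,line;
    # bip = band,sample,line -- permute each to (line, sample, band) = (H, W, C)
    bsq = aperm(array(vals, dim = c(w, h, c)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(w, c, h)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(c, w, h)), c(3, 2, 1))
  )
  wavelengths <- NULL
  if (!is.null(hdr[["wavelength"]])) {
    wavelengths <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
    if (length(wavelengths) != c) {
      abort("ENVI wavelength list length does not match the band count.",
            class = "hsal_error_format")
    }
  }
  meta <- if (file.exists(paths$meta)) {
    jsonlite::read_json(paths$meta, simplifyVector = TRUE)
  } else {
    list()
  }
  sid <- sample_id %||% meta$sample_id %||% basename(paths$stem)
  hyper_cube(pixels, sample_id = sid, wavelengths = wavelengths,
             stage = meta$stage %||% "raw",
             group_id = group_id %||% meta$group_id %||% sid)
}

#' Write a hyperspectral cube to disk
#'
#' Two layouts are supported. `"envi"` writes a `.hdr`/binary pair (float32,
#' BSQ, little-endian) plus a small JSON sidecar carrying the sample id,
#' stage and group id; values round-trip bit-exactly once they are
#' float32-representable. `"array_dir"` writes a directory holding one flat
#' float32 array file (`pixels.bin`, R column-major order over H x W x C)
#' and a `meta.json` sidecar.
#'
#' @param cube a [hyper_cube()].
#' @param path output stem (for `"envi"`: `<path>.hdr` + `<path>.img`) or
#'   directory (for `"array_dir"`).
#' @param format `"envi"` or `"array_dir"`.
#' @return The path written to (invisibly the stem or directory).
#' @export
write_cube <- function(cube, path, format = c("envi", "array_dir")) {
  assert_cube(cube)
  format <- match.arg(format)
  if (dim(cube$pixels)[3] < 1L) {
    abort("cube has 0 channels; refusing to write.",
          class = "hsal_error_validation")
  }
  if (format == "envi") {
    write_cube_envi(cube, path)
  } else {
    write_cube_array_dir(cube, path)
  }
}

#' Read a cube written by [write_cube()] in either layout
#'
#' Dispatches on the path: a directory is read as an array-dir layout,
#' anything else as ENVI.
#'
#' @inheritParams read_envi
#' @return A [hyper_cube()].
#' @export
read_cube <- function(path) {
  if (dir.exists(path)) read_array_dir(path) else read_envi(path)
}

#' Quantize values to 32-bit float precision
#'
#' Rounds doubles to the nearest float32-representable value, the precision
#' cubes carry on disk. Applying this before [write_cube()] makes the
#' write/read round trip bit-exact.
#'
#' @param x numeric vector or array.
#' @return `x` with every element rounded to float32 precision.
#' @export
quantize_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "numeric", n = length(x), size = 4L)
  dim(out) <- d
  out
}

# ---- internals --------------------------------------------------------------

envi_paths <- function(path) {
  stem <- sub("\\.(hdr|img|dat|raw)$", "", path)
  list(stem = stem, hdr = paste0(stem, ".hdr"), bin = paste0(stem, ".img"),
       meta = paste0(stem, ".json"))
}

envi_dtype_spec <- function(dtype) {
  switch(as.character(dtype),
    "1"  = list(what = "integer", size = 1L, signed = FALSE),
    "2"  = list(what = "integer", size = 2L, signed = TRUE),
    "3"  = list(what = "integer", size = 4L, signed = TRUE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "5"  = list(what = "numeric", size = 8L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    abort(sprintf("unsupported ENVI data type %s.", dtype),
          class = "hsal_error_unsupported")
  )
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[[1]])) {
    abort(sprintf("'%s' is not an ENVI header (missing ENVI magic).", hdr_path),
          class = "hsal_error_format")
  }
  # fold brace-continued values ("wavelength = { ... }") onto one line
  text <- paste(lines[-1], collapse = "\n")
  fields <- list()
  pos <- 1L
  pat <- gregexpr("(?m)^([^=\\n]+)=", text, perl = TRUE)[[1]]
  starts <- as.integer(pat)
  lens <- attr(pat, "match.length")
  if (length(starts) == 1 && starts == -1) return(fields)
  for (i in seq_along(starts)) {
    key <- trimws(substr(text, starts[i], starts[i] + lens[i] - 2L))
    val_start <- starts[i] + lens[i]
    val_end <- if (i < length(starts)) starts[i + 1] - 1L else nchar(text)
    val <- substr(text, val_start, val_end)
    val <- trimws(gsub("[{}]", "", gsub("\n", " ", val)))
    fields[[tolower(key)]] <- val
  }
  fields
}

write_cube_envi <- function(cube, path) {
  paths <- envi_paths(path)
  d <- dim(cube$pixels)
  hdr <- c(
    "ENVI",
    "description = { hsal hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0"
  )
  if (!is.null(cube$wavelengths)) {
    hdr <- c(hdr, paste0("wavelength = { ",
                         paste(format(cube$wavelengths, trim = TRUE),
                               collapse = ", "), " }"))
  }
  writeLines(hdr, paths$hdr)
  # BSQ stream: sample fastest, then line, then band
  con <- file(paths$bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube$pixels, c(2, 1, 3))), con, size = 4L,
           endian = "little")
  jsonlite::write_json(
    list(sample_id = cube$sample_id, stage = cube$stage,
         group_id = cube$group_id),
    paths$meta, auto_unbox = TRUE
  )
  invisible(paths$stem)
}

write_cube_array_dir <- function(cube, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("cannot create directory '%s'.", path),
          class = "hsal_error_io")
  }
  con <- file(file.path(path, "pixels.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(cube$pixels), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(
      dims = dim(cube$pixels),
      order = "column-major (H, W, C)",
      dtype = "float32",
      sample_id = cube$sample_id,
      stage = cube$stage,
      group_id = cube$group_id,
      wavelengths = cube$wavelengths
    ),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

read_array_dir <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "pixels.bin")
  if (!file.exists(meta_path) || !file.exists(bin_path)) {
    abort(sprintf("'%s' is not an array-dir cube (need meta.json + pixels.bin).",
                  path),
          class = "hsal_error_format")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  if (file.info(bin_path)$size < n * 4) {
    abort(sprintf("'%s' is truncated.", bin_path), class = "hsal_error_format")
  }
  vals <- readBin(bin_path, "numeric", n = n, size = 4L, endian = "little")
  pixels <- array(vals, dim = dims)
  wl <- meta$wavelengths
  if (length(wl) == 0) wl <- NULL
  hyper_cube(pixels, sample_id = meta$sample_id, wavelengths = wl,
             stage = meta$stage, group_id = meta$group_id)
}
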