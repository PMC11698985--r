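#' Construct a hyperspectral cube
#'
#' The in-memory canonical layout is a `lines x samples x bands` array
#' (each band a contiguous plane, i.e. band-sequential), with row 0-of-1
#' at the top and 0-based pixel conventions used in all serialized
#' artifacts.  Frames are accessed as `cube$data[, , band]`.
#'
#' @param data numeric 3-d array, `lines x samples x bands`.
#' @param wavelengths numeric vector of band-center wavelengths (nm),
#'   strictly increasing, one per band.
#' @param metadata optional named list (provenance, interleave of
#'   origin, description).
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(data, wavelengths = NULL, metadata = list()) {
  if (length(dim(data)) != 3) stop("data must be a 3-d array (lines x samples x bands)")
  nb <- dim(data)[3]
  if (is.null(wavelengths)) {
    warning("no wavelengths supplied; using band indices")
    wavelengths <- seq_len(nb)
  }
  if (length(wavelengths) != nb)
    stop("wavelength count must equal the number of bands")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(data))) stop("cube data must be finite")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 metadata = metadata),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral cube: %d lines x %d samples x %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# ENVI <-> R data type codes
.envi_types <- list(
  `1` = list(what = "integer", size = 1, signed = FALSE),
  `2` = list(what = "integer", size = 2, signed = TRUE),
  `3` = list(what = "integer", size = 4, signed = TRUE),
  `4` = list(what = "numeric", size = 4, signed = TRUE),
  `5` = list(what = "numeric", size = 8, signed = TRUE),
  `12` = list(what = "integer", size = 2, signed = FALSE)
)

# Parse an ENVI header file into a named list; values spanning {...}
# blocks are collapsed first.
parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0 || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header: ", header_path)
  body <- paste(txt[-1], collapse = "\n")
  # join multi-line { ... } values onto one line via brace-depth tracking
  lines <- character(0)
  buf <- ""
  depth <- 0
  for (ln in strsplit(body, "\n")[[1]]) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    depth <- depth + lengths(regmatches(ln, gregexpr("\\{", ln))) -
      lengths(regmatches(ln, gregexpr("\\}", ln)))
    if (depth == 0) { lines <- c(lines, buf); buf <- "" }
  }
  lines <- lines[grepl("=", lines)]
  keys <- tolower(trimws(sub("=.*", "", lines)))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

#' Read a hyperspectral cube in ENVI raster format
#'
#' Supports BSQ, BIL and BIP interleaves, byte / int16 / int32 /
#' float32 / float64 / uint16 samples, and both byte orders.  A header
#' without a wavelength list loads with index-valued wavelengths and a
#' warning.
#'
#' @param header_path path to the `.hdr` text header; the binary is
#'   found by dropping/replacing the extension or via an explicit
#'   `data_path`.
#' @param data_path optional explicit path to the binary cube.
#' @return A [hyper_cube()].
#' @export
read_envi <- function(header_path, data_path = NULL) {
  hdr <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ENVI header missing field(s): ",
                         paste(miss, collapse = ", "))
  samples <- as.integer(hdr$samples)
  lines <- as.integer(hdr$lines)
  bands <- as.integer(hdr$bands)
  dtype <- as.character(as.integer(hdr$`data type`))
  interleave <- tolower(hdr$interleave)
  byte_order <- if (!is.null(hdr$`byte order`)) as.integer(hdr$`byte order`) else 0L
  offset <- if (!is.null(hdr$`header offset`)) as.integer(hdr$`header offset`) else 0L
  if (!dtype %in% names(.envi_types))
    stop("unsupported ENVI data type: ", dtype)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported ENVI interleave: ", interleave)
  tp <- .envi_types[[dtype]]

  if (is.null(data_path)) {
    base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
    cand <- c(base, paste0(base, c(".dat", ".img", ".raw", ".bsq", ".bil", ".bip")))
    data_path <- cand[file.exists(cand)][1]
    if (is.na(data_path)) stop("ENVI binary not found next to header: ", header_path)
  }
  n <- samples * lines * bands
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  raw <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
                 endian = if (byte_order == 1) "big" else "little")
  if (length(raw) < n) stop("ENVI binary truncated: ", data_path)
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, c(samples, bands, lines)), c(3, 1, 2)),
    bip = aperm(array(raw, c(bands, samples, lines)), c(3, 2, 1)))
  wl <- NULL
  if (!is.null(hdr$wavelength)) {
    wl <- as.numeric(strsplit(gsub("[{}]", "", hdr$wavelength), ",")[[1]])
    if (length(wl) != bands) {
      warning("wavelength list length does not match band count; ignored")
      wl <- NULL
    }
  }
  hyper_cube(arr, wl, metadata = list(interleave = interleave,
                                      source = data_path))
}

#' Write a hyperspectral cube in ENVI raster format
#'
#' Reflectance is stored as 32-bit float by default, preserving
#' deconvolution output precision.
#'
#' @param cube a [hyper_cube()].
#' @param header_path output `.hdr` path; the binary is written next to
#'   it with the extension dropped unless `data_path` is given.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code (4 = float32, 5 = float64).
#' @param data_path optional explicit binary path.
#' @return Invisibly, the binary path.
#' @export
write_envi <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4, data_path = NULL) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  dtype <- as.character(as.integer(data_type))
  if (!dtype %in% c("4", "5")) stop("write_envi supports float32 (4) and float64 (5)")
  d <- dim(cube$data)
  lines <- d[1]; samples <- d[2]; bands <- d[3]
  if (is.null(data_path)) data_path <- sub("\\.hdr$", "", header_path,
                                           ignore.case = TRUE)
  flat <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  con <- file(data_path, "wb")
  writeBin(as.numeric(flat), con, size = .envi_types[[dtype]]$size,
           endian = "little")
  close(con)
  hdr <- c("ENVI",
           "description = { wavepsf hyperspectral cube; row 0 = top line, 0-based pixel indices }",
           paste("samples =", samples),
           paste("lines =", lines),
           paste("bands =", bands),
           "header offset = 0",
           "file type = ENVI Standard",
           paste("data type =", dtype),
           paste("interleave =", interleave),
           "byte order = 0",
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  " }"))
  writeLines(hdr, header_path)
  invisible(data_path)
}

#' Write a cube as one 16-bit TIFF frame per band
#'
#' Filenames encode the wavelength (`band_0550.0nm.tif`), so a natural
#' sort recovers an increasing wavelength axis.  Values are clipped to
#' `[0, 1]` and quantized to 16 bits.
#'
#' @param cube a [hyper_cube()].
#' @param path output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_frames_dir <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_along(cube$wavelengths), function(b) {
    f <- file.path(path, sprintf("band_%08.2fnm.tif", cube$wavelengths[b]))
    img <- pmin(pmax(cube$data[, , b], 0), 1)
    tiff::writeTIFF(img, f, bits.per.sample = 16)
    f
  }, character(1))
  invisible(files)
}

#' Read a directory of per-band image frames into a cube
#'
#' @param path directory containing one TIFF/PNG per band with a
#'   wavelength-encoded filename (any run of digits with optional
#'   decimal point before `nm`).
#' @return A [hyper_cube()].
#' @export
read_frames_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stop("no frame images found in ", path)
  wl <- as.numeric(sub(".*?([0-9]+\\.?[0-9]*)nm.*", "\\1", basename(files)))
  if (any(is.na(wl))) stop("cannot parse wavelength from filename(s): ",
                           paste(basename(files)[is.na(wl)], collapse = ", "))
  ord <- order(wl)
  files <- files[ord]; wl <- wl[ord]
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes; first offending file: ",
         basename(files[which(dims[1, ] != dims[1, 1] |
                              dims[2, ] != dims[2, 1])[1]]))
  arr <- array(unlist(frames), c(dims[1, 1], dims[2, 1], length(frames)))
  hyper_cube(arr, wl, metadata = list(source = path))
}

#' Write a stack of PSF kernels as a multi-page TIFF
#'
#' One 32-bit float page per patch; a sidecar `*.index.tsv` records the
#' frame index, wavelength and patch indices of every page.
#'
#' @param psfs list of frames, each a list of `psf_kernel` matrices in
#'   row-major patch order (as from [psf_field_from_coefficients()]).
#' @param path output `.tif` path.
#' @param wavelengths optional wavelengths (nm), one per frame.
#' @return Invisibly, `path`.
#' @export
write_psf_stack <- function(psfs, path, wavelengths = NULL) {
  pages <- list()
  idx <- NULL
  for (f in seq_along(psfs)) {
    for (p in seq_along(psfs[[f]])) {
      pages[[length(pages) + 1]] <- unclass(psfs[[f]][[p]])
      idx <- rbind(idx, data.frame(
        page = length(pages), frame = f - 1L,
        wavelength_nm = if (is.null(wavelengths)) NA_real_ else wavelengths[f],
        patch = p - 1L))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  write.table(idx, paste0(path, ".index.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF PSF stack written by [write_psf_stack()]
#'
#' @param path `.tif` path with its sidecar index.
#' @return List of frames of kernel matrices, with a `wavelengths`
#'   attribute when recorded.
#' @export
read_psf_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  idx_path <- paste0(path, ".index.tsv")
  if (!file.exists(idx_path)) stop("missing PSF stack index: ", idx_path)
  idx <- read.delim(idx_path)
  frames <- sort(unique(idx$frame))
  out <- lapply(frames, function(f) {
    rows <- idx[idx$frame == f, ]
    rows <- rows[order(rows$patch), ]
    lapply(rows$page, function(pg) pages[[pg]])
  })
  wl <- vapply(frames, function(f) idx$wavelength_nm[idx$frame == f][1],
               numeric(1))
  if (!all(is.na(wl))) attr(out, "wavelengths") <- wl
  out
}

#' Read/write key-patch coefficient tables
#'
#' Plain TSV, one row per (frame, patch) knot: `frame`, `wavelength_nm`,
#' `patch_row`, `patch_col` (0-based), then one column per Zernike
#' coefficient named `z<noll>`.
#'
#' @param knots data frame in the layout above.
#' @param path TSV path.
#' @return `write_coef_table` invisibly returns `path`;
#'   `read_coef_table` returns the data frame with an attribute
#'   `noll_indices`.
#' @export
write_coef_table <- function(knots, path) {
  write.table(knots, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coef_table
#' @export
read_coef_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  zc <- grep("^z[0-9]+$", names(tab), value = TRUE)
  if (length(zc) == 0) stop("no z<noll> coefficient columns in ", path)
  attr(tab, "noll_indices") <- as.integer(sub("^z", "", zc))
  tab
}
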