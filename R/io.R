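# File interchange: multi-page TIFF cubes with plain-text wavelength
# headers, PNG frame series with a CSV manifest, calibration CSV/JSON.

#' Write a spectral cube as multi-page TIFF plus sidecar header
#'
#' One 32-bit-float TIFF page per band, values scaled into `[0, 1]` by a
#' global factor recorded in the header. The sidecar is a plain-text,
#' ENVI-style header listing the kind, scale and one wavelength (nm) per
#' line.
#'
#' @param cube A `spectral_cube`.
#' @param path Output TIFF path.
#' @param header_path Sidecar path (default `<path>.hdr.txt`).
#' @return `path`, invisibly.
#' @export
write_spectral_cube <- function(cube, path,
                                header_path = paste0(path, ".hdr.txt")) {
  stopifnot(inherits(cube, "spectral_cube"))
  mx <- max(cube$data, na.rm = TRUE)
  scale <- if (is.finite(mx) && mx > 0) mx else 1
  pages <- lapply(seq_along(cube$wavelengths), function(i) {
    m <- cube$data[i, , ] / scale
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  writeLines(c(paste0("kind = ", cube$kind),
               paste0("scale = ", format(scale, digits = 17)),
               paste0("bands = ", length(cube$wavelengths)),
               "wavelength_nm:",
               format(cube$wavelengths, digits = 10, trim = TRUE)),
             header_path)
  invisible(path)
}

#' Read a spectral cube written by [write_spectral_cube()]
#'
#' Validates that the page count of the TIFF matches the number of
#' wavelengths in the header.
#'
#' @param path TIFF path.
#' @param header_path Sidecar path (default `<path>.hdr.txt`).
#' @return A `spectral_cube`.
#' @export
read_spectral_cube <- function(path, header_path = paste0(path, ".hdr.txt")) {
  lines <- readLines(header_path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, " ?="), lines, value = TRUE)
    if (length(ln) != 1L) stop("header missing field: ", key)
    trimws(sub("^[^=]*=", "", ln))
  }
  kind <- get_field("kind")
  scale <- as.numeric(get_field("scale"))
  nb <- as.integer(get_field("bands"))
  wl_at <- grep("^wavelength_nm:", lines)
  wl <- as.numeric(lines[(wl_at + 1L):length(lines)])
  if (length(wl) != nb) stop("header band count does not match wavelengths")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != nb) {
    stop("TIFF has ", length(pages), " pages but header declares ", nb)
  }
  d <- dim(pages[[1]])
  data <- array(NA_real_, c(nb, d[1], d[2]))
  for (i in seq_len(nb)) data[i, , ] <- pages[[i]] * scale
  spectral_cube(wl, data, kind)
}

#' Write an optode frame series as 16-bit TIFFs with a CSV manifest
#'
#' @param frames List of [rgb_frame()] objects with channel values in
#'   `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the manifest CSV (`<dir>/manifest.csv`), invisibly.
#' @export
write_optode_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    arr <- array(0, c(dim(f$red), 3))
    arr[, , 1] <- pmin(pmax(f$red, 0), 1)
    arr[, , 2] <- pmin(pmax(f$green, 0), 1)
    arr[, , 3] <- pmin(pmax(f$blue, 0), 1)
    fn <- sprintf("%s_%03d.tif", prefix, i)
    tiff::writeTIFF(arr, file.path(dir, fn), bits.per.sample = 16)
    data.frame(filename = fn, t_minutes = f$t, light_state = f$light)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read an optode frame series from a manifest CSV
#'
#' @param manifest_path Path to a manifest CSV with columns `filename`,
#'   `t_minutes`, `light_state`; frame files are resolved relative to the
#'   manifest's directory.
#' @return List of [rgb_frame()] objects ordered by `t_minutes`.
#' @export
read_optode_frames <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "t_minutes", "light_state") %in% names(man)))
  man <- man[order(man$t_minutes), ]
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    arr <- tiff::readTIFF(file.path(dir, man$filename[i]))
    rgb_frame(arr[, , 1], arr[, , 2], arr[, , 3],
              t = man$t_minutes[i], light = man$light_state[i])
  })
}

#' Write / read a calibration model as JSON
#'
#' @param model An `o2_calibration`.
#' @param path JSON path.
#' @return `path` invisibly (write); an `o2_calibration` without the raw
#'   `nls` fit object (read).
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "o2_calibration"))
  jsonlite::write_json(list(a = model$a, b = model$b, rss = model$rss,
                            n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = x$a, b = x$b, rss = x$rss, n = x$n, fit = NULL),
            class = "o2_calibration")
}

#' Write a scalar image as CSV
#'
#' Plain matrix CSV (no row/column names); the units tag goes into a
#' `# units:` comment on the first line.
#'
#' @param img A `scalar_image`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scalar_image_csv <- function(img, path) {
  stopifnot(inherits(img, "scalar_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", img$units), con)
  utils::write.table(img$data, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a scalar image written by [write_scalar_image_csv()]
#'
#' @param path CSV path.
#' @return A `scalar_image`.
#' @export
read_scalar_image_csv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- if (startsWith(first, "# units:")) {
    trimws(sub("^# units:", "", first))
  } else "dimensionless"
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  scalar_image(m, units = units)
}
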