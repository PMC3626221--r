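# File formats
#
# Floating-point images and sinograms use a plain-text CSV container
# (full "%.17g" precision, hence lossless for doubles).  Sinograms carry
# a JSON sidecar <path>.meta.json with the acquisition geometry; images
# carry one with the pixel size.  For raster interchange the ASCII PGM
# (portable graymap, "P2") format is supported: 16-bit quantized, with
# the min/max scaling recorded in the sidecar so the attenuation scale
# can be recovered.

write_matrix_csv <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

read_matrix_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (anyNA(m)) stop("non-numeric values in ", path)
  m
}

meta_path <- function(path) paste0(path, ".meta.json")

#' Read and write images
#'
#' `write_image`/`read_image` round-trip an [image_grid()] through a
#' file chosen by extension: `.csv` (lossless text container, with a
#' JSON sidecar holding the pixel size) or `.pgm` (ASCII 16-bit
#' portable graymap; values are min-max scaled to 0..65535 and the
#' scaling is stored in the sidecar, so the round trip is lossless up
#' to the 16-bit quantization).
#'
#' @param grid an [image_grid()].
#' @param path file path ending in `.csv` or `.pgm`.
#' @return `read_image` returns an [image_grid()].
#' @export
write_image <- function(grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write_matrix_csv(grid$values, path)
    jsonlite::write_json(list(pixel_size = grid$pixel_size, format = "csv"),
                         meta_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "pgm") {
    lo <- min(grid$values); hi <- max(grid$values)
    scale <- if (hi > lo) 65535 / (hi - lo) else 0
    q <- round((grid$values - lo) * scale)
    con <- file(path, "w")
    writeLines(c("P2", paste(grid$side_px, grid$side_px), "65535"), con)
    writeLines(apply(q, 1, paste, collapse = " "), con)
    close(con)
    jsonlite::write_json(list(pixel_size = grid$pixel_size, format = "pgm",
                              min = lo, max = hi),
                         meta_path(path), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  meta <- if (file.exists(meta_path(path)))
    jsonlite::read_json(meta_path(path)) else list()
  px <- if (is.null(meta$pixel_size)) 1.0 else meta$pixel_size
  if (ext == "csv") {
    image_grid(read_matrix_csv(path), px)
  } else if (ext == "pgm") {
    lines <- readLines(path)
    lines <- lines[!startsWith(trimws(lines), "#")]
    tok <- as.numeric(unlist(strsplit(paste(lines[-1], collapse = " "), "\\s+")))
    tok <- tok[!is.na(tok)]
    w <- tok[1]; h <- tok[2]; maxv <- tok[3]
    vals <- matrix(tok[-(1:3)], nrow = h, ncol = w, byrow = TRUE)
    if (!is.null(meta$min) && !is.null(meta$max) && meta$max > meta$min)
      vals <- meta$min + vals / maxv * (meta$max - meta$min)
    image_grid(vals, px)
  } else stop("unsupported image format: .", ext)
}

#' Read and write sinograms
#'
#' CSV container (one row per view) with a JSON sidecar recording the
#' view angles, detector count and spacing; the round trip is lossless.
#'
#' @param sino a [sinogram()].
#' @param path file path ending in `.csv`.
#' @return `read_sinogram` returns a [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_matrix_csv(sino$values, path)
  g <- sino$geometry
  jsonlite::write_json(list(angles_deg = g$angles_deg,
                            n_detectors = g$n_detectors,
                            detector_spacing = g$detector_spacing),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  geom <- projection_geometry(meta$angles_deg, meta$n_detectors,
                              meta$detector_spacing)
  sinogram(read_matrix_csv(path), geom)
}
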