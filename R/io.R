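# Plain-text interchange formats: ASCII PGM (P2) images with JSON sidecar
# metadata, and full-precision TSV pairs for complex fields. (No binary
# image library is assumed; P2 is lossless for 16-bit scaled intensities.)

writePGM <- function(mat, path, maxval = 65535L) {
  stopifnot(is.matrix(mat), all(mat >= 0), all(mat <= maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  write(t(round(mat)), file = con, ncolumns = 16L)
}

readPGM <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM files are supported")
  nx <- as.integer(toks[2]); ny <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nx * ny) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a hologram as ASCII PGM plus JSON sidecar
#'
#' The intensity is scaled linearly to 16-bit integer range; the scale and
#' offset, together with the optics metadata (`wavelength_m`,
#' `pixel_pitch_m`, `distance_m`, `reference_amplitude`, `reference_phase`),
#' are stored in a JSON sidecar next to the image so the recording can be
#' reproduced exactly up to quantization.
#'
#' @param hologram a [Hologram-class].
#' @param path output `.pgm` path (sidecar written as `.json` beside it).
#' @return `writeHologram` invisibly returns `path`; `readHologram` returns
#'   a [Hologram-class].
#' @export
writeHologram <- function(hologram, path) {
  stopifnot(is(hologram, "Hologram"))
  intens <- hologram@intensity
  lo <- min(intens); hi <- max(intens)
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  writePGM((intens - lo) * scale, path)
  meta <- list(
    format = "holoSense-hologram-v1",
    wavelength_m = hologram@optics@wavelength,
    pixel_pitch_m = hologram@optics@pixelPitch,
    dims = hologram@optics@dims,
    distance_m = hologram@optics@distance,
    reference_amplitude = hologram@refAmplitude,
    reference_phase = hologram@refPhase,
    scale = scale, offset = lo)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeHologram
#' @export
readHologram <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  img <- readPGM(path)
  cfg <- opticalSetup(meta$wavelength_m, meta$pixel_pitch_m, meta$dims,
                      meta$distance_m)
  new("Hologram", intensity = img / meta$scale + meta$offset, optics = cfg,
      refAmplitude = meta$reference_amplitude,
      refPhase = meta$reference_phase,
      meta = list(source = path))
}

#' Write / read a complex field as a TSV pair plus JSON sidecar
#'
#' Real and imaginary channels are written as full-precision tab-separated
#' matrices `<stem>_re.tsv` / `<stem>_im.tsv` with optics metadata in
#' `<stem>.json`.
#'
#' @param field a [ComplexField-class].
#' @param stem output path stem (no extension).
#' @return `writeField` invisibly returns `stem`; `readField` returns a
#'   [ComplexField-class].
#' @export
writeField <- function(field, stem) {
  stopifnot(is(field, "ComplexField"))
  v <- field@values
  utils::write.table(Re(v), paste0(stem, "_re.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(v), paste0(stem, "_im.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(format = "holoSense-field-v1",
               wavelength_m = field@optics@wavelength,
               pixel_pitch_m = field@optics@pixelPitch,
               dims = field@optics@dims,
               distance_m = field@optics@distance,
               plane_z_m = field@planeZ)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeField
#' @export
readField <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  re <- as.matrix(utils::read.table(paste0(stem, "_re.tsv"), sep = "\t"))
  im <- as.matrix(utils::read.table(paste0(stem, "_im.tsv"), sep = "\t"))
  dimnames(re) <- dimnames(im) <- NULL
  cfg <- opticalSetup(meta$wavelength_m, meta$pixel_pitch_m, meta$dims,
                      meta$distance_m)
  complexField(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)),
               cfg, planeZ = meta$plane_z_m)
}

#' Write / read a binary target mask as ASCII PGM (0/255)
#'
#' @param mask a [TargetMask-class] (or logical matrix).
#' @param path output `.pgm` path.
#' @return `writeMask` invisibly returns `path`; `readMask` returns a
#'   logical matrix.
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "TargetMask")) mask@mask else mask
  writePGM(m * 255, path, maxval = 255L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  readPGM(path) > 0
}
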