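## TIFF / CSV / JSON input-output. Images travel as single-page 16-bit
## grayscale TIFF with a JSON sidecar (pixel size, intensity scale);
## curves as two-column CSV (z_nm, deflection_nm) with the calibration
## constants in a JSON sidecar.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a FilamentImage as 16-bit grayscale TIFF
#'
#' Intensities are scaled into [0, 1] by the recorded scale factor
#' (max(1, max intensity)) and restored on reading from the sidecar
#' JSON, which also carries the pixel size and identifier.
#'
#' @param img a [FilamentImage-class].
#' @param path TIFF file path; the sidecar is written next to it with a
#'   .json extension.
#' @return \code{writeFilamentImage}: the path, invisibly;
#'   \code{readFilamentImage}: a [FilamentImage-class].
#' @export
writeFilamentImage <- function(img, path) {
  px <- pixels(img)
  scale <- max(1, max(px))
  tiff::writeTIFF(px / scale, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = pixelSize(img), scale = scale,
                            id = imageId(img)),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFilamentImage
#' @param pixelSize fallback nm/px when no sidecar is present.
#' @export
readFilamentImage <- function(path, pixelSize = 20) {
  m <- tiff::readTIFF(path)
  meta <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else
    list(pixel_size_nm = pixelSize, scale = 1,
         id = tools::file_path_sans_ext(basename(path)))
  FilamentImage(m * meta$scale, pixelSize = meta$pixel_size_nm,
                id = meta$id)
}

#' Write / read an AFM approach curve as CSV plus JSON metadata
#'
#' The CSV has header columns \code{z_nm, deflection_nm}; spring
#' constant, bead radius and Poisson ratio live in the sidecar JSON.
#'
#' @param curve a [ForceCurve-class].
#' @param path CSV file path.
#' @return \code{writeForceCurve}: the path, invisibly;
#'   \code{readForceCurve}: a [ForceCurve-class].
#' @export
writeForceCurve <- function(curve, path) {
  write.csv(data.frame(z_nm = curve@z, deflection_nm = curve@d),
            path, row.names = FALSE)
  meta <- list(k_N_per_m = curve@k, Rs_nm = curve@Rs, nu = curve@nu,
               id = curve@id)
  if (!is.null(attr(curve, "E"))) meta$true_E_Pa <- attr(curve, "E")
  if (!is.null(attr(curve, "z0"))) meta$true_z0_nm <- attr(curve, "z0")
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeForceCurve
#' @param metadata optional named list overriding the sidecar (k_N_per_m,
#'   Rs_nm, nu, id).
#' @export
readForceCurve <- function(path, metadata = NULL) {
  df <- read.csv(path)
  meta <- if (!is.null(metadata)) metadata else
    if (file.exists(sidecarPath(path)))
      jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else
      stop("no metadata for curve ", path)
  ForceCurve(df$z_nm, df$deflection_nm, k = meta$k_N_per_m,
             Rs = meta$Rs_nm, nu = meta$nu,
             id = if (!is.null(meta$id)) meta$id else
               tools::file_path_sans_ext(basename(path)))
}
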