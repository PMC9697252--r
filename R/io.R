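## On-disk interchange: volumes as NIfTI (spacing in the header, via
## RNifti when available) or raw little-endian float32 with a JSON
## sidecar {dims, spacing_mm}; annotation tables as CSV.

ANNOTATION_COLS <- c("scan_id", "reader_id", "kind", "cx_mm", "cy_mm",
                     "cz_mm", "ex_mm", "ey_mm", "ez_mm")

#' Write / read an annotation table as CSV
#'
#' Column layout: \code{scan_id, reader_id, kind, cx_mm, cy_mm, cz_mm,
#' ex_mm, ey_mm, ez_mm}.
#'
#' @param annotations data.frame in the annotation layout.
#' @param path CSV file path.
#' @return \code{readAnnotations} returns the data.frame;
#'   \code{writeAnnotations} returns the path invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  stopifnot(all(ANNOTATION_COLS %in% names(annotations)))
  utils::write.csv(annotations[, ANNOTATION_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(ANNOTATION_COLS %in% names(ann)))
  ann
}

#' Write a volume to disk
#'
#' NIfTI (\code{.nii} / \code{.nii.gz}, voxel spacing in the header;
#' requires \pkg{RNifti}) or raw little-endian float32 plus a JSON
#' sidecar \code{<path>.json} holding \code{dims} and \code{spacing_mm}.
#'
#' @param volume 3D numeric array.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @param path output path; format chosen by extension (\code{.nii},
#'   \code{.nii.gz} or \code{.raw}).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, spacingMm, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to write NIfTI files")
    img <- RNifti::asNifti(volume, reference = NULL)
    RNifti::pixdim(img) <- spacingMm
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume), con, size = 4L, endian = "little")
    sidecar <- sprintf(
      '{"dims": [%s], "spacing_mm": [%s]}',
      paste(dim(volume), collapse = ", "),
      paste(spacingMm, collapse = ", "))
    writeLines(sidecar, paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' @param path a \code{.nii}/\code{.nii.gz} file or a raw float32 file
#'   with a \code{<path>.json} sidecar.
#' @return List with \code{volume} (3D array) and \code{spacingMm}.
#' @export
readVolume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("RNifti is required to read NIfTI files")
    img <- RNifti::readNifti(path)
    list(volume = array(as.numeric(img), dim = dim(img)),
         spacingMm = RNifti::pixdim(img)[seq_len(3)])
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read raw-volume sidecars")
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = prod(meta$dims), size = 4L,
                    endian = "little")
    list(volume = array(vals, dim = meta$dims), spacingMm = meta$spacing_mm)
  }
}

#' Write a generated dataset to a directory
#'
#' Volumes go to \code{<dir>/<scan_id>.nii} (or \code{.raw} when
#' \code{format = "raw"}); all reader annotations to
#' \code{<dir>/annotations.csv}.
#'
#' @param dataset as returned by \code{\link{generateDataset}}.
#' @param dir output directory.
#' @param format "nii" or "raw".
#' @return The directory, invisibly.
#' @export
writeDataset <- function(dataset, dir, format = c("nii", "raw")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (scan in dataset$scans) {
    ext <- if (format == "nii") ".nii" else ".raw"
    writeVolume(scan@volume, scan@spacingMm,
                file.path(dir, paste0(scan@scanId, ext)))
  }
  writeAnnotations(dataset$annotations, file.path(dir, "annotations.csv"))
  invisible(dir)
}
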