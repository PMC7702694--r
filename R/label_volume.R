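#' Default label dictionary for knee-contact segmentations
#'
#' Integer codes for the anatomical labels used throughout the package.
#' A voxel carries exactly one label; contact labels take precedence over
#' `tibial_cartilage` where they overlap, so the full tibial-cartilage mask
#' is the union of `tibial_cartilage`, `contact_medial` and
#' `contact_lateral`.
#'
#' @return Named integer vector.
#' @export
default_label_dictionary <- function() {
  c(background = 0L, tibial_plateau = 1L, tibial_cartilage = 2L,
    femoral_cartilage = 3L, contact_medial = 4L, contact_lateral = 5L)
}

#' Voxelized label volume
#'
#' The segmentation substrate: a 3-D integer label grid with anisotropic
#' voxel spacing and a world origin. World coordinates follow the
#' voxel-centre convention: voxel index `(i, j, k)` (1-based) has its centre
#' at `origin + ((i,j,k) - 1) * spacing`. The third index is the axial
#' (slice) direction; `spacing[3]` is the slice thickness.
#'
#' @param labels 3-D integer array; values must appear in `dictionary`.
#' @param spacing Length-3 positive voxel spacing `(dx, dy, dz)` in mm.
#' @param origin World coordinate (mm) of the centre of voxel `(1,1,1)`.
#' @param dictionary Named integer label dictionary; see
#'   [default_label_dictionary()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing,
                         origin = c(0, 0, 0),
                         dictionary = default_label_dictionary()) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector (mm)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(dictionary))
  if (length(bad))
    stop("labels contain values absent from the dictionary: ",
         paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = spacing, origin = origin,
                 dictionary = dictionary),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Label volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  counts <- table(factor(x$labels, levels = unname(x$dictionary),
                         labels = names(x$dictionary)))
  nz <- counts[counts > 0]
  cat("  labels:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Binary mask for one or more labels
#'
#' @param vol A [label_volume()].
#' @param which Character vector of label names (or integer codes).
#' @return Logical 3-D array.
#' @export
label_mask <- function(vol, which) {
  stopifnot(inherits(vol, "label_volume"))
  codes <- if (is.character(which)) {
    missing <- setdiff(which, names(vol$dictionary))
    if (length(missing))
      stop("label(s) absent from dictionary: ", paste(missing, collapse = ", "))
    unname(vol$dictionary[which])
  } else as.integer(which)
  array(vol$labels %in% codes, dim = dim(vol$labels))
}

# World coordinates (n x 3, mm) of the centres of TRUE voxels in a mask.
mask_world_coords <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  sweep(sweep(idx - 1, 2L, spacing, `*`), 2L, origin, `+`)
}

#' Write / read a label volume as NIfTI with a JSON sidecar
#'
#' The integer label image is written as NIfTI (spacing in `pixdim`); the
#' label dictionary, origin and spacing are written to a JSON sidecar at
#' `<path>.json` so the world-frame convention survives the round trip
#' independently of NIfTI orientation headers.
#'
#' @param vol A [label_volume()].
#' @param path Path to the `.nii` (or `.nii.gz`) file.
#' @return `read_label_volume` returns a [label_volume()];
#'   `write_label_volume` returns `path` invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(structure(vol$labels, pixdim = vol$spacing),
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(dictionary = as.list(vol$dictionary),
                            origin = vol$origin, spacing = vol$spacing),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dict <- vapply(side$dictionary, as.integer, integer(1))
  label_volume(array(as.integer(img), dim = dim(img)),
               spacing = side$spacing, origin = side$origin,
               dictionary = dict)
}
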