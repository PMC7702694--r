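#' Anatomical landmark set for the tibia
#'
#' Named world points (mm) from which the tibial anatomical frame is built:
#' the medial and lateral tibial plateau edge points, the plateau centre,
#' and a distal point on the tibial shaft (or the midpoint of the
#' malleoli). Additional named points are carried through untouched.
#'
#' @param ... Named length-3 numeric world points (mm). Must include
#'   `medial_edge`, `lateral_edge`, `plateau_center` and `shaft_distal`.
#' @return An object of class `landmark_set` (a named list of 3-vectors).
#' @export
landmark_set <- function(...) {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1]))
    pts <- pts[[1]]
  req <- c("medial_edge", "lateral_edge", "plateau_center", "shaft_distal")
  missing <- setdiff(req, names(pts))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p)))
      stop("each landmark must be a finite 3-vector")
    p
  })
  structure(pts, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set (mm):\n")
  for (nm in names(x))
    cat(sprintf("  %-15s %s\n", nm, paste(format(round(x[[nm]], 3)), collapse = ", ")))
  invisible(x)
}

#' Read or write landmarks as JSON
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @return `read_landmarks` returns a [landmark_set()];
#'   `write_landmarks` returns `path` invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(unclass(landmarks), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

normalize3 <- function(v, what) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate geometry: ", what)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the tibial anatomical frame from landmarks
#'
#' Constructs a right-handed orthonormal joint coordinate frame on the
#' tibia in the Grood-Suntay spirit: the medial-lateral (ML) axis points
#' from the medial to the lateral plateau edge; the superior-inferior (SI)
#' axis points from the distal shaft toward the plateau centre,
#' orthogonalized against ML (ML is fixed first because the plateau edge
#' points are the most reliably identified landmarks); the
#' anterior-posterior (AP) axis completes the basis as `SI x ML`, so that
#' `ML x AP = SI`. The origin is the plateau centre. Centroids are reported
#' along ML (medial 0% to lateral 100%) and AP (posterior 0% to anterior
#' 100%).
#'
#' @param landmarks A [landmark_set()].
#' @param plateau_extents Optional list with numeric length-2 elements `ml`
#'   and `ap`: the plateau's min/max coordinates (mm) along the frame axes,
#'   used by [centroid_percent()]. Usually filled in from the plateau mask
#'   by [measure_contact()].
#' @return An object of class `joint_frame`: `origin`, unit `axes` (columns
#'   `ml`, `ap`, `si` of a rotation matrix) and `plateau_extents`.
#' @examples
#' lm <- landmark_set(medial_edge = c(-35, 0, 0), lateral_edge = c(35, 0, 0),
#'                    plateau_center = c(0, 0, 0), shaft_distal = c(0, 0, -60))
#' build_tibial_frame(lm)$axes
#' @export
build_tibial_frame <- function(landmarks, plateau_extents = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ml <- normalize3(landmarks$lateral_edge - landmarks$medial_edge,
                   "plateau edge points coincide")
  si_raw <- landmarks$plateau_center - landmarks$shaft_distal
  if (sqrt(sum(si_raw^2)) < 1e-9)
    stop("degenerate geometry: shaft point coincides with plateau centre")
  si <- si_raw - sum(si_raw * ml) * ml
  si <- normalize3(si, "shaft axis is collinear with the plateau edge axis")
  ap <- cross3(si, ml)
  axes <- cbind(ml = ml, ap = ap, si = si)
  frame <- structure(list(origin = landmarks$plateau_center, axes = axes,
                          plateau_extents = plateau_extents),
                     class = "joint_frame")
  validate_joint_frame(frame)
  frame
}

validate_joint_frame <- function(frame) {
  err <- max(abs(crossprod(frame$axes) - diag(3)))
  if (err > 1e-9) stop("frame axes are not orthonormal")
  if (det(frame$axes) < 0) stop("frame is not right-handed")
  if (!is.null(frame$plateau_extents)) {
    for (ax in c("ml", "ap")) {
      e <- frame$plateau_extents[[ax]]
      if (is.null(e) || length(e) != 2L || !(e[1] < e[2]))
        stop("plateau extents must satisfy min < max on both axes")
    }
  }
  invisible(frame)
}

#' @export
print.joint_frame <- function(x, ...) {
  cat("Tibial joint frame\n")
  cat("  origin (mm):", format(round(x$origin, 3)), "\n")
  cat("  ML axis:", format(round(x$axes[, "ml"], 4)), "\n")
  cat("  AP axis:", format(round(x$axes[, "ap"], 4)), "\n")
  cat("  SI axis:", format(round(x$axes[, "si"], 4)), "\n")
  if (!is.null(x$plateau_extents))
    cat(sprintf("  plateau extents (mm): ML [%s], AP [%s]\n",
                paste(format(round(x$plateau_extents$ml, 2)), collapse = ", "),
                paste(format(round(x$plateau_extents$ap, 2)), collapse = ", ")))
  invisible(x)
}

#' World points to frame coordinates
#'
#' @param points Length-3 vector or n x 3 matrix of world points (mm).
#' @param frame A [joint_frame()].
#' @return Coordinates (mm) along the ML, AP and SI axes, relative to the
#'   frame origin.
#' @export
frame_coords <- function(points, frame) {
  stopifnot(inherits(frame, "joint_frame"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1L) else as.matrix(points)
  out <- sweep(p, 2L, frame$origin, `-`) %*% frame$axes
  colnames(out) <- c("ml", "ap", "si")
  if (vec) drop(out) else out
}

#' Express a point as percent position on the tibial plateau
#'
#' Converts a world point to percent coordinates on the plateau:
#' 0% at the medial (resp. posterior) extent boundary and 100% at the
#' lateral (resp. anterior) boundary. Values outside `[0, 100]` are
#' returned as computed but flagged via the `off_plateau` attribute.
#'
#' @param point_mm Length-3 world point (mm).
#' @param frame A [joint_frame()] with `plateau_extents` set.
#' @return Named numeric `c(ml_pct, ap_pct)` with attribute `off_plateau`.
#' @export
centroid_percent <- function(point_mm, frame) {
  stopifnot(inherits(frame, "joint_frame"))
  if (is.null(frame$plateau_extents))
    stop("frame has no plateau extents; compute them from the plateau mask first")
  validate_joint_frame(frame)
  q <- frame_coords(point_mm, frame)
  e <- frame$plateau_extents
  out <- c(ml_pct = 100 * (q[["ml"]] - e$ml[1]) / diff(e$ml),
           ap_pct = 100 * (q[["ap"]] - e$ap[1]) / diff(e$ap))
  attr(out, "off_plateau") <- any(out < 0 | out > 100)
  out
}
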