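#' Contact area of a voxel mask
#'
#' Area is the number of contact voxels multiplied by the in-plane (axial)
#' voxel dimensions: `n * dx * dy`. It is deliberately independent of the
#' slice thickness `dz`, reflecting measurement of an axial footprint from
#' slice-wise tracings. With `projected = TRUE` the area counts each
#' in-plane column at most once (the footprint of the mask projected onto
#' the axial plane); the default follows the literal voxel-count formula.
#'
#' @param mask Logical (or 0/1) 3-D array of contact voxels.
#' @param spacing Length-3 positive voxel spacing (mm).
#' @param projected If `TRUE`, count unique in-plane columns instead of
#'   voxels.
#' @return Area in mm2 (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(4, 4, 2)); m[1:2, 1:2, 1] <- TRUE
#' contact_area(m, c(0.859, 0.859, 2.5))
#' @export
contact_area <- function(mask, spacing, projected = FALSE) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  m <- mask != 0
  n <- if (projected) sum(apply(m, c(1L, 2L), any)) else sum(m)
  n * spacing[1] * spacing[2]
}

#' Maximum axial cross-sectional area of the tibial plateau
#'
#' The normalization denominator for contact area: the largest in-plane
#' area over all axial slices of the plateau mask.
#'
#' @param plateau_mask Logical 3-D array; must be non-empty.
#' @param spacing Length-3 positive voxel spacing (mm).
#' @return Area in mm2.
#' @export
plateau_max_axial_area <- function(plateau_mask, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  m <- plateau_mask != 0
  if (!any(m)) stop("plateau mask is empty")
  max(apply(m, 3L, sum)) * spacing[1] * spacing[2]
}

#' Normalize contact area to the plateau cross-section
#'
#' @param area_mm2 Contact area (mm2).
#' @param plateau_area_mm2 Maximum axial cross-sectional area of the
#'   tibial plateau (mm2); must be positive.
#' @return Percent, `100 * area / plateau_area`.
#' @export
normalize_area <- function(area_mm2, plateau_area_mm2) {
  if (!is.finite(plateau_area_mm2) || plateau_area_mm2 <= 0)
    stop("plateau area must be positive")
  if (any(area_mm2 < 0)) stop("area must be non-negative")
  100 * area_mm2 / plateau_area_mm2
}

#' Geometric centre of a voxel mask
#'
#' Arithmetic mean of the world coordinates of the non-zero voxel centres.
#' An empty mask yields an explicitly undefined result (a vector of `NA`
#' with attribute `defined = FALSE`) rather than a silent zero.
#'
#' @param mask Logical 3-D array.
#' @param spacing Length-3 voxel spacing (mm).
#' @param origin World coordinate (mm) of the centre of voxel `(1,1,1)`.
#' @return Length-3 world coordinates (mm) with attribute `defined`.
#' @export
mask_centroid <- function(mask, spacing, origin = c(0, 0, 0)) {
  coords <- mask_world_coords(mask != 0, as.numeric(spacing), as.numeric(origin))
  if (nrow(coords) == 0L) {
    out <- rep(NA_real_, 3L)
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- colMeans(coords)
  attr(out, "defined") <- TRUE
  out
}

#' Split a contact mask into medial and lateral compartments
#'
#' Voxels are partitioned by the sign of their medial-lateral coordinate in
#' the joint frame: strictly positive ML coordinates (the frame's ML axis
#' points medial to lateral) fall in the lateral compartment, the rest in
#' the medial compartment. The outputs are disjoint and their union is the
#' input.
#'
#' @param mask Logical 3-D array.
#' @param frame A [joint_frame()].
#' @param spacing,origin Voxel geometry of the mask.
#' @return List with logical arrays `medial` and `lateral`.
#' @export
split_compartments <- function(mask, frame, spacing, origin = c(0, 0, 0)) {
  validate_joint_frame(frame)
  m <- mask != 0
  medial <- array(FALSE, dim(m)); lateral <- array(FALSE, dim(m))
  idx <- which(m)
  if (length(idx)) {
    coords <- mask_world_coords(m, as.numeric(spacing), as.numeric(origin))
    ml <- frame_coords(coords, frame)[, "ml"]
    lateral[idx[ml > 0]] <- TRUE
    medial[idx[ml <= 0]] <- TRUE
  }
  list(medial = medial, lateral = lateral)
}

#' Detect tibiofemoral contact from cartilage labels
#'
#' Emulates tracing of "no visible separation": for every in-plane column,
#' the topmost tibial-cartilage voxel is marked as contact when the nearest
#' femoral-cartilage voxel above it in the same column is within
#' `gap_tolerance_mm` (the separation is the number of empty voxels between
#' them times the slice thickness; touching or overlapping labels give a
#' separation of zero). The default tolerance of one through-plane spacing
#' expresses that sub-slice gaps cannot be resolved at the acquisition's
#' resolution. Detected contact voxels are relabelled `contact_medial` /
#' `contact_lateral` by the sign of their ML coordinate in `frame`.
#'
#' @param vol A [label_volume()] containing `tibial_cartilage` and
#'   `femoral_cartilage` labels (existing contact labels are treated as
#'   tibial cartilage and re-derived).
#' @param gap_tolerance_mm Maximum surface separation (mm) still counted as
#'   contact; defaults to the through-plane spacing.
#' @param frame Optional [joint_frame()] used to split compartments; if
#'   `NULL`, a frame is derived from the plateau (or cartilage) mask with
#'   ML along world x.
#' @return A [label_volume()] with re-derived contact labels.
#' @export
extract_contact <- function(vol, gap_tolerance_mm = NULL, frame = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  dict <- vol$dictionary
  if (is.null(gap_tolerance_mm)) gap_tolerance_mm <- vol$spacing[3]
  if (gap_tolerance_mm < 0) stop("gap tolerance must be non-negative")
  lab <- vol$labels
  tib <- lab == dict[["tibial_cartilage"]] |
    lab == dict[["contact_medial"]] | lab == dict[["contact_lateral"]]
  fem <- lab == dict[["femoral_cartilage"]]
  for (nm in c("tibial_cartilage", "femoral_cartilage")) {
    present <- if (nm == "tibial_cartilage") any(tib) else any(fem)
    if (!present) stop("missing label: ", nm)
  }
  d <- dim(lab); nz <- d[3]
  # per-column top tibial voxel, lowest femoral voxel above it, and any
  # femoral voxel at or below it (interdigitated columns count as contact)
  tib_top <- matrix(NA_integer_, d[1], d[2])
  for (k in seq_len(nz)) tib_top[tib[, , k]] <- k
  fem_above <- matrix(NA_integer_, d[1], d[2])
  overlap <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(nz)) {
    f <- fem[, , k] & !is.na(tib_top)
    fem_above[f & k > tib_top & is.na(fem_above)] <- k
    overlap <- overlap | (f & k <= tib_top)
  }
  gap_mm <- (fem_above - tib_top - 1L) * vol$spacing[3]
  contact2d <- overlap | (!is.na(fem_above) & gap_mm <= gap_tolerance_mm)
  contact2d[is.na(contact2d)] <- FALSE
  # reset any previous contact labels to plain tibial cartilage
  lab[lab == dict[["contact_medial"]] | lab == dict[["contact_lateral"]]] <-
    dict[["tibial_cartilage"]]
  cmask <- array(FALSE, d)
  idx2d <- which(contact2d)
  if (length(idx2d)) {
    ii <- (idx2d - 1L) %% d[1] + 1L
    jj <- (idx2d - 1L) %/% d[1] + 1L
    cmask[cbind(ii, jj, tib_top[idx2d])] <- TRUE
  }
  if (is.null(frame)) frame <- default_ml_frame(vol)
  comp <- split_compartments(cmask, frame, vol$spacing, vol$origin)
  lab[comp$medial] <- dict[["contact_medial"]]
  lab[comp$lateral] <- dict[["contact_lateral"]]
  label_volume(lab, vol$spacing, vol$origin, dict)
}

# Fallback frame when no landmarks are available: ML along world x, AP
# along world y, origin at the plateau (or tibial cartilage) mask centroid.
default_ml_frame <- function(vol) {
  m <- label_mask(vol, "tibial_plateau")
  if (!any(m))
    m <- label_mask(vol, c("tibial_cartilage", "contact_medial", "contact_lateral"))
  cen <- mask_centroid(m, vol$spacing, vol$origin)
  lm <- landmark_set(medial_edge = cen - c(10, 0, 0),
                     lateral_edge = cen + c(10, 0, 0),
                     plateau_center = cen,
                     shaft_distal = cen - c(0, 0, 10))
  build_tibial_frame(lm)
}

# min/max plateau-mask coordinates along the frame's ML and AP axes.
plateau_extents_from_mask <- function(plateau_mask, frame, spacing, origin) {
  coords <- mask_world_coords(plateau_mask != 0, spacing, origin)
  if (nrow(coords) == 0L) stop("plateau mask is empty")
  q <- frame_coords(coords, frame)
  list(ml = range(q[, "ml"]), ap = range(q[, "ap"]))
}

#' Measure per-compartment tibiofemoral contact
#'
#' The package's measurement pipeline for one label volume: computes, for
#' each compartment, the contact area (mm2), the area normalized to the
#' maximum axial cross-section of the tibial plateau (%), and the contact
#' centroid in the tibial anatomical frame, both in mm and as percent
#' position on the plateau (medial 0% to lateral 100%, posterior 0% to
#' anterior 100%).
#'
#' @param vol A [label_volume()]. If it has no contact labels they are
#'   derived with [extract_contact()].
#' @param landmarks Optional [landmark_set()]; if supplied the frame is
#'   built with [build_tibial_frame()], otherwise a world-axis-aligned
#'   frame through the plateau centroid is used.
#' @param gap_tolerance_mm Passed to [extract_contact()] when contact
#'   labels must be derived.
#' @param projected Use the projected-footprint area variant (see
#'   [contact_area()]).
#' @return A data frame of class `contact_measurement` with one row per
#'   compartment: `compartment`, `area_mm2`, `area_pct`, `centroid_ml_mm`,
#'   `centroid_ap_mm`, `centroid_ml_pct`, `centroid_ap_pct`,
#'   `centroid_defined`, `plateau_area_mm2`, `extent_ml_mm`,
#'   `extent_ap_mm`, and the extent minima `extent_ml_min_mm`,
#'   `extent_ap_min_mm` (so percent and mm centroid coordinates are
#'   mutually convertible from the row alone).
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' measure_contact(ph$volume, ph$landmarks)
#' @export
measure_contact <- function(vol, landmarks = NULL, gap_tolerance_mm = NULL,
                            projected = FALSE) {
  stopifnot(inherits(vol, "label_volume"))
  frame <- if (!is.null(landmarks)) build_tibial_frame(landmarks)
           else default_ml_frame(vol)
  has_contact <- any(vol$labels == vol$dictionary[["contact_medial"]]) ||
    any(vol$labels == vol$dictionary[["contact_lateral"]])
  if (!has_contact)
    vol <- extract_contact(vol, gap_tolerance_mm, frame)
  plateau <- label_mask(vol, "tibial_plateau")
  plateau_area <- plateau_max_axial_area(plateau, vol$spacing)
  frame$plateau_extents <- plateau_extents_from_mask(plateau, frame,
                                                     vol$spacing, vol$origin)
  rows <- lapply(c("medial", "lateral"), function(comp) {
    m <- label_mask(vol, paste0("contact_", comp))
    area <- contact_area(m, vol$spacing, projected = projected)
    cen <- mask_centroid(m, vol$spacing, vol$origin)
    defined <- isTRUE(attr(cen, "defined"))
    if (defined) {
      q <- frame_coords(cen, frame)
      pct <- centroid_percent(cen, frame)
    } else {
      q <- c(ml = NA_real_, ap = NA_real_, si = NA_real_)
      pct <- c(ml_pct = NA_real_, ap_pct = NA_real_)
    }
    data.frame(compartment = comp,
               area_mm2 = area,
               area_pct = normalize_area(area, plateau_area),
               centroid_ml_mm = unname(q[["ml"]]),
               centroid_ap_mm = unname(q[["ap"]]),
               centroid_ml_pct = unname(pct[["ml_pct"]]),
               centroid_ap_pct = unname(pct[["ap_pct"]]),
               centroid_defined = defined,
               plateau_area_mm2 = plateau_area,
               extent_ml_mm = diff(frame$plateau_extents$ml),
               extent_ap_mm = diff(frame$plateau_extents$ap),
               extent_ml_min_mm = frame$plateau_extents$ml[1],
               extent_ap_min_mm = frame$plateau_extents$ap[1])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contact_measurement", "data.frame")
  attr(out, "frame") <- frame
  out
}

#' @export
print.contact_measurement <- function(x, ...) {
  cat("Tibiofemoral contact measurement\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
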