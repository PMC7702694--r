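#' Synthetic knee-contact phantom specification
#'
#' Describes an analytic knee-contact phantom: a flat elliptical tibial
#' plateau in the axial plane carrying a tibial cartilage layer, a femoral
#' cartilage layer, and two elliptical contact patches (medial and lateral)
#' where the cartilage surfaces meet with zero separation. Outside the
#' patches the femoral surface sits `gap_mm` above the tibial surface.
#' Because every structure is an extruded ellipse, contact areas, centroids
#' and the plateau cross-section all have closed-form ground truth,
#' against which the voxel-based measurements can be validated.
#'
#' The default geometry reproduces the scale of in vivo standing-knee
#' measurements: medial patch `pi * 12^2 = 452.4` mm2 and lateral patch
#' `pi * 10^2 = 314.2` mm2 on a plateau of maximum axial cross-section
#' `pi * 35 * 30 = 3299` mm2 (normalized contact 13.7% and 9.5%), sampled
#' at the anisotropic spacing of an upright open-MRI DESS acquisition
#' (0.859 x 0.859 x 2.5 mm).
#'
#' @param grid_shape Length-3 positive integers: voxels along x (ML),
#'   y (AP), z (SI/axial).
#' @param voxel_spacing Length-3 positive spacing (mm).
#' @param plateau_semi_axes Semi-axes (mm) of the plateau ellipse along the
#'   ML and AP directions.
#' @param plateau_thickness Thickness (mm) of the plateau slab.
#' @param cartilage_thickness Thickness (mm) of each cartilage layer.
#' @param gap_mm Tibio-femoral surface separation (mm) outside the patches.
#' @param patches Named list with elements `medial` and `lateral`, each a
#'   [patch_params()].
#' @param pose A planar [rigid_transform()] applied to the whole phantom
#'   (plateau, patches and landmarks); models session-to-session posture.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [perturb_session()]
#' @export
phantom_spec <- function(grid_shape = c(104L, 104L, 16L),
                         voxel_spacing = c(0.859, 0.859, 2.5),
                         plateau_semi_axes = c(35, 30),
                         plateau_thickness = 5,
                         cartilage_thickness = 2.5,
                         gap_mm = 7.5,
                         patches = list(
                           medial = patch_params(c(-0.5, 0), c(12, 12)),
                           lateral = patch_params(c(0.55, 0), c(10, 10))),
                         pose = rigid_transform()) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_spacing = as.numeric(voxel_spacing),
                         plateau_semi_axes = as.numeric(plateau_semi_axes),
                         plateau_thickness = as.numeric(plateau_thickness),
                         cartilage_thickness = as.numeric(cartilage_thickness),
                         gap_mm = as.numeric(gap_mm),
                         patches = patches,
                         pose = pose),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Contact patch parameters
#'
#' @param center_frac Length-2 patch centre as a fraction of the plateau
#'   semi-axes (ML, AP); e.g. `c(-0.5, 0)` puts the centre halfway out on
#'   the medial side.
#' @param semi_axes Length-2 patch ellipse semi-axes (mm). Zero produces an
#'   empty patch.
#' @return A list of class `patch_params`.
#' @export
patch_params <- function(center_frac, semi_axes) {
  center_frac <- as.numeric(center_frac)
  semi_axes <- as.numeric(semi_axes)
  if (length(center_frac) != 2L || length(semi_axes) != 2L)
    stop("center_frac and semi_axes must each have length 2")
  if (any(semi_axes < 0) || anyNA(semi_axes))
    stop("patch semi-axes must be non-negative")
  structure(list(center_frac = center_frac, semi_axes = semi_axes),
            class = "patch_params")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 4L))
      stop("grid_shape must be 3 integers >= 4")
    if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
    if (any(plateau_semi_axes <= 0)) stop("plateau semi-axes must be positive")
    if (plateau_thickness <= 0 || cartilage_thickness <= 0 || gap_mm <= 0)
      stop("thicknesses and gap must be positive")
    if (!identical(sort(names(patches)), c("lateral", "medial")))
      stop("patches must be a named list with elements 'medial' and 'lateral'")
  })
  a <- spec$plateau_semi_axes[1]; b <- spec$plateau_semi_axes[2]
  ang <- seq(0, 2 * pi, length.out = 257L)[-257L]
  for (nm in names(spec$patches)) {
    p <- spec$patches[[nm]]
    if (all(p$semi_axes == 0)) next
    cx <- p$center_frac[1] * a; cy <- p$center_frac[2] * b
    bx <- cx + p$semi_axes[1] * cos(ang); by <- cy + p$semi_axes[2] * sin(ang)
    if (any((bx / a)^2 + (by / b)^2 >= 1))
      stop(sprintf("geometry error: %s patch ellipse is not strictly inside the plateau", nm))
  }
  # posed plateau must fit in the grid, with all structural z-intervals sampled
  half <- (spec$grid_shape - 1) / 2 * spec$voxel_spacing
  bx <- a * cos(ang); by <- b * sin(ang)
  posed <- apply_transform(spec$pose, cbind(bx, by, 0))
  if (any(abs(posed[, 1]) > half[1]) || any(abs(posed[, 2]) > half[2]))
    stop("geometry error: plateau (after pose) does not fit inside the voxel grid")
  zc <- phantom_slice_centers(spec)
  iv <- phantom_z_intervals(spec)
  for (nm in names(iv)) {
    if (!any(zc > iv[[nm]][1] & zc <= iv[[nm]][2]))
      stop(sprintf("grid too coarse along z: no slice centre falls in the %s layer", nm))
  }
  if (min(zc) > -spec$plateau_thickness || max(zc) < iv$femoral_free[2])
    stop("geometry error: phantom does not fit inside the grid along z")
  invisible(spec)
}

# z-intervals (half-open (lo, hi]) of the structural layers; the plateau top
# surface is the z = 0 plane.
phantom_z_intervals <- function(spec) {
  t <- spec$cartilage_thickness
  list(plateau = c(-spec$plateau_thickness - 1e-9, 0),
       tibial_cartilage = c(0, t),
       femoral_contact = c(t, 2 * t),
       femoral_free = c(t + spec$gap_mm, t + spec$gap_mm + t))
}

phantom_grid_origin <- function(spec)
  -(spec$grid_shape - 1) / 2 * spec$voxel_spacing

phantom_slice_centers <- function(spec) {
  o <- phantom_grid_origin(spec)
  o[3] + (seq_len(spec$grid_shape[3]) - 1) * spec$voxel_spacing[3]
}

# In-plane membership masks (nx x ny logical) for the posed plateau and
# patch ellipses, evaluated at the voxel-centre grid.
phantom_plane_masks <- function(spec) {
  o <- phantom_grid_origin(spec)
  x <- o[1] + (seq_len(spec$grid_shape[1]) - 1) * spec$voxel_spacing[1]
  y <- o[2] + (seq_len(spec$grid_shape[2]) - 1) * spec$voxel_spacing[2]
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  # map grid points back to the canonical (unposed) frame
  r <- spec$pose$rotation; tr <- spec$pose$translation
  qx <- r[1, 1] * (X - tr[1]) + r[2, 1] * (Y - tr[2])
  qy <- r[1, 2] * (X - tr[1]) + r[2, 2] * (Y - tr[2])
  a <- spec$plateau_semi_axes[1]; b <- spec$plateau_semi_axes[2]
  masks <- list(plateau = (qx / a)^2 + (qy / b)^2 <= 1)
  for (nm in names(spec$patches)) {
    p <- spec$patches[[nm]]
    if (any(p$semi_axes == 0)) {
      masks[[nm]] <- matrix(FALSE, nrow(qx), ncol(qx))
    } else {
      masks[[nm]] <- ((qx - p$center_frac[1] * a) / p$semi_axes[1])^2 +
        ((qy - p$center_frac[2] * b) / p$semi_axes[2])^2 <= 1
    }
  }
  masks
}

#' Generate a synthetic knee-contact phantom
#'
#' Voxelizes a [phantom_spec()] into a [label_volume()] together with its
#' analytic ground truth and a consistent anatomical landmark set. The
#' construction is fully deterministic: identical `(spec, seed)` give
#' bit-identical output. The voxelized area of each contact patch differs
#' from the analytic ellipse area by at most the patch perimeter times the
#' in-plane voxel diagonal (first-order voxelization error).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer recorded with the phantom (the geometry itself is
#'   deterministic; randomness enters only through the noise models).
#' @return A list of class `phantom` with elements `volume`
#'   ([label_volume()]), `truth` (per-compartment analytic `area_mm2` and
#'   `centroid_mm`, plus `plateau_area_mm2`), `landmarks`
#'   ([landmark_set()]) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' ph$truth$medial$area_mm2   # pi * 12^2
#' @export
generate_phantom <- function(spec, seed = 0L) {
  validate_phantom_spec(spec)
  dict <- default_label_dictionary()
  lab <- array(0L, dim = spec$grid_shape)
  pm <- phantom_plane_masks(spec)
  iv <- phantom_z_intervals(spec)
  zc <- phantom_slice_centers(spec)
  in_iv <- function(z, i) z > i[1] & z <= i[2]
  patch_union <- pm$medial | pm$lateral
  femoral_free_fp <- pm$plateau & !patch_union
  for (k in seq_along(zc)) {
    slab <- lab[, , k]
    if (in_iv(zc[k], iv$plateau)) slab[pm$plateau] <- dict[["tibial_plateau"]]
    if (in_iv(zc[k], iv$tibial_cartilage)) slab[pm$plateau] <- dict[["tibial_cartilage"]]
    if (in_iv(zc[k], iv$femoral_contact)) slab[patch_union] <- dict[["femoral_cartilage"]]
    if (in_iv(zc[k], iv$femoral_free)) slab[femoral_free_fp] <- dict[["femoral_cartilage"]]
    lab[, , k] <- slab
  }
  # contact labels live on the topmost tibial-cartilage slice inside each patch
  k_top <- max(which(in_iv(zc, iv$tibial_cartilage)))
  slab <- lab[, , k_top]
  slab[pm$medial] <- dict[["contact_medial"]]
  slab[pm$lateral] <- dict[["contact_lateral"]]
  lab[, , k_top] <- slab

  vol <- label_volume(lab, spec$voxel_spacing, phantom_grid_origin(spec))
  a <- spec$plateau_semi_axes[1]; b <- spec$plateau_semi_axes[2]
  truth <- structure(list(plateau_area_mm2 = pi * a * b), class = "phantom_truth")
  for (nm in c("medial", "lateral")) {
    p <- spec$patches[[nm]]
    cen <- apply_transform(spec$pose,
                           c(p$center_frac[1] * a, p$center_frac[2] * b, zc[k_top]))
    truth[[nm]] <- list(area_mm2 = pi * p$semi_axes[1] * p$semi_axes[2],
                        centroid_mm = cen)
  }
  lm <- landmark_set(
    medial_edge = apply_transform(spec$pose, c(-a, 0, 0)),
    lateral_edge = apply_transform(spec$pose, c(a, 0, 0)),
    plateau_center = apply_transform(spec$pose, c(0, 0, 0)),
    shaft_distal = apply_transform(spec$pose, c(0, 0, -60)))
  structure(list(volume = vol, truth = truth, landmarks = lm,
                 spec = spec, seed = as.integer(seed)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Synthetic knee-contact phantom\n")
  cat(sprintf("  analytic areas: medial %.1f mm2, lateral %.1f mm2, plateau %.1f mm2\n",
              x$truth$medial$area_mm2, x$truth$lateral$area_mm2,
              x$truth$plateau_area_mm2))
  print(x$volume)
  invisible(x)
}

#' Rater segmentation-noise model
#'
#' Models the variability of manual contact tracing: each voxel on the
#' in-plane contour of a contact patch may be toggled. `boundary_flip_prob`
#' controls the overall magnitude; `erosion_dilation_bias` in `[-1, 1]`
#' shifts the balance toward under- (-1) or over- (+1) segmentation. Add and
#' remove probabilities are balanced against the contour sizes so that a
#' bias of 0 gives zero expected signed area change.
#'
#' @param boundary_flip_prob Probability in `[0, 1]` that a contour voxel is
#'   toggled.
#' @param erosion_dilation_bias Signed tendency in `[-1, 1]`.
#' @param seed Integer seed; perturbation is deterministic given the seed
#'   (streams are split per compartment).
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(boundary_flip_prob, erosion_dilation_bias = 0, seed = 1L) {
  if (boundary_flip_prob < 0 || boundary_flip_prob > 1)
    stop("boundary_flip_prob must be in [0, 1]")
  if (erosion_dilation_bias < -1 || erosion_dilation_bias > 1)
    stop("erosion_dilation_bias must be in [-1, 1]")
  structure(list(boundary_flip_prob = boundary_flip_prob,
                 erosion_dilation_bias = erosion_dilation_bias,
                 seed = as.integer(seed)),
            class = "rater_model")
}

# 4-connected in-plane shifts of a 2-D logical mask (zero-padded).
shift2d <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)); sj <- seq_len(ncol(m))
  ti <- si + di; tj <- sj + dj
  ok_i <- ti >= 1L & ti <= nrow(m); ok_j <- tj >= 1L & tj <= ncol(m)
  out[ti[ok_i], tj[ok_j]] <- m[si[ok_i], sj[ok_j]]
  out
}

neighbor_any <- function(m)
  shift2d(m, 1L, 0L) | shift2d(m, -1L, 0L) | shift2d(m, 0L, 1L) | shift2d(m, 0L, -1L)

neighbor_all <- function(m)
  shift2d(m, 1L, 0L) & shift2d(m, -1L, 0L) & shift2d(m, 0L, 1L) & shift2d(m, 0L, -1L)

#' Apply rater boundary noise to contact labels
#'
#' Perturbs the in-plane contour of each contact patch: contour voxels of
#' the mask may be removed (relabelled as plain tibial cartilage) and
#' tibial-cartilage voxels 4-adjacent to the mask may be added, emulating a
#' rater's slice-by-slice tracing variability. Only voxels on the mask
#' boundary change; an empty mask is returned unchanged; the expected
#' absolute area change grows monotonically with `boundary_flip_prob`.
#'
#' @param vol A [label_volume()] containing contact labels.
#' @param model A [rater_model()].
#' @return A perturbed [label_volume()].
#' @export
perturb_rater <- function(vol, model) {
  stopifnot(inherits(vol, "label_volume"), inherits(model, "rater_model"))
  dict <- vol$dictionary
  lab <- vol$labels
  set.seed(model$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  p <- model$boundary_flip_prob
  bias <- model$erosion_dilation_bias
  comps <- c(contact_medial = 1L, contact_lateral = 2L)
  for (nm in names(comps)) {
    code <- dict[[nm]]
    set.seed(sub_seeds[comps[[nm]]])
    ks <- which(apply(lab == code, 3L, any))
    for (k in ks) {
      slab <- lab[, , k]
      m <- slab == code
      inner <- m & !neighbor_all(m)
      outer <- !m & neighbor_any(m) & slab == dict[["tibial_cartilage"]]
      n_in <- sum(inner); n_out <- sum(outer)
      if (n_in == 0L && n_out == 0L) next
      p_add <- p * (1 + bias) / 2
      p_rm <- if (n_in > 0L) min(1, p * (1 - bias) / 2 * n_out / n_in) else 0
      if (n_out > 0L) {
        sel <- which(outer)[stats::runif(n_out) < p_add]
        slab[sel] <- code
      }
      if (n_in > 0L) {
        sel <- which(inner)[stats::runif(n_in) < p_rm]
        slab[sel] <- dict[["tibial_cartilage"]]
      }
      lab[, , k] <- slab
    }
  }
  label_volume(lab, vol$spacing, vol$origin, dict)
}

#' Session (test-retest) noise model
#'
#' Models posture and loading differences between repeat scanning sessions
#' as (i) a multiplicative jitter on the contact-patch semi-axes (cartilage
#' load response) and (ii) a small in-plane rigid pose change of the whole
#' knee. Jitter is applied to the phantom specification before
#' voxelization, so the analytic ground truth of the jittered phantom
#' remains exact.
#'
#' @param scale_center Centre of the patch semi-axis scale factor
#'   (1 = no systematic change).
#' @param scale_sdlog SD of the log scale factor (lognormal jitter, so
#'   factors are always positive); one factor per compartment.
#' @param rot_sd_deg SD (degrees) of the axial-plane rotation.
#' @param trans_sd_mm SD (mm) of each in-plane translation component.
#' @param seed Integer seed.
#' @return An object of class `session_model`.
#' @export
session_model <- function(scale_center = 1, scale_sdlog = 0,
                          rot_sd_deg = 0, trans_sd_mm = 0, seed = 1L) {
  if (scale_center <= 0 || scale_sdlog < 0 || rot_sd_deg < 0 || trans_sd_mm < 0)
    stop("scale_center must be positive and SDs non-negative")
  structure(list(scale_center = scale_center, scale_sdlog = scale_sdlog,
                 rot_sd_deg = rot_sd_deg, trans_sd_mm = trans_sd_mm,
                 seed = as.integer(seed)),
            class = "session_model")
}

# Normal draw truncated at +/- 2 SD: keeps sampled geometry jitter within a
# range that cannot push a valid spec into an invalid one.
rnorm_trunc2 <- function(n, mean = 0, sd = 1) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, mean - 2 * sd), mean + 2 * sd)
}

#' Apply session noise to a phantom specification
#'
#' Returns a new, valid [phantom_spec()] whose patch semi-axes are scaled by
#' sampled jitter factors and whose pose is composed with a sampled
#' in-plane rigid motion. Jitter draws are truncated at two standard
#' deviations so that realistic noise levels cannot produce degenerate
#' geometry. With zero jitter the spec is returned unchanged.
#'
#' @param spec A [phantom_spec()].
#' @param model A [session_model()].
#' @return A [phantom_spec()].
#' @export
perturb_session <- function(spec, model) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "session_model"))
  set.seed(model$seed)
  fac <- exp(rnorm_trunc2(2L, log(model$scale_center), model$scale_sdlog))
  theta <- rnorm_trunc2(1L, 0, model$rot_sd_deg)
  tr <- rnorm_trunc2(2L, 0, model$trans_sd_mm)
  out <- spec
  for (i in seq_along(c("medial", "lateral"))) {
    nm <- c("medial", "lateral")[i]
    ax <- spec$patches[[nm]]$semi_axes * fac[i]
    if (any(ax < 0) || anyNA(ax)) stop("session jitter produced invalid semi-axes")
    out$patches[[nm]]$semi_axes <- ax
  }
  jitter_pose <- planar_pose(theta, tr[1], tr[2])
  if (!is_identity_transform(jitter_pose))
    out$pose <- compose_transforms(jitter_pose, spec$pose)
  validate_phantom_spec(out)
  out
}

#' Simulate a subjects-by-measurements ratings table
#'
#' Variance-component generator for validating the reliability estimators:
#' cell `(i, j)` is `subject_effect_i + rater_offset_j + noise_ij` with
#' `subject_effect ~ N(0, subject_sd^2)` and `noise ~ N(0, error_sd^2)`.
#' The population consistency ICC of such a table is
#' `subject_sd^2 / (subject_sd^2 + error_sd^2)` (rater offsets are fixed
#' column effects and do not enter).
#'
#' @param n_subjects Number of subjects (rows), at least 2.
#' @param k_measurements Number of repeated measurements (columns), at
#'   least 2.
#' @param subject_sd,error_sd Non-negative standard deviations.
#' @param rater_offsets Fixed per-measurement offsets, length
#'   `k_measurements`.
#' @param seed Integer seed.
#' @return A [ratings_table()].
#' @examples
#' rt <- simulate_ratings(50, 2, subject_sd = 3, error_sd = 1, seed = 1)
#' icc31(rt)   # true ICC is 9 / 10
#' @export
simulate_ratings <- function(n_subjects, k_measurements, subject_sd, error_sd,
                             rater_offsets = rep(0, k_measurements), seed = 1L) {
  if (n_subjects < 2L || k_measurements < 2L)
    stop("need at least 2 subjects and 2 measurements")
  if (subject_sd < 0 || error_sd < 0) stop("standard deviations must be non-negative")
  if (length(rater_offsets) != k_measurements)
    stop("rater_offsets must have length k_measurements")
  set.seed(as.integer(seed))
  subj <- stats::rnorm(n_subjects, 0, subject_sd)
  noise <- matrix(stats::rnorm(n_subjects * k_measurements, 0, error_sd),
                  n_subjects, k_measurements)
  m <- subj + noise + matrix(rater_offsets, n_subjects, k_measurements, byrow = TRUE)
  ratings_table(m, design = "inter_rater", metric_name = "simulated", units = "a.u.")
}
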