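test_that("phantom generation is deterministic and carries analytic truth", {
  spec <- small_spec()
  ph1 <- generate_phantom(spec, seed = 3)
  ph2 <- generate_phantom(spec, seed = 3)
  expect_identical(ph1$volume$labels, ph2$volume$labels)
  expect_identical(ph1$truth, ph2$truth)

  expect_equal(ph1$truth$medial$area_mm2, pi * 8 * 8)
  expect_equal(ph1$truth$lateral$area_mm2, pi * 7 * 7)
  expect_equal(ph1$truth$plateau_area_mm2, pi * 24 * 20)
  # centroid lies at the (unposed) patch centre in plane
  expect_equal(ph1$truth$medial$centroid_mm[1:2], c(-0.5 * 24, 0))
})

test_that("default phantom reproduces the in vivo contact scale", {
  ph <- generate_phantom(phantom_spec())
  expect_equal(ph$truth$medial$area_mm2, pi * 144)        # ~452 mm2
  expect_equal(ph$truth$lateral$area_mm2, pi * 100)       # ~314 mm2
  mm <- measure_contact(ph$volume, ph$landmarks)
  med <- mm[mm$compartment == "medial", ]
  expect_lt(abs(med$area_pct - 13.7), 1)                   # normalized scale
})

test_that("voxelized patch areas respect the perimeter x diagonal bound", {
  cases <- list(list(sp = c(0.859, 0.859, 2.5), gs = c(76L, 76L, 12L)),
                list(sp = c(0.4, 0.4, 2.5), gs = c(140L, 124L, 12L)))
  for (case in cases) {
    sp <- case$sp
    spec <- small_spec(voxel_spacing = sp, grid_shape = case$gs)
    ph <- generate_phantom(spec)
    vol <- ph$volume
    for (comp in c("medial", "lateral")) {
      measured <- contact_area(label_mask(vol, paste0("contact_", comp)), sp)
      bound <- voxelization_bound(spec$patches[[comp]]$semi_axes, sp)
      expect_lt(abs(measured - ph$truth[[comp]]$area_mm2), bound)
    }
  }
})

test_that("zero-size patches give empty contact and zero truth", {
  spec <- small_spec(patches = list(medial = patch_params(c(-0.5, 0), c(0, 0)),
                                    lateral = patch_params(c(0.55, 0), c(0, 0))))
  ph <- generate_phantom(spec)
  expect_equal(sum(label_mask(ph$volume, c("contact_medial", "contact_lateral"))), 0)
  expect_equal(ph$truth$medial$area_mm2, 0)
})

test_that("invalid geometry is rejected", {
  expect_error(small_spec(patches = list(
    medial = patch_params(c(-0.5, 0), c(15, 15)),    # pokes out of the plateau
    lateral = patch_params(c(0.55, 0), c(7, 7)))), "geometry error")
  expect_error(phantom_spec(grid_shape = c(16, 16, 12)), "geometry error|grid")
  expect_error(phantom_spec(voxel_spacing = c(0.859, 0.859, -1)), "positive")
})

test_that("rater noise: zero probability is the identity, same seed reproduces", {
  ph <- generate_phantom(small_spec())
  expect_identical(perturb_rater(ph$volume, rater_model(0, seed = 5))$labels,
                   ph$volume$labels)
  a <- perturb_rater(ph$volume, rater_model(0.3, seed = 7))
  b <- perturb_rater(ph$volume, rater_model(0.3, seed = 7))
  d <- perturb_rater(ph$volume, rater_model(0.3, seed = 8))
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, d$labels))
})

test_that("full dilation bias matches the brute-force morphological oracle", {
  ph <- generate_phantom(small_spec())
  out <- perturb_rater(ph$volume, rater_model(1, erosion_dilation_bias = 1, seed = 1))
  dict <- ph$volume$dictionary
  for (nm in c("contact_medial", "contact_lateral")) {
    code <- dict[[nm]]
    ks <- which(apply(ph$volume$labels == code, 3, any))
    for (k in ks) {
      expected <- bf_dilate_slice(ph$volume$labels[, , k], code,
                                  dict[["tibial_cartilage"]])
      expect_identical(out$labels[, , k] == code, expected == code)
    }
    expect_gt(sum(out$labels == code), sum(ph$volume$labels == code))
  }
})

test_that("rater noise only toggles voxels on the in-plane mask boundary", {
  ph <- generate_phantom(small_spec())
  spacing <- ph$volume$spacing
  for (seed in 1:5) {
    out <- perturb_rater(ph$volume, rater_model(0.2, seed = seed))
    changed <- which(out$labels != ph$volume$labels, arr.ind = TRUE)
    for (nm in c("contact_medial", "contact_lateral")) {
      m <- label_mask(ph$volume, nm)
      n_boundary <- sum(m)  # mask is one voxel thick: every voxel near contour
      da <- contact_area(label_mask(out, nm), spacing) - contact_area(m, spacing)
      expect_lte(abs(da), n_boundary * spacing[1] * spacing[2])
    }
    # every changed voxel is 4-adjacent (in plane) to the original contact mask
    m_any <- label_mask(ph$volume, c("contact_medial", "contact_lateral"))
    for (r in seq_len(nrow(changed))) {
      i <- changed[r, 1]; j <- changed[r, 2]; k <- changed[r, 3]
      nbhd <- m_any[max(1, i - 1):min(dim(m_any)[1], i + 1),
                    max(1, j - 1):min(dim(m_any)[2], j + 1), k]
      expect_true(any(nbhd))
    }
  }
})

test_that("unbiased rater noise has zero mean signed area change", {
  ph <- generate_phantom(small_spec())
  m0 <- contact_area(label_mask(ph$volume, "contact_medial"), ph$volume$spacing)
  deltas <- vapply(1:120, function(s) {
    out <- perturb_rater(ph$volume, rater_model(0.3, 0, seed = s))
    contact_area(label_mask(out, "contact_medial"), out$spacing) - m0
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 2 * se)
})

test_that("expected rater-noise magnitude grows with the flip probability", {
  ph <- generate_phantom(small_spec())
  m0 <- contact_area(label_mask(ph$volume, "contact_medial"), ph$volume$spacing)
  mag <- function(p) mean(vapply(1:40, function(s) {
    out <- perturb_rater(ph$volume, rater_model(p, 0, seed = s))
    abs(contact_area(label_mask(out, "contact_medial"), out$spacing) - m0)
  }, numeric(1)))
  expect_lt(mag(0.05), mag(0.4))
})

test_that("session jitter: identity, quadratic area scaling, translation equivariance", {
  spec <- small_spec()
  expect_equal(perturb_session(spec, session_model(seed = 2)), spec)

  scaled <- perturb_session(spec, session_model(scale_center = 1.1, seed = 2))
  expect_equal(scaled$patches$medial$semi_axes, spec$patches$medial$semi_axes * 1.1)
  expect_equal(generate_phantom(scaled)$truth$medial$area_mm2,
               generate_phantom(spec)$truth$medial$area_mm2 * 1.21)

  shifted <- spec
  shifted$pose <- planar_pose(0, 2, -1.5)
  t0 <- generate_phantom(spec)$truth
  t1 <- generate_phantom(shifted)$truth
  expect_equal(t1$medial$centroid_mm - t0$medial$centroid_mm, c(2, -1.5, 0))
})

test_that("simulated ratings recover their variance components", {
  # zero error: perfect agreement up to fixed offsets
  rt <- simulate_ratings(20, 3, subject_sd = 2, error_sd = 0,
                         rater_offsets = c(0, 5, -1), seed = 1)
  expect_equal(max(abs((rt$matrix[, 2] - rt$matrix[, 1]) - 5)), 0, tolerance = 1e-12)
  fit <- suppressWarnings(icc31(rt))
  expect_equal(fit$icc, 1, tolerance = 1e-6)

  # subject_sd 3, error_sd 1 -> true ICC 0.9; large-n estimate is close
  rt <- simulate_ratings(1000, 2, subject_sd = 3, error_sd = 1, seed = 11)
  comp <- anova_components(rt)
  expect_equal(icc31(rt)$icc, 0.9, tolerance = 0.02)
  expect_equal(comp$EMS, 1, tolerance = 0.1)           # error variance
  expect_equal((comp$BMS - comp$EMS) / 2, 9, tolerance = 1)  # subject variance

  expect_error(simulate_ratings(1, 2, 1, 1), "at least 2")
  expect_error(simulate_ratings(5, 2, 1, 1, rater_offsets = c(0, 1, 2)), "length")
})
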