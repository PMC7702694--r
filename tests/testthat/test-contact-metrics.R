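spacing_uo <- c(0.859, 0.859, 2.5)

test_that("contact area is voxel count times in-plane dimensions", {
  m <- array(FALSE, c(20, 20, 4))
  set.seed(1)
  m[sample(length(m), 100)] <- TRUE
  expect_equal(contact_area(m, spacing_uo), 100 * 0.859^2)  # 73.7881 mm2
  expect_equal(contact_area(m, spacing_uo), 73.7881)
  expect_equal(contact_area(array(FALSE, c(4, 4, 2)), spacing_uo), 0)

  # independent of slice thickness
  expect_equal(contact_area(m, c(0.859, 0.859, 99)), contact_area(m, spacing_uo))

  # additive over disjoint masks
  a <- array(FALSE, c(10, 10, 2)); a[1:3, 1:3, 1] <- TRUE
  b <- array(FALSE, c(10, 10, 2)); b[7:9, 7:9, 2] <- TRUE
  expect_equal(contact_area(a | b, spacing_uo),
               contact_area(a, spacing_uo) + contact_area(b, spacing_uo))

  # invariant under in-plane 90-degree rotation and translation
  r <- aperm(m[20:1, , , drop = FALSE], c(2, 1, 3))
  expect_equal(contact_area(r, spacing_uo), contact_area(m, spacing_uo))
  shifted <- array(FALSE, c(22, 22, 4)); shifted[2:21, 2:21, ] <- m
  expect_equal(contact_area(shifted, spacing_uo), contact_area(m, spacing_uo))

  # projected variant counts each in-plane column once
  stack <- array(FALSE, c(5, 5, 3)); stack[2, 2, ] <- TRUE
  expect_equal(contact_area(stack, c(1, 1, 1)), 3)
  expect_equal(contact_area(stack, c(1, 1, 1), projected = TRUE), 1)
})

test_that("plateau maximum axial cross-section", {
  m <- array(FALSE, c(40, 40, 5))
  m[cbind(rep(1:25, 40), rep(1:40, each = 25), 3)] <- TRUE
  expect_equal(plateau_max_axial_area(m, c(1, 1, 2)), 1000)
  # identical mask on every slice equals the single-slice area
  all_slices <- array(rep(m[, , 3], 5), dim = dim(m))
  expect_equal(plateau_max_axial_area(all_slices, c(1, 1, 2)), 1000)
  expect_error(plateau_max_axial_area(array(FALSE, c(4, 4, 2)), c(1, 1, 1)),
               "empty")

  # voxelized elliptical plateau approaches pi * a * b
  spec <- small_spec()
  ph <- generate_phantom(spec)
  measured <- plateau_max_axial_area(label_mask(ph$volume, "tibial_plateau"),
                                     ph$volume$spacing)
  expect_lt(abs(measured - pi * 24 * 20),
            voxelization_bound(c(24, 20), ph$volume$spacing))
})

test_that("area normalization to the plateau cross-section", {
  expect_equal(normalize_area(500, 500), 100)
  expect_equal(normalize_area(0, 500), 0)
  # the in vivo pairing: 452 mm2 on a 3299 mm2 plateau is 13.7%
  expect_equal(round(normalize_area(452, 3299), 1), 13.7)
  expect_error(normalize_area(10, 0), "positive")
})

test_that("mask centroid: world-coordinate mean with explicit empty flag", {
  m <- array(FALSE, c(6, 6, 6))
  m[3, 4, 5] <- TRUE  # 0-based index (2, 3, 4)
  cen <- mask_centroid(m, c(1, 1, 1))
  expect_equal(unclass(cen), c(2, 3, 4), ignore_attr = TRUE)
  expect_true(attr(cen, "defined"))

  # symmetric block: geometric centre, scaled by spacing and shifted by origin
  m2 <- array(FALSE, c(10, 10, 4)); m2[3:6, 2:9, 1:2] <- TRUE
  cen2 <- mask_centroid(m2, c(0.5, 2, 2.5), origin = c(10, -5, 0))
  expect_equal(unclass(cen2), c(10 + 3.5 * 0.5, -5 + 4.5 * 2, 0.5 * 2.5),
               ignore_attr = TRUE)

  # two voxels at world x = 0 and x = 2: midpoint 1
  m3 <- array(FALSE, c(3, 1, 1)); m3[c(1, 3), 1, 1] <- TRUE
  expect_equal(mask_centroid(m3, c(1, 1, 1))[1], 1, ignore_attr = TRUE)

  empty <- mask_centroid(array(FALSE, c(2, 2, 2)), c(1, 1, 1))
  expect_false(attr(empty, "defined"))
  expect_true(all(is.na(empty)))
})

test_that("compartment split partitions by the frame's ML coordinate", {
  lm <- landmark_set(medial_edge = c(-24, 0, 0), lateral_edge = c(24, 0, 0),
                     plateau_center = c(0.3, 0, 0), shaft_distal = c(0.3, 0, -60))
  frame <- build_tibial_frame(lm)
  m <- array(FALSE, c(20, 20, 3))
  set.seed(2)
  m[sample(length(m), 60)] <- TRUE
  origin <- c(-9.5, -9.5, 0)
  sp <- split_compartments(m, frame, c(1, 1, 1), origin)
  expect_equal(sum(sp$medial & sp$lateral), 0)
  expect_identical(sp$medial | sp$lateral, m)

  # mirroring the mask across the frame's sagittal plane swaps the outputs
  mm <- m[20:1, , , drop = FALSE]
  origin_m <- c(-9.5 + 2 * 0.3, -9.5, 0)  # mirror about x = 0.3
  spm <- split_compartments(mm, frame, c(1, 1, 1), origin_m)
  expect_equal(sum(spm$medial), sum(sp$lateral))
  expect_equal(sum(spm$lateral), sum(sp$medial))

  # all voxels on one side
  left <- array(FALSE, c(20, 20, 3)); left[1:5, , 2] <- TRUE
  spl <- split_compartments(left, frame, c(1, 1, 1), origin)
  expect_equal(sum(spl$lateral), 0)
  expect_equal(sum(spl$medial), sum(left))

  # phantom contact voxels split into the generator's own compartments
  ph <- generate_phantom(small_spec())
  cmask <- label_mask(ph$volume, c("contact_medial", "contact_lateral"))
  frame_ph <- build_tibial_frame(ph$landmarks)
  sp_ph <- split_compartments(cmask, frame_ph, ph$volume$spacing, ph$volume$origin)
  expect_identical(sp_ph$medial, label_mask(ph$volume, "contact_medial"))
  expect_identical(sp_ph$lateral, label_mask(ph$volume, "contact_lateral"))
})

test_that("contact extraction matches the brute-force column-scan oracle", {
  dict <- default_label_dictionary()
  set.seed(42)
  for (rep in 1:5) {
    lab <- array(0L, c(8, 8, 10))
    # random tibial columns with random heights, femoral voxels above
    for (i in 1:8) for (j in 1:8) {
      if (stats::runif(1) < 0.7) {
        ht <- sample(2:4, 1)
        lab[i, j, 1:ht] <- dict[["tibial_cartilage"]]
        if (stats::runif(1) < 0.8) {
          fk <- min(10, ht + sample(1:4, 1))
          lab[i, j, fk:min(10, fk + 1)] <- dict[["femoral_cartilage"]]
        }
      }
    }
    vol <- label_volume(lab, c(1, 1, 1.7))
    tol <- stats::runif(1, 0, 3)
    out <- extract_contact(vol, gap_tolerance_mm = tol)
    got2d <- apply(label_mask(out, c("contact_medial", "contact_lateral")),
                   c(1, 2), any)
    expect_identical(got2d, bf_contact_columns(lab, dict, 1.7, tol))
  }
})

test_that("contact extraction respects separation and recovers phantom patches", {
  dict <- default_label_dictionary()
  # everywhere separated by more than the tolerance: no contact
  lab <- array(0L, c(6, 6, 8))
  lab[, , 2] <- dict[["tibial_cartilage"]]
  lab[, , 7] <- dict[["femoral_cartilage"]]  # 4 empty voxels * 1 mm = 4 mm gap
  vol <- label_volume(lab, c(1, 1, 1))
  out <- extract_contact(vol, gap_tolerance_mm = 2)
  expect_equal(sum(label_mask(out, c("contact_medial", "contact_lateral"))), 0)

  # overlap in a column is contact even at zero tolerance
  lab[3, 3, 2] <- dict[["femoral_cartilage"]]
  lab[3, 3, 1] <- dict[["tibial_cartilage"]]
  vol <- label_volume(lab, c(1, 1, 1))
  out <- extract_contact(vol, gap_tolerance_mm = 0)
  expect_equal(sum(label_mask(out, c("contact_medial", "contact_lateral"))), 1)

  expect_error(extract_contact(label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "missing label")

  # rederiving contact on a phantom reproduces the generator's patch areas
  ph <- generate_phantom(small_spec())
  frame <- build_tibial_frame(ph$landmarks)
  red <- extract_contact(ph$volume, frame = frame)
  for (nm in c("contact_medial", "contact_lateral"))
    expect_identical(label_mask(red, nm), label_mask(ph$volume, nm))
})

test_that("measure_contact reports consistent percent and absolute values", {
  ph <- generate_phantom(small_spec())
  mm <- measure_contact(ph$volume, ph$landmarks)
  expect_setequal(mm$compartment, c("medial", "lateral"))
  expect_equal(mm$area_pct, 100 * mm$area_mm2 / mm$plateau_area_mm2)
  expect_true(all(mm$centroid_defined))
  # medial centroid on the medial half, lateral on the lateral half
  expect_lt(mm$centroid_ml_pct[mm$compartment == "medial"], 50)
  expect_gt(mm$centroid_ml_pct[mm$compartment == "lateral"], 50)

  # empty contact is flagged, not silently zero
  spec0 <- small_spec(patches = list(medial = patch_params(c(-0.5, 0), c(0, 0)),
                                     lateral = patch_params(c(0.55, 0), c(6, 6))))
  ph0 <- generate_phantom(spec0)
  mm0 <- measure_contact(ph0$volume, ph0$landmarks)
  med <- mm0[mm0$compartment == "medial", ]
  expect_false(med$centroid_defined)
  expect_true(is.na(med$centroid_ml_pct))
  expect_equal(med$area_mm2, 0)
})
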