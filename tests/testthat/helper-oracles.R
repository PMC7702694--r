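# Small, fast phantom geometry used across tests.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    grid_shape = c(76L, 76L, 12L),
    plateau_semi_axes = c(24, 20),
    patches = list(medial = patch_params(c(-0.5, 0), c(8, 8)),
                   lateral = patch_params(c(0.55, 0), c(7, 7))))
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Ramanujan approximation of an ellipse perimeter (exact for circles),
# used only to evaluate the voxelization error bound.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

voxelization_bound <- function(semi_axes, spacing)
  ellipse_perimeter(semi_axes[1], semi_axes[2]) * sqrt(sum(spacing[1:2]^2))

# Brute-force two-way ANOVA decomposition by explicit double loops,
# independent of the package's matrix-algebra path.
bf_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_b <- 0; ss_j <- 0; ss_e <- 0
  row_means <- numeric(n); col_means <- numeric(k)
  for (i in 1:n) row_means[i] <- sum(m[i, ]) / k
  for (j in 1:k) col_means[j] <- sum(m[, j]) / n
  for (i in 1:n) ss_b <- ss_b + (row_means[i] - grand)^2
  ss_b <- k * ss_b
  for (j in 1:k) ss_j <- ss_j + (col_means[j] - grand)^2
  ss_j <- n * ss_j
  for (i in 1:n) for (j in 1:k)
    ss_e <- ss_e + (m[i, j] - row_means[i] - col_means[j] + grand)^2
  list(BMS = ss_b / (n - 1), JMS = ss_j / (k - 1),
       EMS = ss_e / ((n - 1) * (k - 1)))
}

bf_icc31 <- function(m) {
  a <- bf_anova(m)
  k <- ncol(m)
  (a$BMS - a$EMS) / (a$BMS + (k - 1) * a$EMS)
}

# Brute-force in-plane 4-connected dilation of a contact label within one
# axial slice, constrained to tibial-cartilage voxels.
bf_dilate_slice <- function(slab, code, cart_code) {
  out <- slab
  nr <- nrow(slab); nc <- ncol(slab)
  for (i in 1:nr) for (j in 1:nc) {
    if (slab[i, j] != cart_code) next
    nb <- c(if (i > 1) slab[i - 1, j], if (i < nr) slab[i + 1, j],
            if (j > 1) slab[i, j - 1], if (j < nc) slab[i, j + 1])
    if (any(nb == code)) out[i, j] <- code
  }
  out
}

# Brute-force column scan for tibiofemoral contact: for every in-plane
# column, the top tibial voxel is in contact when the nearest femoral voxel
# above (or any femoral voxel at/below it) is within the gap tolerance.
bf_contact_columns <- function(lab, dict, dz, tol) {
  d <- dim(lab)
  tib_codes <- c(dict[["tibial_cartilage"]], dict[["contact_medial"]],
                 dict[["contact_lateral"]])
  out <- matrix(FALSE, d[1], d[2])
  for (i in 1:d[1]) for (j in 1:d[2]) {
    col <- lab[i, j, ]
    kt <- which(col %in% tib_codes)
    if (!length(kt)) next
    kt <- max(kt)
    kf <- which(col == dict[["femoral_cartilage"]])
    if (!length(kf)) next
    if (any(kf <= kt)) { out[i, j] <- TRUE; next }
    gap <- (min(kf[kf > kt]) - kt - 1) * dz
    if (gap <= tol) out[i, j] <- TRUE
  }
  out
}

random_landmarks <- function() {
  repeat {
    pts <- lapply(1:4, function(i) stats::rnorm(3, 0, 30))
    lm <- try(landmark_set(medial_edge = pts[[1]], lateral_edge = pts[[2]],
                           plateau_center = pts[[3]], shaft_distal = pts[[4]]),
              silent = TRUE)
    if (inherits(lm, "try-error")) next
    fr <- try(build_tibial_frame(lm), silent = TRUE)
    if (!inherits(fr, "try-error")) return(lm)
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}
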