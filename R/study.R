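#' Configuration of a synthetic reliability study
#'
#' Bundles every parameter of an end-to-end synthetic study -- cohort size,
#' base phantom geometry, between-subject variability, rater and session
#' noise, which reliability designs to run, and the master seed -- so that
#' a run is fully reproducible from its configuration alone. The
#' configuration round-trips through JSON unchanged.
#'
#' Defaults emulate the in vivo study conditions: 5 subjects, two raters
#' for inter-rater reliability, two sessions about a month apart for
#' test-retest (one rater), and three repeat segmentations by one rater
#' for intra-rater reliability. Between-subject anatomy varies through a
#' shared knee-size factor (scaling plateau and patches together), a
#' per-compartment contact-patch factor, and jitter of the patch centres;
#' together these give absolute medial areas a CV near 23% around 452 mm2
#' and normalized areas a CV near 16%, the in vivo mean +/- SD scale, and
#' give contact centroids genuine between-subject spread (without which
#' centroid reliability would be undefined). Rater/session noise
#' magnitudes are calibrated to yield area SEMs of a few tenths of a
#' percent of the plateau cross-section, the printed order of magnitude.
#' All jitter draws are truncated at 2 SD so every sampled subject is a
#' valid geometry.
#'
#' @param n_subjects Cohort size (default 5).
#' @param base_spec A [phantom_spec()] for the prototypical subject.
#' @param subject_size_sdlog SD of the log overall knee-size factor
#'   (scales plateau and patch semi-axes together).
#' @param subject_patch_sdlog SD of the log patch-size factor across
#'   subjects (per compartment, on top of the size factor).
#' @param subject_center_sd_frac SD of the patch-centre jitter across
#'   subjects, as a fraction of the plateau semi-axes (per component).
#' @param rater_flip_prob Boundary flip probability of both raters.
#' @param rater_biases Length-2 erosion/dilation biases of raters 1 and 2.
#' @param session_scale_sdlog,session_rot_sd_deg,session_trans_sd_mm
#'   Session (test-retest) jitter magnitudes; see [session_model()].
#' @param designs Character subset of `inter_rater`, `test_retest`,
#'   `intra_rater`.
#' @param n_intra_repeats Number of repeat segmentations for the
#'   intra-rater design.
#' @param accuracy_n Number of samples for the accuracy sub-study (0
#'   disables it).
#' @param accuracy_fine_spacing_mm In-plane spacing of the high-resolution
#'   reference re-measurement.
#' @param seed Master seed; all per-stage streams derive from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 5L,
                         base_spec = phantom_spec(),
                         subject_size_sdlog = 0.08,
                         subject_patch_sdlog = 0.08,
                         subject_center_sd_frac = 0.03,
                         rater_flip_prob = 0.25,
                         rater_biases = c(-0.15, 0.15),
                         session_scale_sdlog = 0.02,
                         session_rot_sd_deg = 1,
                         session_trans_sd_mm = 1,
                         designs = c("inter_rater", "test_retest", "intra_rater"),
                         n_intra_repeats = 3L,
                         accuracy_n = 3L,
                         accuracy_fine_spacing_mm = 0.2,
                         seed = 1L) {
  designs <- match.arg(designs, several.ok = TRUE)
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        base_spec = base_spec,
                        subject_size_sdlog = subject_size_sdlog,
                        subject_patch_sdlog = subject_patch_sdlog,
                        subject_center_sd_frac = subject_center_sd_frac,
                        rater_flip_prob = rater_flip_prob,
                        rater_biases = as.numeric(rater_biases),
                        session_scale_sdlog = session_scale_sdlog,
                        session_rot_sd_deg = session_rot_sd_deg,
                        session_trans_sd_mm = session_trans_sd_mm,
                        designs = designs,
                        n_intra_repeats = as.integer(n_intra_repeats),
                        accuracy_n = as.integer(accuracy_n),
                        accuracy_fine_spacing_mm = accuracy_fine_spacing_mm,
                        seed = as.integer(seed)),
                   class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg$base_spec, "phantom_spec"))
  if (cfg$n_subjects < 2L) stop("need at least 2 subjects")
  if (cfg$rater_flip_prob < 0 || cfg$rater_flip_prob > 1)
    stop("rater_flip_prob must be in [0, 1]")
  if (length(cfg$rater_biases) != 2L || any(abs(cfg$rater_biases) > 1))
    stop("rater_biases must be two values in [-1, 1]")
  if (cfg$n_intra_repeats < 2L) stop("intra-rater design needs >= 2 repeats")
  if (any(c(cfg$subject_size_sdlog, cfg$subject_patch_sdlog,
            cfg$subject_center_sd_frac,
            cfg$session_scale_sdlog, cfg$session_rot_sd_deg,
            cfg$session_trans_sd_mm) < 0))
    stop("variability parameters must be non-negative")
  if (cfg$accuracy_n > 0 && cfg$accuracy_fine_spacing_mm <= 0)
    stop("accuracy_fine_spacing_mm must be positive")
  invisible(cfg)
}

#' Read or write a study configuration as JSON
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_study_config` returns a [study_config()];
#'   `write_study_config` returns `path` invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$base_spec <- serialize_phantom_spec(config$base_spec)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- deserialize_phantom_spec(x$base_spec)
  x$base_spec <- NULL
  do.call(study_config, c(x, list(base_spec = spec)))
}

serialize_phantom_spec <- function(spec) {
  list(grid_shape = spec$grid_shape,
       voxel_spacing = spec$voxel_spacing,
       plateau_semi_axes = spec$plateau_semi_axes,
       plateau_thickness = spec$plateau_thickness,
       cartilage_thickness = spec$cartilage_thickness,
       gap_mm = spec$gap_mm,
       patches = lapply(spec$patches, unclass),
       pose = list(rotation = spec$pose$rotation,
                   translation = spec$pose$translation))
}

deserialize_phantom_spec <- function(x) {
  phantom_spec(grid_shape = x$grid_shape,
               voxel_spacing = x$voxel_spacing,
               plateau_semi_axes = x$plateau_semi_axes,
               plateau_thickness = x$plateau_thickness,
               cartilage_thickness = x$cartilage_thickness,
               gap_mm = x$gap_mm,
               patches = lapply(x$patches, function(p)
                 patch_params(p$center_frac, p$semi_axes)),
               pose = rigid_transform(matrix(unlist(x$pose$rotation), 3L, 3L),
                                      x$pose$translation))
}

# Deterministic per-stage sub-seeds derived from the master seed.
derive_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# Anatomically structured subject variation: a shared size factor scales
# plateau and patches together; per-compartment patch factors and
# patch-centre jitter (fractions of the plateau semi-axes) vary contact
# size and location between subjects.
vary_subject_spec <- function(spec, size_factor = 1, patch_factors = c(1, 1),
                              center_jitter = matrix(0, 2L, 2L)) {
  out <- spec
  out$plateau_semi_axes <- spec$plateau_semi_axes * size_factor
  for (i in seq_along(c("medial", "lateral"))) {
    nm <- c("medial", "lateral")[i]
    out$patches[[nm]]$semi_axes <-
      spec$patches[[nm]]$semi_axes * size_factor * patch_factors[i]
    out$patches[[nm]]$center_frac <-
      spec$patches[[nm]]$center_frac + center_jitter[, i]
  }
  validate_phantom_spec(out)
  out
}

measure_row <- function(vol, landmarks, subject, measurement) {
  mm <- measure_contact(vol, landmarks)
  cbind(data.frame(subject = subject, measurement = measurement),
        as.data.frame(mm))
}

#' Run a complete synthetic reliability study
#'
#' Orchestrates the whole pipeline on synthetic data: generates a cohort of
#' subject phantoms (between-subject size variability), simulates raters
#' and repeat sessions, measures per-compartment contact area and centroid
#' location in the tibial frame, computes a [reliability_report()] for each
#' requested design, and (optionally) an accuracy sub-study comparing
#' measurements at acquisition resolution with a high-resolution reference
#' re-measurement of the same specimens, summarized by the mean absolute
#' error.
#'
#' Everything derives deterministically from `config$seed`: the same
#' configuration produces byte-identical reports.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, measurements (CSV),
#'   reports (CSV + JSON), the accuracy table (CSV) and a config echo
#'   (JSON) are written there.
#' @return An object of class `tf_study`: `reports` (named list of
#'   [reliability_report()]s), `accuracy` (list with `pairs` and
#'   `mae_mm2`, or `NULL`), `measurements` (long data frame), `config`,
#'   and `seeds` (the per-stage RNG seeds used).
#' @examples
#' \donttest{
#' st <- run_study(study_config(seed = 7))
#' st
#' }
#' @export
run_study <- function(config, out_dir = NULL) {
  validate_study_config(config)
  seeds <- derive_seeds(config$seed, 6L)
  names(seeds) <- c("subjects", "raters", "sessions", "intra", "accuracy", "spare")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  # --- cohort specs -------------------------------------------------------
  subject_specs <- stage("cohort", {
    set.seed(seeds[["subjects"]])
    lapply(seq_len(config$n_subjects), function(i) {
      size <- exp(rnorm_trunc2(1L, 0, config$subject_size_sdlog))
      patch <- exp(rnorm_trunc2(2L, 0, config$subject_patch_sdlog))
      cen <- matrix(rnorm_trunc2(4L, 0, config$subject_center_sd_frac), 2L, 2L)
      vary_subject_spec(config$base_spec, size, patch, cen)
    })
  })

  rater_models <- function(seed_vec)
    lapply(1:2, function(r)
      rater_model(config$rater_flip_prob, config$rater_biases[r], seed_vec[r]))

  measurements <- list()
  add <- function(design, df) {
    df$design <- design
    measurements[[length(measurements) + 1L]] <<- df
  }

  session1 <- stage("generate", lapply(subject_specs, generate_phantom))

  if ("inter_rater" %in% config$designs) stage("inter_rater", {
    rseeds <- matrix(derive_seeds(seeds[["raters"]], 2L * config$n_subjects),
                     ncol = 2L)
    for (i in seq_len(config$n_subjects)) {
      models <- rater_models(rseeds[i, ])
      for (r in 1:2) {
        vol <- perturb_rater(session1[[i]]$volume, models[[r]])
        add("inter_rater", measure_row(vol, session1[[i]]$landmarks, i, r))
      }
    }
  })

  if ("test_retest" %in% config$designs) stage("test_retest", {
    sseeds <- matrix(derive_seeds(seeds[["sessions"]], 3L * config$n_subjects),
                     ncol = 3L)
    for (i in seq_len(config$n_subjects)) {
      # one rater (rater 1) segments both sessions, with fresh tracing noise
      m1 <- rater_model(config$rater_flip_prob, config$rater_biases[1], sseeds[i, 1])
      vol1 <- perturb_rater(session1[[i]]$volume, m1)
      add("test_retest", measure_row(vol1, session1[[i]]$landmarks, i, 1L))
      sm <- session_model(1, config$session_scale_sdlog, config$session_rot_sd_deg,
                          config$session_trans_sd_mm, sseeds[i, 2])
      spec2 <- perturb_session(subject_specs[[i]], sm)
      ph2 <- generate_phantom(spec2)
      m2 <- rater_model(config$rater_flip_prob, config$rater_biases[1], sseeds[i, 3])
      vol2 <- perturb_rater(ph2$volume, m2)
      add("test_retest", measure_row(vol2, ph2$landmarks, i, 2L))
    }
  })

  if ("intra_rater" %in% config$designs) stage("intra_rater", {
    iseeds <- matrix(derive_seeds(seeds[["intra"]],
                                  config$n_intra_repeats * config$n_subjects),
                     ncol = config$n_intra_repeats)
    for (i in seq_len(config$n_subjects)) {
      for (r in seq_len(config$n_intra_repeats)) {
        m <- rater_model(config$rater_flip_prob, config$rater_biases[2], iseeds[i, r])
        vol <- perturb_rater(session1[[i]]$volume, m)
        add("intra_rater", measure_row(vol, session1[[i]]$landmarks, i, r))
      }
    }
  })

  measurements <- do.call(rbind, measurements)
  reports <- stage("reliability", {
    out <- list()
    for (d in config$designs)
      out[[d]] <- reliability_report(measurements[measurements$design == d, ],
                                     design = d)
    out
  })

  accuracy <- NULL
  if (config$accuracy_n > 0) accuracy <- stage("accuracy", {
    accuracy_substudy(config, seeds[["accuracy"]])
  })

  study <- structure(list(reports = reports, accuracy = accuracy,
                          measurements = measurements, config = config,
                          seeds = seeds),
                     class = "tf_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# Degraded-vs-reference accuracy comparison on a few specimens: the same
# analytic specimen voxelized at acquisition spacing (test) and at fine
# in-plane spacing (reference), medial contact area compared by MAE.
accuracy_substudy <- function(config, seed) {
  set.seed(seed)
  facs <- exp(rnorm_trunc2(config$accuracy_n, 0, config$subject_patch_sdlog))
  test <- numeric(config$accuracy_n); ref <- numeric(config$accuracy_n)
  for (s in seq_len(config$accuracy_n)) {
    spec <- vary_subject_spec(config$base_spec, 1, rep(facs[s], 2L))
    ph <- generate_phantom(spec)
    test[s] <- measure_contact(ph$volume, ph$landmarks)$area_mm2[1]
    fine <- spec
    fine$voxel_spacing[1:2] <- config$accuracy_fine_spacing_mm
    fine$grid_shape[1:2] <- as.integer(ceiling(
      spec$grid_shape[1:2] * spec$voxel_spacing[1:2] / config$accuracy_fine_spacing_mm))
    phf <- generate_phantom(fine)
    ref[s] <- measure_contact(phf$volume, phf$landmarks)$area_mm2[1]
  }
  list(pairs = data.frame(sample = seq_len(config$accuracy_n),
                          test_mm2 = test, reference_mm2 = ref),
       mae_mm2 = mae(test, ref))
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$measurements,
                   file.path(out_dir, "measurements.csv"), row.names = FALSE)
  for (d in names(study$reports))
    write_reliability_report(study$reports[[d]],
                             file.path(out_dir, paste0("report_", d)))
  if (!is.null(study$accuracy)) {
    utils::write.csv(study$accuracy$pairs,
                     file.path(out_dir, "accuracy_pairs.csv"), row.names = FALSE)
    jsonlite::write_json(list(mae_mm2 = study$accuracy$mae_mm2),
                         file.path(out_dir, "accuracy.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  write_study_config(study$config, file.path(out_dir, "config.json"))
  jsonlite::write_json(as.list(study$seeds), file.path(out_dir, "seeds.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.tf_study <- function(x, ...) {
  cat(sprintf("Synthetic contact reliability study: %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  for (d in names(x$reports)) {
    cat("\n")
    print(x$reports[[d]])
  }
  if (!is.null(x$accuracy))
    cat(sprintf("\nAccuracy sub-study (%d samples): MAE = %.1f mm2\n",
                nrow(x$accuracy$pairs), x$accuracy$mae_mm2))
  invisible(x)
}
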