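# Synthetic two-group rsfMRI cohort with planted, ground-truth-recorded
# effects.
#
# Entropy is manipulated through the mixing weight w of a unit-variance
# AR(1) process with white noise: x = (1 - w) * s_AR + w * e. Sample entropy
# decreases with temporal autocorrelation, so mean SampEn is monotonically
# increasing in w, giving an analytically interpretable knob for planting
# regional group differences. Clinical scores are linear in the per-subject
# ROI entropy offsets plus Gaussian noise, and MD maps are a baseline plus a
# coupling times the same offsets, so every planted effect is recoverable
# from the ground-truth record alone.

#' Entropy-tunable voxel signal
#'
#' Returns `x = (1 - w) * s + w * e`, where `s` is a unit-variance AR(1)
#' process with coefficient `phi` and `e` unit-variance white noise, both
#' drawn from the seeded generator. Larger `w` means weaker autocorrelation
#' and hence higher sample entropy.
#'
#' @param w Noise-mix weight in `[0, 1]`.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param n Series length (>= 20).
#' @param seed Optional RNG seed (the global RNG state is restored).
#' @return Numeric vector of length `n`.
#' @export
synth_voxel_signal <- function(w, phi, n, seed = NULL) {
  if (w < 0 || w > 1) stopf("w must be in [0, 1]")
  if (abs(phi) >= 1) stopf("|phi| must be < 1")
  if (n < 20) stopf("n must be >= 20")
  with_seed(seed, {
    e1 <- rnorm(n)
    s <- numeric(n)
    s[1] <- e1[1]
    innov_sd <- sqrt(1 - phi^2)
    for (t in 2:n) s[t] <- phi * s[t - 1] + innov_sd * e1[t]
    e2 <- rnorm(n)
    (1 - w) * s + w * e2
  })
}

#' Rectangular ROI voxel set
#'
#' @param center Voxel centre (1-based i, j, k).
#' @param half_widths Half-widths per axis; the box spans
#'   `center +/- half_widths`.
#' @return Integer matrix of voxel indices (rows = voxels, columns i, j, k).
#' @export
roi_box <- function(center, half_widths) {
  rng <- lapply(1:3, function(a)
    seq.int(center[a] - half_widths[a], center[a] + half_widths[a]))
  as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
}

#' ROI specification for the synthetic cohort
#'
#' @param name ROI label.
#' @param voxel_set Integer matrix of 1-based voxel indices (n x 3).
#' @param w_patient,w_control Noise-mix weights in `[0, 1]` used inside the
#'   ROI for each group.
#' @param md_coupling Slope linking a subject's entropy offset (realized w
#'   minus the group mean w) to mean diffusivity inside the ROI, in
#'   mm^2/s per unit w.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, voxel_set, w_patient, w_control, md_coupling = 0) {
  if (any(c(w_patient, w_control) < 0 | c(w_patient, w_control) > 1))
    stopf("ROI weights must be in [0, 1]")
  voxel_set <- matrix(as.integer(voxel_set), ncol = 3)
  structure(list(name = name, voxel_set = voxel_set, w_patient = w_patient,
                 w_control = w_control, md_coupling = md_coupling),
            class = "roi_spec")
}

default_roi_specs <- function(grid_shape) {
  half <- pmax(1L, round(grid_shape / 12))
  list(
    # entropy increase in patients (motor-area analogue)
    roi_spec("SMA", roi_box(round(grid_shape * c(0.5, 0.5, 0.72)), half),
             w_patient = 0.85, w_control = 0.5, md_coupling = 4e-4),
    # entropy decrease in patients (parahippocampal analogue)
    roi_spec("pHIPP", roi_box(round(grid_shape * c(0.5, 0.5, 0.3)), half),
             w_patient = 0.15, w_control = 0.5, md_coupling = 0))
}

#' Clinical link parameters
#'
#' Per clinical score: an intercept, a named vector of slopes on ROI entropy
#' offsets, and a Gaussian noise SD. Defaults plant an EDSS link to the
#' "SMA" ROI and an MFIS-5 link to the "pHIPP" ROI at a planted R-squared of
#' about 0.3 given the default subject-weight jitter, and leave PASAT
#' unlinked (slope 0).
#'
#' @param edss,mfis5,pasat Lists with fields `intercept`, `slopes` (named
#'   numeric, possibly empty) and `noise_sd` (>= 0).
#' @return An object of class `link_params`.
#' @export
link_params <- function(
    edss = list(intercept = 2, slopes = c(SMA = 8), noise_sd = 0.6),
    mfis5 = list(intercept = 11.3, slopes = c(pHIPP = 20), noise_sd = 1.5),
    pasat = list(intercept = 84, slopes = numeric(), noise_sd = 8)) {
  for (s in list(edss, mfis5, pasat))
    if (s$noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(edss = edss, mfis5 = mfis5, pasat = pasat),
            class = "link_params")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a two-group resting-state study: 34 patients and 34
#' controls, 240 timepoints at TR 2 s, 3 mm isotropic voxels on a desk-scale
#' 24 x 24 x 16 grid, sex ratio 13M/21F per group and ages uniform on 20-58.
#'
#' @param n_patients,n_controls Group sizes.
#' @param grid_shape Three voxel counts (all >= 8).
#' @param voxel_size_mm Isotropic voxel size in mm (default 3).
#' @param n_timepoints Number of volumes (default 240, >= 20).
#' @param tr_s Repetition time in seconds (default 2).
#' @param roi_specs List of [roi_spec()] objects; default plants one
#'   entropy-increase and one entropy-decrease ROI.
#' @param clinical_link A [link_params()].
#' @param baseline_w Noise-mix weight outside the ROIs (default 0.5).
#' @param phi AR(1) coefficient of the autocorrelated component (default 0.9).
#' @param subject_w_sd SD of the per-subject ROI weight jitter (default 0.05).
#' @param signal_amp,baseline_intensity BOLD fluctuation amplitude and mean
#'   intensity inside the brain.
#' @param md_baseline,md_subject_sd,md_voxel_sd Mean-diffusivity baseline and
#'   noise components (mm^2/s).
#' @param qc_fail_frac Fraction of subjects given motion exceeding the QC
#'   threshold (default 0).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 34L, n_controls = 34L,
                          grid_shape = c(24L, 24L, 16L), voxel_size_mm = 3,
                          n_timepoints = 240L, tr_s = 2,
                          roi_specs = default_roi_specs(grid_shape),
                          clinical_link = link_params(),
                          baseline_w = 0.5, phi = 0.9, subject_w_sd = 0.05,
                          signal_amp = 20, baseline_intensity = 1000,
                          md_baseline = 8e-4, md_subject_sd = 2e-5,
                          md_voxel_sd = 2e-5,
                          qc_fail_frac = 0, seed = 1L) {
  if (n_timepoints < 20) stopf("n_timepoints must be >= 20")
  if (any(grid_shape < 8)) stopf("all grid dimensions must be >= 8")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
    roi_specs = roi_specs, clinical_link = clinical_link,
    baseline_w = baseline_w, phi = phi, subject_w_sd = subject_w_sd,
    signal_amp = signal_amp, baseline_intensity = baseline_intensity,
    md_baseline = md_baseline, md_subject_sd = md_subject_sd,
    md_voxel_sd = md_voxel_sd,
    qc_fail_frac = qc_fail_frac, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Ellipsoidal brain mask and concentric tissue shells
#'
#' The brain mask is a centred ellipsoid covering roughly 60% of the grid;
#' "tissue" probability maps are concentric shells of the normalized
#' ellipsoidal radius rho: WM core (rho <= 0.55), GM shell
#' (0.55 < rho <= 0.85), CSF rim (0.85 < rho <= 1).
#'
#' @param grid_shape Three voxel counts.
#' @return List with `mask` (logical 3D), `rho` (normalized radius), and
#'   binary probability maps `gm`, `wm`, `csf`.
#' @export
synth_brain_geometry <- function(grid_shape) {
  d <- grid_shape
  ctr <- (d + 1) / 2
  semi <- 1.1 * d / 2  # slightly clipped ellipsoid, ~60% of the grid
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / semi[a])^2)
  rho <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  mask <- rho <= 1
  shell <- function(lo, hi) array(as.numeric(rho > lo & rho <= hi), d)
  list(mask = mask, rho = rho,
       wm = shell(-1, 0.55), gm = shell(0.55, 0.85), csf = shell(0.85, 1))
}

#' Generate a synthetic two-group cohort
#'
#' Builds the full cohort description: brain and ROI masks, tissue maps,
#' subject manifest with demographics and clinical scores, motion parameter
#' tables, MD maps, per-subject BOLD seeds and a complete ground-truth
#' record of every planted parameter. The (heavy) 4D BOLD images are
#' materialised lazily via [simulate_bold()] or written by [write_cohort()].
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `ben_cohort`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  d <- cfg$grid_shape
  geom <- synth_brain_geometry(d)
  mask <- geom$mask
  # ROI masks; every ROI voxel must be inside the grid and the brain mask
  roi_masks <- list()
  for (spec in cfg$roi_specs) {
    vs <- spec$voxel_set
    if (any(vs < 1) || any(vs > matrix(d, nrow(vs), 3, byrow = TRUE)))
      stopf("ROI '%s' extends outside the grid", spec$name)
    rm3 <- array(FALSE, d)
    rm3[vs] <- TRUE
    if (any(rm3 & !mask))
      stopf("ROI '%s' extends outside the brain mask", spec$name)
    roi_masks[[spec$name]] <- rm3
  }

  n <- cfg$n_patients + cfg$n_controls
  seeds <- derive_seeds(cfg$seed, 6L)
  group <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  subject_id <- sprintf("sub-%03d", seq_len(max(n, 1)))[seq_len(n)]

  # demographics: Table-1-style marginals
  demo <- with_seed(seeds[1], {
    sex <- unlist(lapply(c(cfg$n_patients, cfg$n_controls), function(k) {
      m <- round(k * 13 / 34)
      sample(rep(c("M", "F"), c(m, k - m)))
    }))
    list(age = round(runif(n, 20, 58)),
         sex = if (n) sex else character(),
         education = pmin(18, pmax(6, round(rnorm(n, 12, 3)))))
  })

  # per-subject ROI weights and entropy offsets
  n_roi <- length(cfg$roi_specs)
  w_subject <- offsets <- matrix(0, n, n_roi,
                                 dimnames = list(subject_id,
                                                 names(roi_masks)))
  with_seed(seeds[2], {
    for (r in seq_len(n_roi)) {
      spec <- cfg$roi_specs[[r]]
      w_grp <- ifelse(group == "patient", spec$w_patient, spec$w_control)
      jit <- rnorm(n, 0, cfg$subject_w_sd)
      w <- pmin(1, pmax(0, w_grp + jit))
      w_subject[, r] <- w
      offsets[, r] <- w - w_grp
    }
  })

  # motion: small random walks; a configurable fraction exceed the QC rule
  motion <- with_seed(seeds[3], {
    n_fail <- round(cfg$qc_fail_frac * n)
    fail <- rep(FALSE, n)
    if (n_fail > 0) fail[sample.int(n, n_fail)] <- TRUE
    lapply(seq_len(n), function(i) {
      m <- apply(matrix(rnorm(cfg$n_timepoints * 6, 0, 0.01),
                        cfg$n_timepoints, 6), 2, cumsum)
      if (fail[i]) m[, 3] <- m[, 3] + 2.5  # z-translation offset
      m
    })
  })

  # MD maps: baseline + coupling * entropy offset inside coupled ROIs + noise
  md_maps <- with_seed(seeds[4], {
    lapply(seq_len(n), function(i) {
      md <- array(0, d)
      md[mask] <- cfg$md_baseline + rnorm(1, 0, cfg$md_subject_sd) +
        rnorm(sum(mask), 0, cfg$md_voxel_sd)
      for (r in seq_len(n_roi)) {
        spec <- cfg$roi_specs[[r]]
        if (spec$md_coupling != 0) {
          rm3 <- roi_masks[[spec$name]]
          md[rm3] <- md[rm3] + spec$md_coupling * offsets[i, r]
        }
      }
      md
    })
  })

  manifest <- data.frame(subject_id = subject_id, group = group,
                         age = demo$age, sex = demo$sex,
                         education = demo$education,
                         stringsAsFactors = FALSE)
  manifest <- assign_clinical_scores(manifest, w_offsets(offsets),
                                     cfg$clinical_link, seed = seeds[5])

  bold_seeds <- derive_seeds(seeds[6], max(n, 1))[seq_len(n)]

  ground_truth <- list(
    baseline_w = cfg$baseline_w, phi = cfg$phi,
    subject_w_sd = cfg$subject_w_sd,
    rois = lapply(cfg$roi_specs, function(s)
      list(name = s$name, w_patient = s$w_patient, w_control = s$w_control,
           md_coupling = s$md_coupling, n_voxels = nrow(s$voxel_set))),
    w_subject = w_subject, entropy_offsets = offsets,
    clinical_link = unclass(cfg$clinical_link),
    md_baseline = cfg$md_baseline,
    seed = cfg$seed, bold_seeds = bold_seeds)

  structure(list(config = cfg, mask = mask, tissue = geom[c("gm", "wm", "csf")],
                 roi_masks = roi_masks, manifest = manifest, motion = motion,
                 md_maps = md_maps, ground_truth = ground_truth,
                 bold_seeds = bold_seeds),
            class = "ben_cohort")
}

# offsets matrix in the data.frame form assign_clinical_scores expects
w_offsets <- function(offsets) {
  as.data.frame(offsets)
}

#' @export
print.ben_cohort <- function(x, ...) {
  cat(sprintf("<ben_cohort> %d patients + %d controls, grid %s, %d timepoints\n",
              x$config$n_patients, x$config$n_controls,
              paste(x$config$grid_shape, collapse = "x"),
              x$config$n_timepoints))
  invisible(x)
}

#' Assign clinical scores from planted entropy offsets
#'
#' Patients receive `score = intercept + sum(slope * roi_offset) + N(0,
#' noise_sd)`, clipped to the score's plausible range (EDSS in [0, 10],
#' MFIS-5 and PASAT >= 0). Controls are drawn from a separate null
#' distribution matching a healthy population (EDSS 0, MFIS-5 Bernoulli
#' around 0.3, PASAT around 98).
#'
#' @param manifest Data frame with `subject_id` and `group` columns.
#' @param entropy_means Data frame of per-subject ROI entropy offsets/means,
#'   one named column per ROI, rows in manifest order.
#' @param link A [link_params()].
#' @param seed Optional RNG seed.
#' @return The manifest with `edss`, `mfis5`, `pasat` columns appended.
#' @export
assign_clinical_scores <- function(manifest, entropy_means,
                                   link = link_params(), seed = NULL) {
  stopifnot(inherits(link, "link_params"))
  entropy_means <- as.data.frame(entropy_means)
  if (nrow(entropy_means) != nrow(manifest))
    stopf("entropy_means rows (%d) must match manifest rows (%d)",
          nrow(entropy_means), nrow(manifest))
  pat <- manifest$group == "patient"
  n <- nrow(manifest)
  linear_score <- function(spec) {
    val <- rep(spec$intercept, n)
    for (roi in names(spec$slopes)) {
      if (!roi %in% names(entropy_means))
        stopf("no entropy mean supplied for linked ROI '%s'", roi)
      val <- val + spec$slopes[[roi]] * entropy_means[[roi]]
    }
    val + rnorm(n, 0, spec$noise_sd)
  }
  with_seed(seed, {
    edss <- linear_score(link$edss)
    mfis <- linear_score(link$mfis5)
    pasat <- linear_score(link$pasat)
    manifest$edss <- ifelse(pat, pmin(10, pmax(0, edss)), 0)
    manifest$mfis5 <- ifelse(pat, pmax(0, mfis), rbinom(n, 1, 0.3))
    manifest$pasat <- ifelse(pat, pmax(0, pasat),
                             pmax(0, rnorm(n, 97.8, 8)))
    manifest
  })
}

#' Materialise one subject's 4D BOLD image
#'
#' Deterministically regenerates subject `i`'s BOLD series from the cohort's
#' stored per-subject seed: inside the brain mask each voxel carries
#' `baseline_intensity + signal_amp * x`, where `x` mixes a shared-parameter
#' AR(1) process and white noise with the voxel's planted weight; the
#' background is exactly 0.
#'
#' @param cohort A `ben_cohort` from [generate_cohort()].
#' @param i Subject index (manifest row).
#' @return A [bold_series].
#' @export
simulate_bold <- function(cohort, i) {
  stopifnot(inherits(cohort, "ben_cohort"))
  cfg <- cohort$config
  d <- cfg$grid_shape
  t <- cfg$n_timepoints
  mask <- cohort$mask
  V <- sum(mask)
  # per-voxel mixing weights for this subject
  w <- rep(cfg$baseline_w, V)
  mask_idx <- which(mask)
  for (r in seq_along(cfg$roi_specs)) {
    name <- cfg$roi_specs[[r]]$name
    roi_in_mask <- which(mask_idx %in% which(cohort$roi_masks[[name]]))
    w[roi_in_mask] <- cohort$ground_truth$w_subject[i, name]
  }
  x <- with_seed(cohort$bold_seeds[i], .simulate_mix(t, w, cfg$phi))
  arr <- array(0, c(d, t))
  flat <- matrix(arr, prod(d), t)
  flat[mask_idx, ] <- t(cfg$baseline_intensity + cfg$signal_amp * x)
  bold_series(array(flat, c(d, t)), voxel_size_mm = cfg$voxel_size_mm,
              tr_s = cfg$tr_s,
              provenance = sprintf("simulate:%s", cohort$manifest$subject_id[i]))
}

#' Write a synthetic cohort to disk
#'
#' Writes one 4D NIfTI-1 per subject (RAS affine, TR in the header), the
#' brain mask, ROI masks and tissue probability maps as 3D NIfTI-1, MD maps,
#' motion parameters as 6-column whitespace-delimited text (translations mm,
#' rotations degrees), the manifest as TSV, and the ground truth as a single
#' YAML file.
#'
#' @param cohort A `ben_cohort`.
#' @param dir Output directory (created if needed).
#' @param bold Write the 4D BOLD images (default `TRUE`; they dominate the
#'   disk footprint).
#' @return `dir`, invisibly; paths are recorded in `<dir>/manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir, bold = TRUE) {
  stopifnot(inherits(cohort, "ben_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  vs <- cfg$voxel_size_mm
  man <- cohort$manifest
  n <- nrow(man)
  write_nifti_map(array(as.numeric(cohort$mask), cfg$grid_shape),
                  file.path(dir, "brain_mask.nii.gz"), voxel_size_mm = vs)
  for (nm in names(cohort$roi_masks))
    write_nifti_map(array(as.numeric(cohort$roi_masks[[nm]]), cfg$grid_shape),
                    file.path(dir, sprintf("roi_%s.nii.gz", nm)),
                    voxel_size_mm = vs)
  for (nm in names(cohort$tissue))
    write_nifti_map(cohort$tissue[[nm]],
                    file.path(dir, sprintf("tpm_%s.nii.gz", nm)),
                    voxel_size_mm = vs)
  bold_path <- motion_path <- md_path <- character(n)
  for (i in seq_len(n)) {
    id <- man$subject_id[i]
    motion_path[i] <- file.path(dir, sprintf("%s_motion.txt", id))
    write.table(format(cohort$motion[[i]], digits = 10),
                motion_path[i], row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    md_path[i] <- file.path(dir, sprintf("%s_md.nii.gz", id))
    write_nifti_map(cohort$md_maps[[i]], md_path[i], voxel_size_mm = vs)
    if (bold) {
      bold_path[i] <- file.path(dir, sprintf("%s_bold.nii.gz", id))
      write_nifti_map(simulate_bold(cohort, i), bold_path[i])
    }
  }
  man$bold_path <- if (bold) basename(bold_path) else NA_character_
  man$motion_path <- basename(motion_path)
  man$md_path <- basename(md_path)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  gt$w_subject <- as.data.frame(gt$w_subject)
  gt$entropy_offsets <- as.data.frame(gt$entropy_offsets)
  yaml::write_yaml(gt, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
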