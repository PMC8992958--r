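#' Configuration for the multicontrast brain phantom simulator
#'
#' The phantom emulates the properties of skull-stripped, co-registered
#' multicontrast brain MR subjects: zero-valued background, null axial
#' slices at the bottom and top of the stack, contrast-dependent tissue
#' intensities (including a lesion class), a smooth multiplicative
#' intensity-inhomogeneity (bias) field, and additive Gaussian noise.
#'
#' @param grid_shape integer triple of voxel counts, axial slices last.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @param lesion_probability probability in `[0,1]` that a subject carries a
#'   single ellipsoidal lesion straddling the white/grey-matter boundary.
#' @param noise_sd standard deviation of the additive zero-mean Gaussian
#'   noise, on the `[0,1]` intensity scale of the lookup tables.
#' @param bias_field_amplitude maximum fractional deviation of the
#'   multiplicative bias field from 1 (0 disables the field).
#' @param bias_field_smoothness spatial scale of the bias field in mm;
#'   larger values give smoother fields.
#' @param n_null_slices integer pair: number of all-background axial slices
#'   at the bottom and top of the stack. The default takes ~17.5% of the
#'   stack on each side (27 and 28 slices at the default 155), so roughly
#'   100 of 155 slices are retained — the proportion typical of
#'   skull-stripped clinical volumes.
#' @param seed integer seed; all phantom randomness derives from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(240L, 240L, 155L),
                           voxel_size_mm = 1,
                           lesion_probability = 0.6,
                           noise_sd = 0.02,
                           bias_field_amplitude = 0.1,
                           bias_field_smoothness = 16,
                           n_null_slices = NULL,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(n_null_slices))
    n_null_slices <- c(floor(0.175 * grid_shape[3]),
                       ceiling(0.175 * grid_shape[3]))
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            voxel_size_mm > 0, noise_sd >= 0,
            lesion_probability >= 0, lesion_probability <= 1,
            bias_field_amplitude >= 0, bias_field_smoothness > 0,
            length(n_null_slices) == 2L, all(n_null_slices >= 0L))
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm,
                 lesion_probability = lesion_probability,
                 noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 bias_field_smoothness = bias_field_smoothness,
                 n_null_slices = as.integer(n_null_slices),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Quadratic form ((x-c)/a)^2 summed over axes for a full grid; returns a
# logical 3D array marking the ellipsoid interior.
ellipsoid_mask <- function(dims, centre, semi) {
  dx2 <- ((seq_len(dims[1]) - centre[1]) / semi[1])^2
  dy2 <- ((seq_len(dims[2]) - centre[2]) / semi[2])^2
  dz2 <- ((seq_len(dims[3]) - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a tissue label volume for one phantom subject
#'
#' Builds a smooth nested-ellipsoid brain: an outer grey-matter shell, an
#' inner white-matter core, two central ellipsoidal CSF ventricles, and —
#' with probability `lesion_probability` — one ellipsoidal lesion placed on
#' the white/grey-matter boundary. The configured bottom and top slice
#' ranges are guaranteed all-background. Deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @return 3D integer array of tissue labels (see [TISSUE_LABELS]), with
#'   attribute `n_null_slices` carried from the configuration.
#' @export
generate_tissue_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  if (any(d < 16L))
    stop("grid too small to contain the nested phantom geometry ",
         "(each axis must be >= 16)")
  nb <- config$n_null_slices[1]; nt <- config$n_null_slices[2]
  zspan <- d[3] - nb - nt
  if (zspan < 8L)
    stop("null-slice ranges leave fewer than 8 slices for brain tissue")

  with_seed(config$seed, {
    jit <- runif(6, -1, 1)
    has_lesion <- runif(1) < config$lesion_probability
    lesion_dir <- runif(1, 0, 2 * pi)
    lesion_jit <- runif(2, -0.1, 0.1)
  })

  centre <- c((d[1] + 1) / 2 + 0.02 * d[1] * jit[1],
              (d[2] + 1) / 2 + 0.02 * d[2] * jit[2],
              nb + (zspan + 1) / 2)
  # z semi-axis zspan/2: tissue reaches every slice inside the null margins
  # (the configured margins stay empty, and no retained slice is empty)
  semi <- c(0.40 * d[1] * (1 + 0.05 * jit[3]),
            0.42 * d[2] * (1 + 0.05 * jit[4]),
            zspan / 2)

  labels <- array(0L, dim = d)
  labels[ellipsoid_mask(d, centre, semi)] <- TISSUE_LABELS[["gm"]]
  wm_semi <- semi * c(0.75, 0.75, 0.72)
  wm <- ellipsoid_mask(d, centre, wm_semi)
  labels[wm] <- TISSUE_LABELS[["wm"]]
  # two lateral ventricles inside the white-matter core
  voff <- c(0.16 * wm_semi[1] * (1 + 0.2 * jit[5]), 0)
  vsemi <- c(0.18 * wm_semi[1], 0.45 * wm_semi[2], 0.45 * wm_semi[3])
  for (s in c(-1, 1)) {
    v <- ellipsoid_mask(d, centre + c(s * (voff[1] + vsemi[1]), 0, 0), vsemi)
    labels[v & wm] <- TISSUE_LABELS[["csf"]]
  }
  if (has_lesion) {
    # centre on the WM boundary in the axial plane through the brain centre
    lc <- centre + c(wm_semi[1] * cos(lesion_dir) * (1 + lesion_jit[1]),
                     wm_semi[2] * sin(lesion_dir) * (1 + lesion_jit[2]), 0)
    lsemi <- pmax(2, 0.10 * semi)
    les <- ellipsoid_mask(d, lc, lsemi) & labels > 0L
    labels[les] <- TISSUE_LABELS[["lesion"]]
  }
  structure(labels, n_null_slices = config$n_null_slices)
}

#' Default intensity lookup tables for the three contrasts
#'
#' Mean tissue intensities on a `[0,1]` scale encoding the standard
#' radiological orderings: on T1-weighted images WM > GM > CSF; on
#' T2-weighted images CSF > GM > WM; on FLAIR the CSF signal is suppressed
#' (near 0) and the lesion is brightest.
#'
#' @return named list of lookup tables, one per contrast; each maps the five
#'   tissue labels (background, CSF, GM, WM, lesion) to a mean intensity.
#' @export
default_luts <- function() {
  list(
    T1    = c(background = 0, csf = 0.15, gm = 0.50, wm = 0.75, lesion = 0.40),
    T2    = c(background = 0, csf = 0.90, gm = 0.55, wm = 0.35, lesion = 0.70),
    FLAIR = c(background = 0, csf = 0.05, gm = 0.50, wm = 0.40, lesion = 0.90)
  )
}

# Smooth random field: coarse standard-normal grid, trilinearly interpolated
# to the full grid. `spacing_vox` sets the coarse-grid spacing in voxels.
smooth_random_field <- function(dims, spacing_vox) {
  nc <- pmax(2L, as.integer(ceiling(dims / spacing_vox)) + 1L)
  coarse <- array(rnorm(prod(nc)), dim = nc)
  # per-axis linear interpolation weights, centre-aligned
  ax <- lapply(1:3, function(k) {
    u <- (seq_len(dims[k]) - 0.5) / dims[k] * (nc[k] - 1) + 1
    i0 <- pmin(floor(u), nc[k] - 1)
    list(i0 = as.integer(i0), w = u - i0)
  })
  out <- array(0, dim = dims)
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    wx <- if (di == 0) 1 - ax[[1]]$w else ax[[1]]$w
    wy <- if (dj == 0) 1 - ax[[2]]$w else ax[[2]]$w
    wz <- if (dk == 0) 1 - ax[[3]]$w else ax[[3]]$w
    sub <- coarse[ax[[1]]$i0 + di, ax[[2]]$i0 + dj, ax[[3]]$i0 + dk,
                  drop = FALSE]
    out <- out + sub * outer(outer(wx, wy), wz)
  }
  out
}

#' Render one contrast volume from a tissue label volume
#'
#' Brain voxels receive `lut[label] * bias + noise`; background voxels are
#' exactly zero regardless of noise or bias settings. The bias field is a
#' smooth multiplicative field with mean 1 over the brain and maximum
#' fractional deviation `bias_field_amplitude`; the noise is additive
#' zero-mean Gaussian with standard deviation `noise_sd`. Seeded and
#' reproducible; the noise and bias realisations differ between contrasts
#' of the same subject (independent acquisitions) but are tied to the
#' configuration seed.
#'
#' @param labels tissue label volume from [generate_tissue_volume()].
#' @param lut named numeric lookup table covering labels 0-4 with
#'   `background == 0` (see [default_luts()]).
#' @param config the [phantom_config()] used to generate `labels`.
#' @param contrast_name one of `"T1"`, `"T2"`, `"FLAIR"`.
#' @param subject_id identifier stored in the returned volume.
#' @return an object of class `contrast_volume`: list with `subject_id`,
#'   `contrast_name`, `intensities` (3D array) and `voxel_size_mm`.
#' @export
render_contrast <- function(labels, lut, config, contrast_name = "T1",
                            subject_id = "subject") {
  stopifnot(inherits(config, "phantom_config"))
  labs <- sort(unique(as.integer(labels)))
  if (length(lut) < 5L || any(labs + 1L > length(lut)))
    stop("lookup table does not cover every label present in the volume")
  if (lut[[1]] != 0) stop("lookup table must map background to 0")
  vals <- unname(lut)[as.integer(labels) + 1L]
  intens <- array(vals, dim = dim(labels))
  brain <- labels > 0L
  nb <- sum(brain)
  cseed <- config$seed * 13L + match(contrast_name, CONTRASTS, nomatch = 0L)
  with_seed(cseed, {
    if (config$bias_field_amplitude > 0) {
      spacing <- config$bias_field_smoothness / config$voxel_size_mm
      g <- smooth_random_field(dim(labels), spacing)
      g <- g - mean(g[brain])
      m <- max(abs(g[brain]))
      if (m > 0) g <- g / m
      intens[brain] <- intens[brain] *
        (1 + config$bias_field_amplitude * g[brain])
    }
    if (config$noise_sd > 0)
      intens[brain] <- intens[brain] + rnorm(nb, sd = config$noise_sd)
  })
  intens[!brain] <- 0
  structure(list(subject_id = subject_id, contrast_name = contrast_name,
                 intensities = intens, voxel_size_mm = config$voxel_size_mm),
            class = "contrast_volume")
}

#' Generate a perfectly co-registered multicontrast phantom subject
#'
#' All contrasts are rendered from the same tissue label volume, so they are
#' voxel-wise aligned and share one background mask — the phantom analogue
#' of rigidly co-registered clinical acquisitions.
#'
#' @param config a [phantom_config()].
#' @param luts named list of lookup tables (default [default_luts()]).
#' @param subject_id identifier for the subject.
#' @return object of class `phantom_subject`: list with `subject_id`,
#'   `labels`, and `volumes` (named list of `contrast_volume`).
#' @export
generate_paired_subject <- function(config, luts = default_luts(),
                                    subject_id = "subject") {
  stopifnot(all(CONTRASTS %in% names(luts)))
  labels <- generate_tissue_volume(config)
  vols <- lapply(CONTRASTS, function(cn)
    render_contrast(labels, luts[[cn]], config, cn, subject_id))
  names(vols) <- CONTRASTS
  structure(list(subject_id = subject_id, labels = labels, volumes = vols),
            class = "phantom_subject")
}

#' Simulate a cohort of phantom subjects
#'
#' Subject `i` uses seed `config$seed + i - 1`, so cohorts are reproducible
#' and subjects are mutually distinct. Optionally writes one NIfTI file per
#' contrast per subject (`<subject_id>_<contrast>.nii.gz`) plus the label
#' volume (`<subject_id>_labels.nii.gz`).
#'
#' @param n_subjects number of subjects.
#' @param config a [phantom_config()]; its `seed` anchors the cohort.
#' @param luts lookup tables, default [default_luts()].
#' @param out_dir if non-NULL, directory to write NIfTI volumes into.
#' @return invisible list of `phantom_subject` objects.
#' @export
simulate_subjects <- function(n_subjects, config = phantom_config(),
                              luts = default_luts(), out_dir = NULL) {
  stopifnot(n_subjects >= 1)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    ci <- config
    ci$seed <- config$seed + i - 1L
    generate_paired_subject(ci, luts,
                            subject_id = sprintf("sub%03d", i))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) write_subject_nifti(s, out_dir)
  }
  invisible(subjects)
}

#' Write a phantom subject to NIfTI files
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory.
#' @return invisible character vector of written paths.
#' @export
write_subject_nifti <- function(subject, dir) {
  stopifnot(inherits(subject, "phantom_subject"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- subject$volumes[[1]]$voxel_size_mm
  paths <- character(0)
  for (cn in names(subject$volumes)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject$subject_id, cn))
    img <- RNifti::asNifti(subject$volumes[[cn]]$intensities,
                           pixdim = rep(vs, 3))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_labels.nii.gz", subject$subject_id))
  RNifti::writeNifti(RNifti::asNifti(subject$labels + 0,
                                     pixdim = rep(vs, 3)), p)
  invisible(c(paths, p))
}
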