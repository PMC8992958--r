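#' Assemble a subject record from contrast volumes
#'
#' @param subject_id identifier.
#' @param volumes named list of `contrast_volume` objects (>= 2 contrasts),
#'   all sharing one grid shape.
#' @return object of class `subject_record`.
#' @export
subject_record <- function(subject_id, volumes) {
  stopifnot(length(volumes) >= 2L)
  dims <- lapply(volumes, function(v) dim(v$intensities))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all contrast volumes of a subject must share one grid shape")
  structure(list(subject_id = subject_id, volumes = volumes),
            class = "subject_record")
}

#' @export
as.subject_record <- function(x) UseMethod("as.subject_record")

#' @export
as.subject_record.phantom_subject <- function(x)
  subject_record(x$subject_id, x$volumes)

#' @export
as.subject_record.subject_record <- function(x) x

#' Discover and read multicontrast subjects from a NIfTI directory
#'
#' Expects the `<subject_id>_<contrast>.nii.gz` naming convention used by
#' [simulate_subjects()]; label volumes are ignored.
#'
#' @param dir directory of NIfTI files.
#' @param contrasts contrasts to load (default all three).
#' @return list of `subject_record` objects, ordered by subject id.
#' @export
read_subjects_nifti <- function(dir, contrasts = CONTRASTS) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  base <- sub("\\.nii(\\.gz)?$", "", basename(files))
  keep <- grepl(paste0("_(", paste(contrasts, collapse = "|"), ")$"), base)
  files <- files[keep]; base <- base[keep]
  ids <- sub("_[^_]+$", "", base)
  cns <- sub("^.*_", "", base)
  lapply(sort(unique(ids)), function(id) {
    vols <- lapply(contrasts, function(cn) {
      p <- files[ids == id & cns == cn]
      if (length(p) != 1L)
        stop("subject ", id, " is missing contrast ", cn)
      img <- RNifti::readNifti(p)
      structure(list(subject_id = id, contrast_name = cn,
                     intensities = array(as.numeric(img), dim = dim(img)),
                     voxel_size_mm = RNifti::pixdim(img)[1]),
                class = "contrast_volume")
    })
    names(vols) <- contrasts
    subject_record(id, vols)
  })
}

#' Two-stage random split of subject ids into train/validation/test
#'
#' The ids are first split 80/20 into a development and a test set, then
#' the development set is split 80/20 into training and validation, giving
#' nominal fractions 64/16/20. Set sizes use round-half-up on the 80%
#' fraction at each stage, with the remainder going to test (respectively
#' validation). Deterministic for a fixed seed.
#'
#' @param ids character or integer vector of subject identifiers (>= 5).
#' @param seed integer seed for the permutation.
#' @return object of class `dataset_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `seed`, `fractions`.
#' @export
split_dataset <- function(ids, seed = 1L) {
  ids <- as.character(ids)
  if (length(ids) < 5L) stop("need at least 5 subject ids to split")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  n <- length(ids)
  perm <- with_seed(seed, sample(ids))
  n_dev <- floor(0.8 * n + 0.5)
  n_train <- floor(0.8 * n_dev + 0.5)
  structure(list(train_ids = sort(perm[seq_len(n_train)]),
                 val_ids = sort(perm[seq.int(n_train + 1L, n_dev)]),
                 test_ids = sort(perm[seq.int(n_dev + 1L, n)]),
                 seed = as.integer(seed),
                 fractions = c(train = 0.64, val = 0.16, test = 0.20)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split (seed %d): %d train / %d val / %d test\n",
              x$seed, length(x$train_ids), length(x$val_ids),
              length(x$test_ids)))
  invisible(x)
}

# A slice is null iff its fraction of nonzero pixels is below this
# threshold; robust to stray interpolation noise in near-empty slices.
NULL_SLICE_THRESHOLD <- 1e-3

null_slice_mask <- function(vol) {
  apply(vol != 0, 3, mean) < NULL_SLICE_THRESHOLD
}

#' Remove null axial slices from a subject
#'
#' An axial slice index is retained iff it contains brain tissue in at
#' least one contrast of the subject; the same retained index set is
#' applied to every contrast so that slice pairing is preserved. Slice
#' order is preserved.
#'
#' @param subject a `subject_record` (or `phantom_subject`).
#' @return the subject with null slices dropped; the retained original
#'   slice indices are stored in attribute `retained_slices`.
#' @export
remove_null_slices <- function(subject) {
  subject <- as.subject_record(subject)
  nulls <- lapply(subject$volumes, function(v) null_slice_mask(v$intensities))
  retain <- which(!Reduce(`&`, nulls))
  if (length(retain) == 0L)
    stop("subject ", subject$subject_id, " has no non-null slices")
  subject$volumes <- lapply(subject$volumes, function(v) {
    v$intensities <- v$intensities[, , retain, drop = FALSE]
    v
  })
  attr(subject, "retained_slices") <- retain
  subject
}

#' Z-score standardisation followed by [0,1] rescaling of one volume
#'
#' Step 1 standardises the volume to zero mean and unit variance using the
#' mean and population standard deviation of the brain (nonzero) voxels of
#' the whole subject volume. Step 2 affinely rescales the standardised
#' volume so its minimum is 0 and its maximum is 1. All four constants are
#' recorded so the transform is exactly invertible (see
#' [inverse_normalization()]).
#'
#' @param volume a `contrast_volume`.
#' @return list with the normalised `volume` and the `record`
#'   (class `normalization_record`).
#' @export
zscore_unit_scale <- function(volume) {
  x <- volume$intensities
  brain <- x != 0
  if (!any(brain)) stop("volume has no brain (nonzero) voxels")
  mu <- mean(x[brain])
  n <- sum(brain)
  sdv <- sqrt(sum((x[brain] - mu)^2) / n)   # population SD
  if (sdv == 0) stop("constant brain intensities: standard deviation is 0")
  z <- (x - mu) / sdv
  lo <- min(z); hi <- max(z)
  if (hi == lo) stop("degenerate volume: constant after standardisation")
  volume$intensities <- (z - lo) / (hi - lo)
  rec <- structure(list(subject_id = volume$subject_id,
                        contrast_name = volume$contrast_name,
                        mean = mu, sd = sdv,
                        post_shift_min = lo, post_shift_max = hi,
                        sd_convention = "population"),
                   class = "normalization_record")
  list(volume = volume, record = rec)
}

#' Invert a recorded intensity normalisation
#'
#' @param values array or vector of normalised intensities in `[0,1]`.
#' @param record a `normalization_record` from [zscore_unit_scale()].
#' @return intensities on the original scale.
#' @export
inverse_normalization <- function(values, record) {
  stopifnot(inherits(record, "normalization_record"))
  z <- values * (record$post_shift_max - record$post_shift_min) +
    record$post_shift_min
  z * record$sd + record$mean
}

#' Resize a 2D slice with bicubic interpolation
#'
#' Keys cubic-convolution resampling (a = -0.5) with edge replication and
#' centre-aligned coordinates. The result is clipped to `[0,1]` to control
#' cubic overshoot, matching the `[0,1]` scale of normalised slices.
#'
#' @param slice 2D numeric matrix with finite values, at least 4x4.
#' @param out_shape integer pair `(rows, cols)`, default `c(224, 224)`.
#' @param clip clip range, or NULL to disable clipping.
#' @return resized matrix of dimension `out_shape`.
#' @export
resize_slice <- function(slice, out_shape = c(224L, 224L), clip = c(0, 1)) {
  stopifnot(is.matrix(slice), all(dim(slice) >= 4L), length(out_shape) == 2L)
  if (any(!is.finite(slice))) stop("slice contains non-finite values")
  out <- resize_bicubic(slice, as.integer(out_shape[1]),
                        as.integer(out_shape[2]))
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  out
}

#' Preprocess a subject: null-slice removal, normalisation, resizing
#'
#' Applies the pipeline in the order: remove null slices (union rule over
#' contrasts), z-score + `[0,1]` normalisation per contrast volume, then
#' bicubic resizing of each retained axial slice to `slice_shape`.
#'
#' @param subject a `subject_record` or `phantom_subject`.
#' @param slice_shape target in-plane shape, default `c(224, 224)`.
#' @return list with `subject` (slices resized, intensities in `[0,1]`),
#'   `records` (named list of `normalization_record`), and
#'   `retained_slices` (original axial indices kept).
#' @export
preprocess_subject <- function(subject, slice_shape = c(224L, 224L)) {
  subject <- remove_null_slices(subject)
  retained <- attr(subject, "retained_slices")
  records <- list()
  subject$volumes <- lapply(subject$volumes, function(v) {
    zs <- zscore_unit_scale(v)
    records[[v$contrast_name]] <<- zs$record
    v <- zs$volume
    nz <- dim(v$intensities)[3]
    out <- array(0, dim = c(slice_shape, nz))
    for (k in seq_len(nz))
      out[, , k] <- resize_slice(v$intensities[, , k], slice_shape)
    v$intensities <- out
    v
  })
  list(subject = subject, records = records, retained_slices = retained)
}

#' Build an aligned source/target slice-pair dataset
#'
#' One pair per retained slice per subject, ordered by subject id then
#' slice index. Subjects must already be preprocessed (values in `[0,1]`,
#' common slice shape).
#'
#' @param subjects list of preprocessed `subject_record`s, or the output
#'   list of [preprocess_subject()] per subject.
#' @param source,target contrast names, e.g. `"T1"`, `"T2"`.
#' @return object of class `slice_pair_dataset`: list with 3D arrays
#'   `source` and `target` of shape `(H, W, n_pairs)`, a `provenance`
#'   data frame (`subject_id`, `slice_index`), and the contrast names.
#' @export
build_slice_pairs <- function(subjects, source, target) {
  stopifnot(source != target)
  subs <- lapply(subjects, function(s) {
    ret <- NULL
    if (!is.null(s$subject)) { ret <- s$retained_slices; s <- s$subject }
    s <- as.subject_record(s)
    if (is.null(ret)) ret <- attr(s, "retained_slices")
    if (is.null(ret)) ret <- seq_len(dim(s$volumes[[1]]$intensities)[3])
    list(rec = s, retained = ret)
  })
  ord <- order(vapply(subs, function(s) s$rec$subject_id, character(1)))
  subs <- subs[ord]
  for (s in subs)
    if (!all(c(source, target) %in% names(s$rec$volumes)))
      stop("subject ", s$rec$subject_id, " lacks contrast ", source,
           " or ", target)
  sh <- dim(subs[[1]]$rec$volumes[[source]]$intensities)[1:2]
  n_tot <- sum(vapply(subs, function(s)
    dim(s$rec$volumes[[source]]$intensities)[3], numeric(1)))
  src <- array(0, dim = c(sh, n_tot))
  tgt <- array(0, dim = c(sh, n_tot))
  prov <- vector("list", length(subs))
  at <- 0L
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    xs <- s$rec$volumes[[source]]$intensities
    xt <- s$rec$volumes[[target]]$intensities
    k <- dim(xs)[3]
    src[, , at + seq_len(k)] <- xs
    tgt[, , at + seq_len(k)] <- xt
    prov[[i]] <- data.frame(subject_id = s$rec$subject_id,
                            slice_index = s$retained,
                            stringsAsFactors = FALSE)
    at <- at + k
  }
  structure(list(source = src, target = tgt,
                 source_contrast = source, target_contrast = target,
                 provenance = do.call(rbind, prov)),
            class = "slice_pair_dataset")
}

#' @export
print.slice_pair_dataset <- function(x, ...) {
  cat(sprintf("slice pair dataset %s -> %s: %d pairs of %dx%d slices (%d subjects)\n",
              x$source_contrast, x$target_contrast, dim(x$source)[3],
              dim(x$source)[1], dim(x$source)[2],
              length(unique(x$provenance$subject_id))))
  invisible(x)
}

#' @export
length.slice_pair_dataset <- function(x) dim(x$source)[3]

#' Write a slice-pair dataset to disk
#'
#' Emits the paired arrays as an RDS container plus a CSV manifest with
#' one row per pair (`subject_id`, `slice_index`).
#'
#' @param dataset a `slice_pair_dataset`.
#' @param dir output directory.
#' @return invisible paths of the written files.
#' @export
write_slice_pairs <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_to_%s", dataset$source_contrast,
                  dataset$target_contrast)
  data_path <- file.path(dir, paste0(stem, "_pairs.rds"))
  manifest_path <- file.path(dir, paste0(stem, "_manifest.csv"))
  saveRDS(dataset, data_path)
  write.csv(dataset$provenance, manifest_path, row.names = FALSE)
  invisible(c(data_path, manifest_path))
}
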