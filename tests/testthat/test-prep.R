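test_that("two-stage split gives 64/16/20 and is reproducible", {
  ids <- sprintf("s%03d", 1:100)
  sp <- split_dataset(ids, seed = 5)
  expect_length(sp$train_ids, 64)
  expect_length(sp$val_ids, 16)
  expect_length(sp$test_ids, 20)
  expect_identical(sp, split_dataset(ids, seed = 5))
  expect_false(identical(sp$test_ids, split_dataset(ids, seed = 6)$test_ids))
})

test_that("split is disjoint and exhaustive for arbitrary sizes", {
  for (n in c(5, 9, 100, 477)) {
    ids <- sprintf("p%04d", seq_len(n))
    sp <- split_dataset(ids, seed = n)
    all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_length(all_ids, n)
    expect_setequal(all_ids, ids)
    expect_equal(anyDuplicated(all_ids), 0)
    # proportions within one subject of nominal
    expect_lte(abs(length(sp$test_ids) - 0.20 * n), 1)
    expect_lte(abs(length(sp$val_ids) - 0.16 * n), 1)
  }
  # documented rounding rule at the clinical cohort size
  sp <- split_dataset(sprintf("p%04d", 1:477), seed = 1)
  expect_length(sp$test_ids, round(477 * 0.20))
  expect_length(sp$train_ids, 306)
  expect_length(sp$val_ids, 76)
  expect_error(split_dataset(letters[1:4]), "at least 5")
})

test_that("null-slice removal uses the union rule and preserves pairing", {
  cfg <- phantom_config(grid_shape = c(64, 64, 40), n_null_slices = c(4, 4),
                        seed = 7, lesion_probability = 1)
  s <- generate_paired_subject(cfg)
  out <- remove_null_slices(s)
  dims <- vapply(out$volumes, function(v) dim(v$intensities)[3], numeric(1))
  expect_true(all(dims == 32))
  expect_identical(attr(out, "retained_slices"), 5:36)

  # slice null in T1 but non-null in T2 is retained in both
  t1 <- array(0, dim = c(8, 8, 3)); t2 <- array(0, dim = c(8, 8, 3))
  t1[, , 2] <- 0.5
  t2[, , 2] <- 0.4; t2[, , 3] <- 0.4
  rec <- subject_record("u", list(T1 = as_cvol(t1, "T1"),
                                  T2 = as_cvol(t2, "T2")))
  out <- remove_null_slices(rec)
  expect_identical(attr(out, "retained_slices"), 2:3)
  expect_equal(dim(out$volumes$T1$intensities)[3], 2)

  # no null slices: identity
  full <- array(runif(8 * 8 * 3, 0.1, 1), dim = c(8, 8, 3))
  rec <- subject_record("v", list(T1 = as_cvol(full, "T1"),
                                  T2 = as_cvol(full, "T2")))
  expect_equal(dim(remove_null_slices(rec)$volumes$T1$intensities)[3], 3)

  # all-null subject errors
  z <- array(0, dim = c(8, 8, 3))
  rec <- subject_record("w", list(T1 = as_cvol(z, "T1"),
                                  T2 = as_cvol(z, "T2")))
  expect_error(remove_null_slices(rec), "no non-null")
})

test_that("z-score + [0,1] scaling matches the hand-worked example", {
  v <- as_cvol(array(c(1, 2, 3), dim = c(3, 1, 1)))
  zs <- zscore_unit_scale(v)
  expect_equal(as.numeric(zs$volume$intensities), c(0, 0.5, 1),
               tolerance = 1e-12)
  expect_equal(zs$record$mean, 2)
  expect_equal(zs$record$sd, sqrt(2 / 3), tolerance = 1e-12)  # population SD
  expect_equal(zs$record$post_shift_min, -1 / sqrt(2 / 3) * 1,
               tolerance = 1e-9)
})

test_that("normalised volumes span [0,1] and the transform inverts", {
  s <- small_subject(2)
  for (cn in CONTRASTS) {
    zs <- zscore_unit_scale(s$volumes[[cn]])
    x <- zs$volume$intensities
    expect_lt(abs(min(x) - 0), 1e-9)
    expect_lt(abs(max(x) - 1), 1e-9)
    back <- inverse_normalization(x, zs$record)
    orig <- s$volumes[[cn]]$intensities
    expect_lt(max(abs(back - orig)) / max(abs(orig)), 1e-6)
  }
  expect_error(zscore_unit_scale(as_cvol(array(0.7, dim = c(4, 4, 2)))),
               "standard deviation is 0")
})

test_that("normalisation is invariant to positive affine input rescaling", {
  s <- small_subject(1)
  v <- s$volumes$T1
  za <- zscore_unit_scale(v)$volume$intensities
  v2 <- v
  brain <- v$intensities != 0
  v2$intensities[brain] <- 3.7 * v$intensities[brain]   # pure gain change
  zb <- zscore_unit_scale(v2)$volume$intensities
  expect_lt(max(abs(za - zb)), 1e-9)
})

test_that("bicubic resizing preserves constants, hits the target shape, and round-trips", {
  const <- matrix(0.37, 40, 40)
  out <- resize_slice(const, c(25, 31))
  expect_equal(dim(out), c(25, 31))
  expect_true(all(abs(out - 0.37) < 1e-12))

  big <- matrix(runif(240 * 240), 240, 240)
  expect_equal(dim(resize_slice(big, c(224, 224))), c(224, 224))

  # band-limited slice: up then down within 0.02
  g <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64),
             function(u, v) 0.5 + 0.3 * sin(2 * pi * u) * cos(2 * pi * v))
  rt <- resize_slice(resize_slice(g, c(96, 96)), c(64, 64))
  expect_lt(max(abs(rt - g)), 0.02)

  bad <- const; bad[3, 3] <- NA
  expect_error(resize_slice(bad, c(20, 20)), "non-finite")
})

test_that("slice pair assembly counts, bounds and provenance round-trip", {
  cfg <- phantom_config(grid_shape = c(32, 32, 16), n_null_slices = c(2, 2),
                        seed = 3)
  prep <- lapply(1:3, function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i
    preprocess_subject(generate_paired_subject(ci, subject_id = paste0("s", i)),
                       slice_shape = c(32, 32))
  })
  n_slices <- vapply(prep, function(p) length(p$retained_slices), numeric(1))
  ds <- build_slice_pairs(prep, "T1", "T2")
  expect_s3_class(ds, "slice_pair_dataset")
  expect_equal(length(ds), sum(n_slices))
  expect_equal(dim(ds$source)[1:2], c(32, 32))
  expect_true(all(ds$source >= 0 & ds$source <= 1))
  expect_true(all(ds$target >= 0 & ds$target <= 1))
  expect_equal(nrow(ds$provenance), length(ds))

  # provenance round-trip: re-reading the named subject/slice reproduces it
  j <- 7
  pv <- ds$provenance[j, ]
  sub <- prep[[match(pv$subject_id, vapply(prep, function(p)
    p$subject$subject_id, character(1)))]]
  k <- match(pv$slice_index, sub$retained_slices)
  expect_equal(ds$source[, , j], sub$subject$volumes$T1$intensities[, , k])
  expect_equal(ds$target[, , j], sub$subject$volumes$T2$intensities[, , k])

  expect_error(build_slice_pairs(prep, "T1", "T1"))
  p2 <- prep
  p2[[1]]$subject$volumes$FLAIR <- NULL
  expect_error(build_slice_pairs(p2, "T1", "FLAIR"), "lacks contrast")
})

test_that("slice pair datasets serialise with a manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(grid_shape = c(32, 32, 16), n_null_slices = c(1, 1),
                        seed = 9)
  prep <- preprocess_subject(generate_paired_subject(cfg, subject_id = "sA"),
                             slice_shape = c(32, 32))
  ds <- build_slice_pairs(list(prep), "T2", "FLAIR")
  paths <- write_slice_pairs(ds, dir)
  expect_true(all(file.exists(file.path(dir, "T2_to_FLAIR_pairs.rds"),
                              file.path(dir, "T2_to_FLAIR_manifest.csv"))))
  man <- read.csv(file.path(dir, "T2_to_FLAIR_manifest.csv"))
  expect_equal(nrow(man), length(ds))
})
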