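#' Metric configuration
#'
#' @param i_max peak intensity of the image scale (1.0 for `[0,1]`-scaled
#'   images); enters PSNR and the SSIM stabilising constants.
#' @param ssim_k1,ssim_k2 SSIM constants; `C1 = (k1*i_max)^2`,
#'   `C2 = (k2*i_max)^2`.
#' @param ssim_map_window odd window size (>= 3) for the local SSIM map.
#' @param aggregation_unit `"slice"` or `"subject"`: the unit over which
#'   metrics are computed before mean +/- SD aggregation.
#' @return object of class `metric_config`.
#' @export
metric_config <- function(i_max = 1.0, ssim_k1 = 0.01, ssim_k2 = 0.03,
                          ssim_map_window = 7L,
                          aggregation_unit = c("slice", "subject")) {
  stopifnot(i_max > 0, ssim_map_window >= 3L, ssim_map_window %% 2L == 1L)
  structure(list(i_max = i_max, ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 C1 = (ssim_k1 * i_max)^2, C2 = (ssim_k2 * i_max)^2,
                 ssim_map_window = as.integer(ssim_map_window),
                 aggregation_unit = match.arg(aggregation_unit)),
            class = "metric_config")
}

check_pair <- function(x, y) {
  if (!all(dim(x) == dim(y)) || length(x) != length(y))
    stop("images must have identical shape")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("images must be finite")
}

#' Mean absolute error between two images
#' @param x ground-truth image (any dimension).
#' @param y predicted image of identical shape.
#' @return mean of `|y - x|` over all pixels.
#' @export
mae <- function(x, y) { check_pair(x, y); mean(abs(y - x)) }

#' Mean squared error between two images
#' @inheritParams mae
#' @return mean of `(y - x)^2` over all pixels.
#' @export
mse <- function(x, y) { check_pair(x, y); mean((y - x)^2) }

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(i_max^2 / MSE)`. Identical images (MSE = 0) return the
#' documented sentinel `Inf` rather than an error; report aggregation
#' excludes such values with a logged count.
#'
#' @inheritParams mae
#' @param config a [metric_config()].
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
psnr <- function(x, y, config = metric_config()) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(config$i_max^2 / m)
}

#' Global structural similarity index
#'
#' Single-value SSIM from whole-image means, variances and covariance
#' (population convention, divisor n), with stabilising constants C1, C2
#' from the configuration. Equals 1 for identical images and is symmetric
#' in its arguments.
#'
#' @inheritParams psnr
#' @return SSIM value (<= 1).
#' @export
ssim_global <- function(x, y, config = metric_config()) {
  check_pair(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + config$C1) * (2 * cxy + config$C2)) /
    ((mx^2 + my^2 + config$C1) * (vx + vy + config$C2))
}

# Mean over all w x w windows via integral images; returns the
# (H-w+1) x (W-w+1) valid-region matrix.
box_mean <- function(m, w) {
  S <- rbind(0, cbind(0, apply(apply(m, 2, cumsum), 1, cumsum)))
  S <- t(S)   # S[i+1, j+1] = sum over m[1:i, 1:j]
  H <- nrow(m); W <- ncol(m)
  i <- seq_len(H - w + 1L); j <- seq_len(W - w + 1L)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

#' Local SSIM map
#'
#' Sliding-window SSIM with a uniform square window of size
#' `ssim_map_window`, evaluated over the valid region (output dimension
#' `(H-w+1) x (W-w+1)`; no padding). Window statistics use the population
#' convention, matching [ssim_global()].
#'
#' @inheritParams psnr
#' @return matrix of local SSIM values (all <= 1).
#' @export
ssim_map <- function(x, y, config = metric_config()) {
  check_pair(x, y)
  w <- config$ssim_map_window
  if (w > min(dim(x))) stop("SSIM window larger than the image")
  mx <- box_mean(x, w); my <- box_mean(y, w)
  vx <- box_mean(x^2, w) - mx^2
  vy <- box_mean(y^2, w) - my^2
  cxy <- box_mean(x * y, w) - mx * my
  ((2 * mx * my + config$C1) * (2 * cxy + config$C2)) /
    ((mx^2 + my^2 + config$C1) * (vx + vy + config$C2))
}

#' Per-pixel difference map (predicted minus ground truth)
#' @inheritParams mae
#' @return matrix/array `y - x`.
#' @export
difference_map <- function(x, y) { check_pair(x, y); y - x }

as_slice_array <- function(v) {
  if (inherits(v, "contrast_volume")) v$intensities else v
}

#' Evaluate one translation direction
#'
#' Computes MAE, MSE, PSNR and global SSIM per aggregation unit (axial
#' slice by default, or whole subject volume), then aggregates to mean and
#' SD per metric. Infinite PSNR values (identical pairs) are excluded from
#' the PSNR aggregates and counted in `n_infinite_psnr`.
#'
#' @param pred list of predicted `contrast_volume`s (or 3D slice arrays).
#' @param truth matching list of ground-truth volumes/arrays, preprocessed
#'   identically to the training targets.
#' @param config a [metric_config()].
#' @param direction optional label, e.g. `"T1->T2"`.
#' @return object of class `metric_report`: `rows` (per-unit data frame),
#'   `aggregates` (mean/sd per metric), `n_infinite_psnr`, `direction`.
#' @export
evaluate_direction <- function(pred, truth, config = metric_config(),
                               direction = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  rows <- list()
  for (i in seq_along(pred)) {
    p <- as_slice_array(pred[[i]]); t <- as_slice_array(truth[[i]])
    check_pair(p, t)
    id <- if (inherits(pred[[i]], "contrast_volume"))
      pred[[i]]$subject_id else sprintf("unit%03d", i)
    if (config$aggregation_unit == "subject" || length(dim(p)) == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, slice_index = NA_integer_,
        MAE = mae(t, p), MSE = mse(t, p), PSNR = psnr(t, p, config),
        SSIM = ssim_global(t, p, config), stringsAsFactors = FALSE)
    } else {
      for (k in seq_len(dim(p)[3])) {
        pk <- p[, , k]; tk <- t[, , k]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, slice_index = k,
          MAE = mae(tk, pk), MSE = mse(tk, pk),
          PSNR = psnr(tk, pk, config),
          SSIM = ssim_global(tk, pk, config), stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  if (nrow(rows) == 0L) stop("no units to evaluate")
  fin <- is.finite(rows$PSNR)
  agg <- data.frame(
    metric = c("MAE", "MSE", "PSNR", "SSIM"),
    mean = c(mean(rows$MAE), mean(rows$MSE), mean(rows$PSNR[fin]),
             mean(rows$SSIM)),
    sd = c(sd_or_zero(rows$MAE), sd_or_zero(rows$MSE),
           sd_or_zero(rows$PSNR[fin]), sd_or_zero(rows$SSIM)),
    stringsAsFactors = FALSE)
  structure(list(direction = direction, rows = rows, aggregates = agg,
                 n_infinite_psnr = sum(!fin), config = config),
            class = "metric_report")
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("Metric report%s: %d %s units\n",
              if (is.null(x$direction)) "" else paste0(" ", x$direction),
              nrow(x$rows), x$config$aggregation_unit))
  a <- x$aggregates
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-5s %s ± %s\n", a$metric[i],
                formatC(a$mean[i], digits = digits, format = "fg"),
                formatC(a$sd[i], digits = digits, format = "fg")))
  if (x$n_infinite_psnr > 0)
    cat(sprintf("  (%d identical pair(s) excluded from PSNR aggregate)\n",
                x$n_infinite_psnr))
  invisible(x)
}

#' Assemble reports into a six-direction mean +/- SD table
#'
#' One row per translation direction, columns PSNR (dB), MAE, MSE and SSIM
#' formatted as `mean ± SD` — the shape of a standard multi-direction
#' synthesis results table.
#'
#' @param reports named list of `metric_report`s (names or `direction`
#'   fields label the rows).
#' @param digits significant digits in the formatted entries.
#' @return data frame with one row per direction.
#' @export
report_table <- function(reports, digits = 4) {
  fmt <- function(m, s) sprintf("%s ± %s",
                                formatC(m, digits = digits, format = "fg"),
                                formatC(s, digits = digits, format = "fg"))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    a <- r$aggregates
    g <- function(met) fmt(a$mean[a$metric == met], a$sd[a$metric == met])
    data.frame(Translation = if (!is.null(names(reports)) &&
                                 nzchar(names(reports)[i]))
                 names(reports)[i] else r$direction,
               PSNR_dB = g("PSNR"), MAE = g("MAE"), MSE = g("MSE"),
               SSIM = g("SSIM"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a metric report to CSV and JSON
#'
#' @param report a `metric_report`.
#' @param stem output path stem; writes `<stem>_rows.csv`,
#'   `<stem>_aggregates.csv` and `<stem>.json`.
#' @return invisible vector of written paths.
#' @export
write_metric_report <- function(report, stem) {
  pr <- paste0(stem, "_rows.csv"); pa <- paste0(stem, "_aggregates.csv")
  write.csv(report$rows, pr, row.names = FALSE)
  write.csv(report$aggregates, pa, row.names = FALSE)
  paths <- c(pr, pa)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    pj <- paste0(stem, ".json")
    jsonlite::write_json(list(direction = report$direction,
                              aggregates = report$aggregates,
                              n_infinite_psnr = report$n_infinite_psnr),
                         pj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pj)
  }
  invisible(paths)
}

#' Save a comparison panel figure for one slice
#'
#' Five panels: source slice, synthetic slice, ground truth, difference
#' map (predicted minus real) and local SSIM map.
#'
#' @param source,synthetic,truth 2D matrices on the `[0,1]` scale.
#' @param path output PNG path.
#' @param config a [metric_config()] (controls the SSIM map window).
#' @return invisible `path`.
#' @export
save_panel_figure <- function(source, synthetic, truth, path,
                              config = metric_config()) {
  grDevices::png(path, width = 1500, height = 320)
  op <- graphics::par(mfrow = c(1, 5), mar = c(1, 1, 3, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  show <- function(m, main, zlim = NULL, col = grDevices::gray.colors(256,
                                                                      0, 1)) {
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, main = main,
                    zlim = zlim, col = col, useRaster = TRUE)
  }
  show(source, "source", c(0, 1))
  show(synthetic, "synthetic", c(0, 1))
  show(truth, "ground truth", c(0, 1))
  dm <- difference_map(truth, synthetic)
  show(dm, "difference (pred - real)", c(-1, 1),
       grDevices::hcl.colors(256, "Blue-Red"))
  show(ssim_map(truth, synthetic, config), "SSIM map", c(-1, 1))
  invisible(path)
}
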