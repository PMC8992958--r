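# Brute-force per-pixel oracles, kept deliberately independent of the
# package implementations.
oracle_mae <- function(x, y) { s <- 0; for (i in seq_along(x))
  s <- s + abs(y[i] - x[i]); s / length(x) }
oracle_mse <- function(x, y) { s <- 0; for (i in seq_along(x))
  s <- s + (y[i] - x[i])^2; s / length(x) }
oracle_ssim <- function(x, y, C1 = 0.01^2, C2 = 0.03^2) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

test_that("MAE and MSE match hand arithmetic and identity cases", {
  x <- matrix(c(0, 0.5), 1); y <- matrix(c(0.1, 0.3), 1)
  expect_equal(mae(x, y), 0.15, tolerance = 1e-15)
  expect_equal(mse(x, y), 0.025, tolerance = 1e-15)
  z <- matrix(runif(16), 4)
  expect_equal(mae(z, z), 0)
  expect_equal(mse(z, z), 0)
  expect_error(mae(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("PSNR follows the closed form with an infinity sentinel at zero MSE", {
  cfg <- metric_config()
  x <- matrix(0, 10, 10); y <- x; y[1:5, ] <- 0.2 * sqrt(2) / sqrt(10)
  expect_equal(psnr(x, y, cfg), 10 * log10(1 / mse(x, y)), tolerance = 1e-12)
  # MSE 0.0005 -> 33.0103 dB; MSE 0.01 -> 20 dB
  mk <- function(m) matrix(sqrt(m), 2, 2)
  expect_equal(psnr(matrix(0, 2, 2), mk(0.0005)), 33.0103, tolerance = 1e-4)
  expect_equal(psnr(matrix(0, 2, 2), mk(0.01)), 20, tolerance = 1e-12)
  expect_identical(psnr(x, x, cfg), Inf)
})

test_that("all four metrics agree with pixel-loop oracles on seeded pairs", {
  set.seed(99)
  cfg <- metric_config()
  for (rep in 1:50) {
    x <- matrix(runif(64), 8, 8)
    y <- matrix(runif(64), 8, 8)
    expect_equal(mae(x, y), oracle_mae(x, y), tolerance = 1e-12)
    expect_equal(mse(x, y), oracle_mse(x, y), tolerance = 1e-12)
    expect_equal(psnr(x, y, cfg), 10 * log10(1 / oracle_mse(x, y)),
                 tolerance = 1e-12)
    expect_equal(ssim_global(x, y, cfg), oracle_ssim(x, y),
                 tolerance = 1e-12)
    expect_equal(ssim_global(x, y, cfg), ssim_global(y, x, cfg))
  }
})

test_that("global SSIM is 1 for identical images and bounded by 1", {
  x <- matrix(runif(400), 20, 20)
  expect_equal(ssim_global(x, x), 1, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
    expect_lte(ssim_global(a, b), 1)
  }
})

test_that("metrics are permutation-invariant over pixels", {
  set.seed(8)
  x <- matrix(runif(144), 12); y <- matrix(runif(144), 12)
  p <- sample(144)
  xp <- matrix(x[p], 12); yp <- matrix(y[p], 12)
  expect_equal(mae(x, y), mae(xp, yp))
  expect_equal(mse(x, y), mse(xp, yp))
  expect_equal(ssim_global(x, y), ssim_global(xp, yp), tolerance = 1e-12)
})

test_that("SSIM map matches a windowed oracle over the valid region", {
  set.seed(12)
  cfg <- metric_config(ssim_map_window = 7)
  x <- matrix(runif(30 * 26), 30, 26)
  y <- pmin(pmax(x + rnorm(30 * 26, sd = 0.1), 0), 1)
  m <- ssim_map(x, y, cfg)
  expect_equal(dim(m), c(24, 20))
  expect_true(all(m <= 1 + 1e-12))
  # direct windowed evaluation
  oracle <- matrix(0, 24, 20)
  for (i in 1:24) for (j in 1:20)
    oracle[i, j] <- oracle_ssim(x[i:(i + 6), j:(j + 6)],
                                y[i:(i + 6), j:(j + 6)])
  expect_lt(abs(mean(m) - mean(oracle)), 1e-9)
  expect_lt(max(abs(m - oracle)), 1e-9)
  expect_true(all(ssim_map(x, x, cfg) == 1))
  expect_gte(mean(m), min(m)); expect_lte(mean(m), max(m))
  expect_error(ssim_map(matrix(0, 5, 5), matrix(0, 5, 5), cfg), "window")
})

test_that("difference maps are signed residuals and vanish iff identical", {
  x <- matrix(runif(25), 5); y <- matrix(runif(25), 5)
  expect_equal(difference_map(x, y), y - x)
  expect_true(all(difference_map(x, x) == 0))
})

test_that("direction evaluation aggregates correctly and is self-consistent", {
  set.seed(21)
  pred <- array(runif(16 * 16 * 6), dim = c(16, 16, 6))
  truth <- pmin(pmax(pred + rnorm(length(pred), sd = 0.05), 0), 1)
  rep <- evaluate_direction(pred, truth, direction = "T1->T2")
  expect_equal(nrow(rep$rows), 6)
  a <- rep$aggregates
  expect_equal(a$mean[a$metric == "MAE"], mean(rep$rows$MAE),
               tolerance = 1e-12)
  expect_equal(a$sd[a$metric == "SSIM"], sd(rep$rows$SSIM),
               tolerance = 1e-12)
  # Jensen: MAE^2 <= MSE per unit
  expect_true(all(rep$rows$MAE^2 <= rep$rows$MSE + 1e-15))
  # PSNR-MSE identity per unit
  expect_equal(rep$rows$PSNR, 10 * log10(1 / rep$rows$MSE),
               tolerance = 1e-12)

  ident <- evaluate_direction(pred, pred)
  expect_true(all(ident$rows$MAE == 0))
  expect_true(all(ident$rows$MSE == 0))
  expect_equal(ident$rows$SSIM, rep(1, 6), tolerance = 1e-12)
  expect_equal(ident$n_infinite_psnr, 6)
  expect_true(all(ident$aggregates$sd[ident$aggregates$metric
                                      %in% c("MAE", "MSE", "SSIM")] == 0))
})

test_that("per-subject aggregation treats a volume as one unit", {
  set.seed(3)
  pred <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  truth <- array(runif(8 * 8 * 5), dim = c(8, 8, 5))
  rep <- evaluate_direction(pred, truth,
                            metric_config(aggregation_unit = "subject"))
  expect_equal(nrow(rep$rows), 1)
  expect_equal(rep$rows$MAE, mae(truth, pred))
})

test_that("report table has the six-direction mean +/- SD shape", {
  set.seed(5)
  dirs <- c("T1->T2", "T2->T1", "T1->FLAIR", "FLAIR->T1",
            "T2->FLAIR", "FLAIR->T2")
  reports <- lapply(dirs, function(d) {
    p <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
    t <- pmin(pmax(p + rnorm(length(p), sd = 0.03), 0), 1)
    evaluate_direction(p, t, direction = d)
  })
  names(reports) <- dirs
  tab <- report_table(reports)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("Translation", "PSNR_dB", "MAE", "MSE", "SSIM"))
  expect_true(all(grepl("±", tab$SSIM)))
})

test_that("panel figures and report files are written", {
  dir <- withr::local_tempdir()
  set.seed(9)
  x <- matrix(runif(32 * 32), 32); y <- pmin(pmax(x + 0.05, 0), 1)
  p <- file.path(dir, "panels.png")
  save_panel_figure(x, y, x, p)
  expect_true(file.exists(p) && file.size(p) > 0)
  rep <- evaluate_direction(array(x, c(32, 32, 1)), array(y, c(32, 32, 1)))
  paths <- write_metric_report(rep, file.path(dir, "m"))
  expect_true(all(file.exists(file.path(dir, c("m_rows.csv",
                                               "m_aggregates.csv")))))
})
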