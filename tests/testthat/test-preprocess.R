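test_that("moving-average smoothing behaves on identity, constant and impulse inputs", {
  s <- tibble::tibble(mz = 1:9 + 100, intensity = c(0, 0, 0, 0, 9, 0, 0, 0, 0))
  expect_equal(smooth_spectrum(s, 1), tibble::as_tibble(s))
  const <- tibble::tibble(mz = 1:11 + 100, intensity = rep(5, 11))
  expect_equal(smooth_spectrum(const, 5)$intensity, rep(5, 11))
  sm <- smooth_spectrum(s, 3)
  expect_equal(sm$intensity[4:6], c(3, 3, 3))
  expect_equal(sm$mz, s$mz)
  expect_equal(sum(sm$intensity), sum(s$intensity)) # impulse away from edges
  expect_error(smooth_spectrum(s, 11), "larger than spectrum")
  expect_error(smooth_spectrum(s, 4))
})

test_that("rolling-minimum baseline correction recovers peaks on sloped baselines", {
  z <- tibble::tibble(mz = 1:50 + 100, intensity = rep(0, 50))
  expect_equal(baseline_correct(z, 5)$intensity, rep(0, 50))
  # constant offset is removed entirely
  flat <- tibble::tibble(mz = 1:50 + 100, intensity = rep(7, 50))
  expect_equal(min(baseline_correct(flat, 5)$intensity), 0)
  # linear ramp plus one peak
  mz <- seq(400, 402, by = 0.01)
  ramp <- 5 + 2 * (mz - 400)
  peak <- 80 * exp(-(mz - 401)^2 / (2 * 0.02^2))
  s <- tibble::tibble(mz = mz, intensity = ramp + peak)
  corrected <- baseline_correct(s, half_window = 30)
  expect_true(all(corrected$intensity >= 0))
  expect_equal(max(corrected$intensity), 80, tolerance = 0.05)
})

test_that("peak picking finds centroids at sub-ppm accuracy", {
  expect_equal(nrow(pick_peaks(tibble::tibble(mz = 1:20 + 100, intensity = rep(0, 20)))), 0)
  s <- gaussian_spectrum(center = 500, sigma = 0.01, height = 100)
  pk <- pick_peaks(s, snr = 3)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(ppm_error(pk$mz, 500)), 1)
  two <- gaussian_spectrum(500, 0.01, 100, from = 499, to = 502)
  two$intensity <- two$intensity + 100 * exp(-(two$mz - 501)^2 / (2 * 0.01^2))
  pk2 <- pick_peaks(two, snr = 3)
  expect_equal(nrow(pk2), 2)
  expect_true(all(diff(pk2$mz) > 0))
  expect_lt(abs(ppm_error(pk2$mz[1], 500)), 1)
  expect_lt(abs(ppm_error(pk2$mz[2], 501)), 1)
})

test_that("alignment bins respect the ppm tolerance", {
  mk <- function(mzs) {
    tibble::tibble(
      row = seq_along(mzs), col = 1, mz = mzs,
      intensity = rep(10, length(mzs))
    )
  }
  fm1 <- align_features(mk(c(500.000, 500.003)), tol_ppm = 10, pixel_cols = c("row", "col"))
  expect_equal(nrow(fm1$features), 1) # 6 ppm apart
  fm2 <- align_features(mk(c(500.000, 500.010)), tol_ppm = 10, pixel_cols = c("row", "col"))
  expect_equal(nrow(fm2$features), 2) # 20 ppm apart
  # one pixel: features are its peaks verbatim
  one <- tibble::tibble(row = 1, col = 1, mz = c(200.1, 300.2, 400.3), intensity = c(1, 2, 3))
  fm3 <- align_features(one, tol_ppm = 10, pixel_cols = c("row", "col"))
  expect_equal(fm3$features$mz, one$mz)
  expect_equal(as.vector(fm3$values), one$intensity)
})

test_that("alignment equals single-linkage clustering on well-separated centroids", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    # centroids in clusters: intra-cluster gaps < 0.5 x tol, inter > 3 x tol
    base <- 500
    mzs <- numeric(0)
    while (length(mzs) < n) {
      base <- base * (1 + runif(1, 40e-6, 100e-6))
      k <- min(sample(1:3, 1), n - length(mzs))
      mzs <- c(mzs, base * (1 + cumsum(runif(k, 0, 4e-6))))
    }
    peaks <- tibble::tibble(
      row = seq_along(mzs), col = 1, mz = mzs,
      intensity = runif(length(mzs), 1, 10)
    )
    fm <- align_features(peaks, tol_ppm = 10, pixel_cols = c("row", "col"))
    oracle <- single_linkage_bins(sort(mzs), 10)
    expect_equal(nrow(fm$features), length(unique(oracle)))
  }
})

test_that("mass-range filtering uses inclusive bounds", {
  peaks <- tibble::tibble(
    row = 1, col = 1:4,
    mz = c(99.5, 100.0, 1200.0, 1200.5), intensity = 1
  )
  fm <- align_features(peaks, tol_ppm = 5, pixel_cols = c("row", "col"))
  expect_equal(nrow(mass_range_filter(fm, 100, 1200)$features), 2)
  expect_equal(nrow(mass_range_filter(fm, 1, 2000)$features), 4)
  expect_message(out <- mass_range_filter(fm, 2000, 3000), "removed all")
  expect_equal(nrow(out$features), 0)
})

test_that("TIC normalisation equalises row sums and is idempotent", {
  set.seed(7)
  peaks <- tidyr::crossing(row = 1:6, col = 1:1, j = 1:5) |>
    dplyr::mutate(mz = 100 + .data$j * 50, intensity = stats::runif(30, 1, 100)) |>
    dplyr::select(-"j")
  fm <- align_features(peaks, tol_ppm = 10, pixel_cols = c("row", "col"))
  norm <- tic_normalize(fm)
  rs <- rowSums(norm$values)
  expect_lt(diff(range(rs)) / mean(rs), 1e-9)
  expect_equal(mean(rs), mean(fm$tic))
  # idempotence
  norm2 <- tic_normalize(norm)
  expect_equal(norm2$values, norm$values, tolerance = 1e-12)
  # scale invariance: a pixel that is an exact multiple of another collapses
  # onto it after normalisation
  fm2 <- fm
  fm2$values[3, ] <- 2 * fm2$values[5, ]
  fm2$tic[3] <- 2 * fm2$tic[5]
  norm3 <- tic_normalize(fm2)
  expect_equal(norm3$values[3, ], norm3$values[5, ], tolerance = 1e-12)
  # zero-TIC pixel excluded with warning
  fm3 <- fm
  fm3$values[2, ] <- 0
  fm3$tic[2] <- 0
  expect_warning(norm4 <- tic_normalize(fm3), "zero total ion count")
  expect_equal(nrow(norm4$pixels), 5)
})

test_that("noiseless synthetic data round-trips through preprocessing proportionally", {
  cfg <- noiseless_config(isotopes = FALSE)
  ds <- simulate_dataset(cfg)
  fms <- preprocess_dataset(ds)
  # map each generated (lipid, adduct, isotope) peak to its aligned feature
  for (m in names(fms)) {
    fm <- fms[[m]]
    truth <- ds$peaks[ds$peaks$mode == m, ] |>
      dplyr::group_by(.data$mouse, .data$row, .data$col, .data$mz) |>
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
    lo <- pmax(findInterval(truth$mz, fm$features$mz), 1L)
    hi <- pmin(lo + 1L, nrow(fm$features))
    fi2 <- ifelse(
      abs(fm$features$mz[lo] - truth$mz) <= abs(fm$features$mz[hi] - truth$mz),
      lo, hi
    )
    pk <- paste(truth$mouse, truth$row, truth$col)
    pi <- match(pk, do.call(paste, fm$pixels))
    rec <- fm$values[cbind(pi, fi2)]
    expect_gt(stats::cor(rec, truth$intensity), 0.999)
  }
})
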