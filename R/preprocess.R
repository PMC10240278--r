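# Spectral preprocessing: smoothing, baseline correction, peak picking,
# cross-pixel alignment, mass-range filtering, TIC normalisation.

.check_spectrum <- function(s) {
  stopifnot(is.data.frame(s), all(c("mz", "intensity") %in% names(s)))
  if (nrow(s) > 1 && any(diff(s$mz) <= 0)) {
    stop("spectrum m/z must be strictly increasing", call. = FALSE)
  }
  if (any(s$intensity < 0)) stop("negative intensities", call. = FALSE)
  invisible(s)
}

#' Moving-average smoothing of a profile spectrum
#'
#' @param s A spectrum: data frame with strictly increasing `mz` and
#'   nonnegative `intensity`.
#' @param window Odd number of points; the window shrinks symmetrically at
#'   the spectrum edges.
#' @return The smoothed spectrum (tibble), m/z unchanged.
#' @export
smooth_spectrum <- function(s, window = 5) {
  .check_spectrum(s)
  stopifnot(window >= 1, window %% 2 == 1)
  n <- nrow(s)
  if (window > n) stop("smoothing window larger than spectrum", call. = FALSE)
  hw <- (window - 1) / 2
  cs <- cumsum(c(0, s$intensity))
  i <- seq_len(n)
  lo <- pmax(1, i - hw)
  hi <- pmin(n, i + hw)
  tibble::tibble(mz = s$mz, intensity = (cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

#' Rolling-minimum baseline correction
#'
#' Subtracts, at each point, the minimum intensity within `half_window`
#' points on either side; the result is nonnegative.
#'
#' @inheritParams smooth_spectrum
#' @param half_window Half-width of the rolling window in points (>= 1).
#' @return The baseline-corrected spectrum (tibble).
#' @export
baseline_correct <- function(s, half_window = 50) {
  .check_spectrum(s)
  stopifnot(half_window >= 1)
  n <- nrow(s)
  if (n == 0) return(tibble::as_tibble(s))
  base <- vapply(seq_len(n), function(i) {
    min(s$intensity[max(1, i - half_window):min(n, i + half_window)])
  }, numeric(1))
  tibble::tibble(mz = s$mz, intensity = s$intensity - base)
}

#' Peak picking with SNR threshold and half-maximum centroiding
#'
#' Local maxima whose intensity reaches `snr` times the noise level (the
#' median absolute deviation of the baseline-corrected intensity) are kept;
#' each peak is centroided as the intensity-weighted mean m/z over the
#' contiguous window above half of the apex intensity, and its area is the
#' summed intensity over that window.
#'
#' @inheritParams smooth_spectrum
#' @param snr Signal-to-noise threshold (> 0), default 3.
#' @return A tibble with one row per peak: `mz` (centroid), `intensity`
#'   (area).
#' @export
pick_peaks <- function(s, snr = 3) {
  stopifnot(snr > 0)
  if (nrow(s) == 0) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  .check_spectrum(s)
  y <- s$intensity
  n <- length(y)
  noise <- stats::mad(y)
  threshold <- max(snr * noise, .Machine$double.eps)
  ypad <- c(-Inf, y, -Inf)
  apex <- which(y >= threshold & ypad[seq_len(n)] < y & y >= ypad[seq_len(n) + 2])
  if (!length(apex)) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  out <- lapply(apex, function(a) {
    half <- y[a] / 2
    lo <- a
    while (lo > 1 && y[lo - 1] >= half && y[lo - 1] <= y[lo]) lo <- lo - 1
    hi <- a
    while (hi < n && y[hi + 1] >= half && y[hi + 1] <= y[hi]) hi <- hi + 1
    w <- lo:hi
    c(stats::weighted.mean(s$mz[w], y[w]), sum(y[w]))
  })
  out <- do.call(rbind, out)
  tibble::tibble(mz = out[, 1], intensity = out[, 2])
}

#' Align peak centroids across pixels into a feature matrix
#'
#' Peaks from all pixels are pooled and scanned in ascending m/z; a peak
#' joins the current bin while it lies within `tol_ppm` of the bin's running
#' intensity-weighted mean m/z, otherwise a new bin opens. Each bin becomes
#' one feature with consensus m/z equal to its intensity-weighted mean; a
#' pixel missing a feature holds 0.
#'
#' @param peaks A tibble of centroided peaks with columns `mz`, `intensity`
#'   and the pixel key columns named in `pixel_cols`.
#' @param tol_ppm Alignment tolerance in ppm (> 0), default 10.
#' @param pixel_cols Columns jointly identifying a pixel.
#' @return A `feature_matrix` object: list with `values` (pixels x features),
#'   `pixels` (tibble of pixel keys), `features` (tibble `feature_id`, `mz`),
#'   `tic` (per-pixel total ion count before normalisation) and `mode`
#'   attribute-style field copied from the peaks if present.
#' @export
align_features <- function(peaks, tol_ppm = 10,
                           pixel_cols = intersect(
                             c("mouse", "row", "col"),
                             names(peaks)
                           )) {
  stopifnot(tol_ppm > 0, all(c("mz", "intensity") %in% names(peaks)))
  stopifnot(length(pixel_cols) >= 1)
  ord <- order(peaks$mz)
  mz <- peaks$mz[ord]
  inten <- peaks$intensity[ord]
  bins <- .bin_scan(mz, inten, tol_ppm)
  n_feat <- if (length(bins)) max(bins) else 0L

  wsum <- rowsum(inten, bins)
  consensus <- rowsum(mz * inten, bins) / ifelse(wsum > 0, wsum, 1)

  pixels <- dplyr::distinct(peaks[, pixel_cols, drop = FALSE])
  pixels <- dplyr::arrange(pixels, dplyr::across(dplyr::all_of(pixel_cols)))
  key <- do.call(paste, c(peaks[ord, pixel_cols, drop = FALSE], sep = "\r"))
  pkey <- do.call(paste, c(pixels, sep = "\r"))
  pxi <- match(key, pkey)

  values <- as.matrix(Matrix::sparseMatrix(
    i = pxi, j = bins, x = inten,
    dims = c(nrow(pixels), n_feat)
  ))
  mode <- if ("mode" %in% names(peaks) && nrow(peaks)) peaks$mode[1] else NA_character_
  structure(
    list(
      values = values,
      pixels = pixels,
      features = tibble::tibble(
        feature_id = sprintf("F%04d", seq_len(n_feat)),
        mz = as.vector(consensus)
      ),
      tic = rowSums(values),
      mode = mode,
      normalized = FALSE
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$pixels), " pixels x ", nrow(x$features),
    " features (", ifelse(is.na(x$mode), "?", x$mode), " mode",
    if (isTRUE(x$normalized)) ", TIC-normalised", ")\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn align_features Long-format view of a feature matrix.
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$pixels)
  long <- long[rep(seq_len(nrow(long)), times = nrow(x$features)), ]
  long$feature_id <- rep(x$features$feature_id, each = nrow(x$pixels))
  long$mz <- rep(x$features$mz, each = nrow(x$pixels))
  long$intensity <- as.vector(x$values)
  long
}

#' Restrict a feature matrix to an acquired mass range
#'
#' @param fm A `feature_matrix`.
#' @param lo,hi Inclusive m/z bounds in Da (`lo < hi`).
#' @return The filtered `feature_matrix`.
#' @export
mass_range_filter <- function(fm, lo = 100, hi = 1200) {
  stopifnot(inherits(fm, "feature_matrix"), lo < hi)
  keep <- fm$features$mz >= lo & fm$features$mz <= hi
  if (!any(keep)) message("mass-range filter removed all features")
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$features <- fm$features[keep, , drop = FALSE]
  fm
}

#' Total-ion-count normalisation
#'
#' Scales each pixel's row so its feature sum equals the mean
#' pre-normalisation total ion count across pixels, preserving relative
#' intensities within a pixel. Pixels with zero TIC are excluded with a
#' warning.
#'
#' @param fm A `feature_matrix`.
#' @return The normalised `feature_matrix` (idempotent).
#' @export
tic_normalize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  rs <- rowSums(fm$values)
  bad <- fm$tic <= 0 | rs <= 0
  if (any(bad)) {
    warning(sum(bad), " pixel(s) with zero total ion count excluded")
    fm$values <- fm$values[!bad, , drop = FALSE]
    fm$pixels <- fm$pixels[!bad, , drop = FALSE]
    fm$tic <- fm$tic[!bad]
    rs <- rs[!bad]
  }
  target <- mean(fm$tic)
  fm$values <- fm$values * (target / rs)
  fm$normalized <- TRUE
  fm
}

#' Preprocess a simulated (or centroided) dataset into feature matrices
#'
#' Runs, per ionisation mode: cross-pixel alignment, mass-range filtering to
#' the acquired range, and TIC normalisation. Input spectra are centroided;
#' for profile data apply [smooth_spectrum()], [baseline_correct()] and
#' [pick_peaks()] per pixel first.
#'
#' @param dataset A `lobule_msi` object (or a peaks tibble with `mode`,
#'   pixel keys, `mz`, `intensity`).
#' @param tol_ppm Alignment tolerance in ppm (default 10).
#' @param mz_range Inclusive mass range in Da (default taken from the
#'   dataset's configuration, else `c(100, 1200)`).
#' @param normalize TIC-normalise (default `TRUE`).
#' @return A named list of `feature_matrix` objects, one per mode.
#' @export
preprocess_dataset <- function(dataset, tol_ppm = 10, mz_range = NULL,
                               normalize = TRUE) {
  peaks <- if (inherits(dataset, "lobule_msi")) dataset$peaks else dataset
  if (is.null(mz_range)) {
    mz_range <- if (inherits(dataset, "lobule_msi")) {
      dataset$config$mz_range
    } else {
      c(100, 1200)
    }
  }
  modes <- unique(peaks$mode)
  out <- lapply(modes, function(m) {
    fm <- align_features(peaks[peaks$mode == m, ], tol_ppm = tol_ppm)
    fm <- mass_range_filter(fm, mz_range[1], mz_range[2])
    if (normalize) fm <- tic_normalize(fm)
    fm
  })
  names(out) <- modes
  out
}
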