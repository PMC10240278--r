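# Synthetic DESI-MSI lobule generator: known zonal lipid effects, mouse-level
# random effects, multiplicative pixel noise, per-pixel TIC variation,
# adduct formation and M+1 isotopologues.

#' Configuration of the synthetic lobule dataset
#'
#' The defaults emulate the study conditions the pipeline is designed for:
#' five mice, positive- and negative-mode acquisitions over m/z 100-1200 at
#' 50-micrometre pixels, a 269-lipid library of which 117 carry a non-flat
#' zonal profile, and multiplicative log-normal noise at three levels
#' (between-mouse, per-pixel, per-pixel total ion count).
#'
#' @param n_mice Number of mice (>= 2, default 5).
#' @param library Lipid library tibble (default [hepatic_lipid_library()]).
#' @param geometry A [lobule_geometry()] (default 40 x 40 grid, 50 um pixels).
#' @param mouse_sd SD of the log-normal mouse random intercept, drawn per
#'   (mouse, lipid) (default 0.3).
#' @param noise_sd SD of the per-(pixel, lipid) multiplicative log-normal
#'   noise (default 0.4).
#' @param tic_sd SD of the per-pixel log-normal total-ion-count scale
#'   (default 0.25).
#' @param mass_error_ppm SD of the per-peak relative m/z jitter in ppm
#'   (default 2).
#' @param n_background Named counts of zone-flat background (chemical-noise)
#'   ions per mode (default 500 positive, 250 negative). Their m/z are drawn
#'   uniformly over `mz_range`, at least 30 ppm away from every library
#'   adduct and M+1 position, so they can never be annotated; they emulate
#'   the untargeted feature space, which in real acquisitions far exceeds
#'   the annotatable lipids and dominates the total ion count.
#' @param background_presence Probability that a background ion appears in a
#'   given pixel (default 0.6).
#' @param background_tic_share Expected ratio of total background signal to
#'   total lipid signal per pixel (default 2).
#' @param adduct_weights Named list subclass -> named weight vector; default
#'   [class_adduct_weights()] for every subclass present in the library.
#' @param mz_range Acquired mass range in Da (default `c(100, 1200)`).
#' @param isotopes Emit M+1 isotopologue peaks at the natural 13C ratio
#'   (default `TRUE`).
#' @param modes Ionisation modes to acquire (default both).
#' @param seed Integer RNG seed (default 2023).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mice = 5, library = hepatic_lipid_library(),
                             geometry = lobule_geometry(c(40, 40)),
                             mouse_sd = 0.3, noise_sd = 0.4, tic_sd = 0.25,
                             mass_error_ppm = 2, adduct_weights = NULL,
                             n_background = c(positive = 500, negative = 250),
                             background_presence = 0.6,
                             background_tic_share = 2,
                             mz_range = c(100, 1200), isotopes = TRUE,
                             modes = c("positive", "negative"), seed = 2023) {
  stopifnot(
    n_mice >= 2,
    is.data.frame(library),
    inherits(geometry, "lobule_geometry"),
    mouse_sd >= 0, noise_sd >= 0, tic_sd >= 0, mass_error_ppm >= 0,
    all(n_background >= 0), background_presence > 0, background_presence <= 1,
    background_tic_share >= 0,
    length(mz_range) == 2, mz_range[1] < mz_range[2],
    all(modes %in% c("positive", "negative"))
  )
  if (nrow(library) == 0) stop("empty lipid library", call. = FALSE)
  if (anyDuplicated(library$id)) stop("duplicated lipid ids in library", call. = FALSE)
  if (any(library$base_abundance <= 0)) stop("base_abundance must be > 0", call. = FALSE)
  if (any(pmax(library$z1, library$z2, library$z3) <= 0)) {
    stop("every zone_profile needs a positive entry", call. = FALSE)
  }
  if (is.null(adduct_weights)) {
    adduct_weights <- class_adduct_weights(unique(library$subclass))
  }
  structure(
    list(
      n_mice = as.integer(n_mice), library = library, geometry = geometry,
      mouse_sd = mouse_sd, noise_sd = noise_sd, tic_sd = tic_sd,
      mass_error_ppm = mass_error_ppm, adduct_weights = adduct_weights,
      n_background = n_background, background_presence = background_presence,
      background_tic_share = background_tic_share,
      mz_range = mz_range, isotopes = isotopes, modes = modes,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_mice, " mice, ", nrow(x$library), " lipids (",
    sum(x$library$differential), " differential), grid ",
    x$geometry$grid_shape[1], "x", x$geometry$grid_shape[2],
    ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Lipid x adduct expansion for one mode: one row per emitted monoisotopic
# peak, with its weight and theoretical m/z.
.lipid_adduct_table <- function(library, mode, adduct_weights) {
  lib_m <- library[library$mode == mode, ]
  if (!nrow(lib_m)) return(NULL)
  rows <- lapply(seq_len(nrow(lib_m)), function(i) {
    w <- adduct_weights[[lib_m$subclass[i]]]
    tibble::tibble(
      lipid_id = lib_m$id[i],
      lipid_idx = i,
      adduct = names(w),
      weight = unname(w),
      mz0 = theoretical_mz(lib_m$monoisotopic_mass[i], names(w)),
      n_c = element_count(lib_m$formula[i])
    )
  })
  list(library = lib_m, la = dplyr::bind_rows(rows))
}

#' Simulate a lobule MSI dataset
#'
#' Generates centroided per-pixel spectra for every mouse and ionisation
#' mode. The per-pixel amount of lipid L is
#' `base_abundance * zone_profile[zone] * mouse_factor * noise_factor *
#' tic_factor`; that amount is split across the mode's adducts by the class
#' adduct weights, an M+1 isotopologue is added at the natural 13C ratio,
#' each peak's m/z is jittered by `mass_error_ppm`, and peaks outside
#' `mz_range` are dropped. The same seed reproduces the dataset exactly.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `lobule_msi`: a list with `peaks` (tibble:
#'   `mouse`, `mode`, `row`, `col`, `mz`, `intensity`, plus generator truth
#'   columns `lipid_id`, `adduct`, `isotope`), `zone_map`, `ground_truth`
#'   (list: `zone_mask`, `differential_lipids`, `true_dominant_zone`) and
#'   `config`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(synthetic_config(n_mice = 2))
#' }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  zone_map <- lobule_zone_map(config$geometry)
  px <- zone_map[!is.na(zone_map$zone), ]
  n_px <- nrow(px)
  zone_idx <- as.integer(px$zone) # 1..3
  lib <- config$library

  # Mouse random intercepts, one per (mouse, lipid), shared across adducts.
  mf <- matrix(
    exp(stats::rnorm(config$n_mice * nrow(lib), 0, config$mouse_sd)),
    nrow = config$n_mice,
    dimnames = list(NULL, lib$id)
  )

  mode_tables <- lapply(config$modes, function(mode) {
    .lipid_adduct_table(lib, mode, config$adduct_weights)
  })
  names(mode_tables) <- config$modes
  absent <- setdiff(lib$id, unlist(lapply(mode_tables, function(t) {
    if (is.null(t)) character(0) else t$library$id
  })))
  if (length(absent)) {
    message(length(absent), " lipid(s) have no adduct in the requested mode(s)")
  }

  # Background-ion table per mode: fixed m/z and per-ion base intensity,
  # shared by all mice; scaled so expected background TIC is
  # background_tic_share times the expected lipid TIC.
  bg_tables <- lapply(config$modes, function(mode) {
    n_bg <- config$n_background[[mode]]
    mt <- mode_tables[[mode]]
    if (is.null(n_bg) || n_bg == 0 || is.null(mt)) return(NULL)
    # keep clear of every mode-compatible adduct position (emitted or not,
    # so no background ion can ever be annotated) and of M+1 positions
    rules <- adduct_rules()
    adduct_pos <- as.vector(outer(
      mt$library$monoisotopic_mass,
      rules$mass_shift[rules$mode == mode], "+"
    ))
    lipid_pos <- sort(c(adduct_pos, adduct_pos + .c13_delta))
    mz <- numeric(0)
    while (length(mz) < n_bg) {
      cand <- stats::runif(n_bg, config$mz_range[1], config$mz_range[2])
      i <- findInterval(cand, lipid_pos)
      d_lo <- abs(cand - lipid_pos[pmax(i, 1L)])
      d_hi <- abs(lipid_pos[pmin(i + 1L, length(lipid_pos))] - cand)
      cand <- cand[pmin(d_lo, d_hi) / cand * 1e6 >= 30]
      mz <- c(mz, cand)
    }
    raw <- exp(stats::rnorm(n_bg, 0, 1))
    s_lip <- sum(mt$library$base_abundance *
      (mt$library$z1 + mt$library$z2 + mt$library$z3) / 3)
    tibble::tibble(
      mz0 = sort(mz[seq_len(n_bg)]),
      base = raw * config$background_tic_share * s_lip /
        (sum(raw) * config$background_presence)
    )
  })
  names(bg_tables) <- config$modes

  out <- vector("list", 2L * config$n_mice * length(config$modes))
  k <- 0L
  for (mouse in seq_len(config$n_mice)) {
    for (mode in config$modes) {
      mt <- mode_tables[[mode]]
      if (is.null(mt)) next
      lib_m <- mt$library
      la <- mt$la
      n_l <- nrow(lib_m)
      prof <- as.matrix(lib_m[, c("z1", "z2", "z3")])
      # amount[pixel, lipid] before the adduct split:
      # base_abundance[l] * zone_profile[l, zone(pixel)]
      amount <- t(prof[, zone_idx, drop = FALSE] * lib_m$base_abundance)
      amount <- amount *
        matrix(mf[mouse, lib_m$id], n_px, n_l, byrow = TRUE) *
        exp(matrix(stats::rnorm(n_px * n_l, 0, config$noise_sd), n_px, n_l))
      tic_factor <- exp(stats::rnorm(n_px, 0, config$tic_sd))
      amount <- amount * tic_factor

      # split across adducts
      inten <- amount[, la$lipid_idx, drop = FALSE] *
        matrix(la$weight, n_px, nrow(la), byrow = TRUE)
      n_pk <- n_px * nrow(la)
      mz0 <- matrix(la$mz0, n_px, nrow(la), byrow = TRUE)
      iso <- rep(FALSE, n_pk)
      if (config$isotopes) {
        inten_iso <- inten * matrix(.c13_ratio_per_c * la$n_c, n_px, nrow(la), byrow = TRUE)
        inten <- cbind(inten, inten_iso)
        mz0 <- cbind(mz0, mz0 + .c13_delta)
        iso <- c(iso, rep(TRUE, n_pk))
        n_pk <- 2L * n_pk
      }
      mz <- as.vector(mz0)
      if (config$mass_error_ppm > 0) {
        mz <- mz * (1 + stats::rnorm(n_pk, 0, config$mass_error_ppm) * 1e-6)
      }
      keep <- mz >= config$mz_range[1] & mz <= config$mz_range[2]
      la_rep <- rep(seq_len(nrow(la)), each = n_px)
      if (config$isotopes) la_rep <- c(la_rep, la_rep)
      px_rep <- rep.int(seq_len(n_px), n_pk / n_px)
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        mouse = mouse,
        mode = mode,
        row = px$row[px_rep][keep],
        col = px$col[px_rep][keep],
        mz = mz[keep],
        intensity = as.vector(inten)[keep],
        lipid_id = la$lipid_id[la_rep][keep],
        adduct = la$adduct[la_rep][keep],
        isotope = iso[keep]
      )

      bg <- bg_tables[[mode]]
      if (!is.null(bg)) {
        n_bg <- nrow(bg)
        present <- stats::runif(n_px * n_bg) < config$background_presence
        inten_bg <- matrix(bg$base, n_px, n_bg, byrow = TRUE) *
          exp(matrix(stats::rnorm(n_px * n_bg, 0, config$noise_sd), n_px, n_bg)) *
          tic_factor
        mz_bg <- rep(bg$mz0, each = n_px)
        if (config$mass_error_ppm > 0) {
          mz_bg <- mz_bg * (1 + stats::rnorm(n_px * n_bg, 0, config$mass_error_ppm) * 1e-6)
        }
        px_bg <- rep.int(seq_len(n_px), n_bg)
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          mouse = mouse,
          mode = mode,
          row = px$row[px_bg][present],
          col = px$col[px_bg][present],
          mz = mz_bg[present],
          intensity = as.vector(inten_bg)[present],
          lipid_id = NA_character_,
          adduct = NA_character_,
          isotope = FALSE
        )
      }
    }
  }
  peaks <- dplyr::bind_rows(out[seq_len(k)])

  truth <- list(
    zone_mask = zone_map,
    differential_lipids = lib$id[lib$differential],
    true_dominant_zone = tibble::tibble(
      lipid_id = lib$id[lib$differential],
      zone = lib$dominant_zone[lib$differential]
    )
  )
  structure(
    list(
      peaks = peaks, zone_map = zone_map, ground_truth = truth,
      config = config
    ),
    class = "lobule_msi"
  )
}

#' @export
print.lobule_msi <- function(x, ...) {
  cat("<lobule_msi> ", nrow(x$peaks), " peaks, ",
    x$config$n_mice, " mice, modes: ",
    paste(unique(x$peaks$mode), collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate replicate acquisitions of one section
#'
#' Repeated acquisitions of the same tissue section share the mouse's lipid
#' amounts and differ only in measurement noise; this is expressed by
#' simulating `n_replicates` "mice" with `mouse_sd = 0`. The `mouse` column
#' of the result indexes the replicate.
#'
#' @param config A [synthetic_config()]; `n_mice` and `mouse_sd` are
#'   overridden.
#' @param n_replicates Number of replicate acquisitions (default 3).
#' @return A `lobule_msi` object.
#' @export
simulate_replicates <- function(config, n_replicates = 3) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 2)
  cfg <- config
  cfg$n_mice <- as.integer(n_replicates)
  cfg$mouse_sd <- 0
  simulate_dataset(cfg)
}
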