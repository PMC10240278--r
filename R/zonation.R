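# Mask-driven ROI sampling and per-zone, per-mouse ROI median intensities,
# replacing the manual histology co-registration step.

#' Sample connected regions of interest within each zone
#'
#' Per zone, grows `n_rois` disjoint 4-connected regions of `roi_pixels`
#' pixels breadth-first from random in-zone seed pixels. Reproducible under a
#' fixed seed.
#'
#' @param zone_mask Tibble from [lobule_zone_map()] (columns `row`, `col`,
#'   `zone`).
#' @param n_rois ROIs per zone (default 3).
#' @param roi_pixels Pixels per ROI (default 10).
#' @param seed Integer RNG seed.
#' @return A tibble with one row per ROI pixel: `zone`, `roi` (1-based
#'   within zone), `row`, `col`.
#' @export
sample_rois <- function(zone_mask, n_rois = 3, roi_pixels = 10, seed = 1) {
  stopifnot(n_rois >= 1, roi_pixels >= 1)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  zm <- zone_mask[!is.na(zone_mask$zone), ]
  out <- list()
  for (z in c("Z1", "Z2", "Z3")) {
    px <- zm[zm$zone == z, c("row", "col")]
    if (nrow(px) < n_rois * roi_pixels) {
      stop(
        "zone ", z, " has only ", nrow(px), " eligible pixels; ",
        n_rois * roi_pixels, " required",
        call. = FALSE
      )
    }
    key <- paste(px$row, px$col)
    used <- rep(FALSE, nrow(px))
    for (r in seq_len(n_rois)) {
      grown <- NULL
      for (attempt in seq_len(200)) {
        free <- which(!used)
        start <- free[sample.int(length(free), 1)]
        sel <- .grow_roi(px, key, used, start, roi_pixels)
        if (length(sel) == roi_pixels) {
          grown <- sel
          break
        }
      }
      if (is.null(grown)) {
        stop(
          "could not grow a ", roi_pixels, "-pixel connected ROI in zone ", z,
          call. = FALSE
        )
      }
      used[grown] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(
        zone = z, roi = r,
        row = px$row[grown], col = px$col[grown]
      )
    }
  }
  dplyr::bind_rows(out)
}

# Breadth-first 4-connected growth among unused in-zone pixels.
.grow_roi <- function(px, key, used, start, size) {
  sel <- integer(0)
  queue <- start
  in_queue <- logical(nrow(px))
  in_queue[start] <- TRUE
  while (length(queue) && length(sel) < size) {
    cur <- queue[1]
    queue <- queue[-1]
    sel <- c(sel, cur)
    nb <- paste(
      px$row[cur] + c(-1L, 1L, 0L, 0L),
      px$col[cur] + c(0L, 0L, -1L, 1L)
    )
    nbi <- match(nb, key)
    nbi <- nbi[!is.na(nbi)]
    nbi <- nbi[!used[nbi] & !in_queue[nbi]]
    in_queue[nbi] <- TRUE
    queue <- c(queue, nbi)
  }
  sel
}

#' Per-ROI median lipid intensities
#'
#' For each rank-1 annotated lipid, its adduct features (within its
#' ionisation mode) are summed per pixel, and the median over each ROI's
#' pixels is reported — one row per (lipid, mouse, zone, ROI).
#'
#' @param fms Named list of `feature_matrix` objects per mode (from
#'   [preprocess_dataset()]).
#' @param annotations Annotation tibble from [match_features()].
#' @param rois ROI tibble from [sample_rois()], with a `mouse` column
#'   (added by the caller when ROIs were sampled per mouse); if absent, the
#'   same ROIs are applied to every mouse in the data.
#' @return A zonal long table: tibble `lipid_id`, `mouse`, `zone`, `roi`,
#'   `median_intensity`.
#' @export
extract_roi_medians <- function(fms, annotations, rois) {
  if (inherits(fms, "feature_matrix")) {
    fms <- stats::setNames(list(fms), fms$mode)
  }
  ann1 <- annotations[annotations$rank == 1, ]
  out <- list()
  for (mode in names(fms)) {
    fm <- fms[[mode]]
    ann_m <- ann1[ann1$mode == mode, ]
    if (!nrow(ann_m)) next
    fidx <- match(ann_m$feature_id, fm$features$feature_id)
    stopifnot(!anyNA(fidx))
    lips <- sort(unique(ann_m$lipid_id))
    # pixel x lipid intensity: sum of the lipid's adduct feature columns
    ind <- Matrix::sparseMatrix(
      i = fidx, j = match(ann_m$lipid_id, lips), x = 1,
      dims = c(nrow(fm$features), length(lips))
    )
    lip_int <- as.matrix(fm$values %*% ind)
    colnames(lip_int) <- lips

    px <- fm$pixels
    mice <- if ("mouse" %in% names(px)) sort(unique(px$mouse)) else NA_integer_
    r_all <- rois
    for (m in mice) {
      r_m <- if ("mouse" %in% names(r_all)) {
        r_all[r_all$mouse == m, ]
      } else {
        r_all
      }
      if (!nrow(r_m)) next
      if (is.na(m)) {
        pkey <- paste(px$row, px$col)
      } else {
        pkey <- paste(px$mouse, px$row, px$col)
      }
      rkey <- if (is.na(m)) {
        paste(r_m$row, r_m$col)
      } else {
        paste(m, r_m$row, r_m$col)
      }
      ridx <- match(rkey, pkey)
      if (anyNA(ridx)) {
        stop("ROI pixel absent from the feature matrix", call. = FALSE)
      }
      grp <- paste(r_m$zone, r_m$roi)
      for (g in unique(grp)) {
        rows <- ridx[grp == g]
        med <- apply(lip_int[rows, , drop = FALSE], 2, stats::median)
        zr <- r_m[grp == g, ][1, ]
        out[[length(out) + 1L]] <- tibble::tibble(
          lipid_id = lips,
          mouse = if (is.na(m)) 1L else m,
          zone = zr$zone,
          roi = zr$roi,
          median_intensity = unname(med)
        )
      }
    }
  }
  tb <- dplyr::bind_rows(out)
  dplyr::arrange(tb, .data$lipid_id, .data$mouse, .data$zone, .data$roi)
}

#' Dominant zone of each lipid
#'
#' The zone with the largest mean ROI median across mice; exact ties are
#' flagged and broken toward the lower zone index.
#'
#' @param table A zonal long table from [extract_roi_medians()].
#' @param lipid Optional lipid id(s) to restrict to.
#' @return A tibble `lipid_id`, `dominant_zone`, `tie`.
#' @export
dominant_zone <- function(table, lipid = NULL) {
  if (!is.null(lipid)) {
    missing <- setdiff(lipid, table$lipid_id)
    if (length(missing)) {
      stop("lipid(s) absent from table: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    table <- table[table$lipid_id %in% lipid, ]
  }
  table |>
    dplyr::group_by(.data$lipid_id, .data$zone) |>
    dplyr::summarise(m = mean(.data$median_intensity), .groups = "drop") |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::summarise(
      dominant_zone = as.character(.data$zone[which.max(.data$m)]),
      tie = sum(.data$m == max(.data$m)) > 1,
      .groups = "drop"
    )
}
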