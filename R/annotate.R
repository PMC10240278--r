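# Accurate-mass lipid annotation with adduct rules and an isotope-pattern
# check, emulating a LIPID MAPS search on aligned features.

#' Isotope-pattern score from the observed M+1 ratio
#'
#' The expected (M+1)/M intensity ratio of a lipid is approximately
#' `0.0107 * nC` (natural 13C abundance per carbon). The score is
#' `max(0, 1 - |observed - expected| / expected)`; a missing M+1 feature
#' scores 0.
#'
#' @param observed_ratio Observed (M+1)/M intensity ratio; `NA` if the M+1
#'   feature is missing.
#' @param formula Molecular formula (character), carbon count >= 1.
#' @return Score in `[0, 1]`, vectorised.
#' @examples
#' isotope_score(0.449, "C42H80NO8P") # ~1
#' @export
isotope_score <- function(observed_ratio, formula) {
  n_c <- element_count(formula)
  if (any(n_c < 1)) stop("formula must contain carbon", call. = FALSE)
  expected <- .c13_ratio_per_c * n_c
  score <- pmax(0, 1 - abs(observed_ratio - expected) / expected)
  ifelse(is.na(observed_ratio), 0, score)
}

#' Match aligned features to a lipid library by accurate mass
#'
#' For every feature and mode-compatible (lipid, adduct) pair whose
#' theoretical m/z lies within `tol_ppm`, an annotation is produced.
#' Candidates per feature are ranked by absolute ppm error, ties broken by
#' larger isotope score and then lexical lipid id. The isotope score uses
#' the feature found at m/z + 1.0034 (within tolerance), with the observed
#' ratio taken from mean intensities across pixels.
#'
#' @param fm A `feature_matrix` (one ionisation mode) or a list of them.
#' @param library Lipid library tibble (see [hepatic_lipid_library()]).
#' @param tol_ppm Matching tolerance in ppm (> 0), default 10.
#' @return A tibble of annotations: `feature_id`, `feature_mz`, `mode`,
#'   `lipid_id`, `lipid_class`, `adduct`, `theoretical_mz`, `ppm_error`,
#'   `isotope_score`, `rank`. The number of unmatched features is attached
#'   as attribute `"n_unannotated"`.
#' @export
match_features <- function(fm, library, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  if (nrow(library) == 0) stop("empty lipid library", call. = FALSE)
  if (inherits(fm, "feature_matrix")) fm <- list(fm)
  res <- lapply(fm, .match_one_mode, library = library, tol_ppm = tol_ppm)
  ann <- dplyr::bind_rows(lapply(res, `[[`, "ann"))
  attr(ann, "n_unannotated") <- sum(vapply(res, `[[`, numeric(1), "n_un"))
  ann
}

.match_one_mode <- function(fm, library, tol_ppm) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- fm$mode
  lib_m <- library[library$mode == mode, ]
  feats <- fm$features
  n_f <- nrow(feats)
  mean_int <- colMeans(fm$values)

  # observed M+1 ratio per feature
  iso_ratio <- rep(NA_real_, n_f)
  if (n_f > 1) {
    target <- feats$mz + .c13_delta
    idx <- findInterval(target, feats$mz)
    for (i in seq_len(n_f)) {
      cand <- unique(pmax(pmin(c(idx[i], idx[i] + 1L), n_f), 1L))
      dppm <- abs(feats$mz[cand] - target[i]) / target[i] * 1e6
      j <- cand[which.min(dppm)]
      if (min(dppm) <= tol_ppm && mean_int[i] > 0) {
        iso_ratio[i] <- mean_int[j] / mean_int[i]
      }
    }
  }

  rules <- adduct_rules()
  rules <- rules[rules$mode == mode, ]
  if (!nrow(lib_m) || n_f == 0) {
    return(list(ann = tibble::tibble(), n_un = n_f))
  }
  cand <- tidyr::crossing(
    lipid_id = lib_m$id,
    adduct = rules$adduct
  )
  cand <- dplyr::left_join(cand,
    lib_m[, c("id", "lipid_class", "formula", "monoisotopic_mass")],
    by = c(lipid_id = "id")
  )
  cand$theoretical_mz <- theoretical_mz(cand$monoisotopic_mass, cand$adduct)
  cand <- cand[order(cand$theoretical_mz), ]

  lo <- findInterval(feats$mz * (1 - tol_ppm * 1e-6), cand$theoretical_mz) + 1L
  hi <- findInterval(feats$mz * (1 + tol_ppm * 1e-6), cand$theoretical_mz)
  hit_rows <- lapply(seq_len(n_f), function(i) {
    if (hi[i] < lo[i]) return(NULL)
    j <- lo[i]:hi[i]
    tibble::tibble(
      feature_id = feats$feature_id[i],
      feature_mz = feats$mz[i],
      mode = mode,
      lipid_id = cand$lipid_id[j],
      lipid_class = cand$lipid_class[j],
      adduct = cand$adduct[j],
      theoretical_mz = cand$theoretical_mz[j],
      ppm_error = ppm_error(feats$mz[i], cand$theoretical_mz[j]),
      isotope_score = isotope_score(iso_ratio[i], cand$formula[j])
    )
  })
  ann <- dplyr::bind_rows(hit_rows)
  n_un <- n_f - length(unique(ann$feature_id))
  if (nrow(ann)) {
    ann <- ann |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::arrange(
        abs(.data$ppm_error), dplyr::desc(.data$isotope_score),
        .data$lipid_id,
        .by_group = TRUE
      ) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  list(ann = ann, n_un = n_un)
}

#' Distinct rank-1 annotated lipids
#'
#' @param annotations Annotation tibble from [match_features()].
#' @return Character vector of distinct lipid ids annotated at rank 1.
#' @export
annotated_lipids <- function(annotations) {
  if (!nrow(annotations)) return(character(0))
  sort(unique(annotations$lipid_id[annotations$rank == 1]))
}
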