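# Synthetic hepatic lipid library: 269 sum-composition entries across 12
# classes, with zonal abundance profiles mirroring the porto-central
# distribution of the major hepatic lipid families (FAs periportal, a PI
# subset midzonal, DG/TG pericentral, PGs flat).

# Sum-composition molecular formula for a lipid subclass with n acyl/backbone
# carbons and d double bonds. Derived from glycerophosphate / sphingoid
# backbone arithmetic; validated against reference monoisotopic masses.
.subclass_formula <- function(subclass, n, d) {
  f <- switch(subclass,
    FA  = c(C = n, H = 2 * n - 2 * d, O = 2),
    LPC = c(C = n + 8, H = 2 * n - 2 * d + 18, N = 1, O = 7, P = 1),
    LPE = c(C = n + 5, H = 2 * n - 2 * d + 12, N = 1, O = 7, P = 1),
    LPA = c(C = n + 3, H = 2 * n - 2 * d + 7, O = 7, P = 1),
    PA  = c(C = n + 3, H = 2 * n - 2 * d + 5, O = 8, P = 1),
    PC  = c(C = n + 8, H = 2 * n - 2 * d + 16, N = 1, O = 8, P = 1),
    PE  = c(C = n + 5, H = 2 * n - 2 * d + 10, N = 1, O = 8, P = 1),
    PG  = c(C = n + 6, H = 2 * n - 2 * d + 11, O = 10, P = 1),
    PI  = c(C = n + 9, H = 2 * n - 2 * d + 15, O = 13, P = 1),
    PS  = c(C = n + 6, H = 2 * n - 2 * d + 10, N = 1, O = 10, P = 1),
    DG  = c(C = n + 3, H = 2 * n - 2 * d + 4, O = 5),
    TG  = c(C = n + 3, H = 2 * n - 2 * d + 2, O = 6),
    Cer = c(C = n, H = 2 * n + 1 - 2 * d, N = 1, O = 3),
    SM  = c(C = n + 5, H = 2 * n + 13 - 2 * d, N = 2, O = 6, P = 1),
    stop("unknown lipid subclass: ", subclass, call. = FALSE)
  )
  f <- f[f > 0]
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

.subclass_to_class <- c(
  FA = "FA", LPC = "LPL", LPE = "LPL", LPA = "LPL", PA = "PA", PC = "PC",
  PE = "PE", PG = "PG", PI = "PI", PS = "PS", DG = "DG", TG = "TG",
  Cer = "Cer", SM = "SL"
)

.subclass_mode <- c(
  FA = "negative", LPC = "positive", LPE = "negative", LPA = "negative",
  PA = "negative", PC = "positive", PE = "positive", PG = "negative",
  PI = "negative", PS = "negative", DG = "positive", TG = "positive",
  Cer = "positive", SM = "positive"
)

# Relative per-class intensity scale (arbitrary units); PCs dominate the
# hepatic lipidome, PIs/LPLs are low abundant.
.class_base <- c(
  FA = 1500, LPC = 300, LPE = 250, LPA = 200, PA = 500, PC = 6000,
  PE = 2500, PG = 400, PI = 2400, PS = 600, DG = 1200, TG = 3000,
  Cer = 350, SM = 450
)

#' Relative adduct intensity weights by lipid class
#'
#' In positive mode most classes ionise mainly as the protonated species with
#' smaller sodiated and ammoniated fractions; neutral glycerides (TG, DG)
#' ionise almost exclusively as sodium and ammonium adducts with only traces
#' of the protonated and potassiated forms. Negative-mode lipids are observed
#' deprotonated.
#'
#' @param subclass Character vector of lipid subclasses (e.g. `"PC"`, `"TG"`).
#' @return A named list (per subclass) of named weight vectors that sum to 1.
#' @export
class_adduct_weights <- function(subclass) {
  pos <- c("[M+H]+" = 0.6, "[M+Na]+" = 0.25, "[M+NH4]+" = 0.15)
  glyceride <- c("[M+Na]+" = 0.5, "[M+NH4]+" = 0.45, "[M+H]+" = 0.025, "[M+K]+" = 0.025)
  neg <- c("[M-H]-" = 1)
  lapply(stats::setNames(subclass, subclass), function(s) {
    if (s %in% c("TG", "DG")) return(glyceride)
    if (.subclass_mode[[s]] == "positive") pos else neg
  })
}

# Parse "36:4" style composition strings.
.parse_comp <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  tibble::tibble(
    c = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    db = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

# Candidate compositions per class, in deterministic priority order:
# differential entries (paper-observed species first, then same-zone backups),
# followed by flat entries and a backup grid. Quotas give 269 entries of
# which 117 are differential.
.library_plan <- function() {
  grid <- function(cs, dbs) {
    g <- expand.grid(db = dbs, c = cs)
    sprintf("%d:%d", g$c, g$db)
  }
  list(
    PC = list(
      n_diff = 18, n_flat = 42,
      diff = list(
        Z1 = c("34:2", "38:6", "32:1", "34:3", "36:3", "37:6", "36:6"),
        Z3 = c("36:4", "35:2", "36:2", "37:1", "37:2", "37:3", "38:0", "39:5", "40:4")
      ),
      diff_backup = list(
        Z1 = c(
          "32:2", "33:1", "33:2", "30:0", "30:1", "31:0", "31:1", "32:0",
          "33:0", "34:1", "34:4", grid(29:37, 0:8)
        ),
        Z3 = c(
          "39:4", "40:5", "41:5", "41:6", "42:4", "42:5", "38:1", "39:0",
          "40:0", grid(38:46, 0:8)
        )
      ),
      flat = c(grid(28:46, 0:8), grid(27:48, 9:10))
    ),
    PA = list(
      n_diff = 6, n_flat = 6,
      diff = list(Z1 = c("40:6", "40:7", "36:2", "36:4", "38:4", "38:6")),
      diff_backup = list(Z1 = c("38:5", "40:5", "42:7")),
      flat = grid(c(32, 34, 36, 38, 42), 0:4)
    ),
    PI = list(
      n_diff = 13, n_flat = 9,
      diff = list(
        Z2 = c("34:2", "36:2", "36:3", "36:4", "38:5", "38:6", "40:5", "40:6"),
        Z3 = c("38:3", "38:4", "39:4", "42:8", "42:9")
      ),
      diff_backup = list(Z2 = c("34:3", "36:5"), Z3 = c("40:7", "42:6")),
      flat = grid(c(32, 33, 34, 35, 36, 37, 40, 41, 44), 0:5)
    ),
    FA = list(
      n_diff = 12, n_flat = 8,
      diff = list(Z1 = c(
        "18:2", "20:2", "20:3", "20:4", "22:4", "22:6",
        "16:1", "18:1", "18:3", "20:5", "22:5", "16:0"
      )),
      diff_backup = list(Z1 = c("18:0", "22:3")),
      flat = c("14:0", "15:0", "17:0", "17:1", "19:0", "24:0", "24:1", "26:0", grid(21:28, 0:2))
    ),
    TG = list(
      n_diff = 22, n_flat = 18,
      diff = list(Z3 = c(
        "50:4", "50:5", "51:1", "52:2", "48:1", "48:2", "50:1", "50:2",
        "50:3", "52:3", "52:4", "52:5", "54:2", "54:3", "54:4", "54:5",
        "54:6", "56:5", "56:6", "56:7", "56:8", "53:2"
      )),
      diff_backup = list(Z3 = c(
        "51:2", "53:3", "55:2", "55:3", "49:1", "49:2",
        "47:1", "47:2", "57:6", "57:7", "45:1", "45:2", grid(43:59, 0:9)
      )),
      flat = grid(42:60, 0:9)
    ),
    DG = list(
      n_diff = 12, n_flat = 6,
      diff = list(Z3 = c(
        "36:2", "36:3", "38:2", "38:4", "38:5", "32:0",
        "34:0", "34:1", "34:2", "36:1", "38:3", "40:6"
      )),
      diff_backup = list(Z3 = c(
        "36:4", "40:7", "33:1", "35:1", "37:2", "39:4", grid(29:41, 0:6)
      )),
      flat = grid(28:42, 0:6)
    ),
    PE = list(
      n_diff = 10, n_flat = 20,
      diff = list(Z1 = c(
        "36:4", "36:5", "38:5", "38:6", "40:6", "40:7",
        "38:4", "40:4", "34:2", "36:3"
      )),
      diff_backup = list(Z1 = c(
        "34:3", "36:1", "38:2", "40:2", "42:6", "42:7", "38:7",
        "42:4", "42:5", "34:4", "36:6", "34:1", grid(31:47, 0:9)
      )),
      flat = c(grid(30:48, 0:9), grid(34:50, 10:12))
    ),
    PS = list(
      n_diff = 6, n_flat = 8,
      diff = list(Z1 = c("42:8", "42:6", "36:1", "38:4", "40:6", "38:3")),
      diff_backup = list(Z1 = c("40:5", "42:7", "36:2", grid(35:43, 0:5))),
      flat = grid(c(34, 36, 38, 40, 42, 44), 0:5)
    ),
    PG = list(
      n_diff = 0, n_flat = 14,
      diff = list(),
      diff_backup = list(),
      flat = grid(32:42, 0:7)
    ),
    SM = list(
      n_diff = 10, n_flat = 5,
      diff = list(
        Z1 = c("36:0", "38:0", "38:2"),
        Z3 = c("34:1", "36:1", "36:2", "40:1", "42:1", "42:2", "42:3")
      ),
      diff_backup = list(
        Z1 = c("40:0", "37:0", "39:0", "43:0", "45:0"),
        Z3 = c("44:2", "44:3", "43:2", "39:1", grid(29:47, 0:6))
      ),
      flat = c(grid(29:47, 0:6), grid(28:48, 7:8))
    ),
    Cer = list(
      n_diff = 2, n_flat = 10,
      diff = list(Z3 = c("37:0", "42:1")),
      diff_backup = list(Z3 = c("44:1", "45:1")),
      flat = grid(32:46, 0:4)
    ),
    LPC = list(
      n_diff = 2, n_flat = 3,
      diff = list(Z1 = c("18:1"), Z3 = c("18:0")),
      diff_backup = list(Z1 = c("18:2", "16:1"), Z3 = c("20:0", "22:0")),
      flat = c("16:0", "20:4", "22:6", "15:0", "17:1", "19:0", "14:0", "20:3", "22:5")
    ),
    LPE = list(
      n_diff = 1, n_flat = 2,
      diff = list(Z1 = c("16:0")),
      diff_backup = list(Z1 = c("16:1")),
      flat = c("18:0", "18:1", "20:4", "22:6")
    ),
    LPA = list(
      n_diff = 3, n_flat = 1,
      diff = list(Z1 = c("18:0", "16:0", "18:1")),
      diff_backup = list(Z1 = c("18:2")),
      flat = c("20:4", "22:6", "14:0")
    )
  )
}

# Zone profile (Z1, Z2, Z3 relative abundances) for a dominant zone and
# dominant-to-minimum fold change f (>= 2).
.zone_profile <- function(zone, f) {
  switch(zone,
    Z1 = c(f, sqrt(f), 1),
    Z2 = c(1, f, 1),
    Z3 = c(1, sqrt(f), f),
    flat = c(1, 1, 1)
  )
}

#' Default synthetic hepatic lipid library
#'
#' Builds a deterministic 269-entry lipid table spanning 12 classes (FA, LPL,
#' PA, PC, PE, PG, PI, PS, DG, TG, Cer, SL), of which 117 carry a non-flat
#' zonal abundance profile with a dominant-zone fold change of at least 2:
#' fatty acids and arachidonate/docosahexaenoate-containing phospholipids are
#' periportal (Z1), a phosphatidylinositol subset is midzonal (Z2),
#' di-/triacylglycerols and most sphingolipids are pericentral (Z3), and
#' phosphatidylglycerols are flat. Compositions are screened so that, within
#' an ionisation mode, every adduct and M+1 isotopologue m/z of distinct
#' lipids is at least `min_sep_ppm` apart; sum compositions whose accurate
#' mass would be ambiguous (e.g. PC/PE isobars) are replaced by same-zone
#' alternatives, so every entry is identifiable by accurate mass alone.
#'
#' @param min_sep_ppm Minimum pairwise m/z separation enforced between
#'   distinct lipids' monoisotopic adduct positions within one mode
#'   (default 30 ppm).
#' @param iso_sep_ppm Minimum separation between a differential lipid's M+1
#'   isotopologue positions and any other lipid's monoisotopic positions
#'   (default 15 ppm — enough that isotopologue peaks can never chain-merge
#'   into another lipid's feature at a 10 ppm alignment tolerance).
#' @return A tibble with one row per lipid: `id`, `name`, `subclass`,
#'   `lipid_class`, `formula`, `monoisotopic_mass`, `mode`, `z1`, `z2`, `z3`
#'   (relative zonal abundances), `base_abundance`, `differential`,
#'   `dominant_zone`.
#' @examples
#' lib <- hepatic_lipid_library()
#' nrow(lib) # 269
#' sum(lib$differential) # 117
#' @export
hepatic_lipid_library <- function(min_sep_ppm = 30, iso_sep_ppm = 15) {
  plan <- .library_plan()
  folds <- c(4, 3, 2.5)
  rules <- adduct_rules()
  kept_mz <- list(positive = numeric(0), negative = numeric(0))
  kept_m1_diff <- list(positive = numeric(0), negative = numeric(0))
  kept <- list()
  min_sep <- function(a, b) {
    if (!length(a) || !length(b)) return(Inf)
    min(abs(outer(a, b, "-")) / outer(a, b, pmin) * 1e6)
  }
  quota <- lapply(plan, function(p) c(diff = 0L, flat = 0L))

  # Candidates in two passes: every class's differential entries first, then
  # flat entries, so abundant flat compositions never displace a planted
  # zonal effect. Within a pass, earlier-listed species win the screen.
  cands <- list()
  for (pass in c("diff", "flat")) {
    for (sub in names(plan)) {
      p <- plan[[sub]]
      if (pass == "diff") {
        for (z in names(p$diff)) {
          cands[[length(cands) + 1L]] <- tibble::tibble(
            sub = sub, comp = p$diff[[z]], zone = z
          )
        }
        for (z in names(p$diff_backup)) {
          cands[[length(cands) + 1L]] <- tibble::tibble(
            sub = sub, comp = p$diff_backup[[z]], zone = z
          )
        }
      } else {
        cands[[length(cands) + 1L]] <- tibble::tibble(
          sub = sub, comp = p$flat, zone = "flat"
        )
      }
    }
  }
  cand <- dplyr::bind_rows(cands)
  # a composition passed over in the differential pass stays available as a
  # flat candidate; only identical (class, composition, zone) rows collapse
  cand <- cand[!duplicated(cand[, c("sub", "comp", "zone")]), ]
  kept_key <- character(0)

  for (i in seq_len(nrow(cand))) {
    sub <- cand$sub[i]
    zone <- cand$zone[i]
    if (paste(sub, cand$comp[i]) %in% kept_key) next
    is_diff <- zone != "flat"
    slot <- if (is_diff) "diff" else "flat"
    if (quota[[sub]][slot] >= plan[[sub]][[paste0("n_", slot)]]) next
    mode <- .subclass_mode[[sub]]
    comp <- .parse_comp(cand$comp[i])
    formula <- .subclass_formula(sub, comp$c, comp$db)
    mass <- formula_mass(formula)
    # Screen the monoisotopic position of every mode-compatible adduct (not
    # only the class's emitted ones) so accurate-mass matching over the full
    # adduct set stays unambiguous. M+1 isotopologues are screened only for
    # differential lipids: a zonal lipid's M+1 co-binning with another
    # lipid's monoisotopic feature would leak its zone profile into that
    # lipid's quantification; flat-lipid M+1 overlap is harmless.
    all_mz <- mass + rules$mass_shift[rules$mode == mode]
    iso_mz <- all_mz + .c13_delta
    ok <- min_sep(all_mz, kept_mz[[mode]]) >= min_sep_ppm &&
      min_sep(all_mz, kept_m1_diff[[mode]]) >= iso_sep_ppm &&
      (!is_diff || min_sep(iso_mz, kept_mz[[mode]]) >= iso_sep_ppm)
    if (!ok) next
    kept_mz[[mode]] <- c(kept_mz[[mode]], all_mz)
    if (is_diff) kept_m1_diff[[mode]] <- c(kept_m1_diff[[mode]], iso_mz)
    kept_key <- c(kept_key, paste(sub, cand$comp[i]))
    quota[[sub]][slot] <- quota[[sub]][slot] + 1L
    kept[[length(kept) + 1L]] <- tibble::tibble(
      id = sprintf("%s(%s)", sub, cand$comp[i]),
      name = sprintf("%s(%s)", sub, cand$comp[i]),
      subclass = sub,
      lipid_class = .subclass_to_class[[sub]],
      formula = formula,
      monoisotopic_mass = mass,
      mode = mode,
      z1 = NA_real_, z2 = NA_real_, z3 = NA_real_,
      differential = is_diff,
      dominant_zone = if (is_diff) zone else NA_character_
    )
  }

  short <- names(plan)[vapply(names(plan), function(s) {
    quota[[s]]["diff"] < plan[[s]]$n_diff || quota[[s]]["flat"] < plan[[s]]$n_flat
  }, logical(1))]
  if (length(short)) {
    stop(
      "lipid library plan could not fill its quota for: ",
      paste(short, collapse = ", "), " under the ", min_sep_ppm,
      " ppm separation screen",
      call. = FALSE
    )
  }

  lib <- dplyr::bind_rows(kept)
  lib$subclass <- factor(lib$subclass, levels = names(plan))
  lib <- dplyr::arrange(lib, .data$subclass, dplyr::desc(.data$differential))
  lib$subclass <- as.character(lib$subclass)
  # zone profile folds cycle deterministically within class
  lib <- lib |>
    dplyr::group_by(.data$subclass) |>
    dplyr::mutate(rank_in_class = dplyr::row_number()) |>
    dplyr::ungroup()
  prof <- t(mapply(function(z, k) {
    .zone_profile(if (is.na(z)) "flat" else z, folds[(k - 1L) %% length(folds) + 1L])
  }, lib$dominant_zone, lib$rank_in_class))
  lib$z1 <- prof[, 1]
  lib$z2 <- prof[, 2]
  lib$z3 <- prof[, 3]
  # Abundance: class scale with a geometric within-class spread; entries are
  # listed most-abundant first so the paper-observed species sit high.
  lib <- lib |>
    dplyr::group_by(.data$subclass) |>
    dplyr::mutate(
      base_abundance = .class_base[[.data$subclass[1]]] *
        exp(0.9 - 1.8 * (.data$rank_in_class - 1) / max(dplyr::n() - 1, 1))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"rank_in_class")
  .balance_zone_totals(lib)
}

# Balance expected total lipid signal across zones within each ionisation
# mode: total lipid content per tissue area is not zonated, only its
# composition, and an unbalanced total would let TIC normalisation imprint
# spurious zone effects on flat lipids. Only the non-dominant profile
# entries of differential lipids are adjusted (bounded, iterative); the
# dominant zone and a >= 2 dominant-to-minimum fold are preserved.
.balance_zone_totals <- function(lib, n_iter = 12) {
  zc <- c("z1", "z2", "z3")
  for (mode in unique(lib$mode)) {
    im <- which(lib$mode == mode)
    dlab <- lib$dominant_zone[im]
    diff <- lib$differential[im]
    b <- lib$base_abundance[im]
    P <- as.matrix(lib[im, zc])
    for (it in seq_len(n_iter)) {
      S <- colSums(P * b)
      target <- mean(S)
      for (z in 1:3) {
        minors <- diff & (is.na(dlab) | dlab != paste0("Z", z))
        M <- sum(b[minors] * P[minors, z])
        if (M > 0) {
          x <- max(0.6, min(1.5, 1 + (target - S[z]) / M))
          P[minors, z] <- pmax(0.1, P[minors, z] * x)
        }
        # residual surplus/deficit moves through the zone's dominant entries
        S <- colSums(P * b)
        doms <- diff & !is.na(dlab) & dlab == paste0("Z", z)
        D <- sum(b[doms] * P[doms, z])
        if (D > 0) {
          y <- max(0.85, min(1.2, 1 + (target - S[z]) / D))
          P[doms, z] <- P[doms, z] * y
        }
      }
      # dominance: strict argmax with margin, and max/min fold >= 2
      di <- which(diff)
      dz <- match(dlab[di], c("Z1", "Z2", "Z3"))
      for (j in seq_along(di)) {
        row <- P[di[j], ]
        dom <- dz[j]
        row[dom] <- max(row[dom], 1.2 * max(row[-dom]), 2 * min(row[-dom]))
        P[di[j], ] <- row
      }
    }
    lib[im, zc] <- P
  }
  lib
}

#' Write / read a lipid library as TSV
#'
#' Plain tab-separated serialisation of the library table, so runs can be
#' reproduced from a fixed file.
#'
#' @param library A lipid library tibble as from [hepatic_lipid_library()].
#' @param path File path.
#' @return `write_lipid_library()` returns `path` invisibly;
#'   `read_lipid_library()` returns the library tibble.
#' @export
write_lipid_library <- function(library, path) {
  utils::write.table(library, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_lipid_library
#' @export
read_lipid_library <- function(path) {
  tb <- tibble::as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  ))
  tb$differential <- as.logical(tb$differential)
  tb
}
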