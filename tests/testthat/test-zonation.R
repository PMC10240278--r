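test_that("ROI sampling reproduces the 10-pixel / 3-ROI / 30-per-zone design", {
  zm <- lobule_zone_map(lobule_geometry(c(40, 40)))
  rois <- sample_rois(zm, seed = 4)
  expect_equal(nrow(rois), 90) # zones x ROIs x pixels
  counts <- table(rois$zone, rois$roi)
  expect_true(all(counts == 10))
  expect_equal(unname(rowSums(counts)), c(30, 30, 30))
  # disjoint pixels
  expect_false(anyDuplicated(rois[, c("row", "col")]) > 0)
  # pixels carry their zone's label
  joined <- dplyr::left_join(rois, zm, by = c("row", "col"), suffix = c("", ".map"))
  expect_equal(as.character(joined$zone), as.character(joined$zone.map))
  # reproducibility
  expect_identical(rois, sample_rois(zm, seed = 4))
  expect_false(identical(rois, sample_rois(zm, seed = 5)))
})

test_that("each ROI is 4-connected", {
  zm <- lobule_zone_map(lobule_geometry(c(40, 40)))
  rois <- sample_rois(zm, seed = 8)
  for (g in split(rois, paste(rois$zone, rois$roi))) {
    key <- paste(g$row, g$col)
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in frontier) {
        nb <- match(paste(
          g$row[i] + c(-1, 1, 0, 0),
          g$col[i] + c(0, 0, -1, 1)
        ), key)
        nb <- setdiff(nb[!is.na(nb)], seen)
        seen <- c(seen, nb)
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    expect_equal(sort(seen), seq_len(nrow(g)))
  }
})

test_that("a zone without enough eligible pixels raises a named error", {
  zm <- tibble::tibble(
    row = c(rep(1, 29), rep(2, 60), rep(3, 60)),
    col = c(1:29, 1:60, 1:60),
    u = 0.5,
    zone = factor(c(rep("Z1", 29), rep("Z2", 60), rep("Z3", 60)),
      levels = c("Z1", "Z2", "Z3")
    )
  )
  expect_error(sample_rois(zm, seed = 1), "zone Z1")
})

test_that("ROI medians use the even-count convention and are outlier-robust", {
  fm <- structure(
    list(
      values = matrix(c(1:10, rep(7, 10), c(rep(1, 9), 1000)), ncol = 3),
      pixels = tibble::tibble(row = 1:10, col = 1),
      features = tibble::tibble(feature_id = c("F1", "F2", "F3"), mz = c(200, 300, 400)),
      tic = rep(1, 10), mode = "negative", normalized = TRUE
    ),
    class = "feature_matrix"
  )
  ann <- tibble::tibble(
    feature_id = c("F1", "F2", "F3"),
    feature_mz = c(200, 300, 400), mode = "negative",
    lipid_id = c("L1", "L2", "L3"), lipid_class = "FA",
    adduct = "[M-H]-", theoretical_mz = feature_mz, ppm_error = 0,
    isotope_score = 1, rank = 1L
  )
  rois <- tibble::tibble(zone = "Z1", roi = 1L, row = 1:10, col = 1)
  out <- extract_roi_medians(fm, ann, rois)
  expect_equal(out$median_intensity[out$lipid_id == "L1"], 5.5)
  expect_equal(out$median_intensity[out$lipid_id == "L2"], 7)
  expect_equal(out$median_intensity[out$lipid_id == "L3"], 1)
  # a ROI pixel absent from the matrix is an error
  bad <- tibble::tibble(zone = "Z1", roi = 1L, row = 99, col = 99)
  expect_error(extract_roi_medians(fm, ann, bad), "absent")
})

test_that("lipid intensity sums adducts before the median", {
  fm <- structure(
    list(
      values = matrix(c(rep(2, 5), rep(3, 5)), ncol = 2),
      pixels = tibble::tibble(row = 1:5, col = 1),
      features = tibble::tibble(feature_id = c("F1", "F2"), mz = c(758.57, 780.55)),
      tic = rep(1, 5), mode = "positive", normalized = TRUE
    ),
    class = "feature_matrix"
  )
  ann <- tibble::tibble(
    feature_id = c("F1", "F2"),
    feature_mz = c(758.57, 780.55), mode = "positive",
    lipid_id = "PC(34:2)", lipid_class = "PC",
    adduct = c("[M+H]+", "[M+Na]+"), theoretical_mz = feature_mz,
    ppm_error = 0, isotope_score = 1, rank = 1L
  )
  rois <- tibble::tibble(zone = "Z2", roi = 1L, row = 1:5, col = 1)
  out <- extract_roi_medians(fm, ann, rois)
  expect_equal(out$median_intensity, 5)
})

test_that("dominant zone takes the largest zone mean with ties to lower zones", {
  mk <- function(z1, z2, z3) {
    tidyr::crossing(mouse = 1:2, roi = 1:3, zone = c("Z1", "Z2", "Z3")) |>
      dplyr::mutate(
        lipid_id = "L",
        median_intensity = c(Z1 = z1, Z2 = z2, Z3 = z3)[.data$zone]
      )
  }
  d1 <- dominant_zone(mk(10, 5, 1))
  expect_equal(d1$dominant_zone, "Z1")
  expect_false(d1$tie)
  d2 <- dominant_zone(mk(1, 1, 1))
  expect_equal(d2$dominant_zone, "Z1")
  expect_true(d2$tie)
  expect_error(dominant_zone(mk(1, 2, 3), lipid = "missing"), "absent")
})

test_that("noiseless pipeline recovers exact zone profiles and dominant zones", {
  cfg <- noiseless_config(isotopes = FALSE)
  ds <- simulate_dataset(cfg)
  fms <- preprocess_dataset(ds, normalize = FALSE)
  ann <- match_features(fms, cfg$library)
  rois <- dplyr::bind_rows(lapply(1:2, function(m) {
    r <- sample_rois(ds$zone_map, seed = m)
    r$mouse <- m
    r
  }))
  zl <- extract_roi_medians(fms, ann, rois)
  # medians equal base_abundance x zone profile exactly
  lib <- cfg$library
  chk <- dplyr::left_join(zl, lib, by = c(lipid_id = "id"))
  prof <- as.matrix(chk[, c("z1", "z2", "z3")])
  zi <- match(chk$zone, c("Z1", "Z2", "Z3"))
  expect_equal(chk$median_intensity,
    chk$base_abundance * prof[cbind(seq_len(nrow(chk)), zi)],
    tolerance = 1e-9
  )
  dz <- dominant_zone(zl)
  truth <- ds$ground_truth$true_dominant_zone
  got <- dz$dominant_zone[match(truth$lipid_id, dz$lipid_id)]
  expect_equal(got, truth$zone)
})
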