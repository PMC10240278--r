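# Per-lipid zonal differential testing: random-intercept mixed model on log
# intensity, likelihood-ratio chi-square test of the zone factor,
# Benjamini-Hochberg control, and reproducibility metrics.

# Profile ML log-likelihood machinery for the random-intercept model
#   y = X beta + b_mouse + e,  b ~ N(0, var_mouse), e ~ N(0, var_resid).
# With lambda = var_mouse / var_resid, V0 = I + lambda Z Z' has the
# block-diagonal inverse I - lambda/(1 + k_g lambda) J within group g, and
# var_resid is profiled out analytically; lambda is maximised on a log grid
# with local refinement.
.profile_ll <- function(lambda, y, X, grp) {
  k <- tabulate(grp)
  w <- lambda / (1 + k * lambda) # per-group shrinkage of group totals
  gX <- rowsum(X, grp)
  gy <- rowsum(y, grp)
  XtVX <- crossprod(X) - crossprod(gX * sqrt(w[seq_len(nrow(gX))]))
  XtVy <- crossprod(X, y) - crossprod(gX, gy * w)
  # note: gX rows are ordered by sorted unique grp; w indexed the same way
  beta <- solve(XtVX, XtVy)
  r <- y - X %*% beta
  gr <- rowsum(r, grp)
  q <- sum(r^2) - sum(w * gr^2)
  n <- length(y)
  sigma2 <- q / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + sum(log(1 + k * lambda)) + n)
  list(ll = ll, beta = beta, sigma2 = sigma2)
}

#' Fit a mouse random-intercept model to one lipid's log intensities
#'
#' Maximum-likelihood fit of `log(median_intensity) ~ zone + (1 | mouse)`
#' (or intercept-only when `include_zone = FALSE`). ML rather than REML is
#' used because the zone test compares fixed-effect structures by likelihood
#' ratio. The variance ratio is profiled on a 1-D log grid with local
#' refinement.
#'
#' @param values Tibble with columns `mouse`, `zone` and `median_intensity`
#'   (> 0) for one lipid.
#' @param include_zone Include the 3-level zone factor as fixed effect.
#' @return An object of class `lmm_ri`: fixed effects (intercept and, when
#'   included, `Z2 - Z1` and `Z3 - Z1` contrasts on the log scale),
#'   `var_mouse`, `var_resid`, `loglik_ml`, `lambda`, `n`.
#' @export
fit_random_intercept <- function(values, include_zone = TRUE) {
  stopifnot(all(c("mouse", "zone", "median_intensity") %in% names(values)))
  if (any(values$median_intensity <= 0)) {
    stop(
      "non-positive intensities; apply the pseudo-count policy ",
      "(see test_zonation) before fitting",
      call. = FALSE
    )
  }
  if (length(unique(values$mouse)) < 2) stop("need >= 2 mice", call. = FALSE)
  if (include_zone && length(unique(values$zone)) < 2) {
    stop("need >= 2 zones for the zone model", call. = FALSE)
  }
  y <- log(values$median_intensity)
  grp <- match(values$mouse, sort(unique(values$mouse)))
  if (include_zone) {
    zone <- factor(values$zone)
    X <- stats::model.matrix(~zone)
    colnames(X) <- c("(Intercept)", paste0(levels(zone)[-1], "-", levels(zone)[1]))
  } else {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }
  grid <- c(0, 10^seq(-4, 3, length.out = 36))
  lls <- vapply(grid, function(l) .profile_ll(l, y, X, grp)$ll, numeric(1))
  best <- which.max(lls)
  if (best == 1) {
    lambda <- 0
  } else {
    lo <- grid[max(best - 1, 1)]
    hi <- grid[min(best + 1, length(grid))]
    opt <- stats::optimize(
      function(ll) .profile_ll(exp(ll), y, X, grp)$ll,
      interval = log(c(max(lo, 1e-8), hi)), maximum = TRUE, tol = 1e-8
    )
    lambda <- exp(opt$maximum)
    if (.profile_ll(0, y, X, grp)$ll >= opt$objective) lambda <- 0
  }
  fit <- .profile_ll(lambda, y, X, grp)
  structure(
    list(
      fixed_effects = stats::setNames(as.vector(fit$beta), colnames(X)),
      var_mouse = lambda * fit$sigma2,
      var_resid = fit$sigma2,
      loglik_ml = fit$ll,
      lambda = lambda,
      n = length(y),
      include_zone = include_zone
    ),
    class = "lmm_ri"
  )
}

#' @export
print.lmm_ri <- function(x, ...) {
  cat("<lmm_ri> ML random-intercept fit, n = ", x$n,
    ", logLik = ", round(x$loglik_ml, 3), "\n",
    sep = ""
  )
  print(round(x$fixed_effects, 4))
  cat(
    "var_mouse = ", signif(x$var_mouse, 4),
    ", var_resid = ", signif(x$var_resid, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy lmm_ri
#' @export
tidy.lmm_ri <- function(x, ...) {
  tibble::tibble(term = names(x$fixed_effects), estimate = unname(x$fixed_effects))
}

#' @method glance lmm_ri
#' @export
glance.lmm_ri <- function(x, ...) {
  tibble::tibble(
    var_mouse = x$var_mouse, var_resid = x$var_resid,
    logLik = x$loglik_ml, lambda = x$lambda, nobs = x$n
  )
}

#' Likelihood-ratio chi-square test of the zone factor
#'
#' @param full,null `lmm_ri` fits of the same data with and without the zone
#'   factor.
#' @return A tibble with `chisq` (clipped at 0), `df` and `p` (upper-tail
#'   chi-square).
#' @export
lrt_zone <- function(full, null) {
  stopifnot(inherits(full, "lmm_ri"), inherits(null, "lmm_ri"))
  if (full$n != null$n) stop("fits are on different row counts", call. = FALSE)
  df <- length(full$fixed_effects) - length(null$fixed_effects)
  stopifnot(df >= 1)
  chisq <- max(0, 2 * (full$loglik_ml - null$loglik_ml))
  tibble::tibble(
    chisq = chisq, df = df,
    p = stats::pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p values in (0, 1].
#' @return Adjusted q values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Percent coefficient of variation
#'
#' @param x Numeric vector of replicate intensities (length >= 2).
#' @return `100 * sd(x) / mean(x)`; `NA` with a warning when the mean is 0.
#' @export
percent_cv <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m == 0) {
    warning("mean is zero; %CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Zone differential test for every lipid
#'
#' Fits the random-intercept model with and without the zone factor per
#' lipid, reports the likelihood-ratio chi-square p value, applies
#' Benjamini-Hochberg adjustment across lipids, and attaches the dominant
#' zone. Zeros are replaced by half the smallest positive intensity of that
#' lipid (reported via a message).
#'
#' @param table Zonal long table from [extract_roi_medians()].
#' @param library Optional lipid library to attach `lipid_class`.
#' @param alpha Significance level on the adjusted values (default 0.05).
#' @return A tibble of class `zonation_test`: `lipid_id`, `chisq`, `df`,
#'   `p`, `q`, `significant`, `dominant_zone`, `tie` and (when the library
#'   is given) `lipid_class`.
#' @export
test_zonation <- function(table, library = NULL, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  n_zero <- sum(table$median_intensity == 0)
  if (n_zero) {
    message(n_zero, " zero intensit(ies) replaced by half the lipid's smallest positive value")
    table <- table |>
      dplyr::group_by(.data$lipid_id) |>
      dplyr::mutate(median_intensity = ifelse(
        .data$median_intensity == 0,
        min(.data$median_intensity[.data$median_intensity > 0]) / 2,
        .data$median_intensity
      )) |>
      dplyr::ungroup()
  }
  lips <- sort(unique(table$lipid_id))
  res <- lapply(lips, function(l) {
    d <- table[table$lipid_id == l, ]
    full <- fit_random_intercept(d, include_zone = TRUE)
    null <- fit_random_intercept(d, include_zone = FALSE)
    lrt_zone(full, null)
  })
  out <- dplyr::bind_rows(res)
  out$lipid_id <- lips
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out <- dplyr::left_join(out, dominant_zone(table), by = "lipid_id")
  if (!is.null(library)) {
    out <- dplyr::left_join(out,
      library[, c("id", "lipid_class")],
      by = c(lipid_id = "id")
    )
  }
  out <- out[, c(
    "lipid_id", "chisq", "df", "p", "q", "significant",
    "dominant_zone", "tie",
    intersect("lipid_class", names(out))
  )]
  class(out) <- c("zonation_test", class(out))
  out
}

#' Reproducibility of zone-median intensities across replicate acquisitions
#'
#' For each lipid and zone, the zone-median intensity (median of the ROI
#' medians) is computed per replicate, and the percent coefficient of
#' variation is taken across replicates; the per-lipid value averages the
#' three zones.
#'
#' @param table Zonal long table whose `mouse` column indexes replicate
#'   acquisitions (see [simulate_replicates()]).
#' @return A tibble `lipid_id`, `mean_intensity`, `cv_percent`.
#' @export
replicate_cv <- function(table) {
  table |>
    dplyr::group_by(.data$lipid_id, .data$mouse, .data$zone) |>
    dplyr::summarise(zm = stats::median(.data$median_intensity), .groups = "drop") |>
    dplyr::group_by(.data$lipid_id, .data$zone) |>
    dplyr::summarise(
      cv = percent_cv(.data$zm),
      m = mean(.data$zm), .groups = "drop"
    ) |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::summarise(
      mean_intensity = mean(.data$m),
      cv_percent = mean(.data$cv), .groups = "drop"
    )
}
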