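# Idealised hexagonal lobule geometry and the porto-central zonal coordinate.

#' Hexagonal lobule geometry
#'
#' Describes one idealised liver lobule on a pixel grid: a central vein at the
#' grid centre and six portal triads at the hexagon vertices. The zonal
#' coordinate of a pixel is `u = d_vertex / (d_vertex + d_center)`, the
#' normalised position along the porto-central axis (`u = 0` at a portal
#' triad, `u = 1` at the central vein), with `d_vertex` the distance to the
#' nearest vertex.
#'
#' @param grid_shape Integer `(rows, cols)` of the pixel grid.
#' @param pixel_size Pixel edge length in micrometres (default 50).
#' @param hexagon_center Grid coordinates `(row, col)` of the central vein;
#'   default is the grid centre.
#' @param radius Circumradius of the hexagon in pixels; default fills the
#'   grid with a one-pixel margin.
#' @param zone_thresholds Two increasing cut points on the zonal coordinate
#'   in (0, 1) separating Z1/Z2/Z3, or `NULL` (default) to use the empirical
#'   terciles of the in-lobule coordinate distribution, which yields three
#'   zones of near-equal pixel area.
#' @return An object of class `lobule_geometry`.
#' @examples
#' geo <- lobule_geometry(c(40, 40))
#' @export
lobule_geometry <- function(grid_shape = c(40, 40), pixel_size = 50,
                            hexagon_center = NULL, radius = NULL,
                            zone_thresholds = NULL) {
  stopifnot(
    length(grid_shape) == 2, all(grid_shape >= 3),
    is.numeric(pixel_size), pixel_size > 0
  )
  grid_shape <- as.integer(grid_shape)
  if (is.null(hexagon_center)) {
    hexagon_center <- (grid_shape + 1) / 2
  }
  if (is.null(radius)) {
    radius <- min(grid_shape) / 2 - 1
  }
  stopifnot(radius > 0)
  if (!is.null(zone_thresholds)) {
    stopifnot(
      length(zone_thresholds) == 2,
      zone_thresholds[1] > 0, zone_thresholds[2] < 1,
      zone_thresholds[1] < zone_thresholds[2]
    )
  }
  ang <- (0:5) * pi / 3
  vertices <- cbind(
    row = hexagon_center[1] + radius * sin(ang),
    col = hexagon_center[2] + radius * cos(ang)
  )
  structure(
    list(
      grid_shape = grid_shape, pixel_size = pixel_size,
      hexagon_center = hexagon_center, radius = radius,
      vertices = vertices, zone_thresholds = zone_thresholds
    ),
    class = "lobule_geometry"
  )
}

#' @export
print.lobule_geometry <- function(x, ...) {
  cat(
    "<lobule_geometry> ", x$grid_shape[1], "x", x$grid_shape[2],
    " grid, pixel ", x$pixel_size, " um, circumradius ", round(x$radius, 1),
    " px\n",
    sep = ""
  )
  invisible(x)
}

# Point-in-convex-polygon (boundary inclusive, orientation-agnostic).
.in_hexagon <- function(row, col, vertices) {
  n <- nrow(vertices)
  pos <- rep(TRUE, length(row))
  neg <- rep(TRUE, length(row))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    er <- vertices[j, "row"] - vertices[i, "row"]
    ec <- vertices[j, "col"] - vertices[i, "col"]
    cr <- ec * (row - vertices[i, "row"]) - er * (col - vertices[i, "col"])
    pos <- pos & (cr >= -1e-9)
    neg <- neg & (cr <= 1e-9)
  }
  pos | neg
}

#' Zonal classification of every grid pixel
#'
#' Computes the porto-central coordinate of every pixel and labels in-lobule
#' pixels Z1 (periportal), Z2 (midzone) or Z3 (pericentral) by thresholding.
#' Pixels outside the hexagon carry `NA` (background).
#'
#' @param geometry A [lobule_geometry()].
#' @return A tibble with columns `row`, `col`, `u` (zonal coordinate, `NA`
#'   outside the lobule) and `zone` (factor Z1/Z2/Z3 or `NA`), plus the
#'   thresholds used as attribute `"zone_thresholds"`.
#' @examples
#' zm <- lobule_zone_map(lobule_geometry(c(40, 40)))
#' table(zm$zone)
#' @export
lobule_zone_map <- function(geometry) {
  stopifnot(inherits(geometry, "lobule_geometry"))
  v <- geometry$vertices
  ctr <- geometry$hexagon_center
  dcv <- sqrt((v[, "row"] - ctr[1])^2 + (v[, "col"] - ctr[2])^2)
  if (any(dcv < 1e-9)) {
    stop("invalid geometry: hexagon center coincides with a vertex", call. = FALSE)
  }
  if (!.in_hexagon(ctr[1], ctr[2], v)) {
    stop("invalid geometry: center not inside the hexagon", call. = FALSE)
  }
  g <- expand.grid(
    col = seq_len(geometry$grid_shape[2]),
    row = seq_len(geometry$grid_shape[1])
  )
  inside <- .in_hexagon(g$row, g$col, v)
  d_center <- sqrt((g$row - ctr[1])^2 + (g$col - ctr[2])^2)
  d_vertex <- sqrt(
    (outer(g$row, v[, "row"], "-"))^2 + (outer(g$col, v[, "col"], "-"))^2
  )
  d_vertex <- apply(d_vertex, 1, min)
  denom <- d_vertex + d_center
  u <- ifelse(denom > 0, d_vertex / denom, 1) # center pixel: u = 1
  u[!inside] <- NA_real_
  thr <- geometry$zone_thresholds
  if (is.null(thr)) {
    thr <- unname(stats::quantile(u[inside], c(1 / 3, 2 / 3), names = FALSE))
  }
  zone <- cut(u, c(-Inf, thr, Inf), labels = c("Z1", "Z2", "Z3"))
  out <- tibble::tibble(
    row = as.integer(g$row), col = as.integer(g$col),
    u = u, zone = zone
  )
  attr(out, "zone_thresholds") <- thr
  out
}

#' Plot the zone map of a lobule
#'
#' @param zone_map A tibble from [lobule_zone_map()].
#' @return A ggplot object.
#' @export
plot_zone_map <- function(zone_map) {
  ggplot2::ggplot(
    dplyr::filter(zone_map, !is.na(.data$zone)),
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$zone)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(Z1 = "#c0392b", Z2 = "#f1c40f", Z3 = "#2980b9"),
      name = "Zone"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "column", y = "row",
      title = "Lobule zonation (Z1 periportal, Z2 midzone, Z3 pericentral)"
    ) +
    ggplot2::theme_minimal()
}
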