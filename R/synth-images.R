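# Synthetic cell image generator.
#
# The head outline is an ellipse (semi-axes L/2 and HW/2) modulated by a
# four-fold radial ripple r(theta) = e(theta) * (1 - eps*(1 - cos 4theta)/2).
# The ripple vanishes along both principal axes, so head length and width
# are preserved exactly, while increasing eps lengthens the boundary and
# lowers circularity; eps is solved numerically so the rendered head matches
# a requested C. Brightfield renders the head at a baseline gray with an
# elevated-gray anterior acrosome, darker circular vacuoles inside the
# acrosome and a dimmer midpiece rectangle adjoining the posterior pole.
# Green/red fluorescence are uniform over the head and encode DFI.

MAX_RIPPLE <- 0.35

# boundary radius at polar angle theta for semi-axes a >= b
shape_radius <- function(theta, a, b, eps) {
  e <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  e * (1 - eps * (1 - cos(4 * theta)) / 2)
}

#' Analytic area, perimeter and circularity of a generator head outline
#'
#' @param L,HW head length and width in micrometers.
#' @param eps ripple amplitude in `[0, 0.35]`.
#' @param n number of polygon vertices used for the quadrature.
#' @return list with `area` (um^2), `perimeter` (um) and `C`.
#' @export
head_shape_metrics <- function(L, HW, eps = 0, n = 1024L) {
  stopifnot(L > 0, HW > 0, eps >= 0)
  theta <- seq(0, 2 * pi, length.out = n + 1L)
  r <- shape_radius(theta, L / 2, HW / 2, eps)
  x <- r * cos(theta)
  y <- r * sin(theta)
  area <- abs(sum(x[-1] * y[-(n + 1)] - x[-(n + 1)] * y[-1])) / 2
  perim <- sum(sqrt(diff(x)^2 + diff(y)^2))
  list(area = area, perimeter = perim, C = 4 * pi * area / perim^2)
}

#' Circularity range renderable for a given head length and width
#'
#' @inheritParams head_shape_metrics
#' @return numeric vector `c(min, max)`: circularity at the maximum ripple
#'   amplitude and at zero ripple (plain ellipse).
#' @export
shape_c_range <- function(L, HW) {
  c(head_shape_metrics(L, HW, MAX_RIPPLE)$C, head_shape_metrics(L, HW, 0)$C)
}

# largest radius <= r0 at which a disc centered on the major axis at u = cu
# fits inside the head outline with the given margin and stays anterior of
# u_min; 0 when no disc of at least 0.05 um fits
fit_disc_radius <- function(r0, cu, a, b, eps, u_min, margin = 0.15) {
  phi <- seq(0, 2 * pi, length.out = 33L)[-33L]
  fits <- function(r) {
    if (cu - r < u_min) return(FALSE)
    px <- cu + r * cos(phi)
    py <- r * sin(phi)
    all(sqrt(px^2 + py^2) <= shape_radius(atan2(py, px), a, b, eps) - margin)
  }
  r <- r0
  for (i in 1:25) {
    if (fits(r)) return(r)
    r <- 0.92 * r
    if (r < 0.05) return(0)
  }
  0
}

# solve ripple amplitude for a target circularity; clamps to the renderable
# range and reports the achieved C
solve_ripple <- function(L, HW, C_target) {
  rng <- shape_c_range(L, HW)
  if (C_target >= rng[2]) {
    eps <- 0
  } else if (C_target <= rng[1]) {
    eps <- MAX_RIPPLE
  } else {
    eps <- stats::uniroot(function(e) head_shape_metrics(L, HW, e)$C - C_target,
                          c(0, MAX_RIPPLE), tol = 1e-6)$root
  }
  m <- head_shape_metrics(L, HW, eps)
  list(eps = eps, C = m$C, area = m$area, perimeter = m$perimeter)
}

#' Render a synthetic cell image set
#'
#' Rasterizes one cell's paired brightfield and green/red fluorescence
#' images from its feature record and ground truth. Deterministic given its
#' arguments; randomized placement is drawn by [generate_image_dataset()].
#'
#' @param record one-row data.frame with columns `C`, `HW`, `L`, `MW`, `AA`,
#'   `VA` and `DFI` (the feature-table row type).
#' @param truth optional one-row data.frame from the generator's ground
#'   truth (used for the acrosome fraction); when `NULL` the fraction is
#'   `AA` divided by the rendered head area.
#' @param config a [synth_config()]; supplies pixel size, gray levels,
#'   fluorescence brightness and noise scales.
#' @param orientation_deg rotation of the head's major axis, degrees
#'   counter-clockwise from the raster x (row) axis.
#' @param center_offset_px sub-pixel offset of the head center, length-2.
#' @param midpiece logical; render the midpiece (skipped when `MW` is 0 or
#'   missing).
#' @param noise logical; add the configured Gaussian raster noise.
#' @return an object of class `cell_image_set`: list with numeric matrices
#'   `brightfield`, `green`, `red` (values in `[0, 1]`), `pixel_size_um`,
#'   and a `truth` list recording the rendered geometry (ripple amplitude,
#'   achieved circularity, acrosome fraction, rendered vacuole area in
#'   um^2).
#' @export
generate_cell_images <- function(record, truth = NULL, config = synth_config(),
                                 orientation_deg = 0,
                                 center_offset_px = c(0, 0),
                                 midpiece = TRUE, noise = TRUE) {
  px <- config$pixel_size_um
  stopifnot(px > 0)
  L <- record$L; HW <- record$HW; MW <- record$MW
  if (!is.finite(MW) || MW <= 0) midpiece <- FALSE
  a <- L / 2; b <- HW / 2
  if (HW > L) stop("generation error: head width exceeds head length")
  sol <- solve_ripple(L, HW, record$C)

  mp_len <- config$midpiece_length_um
  half_um <- a + (if (midpiece) mp_len else 0) + config$raster_margin_um
  n_side <- 2L * as.integer(ceiling(half_um / px)) + 1L
  if (n_side > config$max_raster_px) {
    stop("generation error: head does not fit in the raster")
  }
  ctr <- (n_side + 1) / 2
  xs <- (seq_len(n_side) - ctr - center_offset_px[1]) * px
  ys <- (seq_len(n_side) - ctr - center_offset_px[2]) * px
  th <- orientation_deg * pi / 180
  # coordinates in the head frame (u along the major axis, anterior = +u)
  u <- outer(xs, ys, function(x, y) cos(th) * x + sin(th) * y)
  v <- outer(xs, ys, function(x, y) -sin(th) * x + cos(th) * y)
  ang <- atan2(v, u)
  rad <- sqrt(u^2 + v^2)
  head <- rad <= shape_radius(ang, a, b, sol$eps)
  if (!any(head)) stop("generation error: empty head raster")

  g <- config$gray_levels
  bf <- matrix(g[["background"]], n_side, n_side)
  bf[head] <- g[["head"]]

  # acrosome: anterior region holding a fraction `frac` of the head pixels
  frac <- if (!is.null(truth) && !is.null(truth$acrosome_fraction)) {
    truth$acrosome_fraction
  } else {
    min(max(record$AA / sol$area, 0), 0.95)
  }
  acro <- head & FALSE
  if (frac > 0) {
    u_cut <- stats::quantile(u[head], 1 - frac, names = FALSE, type = 7)
    acro <- head & (u > u_cut)
    bf[acro] <- g[["acrosome"]]
  }

  # vacuoles: circles on the major axis inside the acrosome
  vac_area_req <- if (!is.null(truth) && !is.null(truth$vacuole_area)) {
    truth$vacuole_area
  } else {
    record$VA
  }
  vac <- head & FALSE
  if (is.finite(vac_area_req) && vac_area_req > 0 && any(acro)) {
    u_cut <- min(u[acro])
    u_tip <- max(u[acro])
    depth <- u_tip - u_cut
    n_vac <- if (vac_area_req > 1.1) 2L else 1L
    shares <- if (n_vac == 2L) c(0.6, 0.4) else 1
    pos <- if (n_vac == 2L) c(0.3, 0.72) else 0.5
    for (i in seq_len(n_vac)) {
      r_i <- sqrt(shares[i] * vac_area_req / pi)
      cu <- u_cut + pos[i] * depth
      # shrink the disc until it fits inside the head boundary (with a
      # margin) and stays clear of the acrosome step
      r_i <- fit_disc_radius(r_i, cu, a, b, sol$eps,
                             u_min = u_cut + 0.1, margin = 0.15)
      if (r_i > 0) vac <- vac | ((u - cu)^2 + v^2 <= r_i^2 & acro)
    }
    bf[vac] <- g[["vacuole"]]
  }

  if (midpiece) {
    mp <- !head & u >= -(a + mp_len) & u <= -a + 0.2 & abs(v) <= MW / 2
    bf[mp] <- g[["midpiece"]]
  }

  gb <- config$fluor_brightness * (1 - record$DFI)
  rb <- config$fluor_brightness * record$DFI
  green <- matrix(0, n_side, n_side); green[head] <- gb
  red <- matrix(0, n_side, n_side); red[head] <- rb
  if (noise) {
    bf <- bf + stats::rnorm(length(bf), 0, config$image_noise_sd)
    green <- green + stats::rnorm(length(green), 0, config$fluor_noise_sd)
    red <- red + stats::rnorm(length(red), 0, config$fluor_noise_sd)
  }
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  structure(list(
    brightfield = clip01(bf), green = clip01(green), red = clip01(red),
    pixel_size_um = px,
    truth = list(eps = sol$eps, C = sol$C, head_area = sol$area,
                 head_perimeter = sol$perimeter,
                 acrosome_fraction = frac,
                 vacuole_area = sum(vac) * px^2)
  ), class = "cell_image_set")
}

#' @export
print.cell_image_set <- function(x, ...) {
  cat(sprintf("cell_image_set: %d x %d px at %.3f um/px\n",
              nrow(x$brightfield), ncol(x$brightfield), x$pixel_size_um))
  invisible(x)
}

#' Generate a full synthetic image dataset
#'
#' Draws a feature table with [generate_feature_table()] (forcing
#' shape-consistent features so every record is renderable) and rasterizes
#' each cell with a seeded random orientation and sub-pixel placement.
#'
#' @param config a [synth_config()].
#' @return list with `table`, `truth` (as [generate_feature_table()]) and
#'   `images`, a list of `cell_image_set` objects (one per row).
#' @export
generate_image_dataset <- function(config = synth_config()) {
  config$shape_consistent <- TRUE
  ft <- generate_feature_table(config)
  n <- nrow(ft$table)
  with_seed(config$seed + 1L, {
    angles <- stats::runif(n, 0, 360)
    offs <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2)
    images <- lapply(seq_len(n), function(i) {
      generate_cell_images(ft$table[i, ], ft$truth[i, ], config,
                           orientation_deg = angles[i],
                           center_offset_px = offs[i, ])
    })
  })
  list(table = ft$table, truth = ft$truth, images = images)
}
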