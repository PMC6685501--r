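# Brightfield morphometry: head segmentation and the six morphological
# parameters (A, P, HW, L, MW, AA, VA) plus circularity C = 4*pi*A/P^2.
#
# Conventions: rasters are numeric matrices indexed [x, y] with pixel
# centers at integer coordinates (row-major, 1-based in R); every reported
# length/area is converted to micrometers before leaving the module.

#' Segment the sperm head from a brightfield image
#'
#' Foreground is taken above an Otsu gray threshold, cleaned by a small
#' morphological opening, reduced to its largest connected component and
#' hole-filled. A dim thin appendage (the midpiece/tail) is excluded by a
#' second, guarded Otsu split of the foreground grays: the split is applied
#' only when the two gray classes are well separated (between-class mean
#' difference above `split_guard` times the within-class sd) and only
#' removes low-gray components markedly thinner than the cell (maximum
#' inscribed width below 0.7x the hole-filled foreground's), so a uniform
#' head or a bright acrosome is never cut.
#'
#' @param brightfield numeric matrix, gray values in `[0, 1]`.
#' @param pixel_size_um pixel size in micrometers.
#' @param min_area_um2 minimum head area; smaller foregrounds raise
#'   `NoCellFound`.
#' @param noise_opening_um radius of the noise-cleanup opening.
#' @param split_guard bimodality guard ratio (an Otsu split of a unimodal
#'   normal yields about 2.65).
#' @return an object of class `head_mask`: list with logical `mask`,
#'   `centroid` (pixel coords), `axis` (unit vector of the principal axis),
#'   `pixel_size_um`.
#' @export
segment_head <- function(brightfield, pixel_size_um,
                         min_area_um2 = 1, noise_opening_um = 0.05,
                         split_guard = 3) {
  stopifnot(length(dim(brightfield)) == 2, pixel_size_um > 0)
  thr <- otsu_threshold(as.numeric(brightfield))
  fg <- brightfield > thr
  fg <- open_disc(fg, noise_opening_um / pixel_size_um)
  if (!any(fg)) stop("NoCellFound: no foreground above threshold")

  # guarded intensity split: head vs dim thin appendage
  vals <- brightfield[fg]
  t2 <- otsu_threshold(vals)
  lo <- vals[vals <= t2]; hi <- vals[vals > t2]
  keep <- fg
  if (length(lo) > 20 && length(hi) > 20) {
    sw <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                 (length(vals) - 2))
    # sw = 0 (noiseless classes) counts as perfect separation
    if ((mean(hi) - mean(lo)) > split_guard * sw) {
      head_part <- fg & brightfield > t2
      if (any(head_part)) {
        # reference width: the whole (hole-filled) cell, which the head
        # dominates; an appendage is markedly thinner than it
        cell_width <- max_inscribed_radius(fill_holes(fg))
        lab <- EBImage::bwlabel(EBImage::Image((fg & !head_part) * 1))
        labm <- EBImage::imageData(lab)
        for (id in seq_len(max(labm))) {
          comp <- labm == id
          if (max_inscribed_radius(comp) < 0.7 * cell_width) {
            keep <- keep & !comp
          }
        }
      }
    }
  }

  comp <- largest_component(keep, warn_multiple = TRUE)
  if (is.null(comp)) stop("NoCellFound: no component above threshold")
  comp <- fill_holes(comp)
  if (sum(comp) * pixel_size_um^2 < min_area_um2) {
    stop("NoCellFound: largest component smaller than ", min_area_um2, " um^2")
  }
  idx <- which(comp, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (axis[1] < 0 || (axis[1] == 0 && axis[2] < 0)) axis <- -axis
  structure(list(mask = comp, centroid = ctr, axis = axis,
                 pixel_size_um = pixel_size_um),
            class = "head_mask")
}

#' @export
print.head_mask <- function(x, ...) {
  cat(sprintf("head_mask: %d px (%.2f um^2), centroid (%.1f, %.1f)\n",
              sum(x$mask), sum(x$mask) * x$pixel_size_um^2,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

# projections of mask pixels onto the principal and perpendicular axes, px
mask_projections <- function(mask_obj) {
  idx <- which(mask_obj$mask, arr.ind = TRUE)
  cc <- sweep(idx, 2, mask_obj$centroid)
  list(along = cc %*% mask_obj$axis,
       across = cc %*% c(-mask_obj$axis[2], mask_obj$axis[1]),
       idx = idx)
}

#' Measure head area, perimeter, length and width
#'
#' Area is the pixel count times the pixel area. The perimeter is the
#' length of the sub-pixel marching-squares contour of the Gaussian-smoothed
#' (sigma = 1 px) mask at the 0.5 level; raw boundary-pixel counting biases
#' circularity low by up to 20%. Length and width are full extents of the
#' mask along/perpendicular to the principal axis (plus one pixel for the
#' pixel footprint).
#'
#' @param mask a `head_mask` from [segment_head()].
#' @param pixel_size_um pixel size; defaults to the mask's.
#' @return list with `A` (um^2), `P` (um), `L`, `HW` (um).
#' @export
measure_head <- function(mask, pixel_size_um = mask$pixel_size_um) {
  stopifnot(inherits(mask, "head_mask"))
  npx <- sum(mask$mask)
  if (npx < 4) stop("MeasurementError: degenerate mask")
  px <- pixel_size_um
  A <- npx * px^2
  cont <- subpixel_contour(mask$mask)
  if (is.null(cont)) stop("MeasurementError: no contour found")
  P <- cont$length_px * px
  pr <- mask_projections(mask)
  L <- (max(pr$along) - min(pr$along) + 1) * px
  HW <- (max(pr$across) - min(pr$across) + 1) * px
  if (HW > L) { tmp <- L; L <- HW; HW <- tmp }
  list(A = A, P = P, L = L, HW = HW)
}

#' Head circularity
#'
#' C = 4*pi*A/P^2: 1 for a perfect circle, decreasing with elongation or
#' boundary irregularity.
#'
#' @param A head area (um^2), positive.
#' @param P head perimeter (um), positive.
#' @return circularity, dimensionless.
#' @export
circularity <- function(A, P) {
  if (any(A <= 0) || any(P <= 0)) {
    stop("DomainError: area and perimeter must be positive")
  }
  4 * pi * A / P^2
}

#' Gray-value profile along the head's major axis
#'
#' Mean gray of mask pixels in one-pixel-wide slabs perpendicular to the
#' principal axis, ordered posterior (tail) to anterior (tip). When
#' `tip_direction` is not given, the anterior end is taken as the end whose
#' outer quarter is brighter (the acrosome convention).
#'
#' @param brightfield numeric matrix.
#' @param mask a `head_mask`.
#' @param tip_direction optional +1/-1: sign of the principal-axis
#'   direction pointing to the anterior tip.
#' @return data.frame with `position_um` (slab center along the axis,
#'   relative to the posterior end) and `gray`.
#' @export
axial_gray_profile <- function(brightfield, mask, tip_direction = NULL) {
  stopifnot(inherits(mask, "head_mask"))
  pr <- mask_projections(mask)
  gray <- brightfield[pr$idx]
  prof <- slab_means(gray, pr$along)
  if (is.null(tip_direction)) {
    k <- max(1L, floor(length(prof) / 4))
    tip_direction <- if (mean(utils::tail(prof, k)) >= mean(utils::head(prof, k))) 1 else -1
  }
  if (tip_direction < 0) prof <- rev(prof)
  data.frame(position_um = (seq_along(prof) - 0.5) * mask$pixel_size_um,
             gray = unname(prof),
             row.names = NULL)
}

# per-slab statistic of `values` in 1-px slabs along the projection, in
# axis order; empty slabs are interpolated from neighbours
slab_stats <- function(values, along, stat = mean) {
  slab <- floor(along - min(along)) + 1L
  n <- max(slab)
  sums <- tapply(values, factor(slab, levels = seq_len(n)), stat)
  out <- as.numeric(sums)
  if (anyNA(out)) {
    ok <- which(!is.na(out))
    out <- stats::approx(ok, out[ok], xout = seq_len(n), rule = 2)$y
  }
  out
}

slab_means <- function(values, along) slab_stats(values, along, mean)

#' Acrosome area from the axial gray step
#'
#' The acrosome boundary is where the gray value along the major axis
#' sharply increases: the position of the maximum of the smoothed profile's
#' first derivative (smoothing window 3 slabs, reflective ends). The step is
#' accepted when its height exceeds `k` times the profile noise sd
#' (estimated from first differences); otherwise AA = 0 is returned with
#' the `no_acrosome_detected` flag. AA is the head area anterior to the
#' boundary, so AA plus the posterior area partitions A exactly.
#'
#' When the brightfield raster is supplied, boundary detection uses a
#' vacuole-robust profile (the 90th-percentile gray per slab) instead of the
#' supplied mean profile: an intra-acrosomal vacuole depresses the slab mean
#' and its anterior edge can out-slope the acrosome step, whereas an upper
#' quantile ignores a partial-width vacuole entirely.
#'
#' @param profile data.frame from [axial_gray_profile()] (must be oriented
#'   with the same `tip_direction` used here).
#' @param mask a `head_mask`.
#' @param brightfield numeric matrix (used to orient the axis when
#'   `tip_direction` is `NULL` and for the robust boundary profile).
#' @param k step-height acceptance multiple (default 3).
#' @param tip_direction optional +1/-1, as in [axial_gray_profile()].
#' @return list with `AA` (um^2), `boundary_um` (position from the
#'   posterior end, `NA` when rejected), `flag` (`"ok"` or
#'   `"no_acrosome_detected"`).
#' @export
measure_acrosome <- function(profile, mask, brightfield = NULL, k = 3,
                             tip_direction = NULL) {
  stopifnot(inherits(mask, "head_mask"))
  pr0 <- mask_projections(mask)
  if (!is.null(brightfield)) {
    if (is.null(tip_direction)) {
      raw <- slab_means(brightfield[pr0$idx], pr0$along)
      kq <- max(1L, floor(length(raw) / 4))
      tip_direction <- if (mean(utils::tail(raw, kq)) >= mean(utils::head(raw, kq))) 1 else -1
    }
    g <- slab_stats(brightfield[pr0$idx], pr0$along,
                    function(v) stats::quantile(v, 0.9, names = FALSE))
    if (tip_direction < 0) g <- rev(g)
  } else {
    if (is.null(tip_direction)) tip_direction <- 1
    g <- profile$gray
  }
  n <- length(g)
  if (n < 4) return(list(AA = 0, boundary_um = NA_real_,
                         flag = "no_acrosome_detected"))
  gs <- smooth_reflect(g, 3L)
  d <- diff(gs)
  b <- which.max(d)
  lo <- mean(g[max(1, b - 4):b])
  hi <- mean(g[(b + 1):min(n, b + 5)])
  step <- hi - lo
  noise <- stats::mad(diff(g)) / sqrt(2)
  if (noise == 0) noise <- stats::sd(g) / sqrt(max(n, 2))
  if (!is.finite(step) || step <= k * max(noise, 1e-12)) {
    return(list(AA = 0, boundary_um = NA_real_,
                flag = "no_acrosome_detected"))
  }
  # sub-slab boundary: where the smoothed profile crosses the midpoint of
  # the two plateaus, linearly interpolated between slab centers
  target <- (lo + hi) / 2
  jr <- seq(max(1, b - 2), min(n - 1, b + 2))
  jc <- jr[gs[jr] <= target & gs[jr + 1] > target]
  boundary_um <- if (length(jc) > 0) {
    j <- jc[which.min(abs(jc - b))]
    frac <- (target - gs[j]) / (gs[j + 1] - gs[j])
    (j - 0.5 + frac) * mask$pixel_size_um
  } else {
    b * mask$pixel_size_um  # between slab b and b + 1
  }
  along <- pr0$along * tip_direction
  pos <- along - min(along)  # 0 at posterior end, px
  AA_px <- sum(pos * mask$pixel_size_um >= boundary_um)
  list(AA = AA_px * mask$pixel_size_um^2, boundary_um = boundary_um,
       flag = "ok")
}

# moving average with reflective ends, odd window
smooth_reflect <- function(v, w = 3L) {
  r <- (w - 1L) %/% 2L
  vp <- c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2))[(r + 1):(r + length(v))]
}

#' Total acrosomal vacuole area
#'
#' Vacuoles are connected regions inside the head whose gray deviates from
#' the local head gray by more than `contrast_threshold` and whose area is
#' at least `min_area_um2`. The local reference gray is the median within
#' the acrosomal and posterior sub-regions separately (each eroded by one
#' pixel to avoid boundary mixing), so the acrosome's elevated baseline is
#' not itself flagged.
#'
#' @param brightfield numeric matrix.
#' @param mask a `head_mask`.
#' @param acrosome_mask optional logical matrix of the acrosomal region;
#'   when `NULL` the whole head is treated as one region.
#' @param contrast_threshold gray deviation (fraction of dynamic range)
#'   above which a pixel is vacuole-candidate (default 0.12).
#' @param min_area_um2 minimum vacuole size (default 0.05 um^2).
#' @return list with `VA` (um^2) and `n_vacuoles`.
#' @export
measure_vacuoles <- function(brightfield, mask, acrosome_mask = NULL,
                             contrast_threshold = 0.12, min_area_um2 = 0.05) {
  stopifnot(inherits(mask, "head_mask"))
  px <- mask$pixel_size_um
  regions <- if (is.null(acrosome_mask) || !any(acrosome_mask)) {
    list(mask$mask)
  } else {
    list(mask$mask & acrosome_mask, mask$mask & !acrosome_mask)
  }
  cand <- mask$mask & FALSE
  for (reg in regions) {
    if (!any(reg)) next
    reg_in <- !open_disc(!reg, 1) & reg  # 1-px erosion
    if (!any(reg_in)) reg_in <- reg
    ref <- stats::median(brightfield[reg_in])
    cand <- cand | (reg_in & abs(brightfield - ref) > contrast_threshold)
  }
  if (!any(cand)) return(list(VA = 0, n_vacuoles = 0L))
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  labm <- EBImage::imageData(lab)
  counts <- tabulate(labm[labm > 0])
  keep <- which(counts * px^2 >= min_area_um2)
  list(VA = sum(counts[keep]) * px^2, n_vacuoles = length(keep))
}

#' Midpiece width
#'
#' The midpiece is the thin foreground structure adjoining the head's
#' posterior pole (foreground above the Otsu threshold, minus the head).
#' Its width is measured perpendicular to the head's principal axis in
#' one-pixel slabs over the first micrometer posterior to the head; MW is
#' the median slab width. Cells without an adjoining structure return
#' `NA` with the `no_midpiece` flag.
#'
#' @param brightfield numeric matrix.
#' @param mask a `head_mask`.
#' @param extent_um axial distance over which widths are collected.
#' @return list with `MW` (um, `NA` when missing) and `flag`.
#' @export
measure_midpiece <- function(brightfield, mask, extent_um = 1) {
  stopifnot(inherits(mask, "head_mask"))
  px <- mask$pixel_size_um
  thr <- otsu_threshold(as.numeric(brightfield))
  fg <- brightfield > thr
  fg <- open_disc(fg, 0.05 / px)
  rest <- fg & !mask$mask
  if (!any(rest)) return(list(MW = NA_real_, flag = "no_midpiece"))
  # components adjacent to the head
  dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask$mask * 1), EBImage::makeBrush(5, "disc"))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(rest * 1))
  labm <- EBImage::imageData(lab)
  touching <- unique(labm[dil & labm > 0])
  touching <- touching[touching > 0]
  if (length(touching) == 0) return(list(MW = NA_real_, flag = "no_midpiece"))
  mp <- matrix(labm %in% touching, nrow(labm), ncol(labm))
  idx <- which(mp, arr.ind = TRUE)
  cc <- sweep(idx, 2, mask$centroid)
  along <- cc %*% mask$axis
  across <- cc %*% c(-mask$axis[2], mask$axis[1])
  prh <- mask_projections(mask)
  # posterior side: where the adjoining structure's mass lies
  side <- if (mean(along) < 0) -1 else 1
  head_edge <- if (side < 0) min(prh$along) else max(prh$along)
  dist_beyond <- side * (along - head_edge)
  sel <- dist_beyond > 0 & dist_beyond <= extent_um / px
  if (sum(sel) < 3) return(list(MW = NA_real_, flag = "no_midpiece"))
  slab <- floor(dist_beyond[sel])
  widths <- vapply(split(across[sel], slab),
                   function(v) (max(v) - min(v) + 1) * px, numeric(1))
  list(MW = stats::median(widths), flag = "ok")
}

#' Measure all morphological parameters of one cell image set
#'
#' Runs segmentation and every morphometric estimator, plus the
#' fluorescence DFI, returning one feature-table row.
#'
#' @param images a `cell_image_set` (fields `brightfield`, `green`, `red`,
#'   `pixel_size_um`).
#' @param contrast_enhance logical; apply a linear 1st-99th percentile
#'   stretch to the brightfield before measuring.
#' @return one-row data.frame with `C`, `HW`, `L`, `MW`, `VA`, `AA`, `A`,
#'   `P`, `green`, `red`, `DFI`, `ln_dfi` and a `flags` string.
#' @export
measure_cell <- function(images, contrast_enhance = FALSE) {
  bf <- images$brightfield
  if (contrast_enhance) bf <- stretch_percentile(bf)
  px <- images$pixel_size_um
  mask <- segment_head(bf, px)
  hm <- measure_head(mask)
  C <- circularity(hm$A, hm$P)
  mw <- measure_midpiece(bf, mask)
  prof <- axial_gray_profile(bf, mask)
  acr <- measure_acrosome(prof, mask, bf)
  acro_mask <- acrosome_region(mask, acr, bf)
  vac <- measure_vacuoles(bf, mask, acro_mask)
  g <- channel_intensity(images$green, mask)
  r <- channel_intensity(images$red, mask)
  d <- compute_dfi(r, g)
  flags <- c(acr$flag, mw$flag)
  flags <- paste(flags[flags != "ok"], collapse = ";")
  data.frame(C = C, HW = hm$HW, L = hm$L, MW = mw$MW, VA = vac$VA,
             AA = acr$AA, A = hm$A, P = hm$P,
             green = g, red = r, DFI = d$DFI, ln_dfi = d$ln_dfi,
             flags = flags, stringsAsFactors = FALSE)
}

# logical raster of the head region anterior to the acrosome boundary
acrosome_region <- function(mask, acr, brightfield) {
  if (!is.finite(acr$boundary_um %||% NA_real_) || acr$AA <= 0) return(NULL)
  pr <- mask_projections(mask)
  prof <- slab_means(brightfield[pr$idx], pr$along)
  kq <- max(1L, floor(length(prof) / 4))
  tip <- if (mean(utils::tail(prof, kq)) >= mean(utils::head(prof, kq))) 1 else -1
  along <- pr$along * tip
  pos_um <- (along - min(along)) * mask$pixel_size_um
  out <- mask$mask & FALSE
  out[pr$idx[pos_um >= acr$boundary_um, , drop = FALSE]] <- TRUE
  out
}

#' Linear percentile contrast stretch
#'
#' Rescales gray values linearly so the 1st and 99th percentiles map to 0
#' and 1 (values outside are clipped); the standard brightfield contrast
#' adjustment applied before acrosome/vacuole reading.
#'
#' @param m numeric matrix.
#' @param probs lower/upper percentiles.
#' @return rescaled matrix.
#' @export
stretch_percentile <- function(m, probs = c(0.01, 0.99)) {
  q <- stats::quantile(m, probs, names = FALSE)
  if (q[2] <= q[1]) return(m)
  pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
}
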