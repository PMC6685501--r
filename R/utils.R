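# Internal helpers: seeded evaluation, truncated normals, raster utilities.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Truncated normal draws by inverse-CDF sampling
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}

#' Separable Gaussian blur of a numeric matrix (reflective boundaries)
#' @noRd
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' Otsu threshold of a numeric vector (256-bin histogram)
#' @noRd
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  # between-class variance for every split point
  w0 <- w[-n_bins]
  w1 <- tot_w - w0
  ok <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (tot_mu - mu[-n_bins]) / w1
  bcv <- ifelse(ok, w0 * w1 * (m0 - m1)^2, -Inf)
  mids[which.max(bcv)] + diff(mids[1:2]) / 2
}

#' Largest connected component of a logical matrix
#' @return logical matrix, or NULL when no component exists
#' @noRd
largest_component <- function(mask, warn_multiple = FALSE) {
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  counts <- tabulate(labm[labm > 0])
  if (warn_multiple && length(counts) > 1) {
    warning("multiple disjoint objects found; keeping the largest",
            call. = FALSE)
  }
  labm == which.max(counts)
}

#' Fill interior holes of a logical matrix
#' @noRd
fill_holes <- function(mask) {
  EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
}

#' Morphological opening with a disc brush of given pixel radius
#' @noRd
open_disc <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  size <- 2L * as.integer(round(radius_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1), brush)) > 0
}

#' Maximum inscribed radius (px) of a logical mask via distance transform
#' @noRd
max_inscribed_radius <- function(mask) {
  if (!any(mask)) return(0)
  max(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
}

#' Length of the longest closed sub-pixel contour of a smoothed mask
#'
#' Marching-squares contour of the Gaussian-smoothed (sigma = 1 px)
#' indicator at the 0.5 level. Returns the polygon (in pixel coordinates)
#' of the longest contour, closed.
#' @noRd
subpixel_contour <- function(mask, sigma = 1) {
  sm <- gauss_blur(mask * 1, sigma)
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)), y = seq_len(ncol(sm)),
                                z = sm, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(p) {
    xs <- c(p$x, p$x[1]); ys <- c(p$y, p$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1))
  p <- cl[[which.max(lens)]]
  list(x = c(p$x, p$x[1]), y = c(p$y, p$y[1]), length_px = max(lens))
}

#' MD5 hash of an R object via its canonical JSON serialization
#' @noRd
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
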