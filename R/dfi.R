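# Per-cell DNA fragmentation index from acridine-orange fluorescence.
#
# Green emission reports native (double-stranded) DNA stainability, red
# reports fragmented (single-stranded) DNA; DFI = red / (red + green).

#' Per-cell channel intensity
#'
#' The cell's intensity in one fluorescence channel: the maximum projected
#' intensity, i.e. the maximum pixel value within the head mask (supply a
#' z-max-projected raster for stacks). Set `integrated = TRUE` to use the
#' summed intensity instead.
#'
#' @param channel numeric matrix, one fluorescence channel.
#' @param mask a `head_mask` or a logical matrix.
#' @param integrated logical; sum instead of max.
#' @param background_subtract logical; subtract the channel's modal
#'   (most frequent, off-cell) gray value first.
#' @return scalar intensity in the channel's native units.
#' @export
channel_intensity <- function(channel, mask, integrated = FALSE,
                              background_subtract = FALSE) {
  m <- if (inherits(mask, "head_mask")) mask$mask else mask
  if (!any(m)) stop("MeasurementError: empty mask")
  if (any(dim(channel) != dim(m))) {
    stop("MeasurementError: mask and channel shapes differ")
  }
  v <- channel[m]
  if (background_subtract) {
    d <- stats::density(as.numeric(channel), n = 512)
    v <- pmax(v - d$x[which.max(d$y)], 0)
  }
  if (integrated) sum(v) else max(v)
}

#' DNA fragmentation index from red and green intensities
#'
#' DFI = red / (red + green); `ln_dfi` is the natural log of DFI after
#' clipping to (1e-6, 1 - 1e-6) so it stays finite at the boundaries.
#'
#' @param red,green non-negative intensities (same units); their sum must be
#'   positive.
#' @return object of class `dfi_result`: list with `green_intensity`,
#'   `red_intensity`, `DFI`, `ln_dfi`.
#' @export
compute_dfi <- function(red, green) {
  if (red < 0 || green < 0) stop("UndefinedDFI: intensities must be >= 0")
  if (red + green <= 0) stop("UndefinedDFI: red + green must be positive")
  dfi <- red / (red + green)
  structure(list(green_intensity = green, red_intensity = red, DFI = dfi,
                 ln_dfi = log(pmin(pmax(dfi, DFI_EPS), 1 - DFI_EPS))),
            class = "dfi_result")
}

#' Summarize a set of DFI results
#'
#' Histogram counts over configurable bins, the fraction of cells within a
#' query interval, and a (green, red) scatter table for the stainability
#' plot.
#'
#' @param results list of `dfi_result` objects, or a numeric vector of DFI
#'   values (scatter omitted).
#' @param breaks histogram breaks over `[0, 1]`.
#' @param interval optional query interval `c(lo, hi)` (closed).
#' @return list with `histogram` (data.frame `bin_lo`, `bin_hi`, `count`),
#'   `fraction_in_interval` (or `NA`), `scatter` (data.frame `green`,
#'   `red`, `DFI`, or `NULL`), `n`.
#' @export
summarize_dfi <- function(results, breaks = seq(0, 1, by = 0.01),
                          interval = NULL) {
  if (is.numeric(results)) {
    dfi <- results
    scatter <- NULL
  } else {
    stopifnot(length(results) > 0)
    dfi <- vapply(results, function(r) r$DFI, numeric(1))
    scatter <- data.frame(
      green = vapply(results, function(r) r$green_intensity, numeric(1)),
      red = vapply(results, function(r) r$red_intensity, numeric(1)),
      DFI = dfi)
  }
  if (length(dfi) == 0) stop("no DFI values to summarize")
  h <- graphics::hist(dfi, breaks = breaks, plot = FALSE)
  frac <- if (is.null(interval)) {
    NA_real_
  } else {
    mean(dfi >= interval[1] & dfi <= interval[2])
  }
  list(histogram = data.frame(bin_lo = h$breaks[-length(h$breaks)],
                              bin_hi = h$breaks[-1], count = h$counts),
       fraction_in_interval = frac,
       scatter = scatter,
       n = length(dfi))
}
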