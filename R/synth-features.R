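# Synthetic feature-table generator.
#
# Feature marginals are independent truncated normals around the reference
# model's centering constants; Ln(DFI) is the reference model prediction
# plus a centered per-donor shift and Gaussian observation noise. The noise
# scale default is calibrated (see calibrate_noise_sd) so a refit of the
# reference model attains a held-out Pearson r of about 0.57, the
# correlation strength the assay reports.

#' Synthetic-data configuration
#'
#' @param n_cells number of cells (default 1056, the reference cohort size).
#' @param n_donors number of donors (default 6); cells are assigned in
#'   near-equal blocks.
#' @param feature_means named means of the six features: `C`
#'   (dimensionless), `HW`, `L`, `MW` (um), `VA`, `AA` (um^2). Defaults are
#'   the reference model's centering constants.
#' @param feature_sds named sds, same units; default 15% of the means.
#' @param donor_shift_sd sd of the additive per-donor shift on Ln(DFI);
#'   shifts are centered to mean zero across donors.
#' @param noise_sd sd of the Gaussian noise added to the model Ln(DFI).
#' @param seed integer seed; identical config and seed give byte-identical
#'   tables.
#' @param pixel_size_um raster pixel size for image generation (um/px).
#' @param shape_consistent logical; clamp `C`, `MW`, `AA` and `VA` into the
#'   window the image renderer can realize *before* computing Ln(DFI), so a
#'   rendered and re-measured cell carries the same features the table
#'   holds. Off by default for feature-table-only studies.
#' @param fluor_brightness common brightness factor of the fluorescence
#'   channels (fraction of dynamic range; green max = brightness*(1-DFI)).
#' @param image_noise_sd additive Gaussian noise on the brightfield raster,
#'   as a fraction of dynamic range (default 2%).
#' @param fluor_noise_sd additive noise on the fluorescence rasters.
#' @param gray_levels named gray levels (fractions of dynamic range) for
#'   `background`, `head`, `acrosome`, `vacuole`, `midpiece`.
#' @param midpiece_length_um rendered midpiece length.
#' @param raster_margin_um background margin around the cell.
#' @param max_raster_px safety bound on the raster side length.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_cells = 1056L,
                         n_donors = 6L,
                         feature_means = reference_centers,
                         feature_sds = 0.15 * reference_centers,
                         donor_shift_sd = 0.08,
                         noise_sd = 0.113,
                         seed = 1L,
                         pixel_size_um = 0.05,
                         shape_consistent = FALSE,
                         fluor_brightness = 0.8,
                         image_noise_sd = 0.02,
                         fluor_noise_sd = 5e-4,
                         gray_levels = c(background = 0.10, head = 0.58,
                                         acrosome = 0.68, vacuole = 0.44,
                                         midpiece = 0.40),
                         midpiece_length_um = 2.0,
                         raster_margin_um = 1.5,
                         max_raster_px = 2048L) {
  feats <- c("C", "HW", "L", "MW", "VA", "AA")
  feature_means <- feature_means[feats]
  feature_sds <- feature_sds[feats]
  cfg <- list(n_cells = as.integer(n_cells), n_donors = as.integer(n_donors),
              feature_means = feature_means, feature_sds = feature_sds,
              donor_shift_sd = donor_shift_sd, noise_sd = noise_sd,
              seed = as.integer(seed), pixel_size_um = pixel_size_um,
              shape_consistent = isTRUE(shape_consistent),
              fluor_brightness = fluor_brightness,
              image_noise_sd = image_noise_sd,
              fluor_noise_sd = fluor_noise_sd,
              gray_levels = gray_levels,
              midpiece_length_um = midpiece_length_um,
              raster_margin_um = raster_margin_um,
              max_raster_px = as.integer(max_raster_px))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_cells < 1) stop("configuration error: n_cells must be >= 1")
  if (cfg$n_donors < 1) stop("configuration error: n_donors must be >= 1")
  if (anyNA(cfg$feature_means) || anyNA(cfg$feature_sds)) {
    stop("configuration error: feature means/sds must name C, HW, L, MW, VA, AA")
  }
  if (any(cfg$feature_sds < 0) || cfg$donor_shift_sd < 0 || cfg$noise_sd < 0) {
    stop("configuration error: all sds must be >= 0")
  }
  if (cfg$feature_means[["C"]] <= 0 || cfg$feature_means[["C"]] > 1) {
    stop("configuration error: mean circularity must lie in (0, 1]")
  }
  if (any(cfg$feature_means[c("HW", "L", "MW", "VA", "AA")] <= 0)) {
    stop("configuration error: lengths and areas must be positive")
  }
  if (cfg$pixel_size_um <= 0) {
    stop("configuration error: pixel_size_um must be positive")
  }
  invisible(cfg)
}

# DFI is kept strictly inside (0, 1) so Ln(DFI) stays finite
DFI_EPS <- 1e-6

#' Generate a synthetic single-sperm feature table
#'
#' Draws the six morphology features as independent truncated normals
#' (circularity in (0, 1], lengths and areas positive), computes the ground
#' truth Ln(DFI) from the reference interaction model plus a centered donor
#' shift, adds Gaussian noise, and maps to DFI = exp(Ln(DFI)) clipped to
#' (1e-6, 1 - 1e-6).
#'
#' @param config a [synth_config()].
#' @return list with `table` (data.frame: `donor`, `cell_id`, `C`, `HW`,
#'   `L`, `MW`, `VA`, `AA`, `DFI`, `ln_dfi`) and `truth` (data.frame:
#'   per-cell noiseless `eta`, donor `shift`, `acrosome_fraction`,
#'   `vacuole_area`, head semi-axes `semi_a`, `semi_b`).
#' @export
generate_feature_table <- function(config = synth_config()) {
  validate_synth_config(config)
  n <- config$n_cells
  mu <- config$feature_means
  sd <- config$feature_sds
  with_seed(config$seed, {
    donor <- rep_len(seq_len(config$n_donors), n)
    feats <- data.frame(
      C  = rtrunc_norm(n, mu[["C"]],  sd[["C"]],  lower = DFI_EPS, upper = 1),
      HW = rtrunc_norm(n, mu[["HW"]], sd[["HW"]], lower = DFI_EPS),
      L  = rtrunc_norm(n, mu[["L"]],  sd[["L"]],  lower = DFI_EPS),
      MW = rtrunc_norm(n, mu[["MW"]], sd[["MW"]], lower = DFI_EPS),
      VA = rtrunc_norm(n, mu[["VA"]], sd[["VA"]], lower = DFI_EPS),
      AA = rtrunc_norm(n, mu[["AA"]], sd[["AA"]], lower = DFI_EPS)
    )
    if (config$shape_consistent) feats <- clamp_renderable(feats)
    shift <- if (config$n_donors > 1 && config$donor_shift_sd > 0) {
      s <- stats::rnorm(config$n_donors, 0, config$donor_shift_sd)
      s - mean(s)
    } else {
      rep(0, config$n_donors)
    }
    eta <- predict(reference_model(), feats) + shift[donor]
    ln <- eta + stats::rnorm(n, 0, config$noise_sd)
    dfi <- pmin(pmax(exp(ln), DFI_EPS), 1 - DFI_EPS)
  })
  table <- data.frame(donor = donor, cell_id = seq_len(n), feats,
                      DFI = dfi, ln_dfi = log(dfi))
  a <- feats$L / 2
  b <- feats$HW / 2
  # head area of the shape the renderer draws (ripple shrinks the ellipse)
  head_area <- if (config$shape_consistent) {
    mapply(function(L, HW, C) solve_ripple(L, HW, C)$area,
           feats$L, feats$HW, feats$C)
  } else {
    pi * a * b
  }
  truth <- data.frame(
    cell_id = seq_len(n), donor = donor, eta = eta, shift = shift[donor],
    acrosome_fraction = pmin(feats$AA / head_area, 0.95),
    vacuole_area = pmin(feats$VA, feats$AA),
    semi_a = a, semi_b = b, head_area = head_area
  )
  list(table = table, truth = truth)
}

# Clamp features into the window the image renderer realizes exactly:
# HW below L, MW thin enough to be excluded from the head as an appendage,
# C inside the ripple family's range for the cell's aspect ratio, the
# acrosome within 90% of the rendered head, vacuoles within 60% of the
# acrosome.
clamp_renderable <- function(feats) {
  feats$HW <- pmin(feats$HW, 0.95 * feats$L)
  feats$MW <- pmin(feats$MW, 0.40 * feats$HW)
  rng <- t(mapply(shape_c_range, feats$L, feats$HW))
  feats$C <- pmin(pmax(feats$C, rng[, 1] + 0.01), rng[, 2] - 0.005)
  area <- mapply(function(L, HW, C) solve_ripple(L, HW, C)$area,
                 feats$L, feats$HW, feats$C)
  feats$AA <- pmin(feats$AA, 0.9 * area)
  feats$VA <- pmin(feats$VA, 0.6 * feats$AA)
  feats
}

#' Calibrate the generator noise to a target held-out correlation
#'
#' Bisects `noise_sd` so that refitting the 14-term reference model on a
#' training split and scoring the test split attains a target Pearson r
#' (default 0.571, the reference cohort's model correlation). The objective
#' is averaged over `n_reps` seeds.
#'
#' @param target_r target held-out Pearson correlation.
#' @param config baseline [synth_config()]; its `noise_sd` is ignored.
#' @param interval search interval for `noise_sd`.
#' @param n_reps number of seeded replicates averaged per evaluation.
#' @param fractions train/validation/test fractions.
#' @param tol bisection tolerance on `noise_sd`.
#' @return the calibrated `noise_sd`.
#' @export
calibrate_noise_sd <- function(target_r = 0.571, config = synth_config(),
                               interval = c(0.01, 1), n_reps = 5,
                               fractions = c(0.65, 0.10, 0.25), tol = 1e-3) {
  mean_r <- function(noise_sd) {
    cfg <- config
    cfg$noise_sd <- noise_sd
    rs <- vapply(seq_len(n_reps), function(i) {
      cfg$seed <- config$seed + i
      tab <- generate_feature_table(cfg)$table
      split <- split_data(nrow(tab), fractions, seed = cfg$seed)
      spec <- reference_model()
      fit <- fit_linear(tab[split == "train", ], spec)
      test <- tab[split == "test", ]
      pearson_r(test$ln_dfi, predict(fit$spec, test))
    }, numeric(1))
    mean(rs)
  }
  f <- function(s) mean_r(s) - target_r
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0) return(lo)
  if (fhi > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
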