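test_that("circle and ellipse measurements match analytic oracles", {
  cfg <- synth_config()
  # circle of radius 2 um at 0.05 um/px
  rs <- render_and_segment(make_record(L = 4, HW = 4), cfg, noise = FALSE)
  hm <- measure_head(rs$mask)
  expect_equal(hm$A, 4 * pi, tolerance = 0.01)
  expect_equal(hm$L, hm$HW, tolerance = 0.02)
  expect_equal(hm$P, 4 * pi, tolerance = 0.02)
  expect_equal(circularity(hm$A, hm$P), 1, tolerance = 0.02)
  # ellipse with semi-axes 2.48 and 1.68 um
  rs <- render_and_segment(make_record(L = 4.96, HW = 3.36), cfg,
                           noise = FALSE)
  hm <- measure_head(rs$mask)
  expect_equal(hm$A, pi * 2.48 * 1.68, tolerance = 0.01)
  expect_equal(hm$P, ramanujan_perimeter(2.48, 1.68), tolerance = 0.02)
  expect_equal(hm$L, 4.96, tolerance = 0.02)
  expect_equal(hm$HW, 3.36, tolerance = 0.02)
})

test_that("circularity follows its closed forms", {
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  e <- render_and_segment(make_record(L = 4.96, HW = 3.36), synth_config(),
                          noise = FALSE)
  hm <- measure_head(e$mask)
  c_oracle <- 4 * pi * (pi * 2.48 * 1.68) / ramanujan_perimeter(2.48, 1.68)^2
  expect_equal(circularity(hm$A, hm$P), c_oracle, tolerance = 0.02)
  expect_error(circularity(0, 1), "DomainError")
  expect_error(circularity(1, -1), "DomainError")
})

test_that("circularity of rasterized convex shapes never exceeds 1 and falls with aspect", {
  cfg <- synth_config()
  cs <- vapply(c(1, 1.5, 2, 3, 4), function(q) {
    rs <- render_and_segment(make_record(L = 3 * q, HW = 3), cfg,
                             noise = FALSE)
    hm <- measure_head(rs$mask)
    circularity(hm$A, hm$P)
  }, numeric(1))
  expect_true(all(cs <= 1.02))
  expect_true(all(diff(cs) < 0))
})

test_that("segmentation handles degenerate and multi-object rasters", {
  px <- 0.05
  expect_error(segment_head(matrix(0.1, 50, 50), px), "NoCellFound")
  # two disjoint heads: the larger is returned with a warning
  m <- matrix(0.1, 200, 120)
  xy <- expand.grid(x = 1:200, y = 1:120)
  d1 <- (xy$x - 60)^2 + (xy$y - 60)^2 <= 30^2
  d2 <- (xy$x - 150)^2 + (xy$y - 60)^2 <= 18^2
  m[cbind(xy$x, xy$y)[d1 | d2, ]] <- 0.6
  expect_warning(mask <- segment_head(m, px), "largest")
  expect_equal(sum(mask$mask), sum(d1), tolerance = 0.02)
})

test_that("segmented masks overlap the generator ground truth", {
  cfg <- synth_config(n_cells = 5, seed = 31, shape_consistent = TRUE)
  ds <- generate_image_dataset(cfg)
  for (i in seq_len(5)) {
    im <- ds$images[[i]]
    mask <- suppressWarnings(segment_head(im$brightfield, im$pixel_size_um))
    # IoU against the ideal head raster, recovered from gray levels
    ideal <- im$green > 0.5 * max(im$green)
    iou <- sum(mask$mask & ideal) / sum(mask$mask | ideal)
    expect_gt(iou, 0.95)
  }
})

test_that("axial profile is flat for a uniform head and steps at the acrosome", {
  cfg <- synth_config()
  rs <- render_and_segment(make_record(), cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  expect_lt(diff(range(prof$gray)), 1e-9)
  expect_lt(abs(nrow(prof) - 4.9618 / cfg$pixel_size_um), 3)

  # acrosome over the anterior 40% of the head area: the profile step sits
  # near the boundary implied by the rendered cut
  rec <- make_record(AA = 0.4 * pi * 2.48 * 1.68)
  rs <- render_and_segment(rec, cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  d <- diff(prof$gray)
  step_pos <- prof$position_um[which.max(d)]
  # anterior 40% of an ellipse's area lies beyond x/a = 0.194
  a <- 4.96 / 2
  x_cut <- uniroot(function(x) {
    (0.5 - (x * sqrt(1 - x^2) + asin(x)) / pi) - 0.4
  }, c(0, 1))$root
  expected <- a + x_cut * a  # measured from the posterior end
  expect_lt(abs(step_pos - expected), 0.15)
})

test_that("acrosome area tracks the generator fraction and partitions the head", {
  cfg <- synth_config()
  for (f in c(0.25, 0.4)) {
    rec <- make_record(AA = f * pi * 2.48 * 1.68)
    rs <- render_and_segment(rec, cfg, noise = FALSE)
    prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
    acr <- measure_acrosome(prof, rs$mask, rs$images$brightfield)
    hm <- measure_head(rs$mask)
    expect_equal(acr$flag, "ok")
    expect_equal(acr$AA, f * hm$A, tolerance = 0.05)
    # partition: anterior + posterior pixel areas equal A exactly
    post <- sum(rs$mask$mask) * cfg$pixel_size_um^2 - acr$AA
    expect_equal(acr$AA + post, hm$A, tolerance = 1e-12)
  }
})

test_that("flat and fully elevated heads are acrosome boundary cases", {
  cfg <- synth_config()
  rs <- render_and_segment(make_record(), cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  acr <- measure_acrosome(prof, rs$mask, rs$images$brightfield)
  expect_equal(acr$AA, 0)
  expect_equal(acr$flag, "no_acrosome_detected")

  # whole head elevated: boundary at the posterior edge, AA ~ A
  rec <- make_record(AA = 0.999 * pi * 2.48 * 1.68)
  im <- generate_cell_images(rec, truth = data.frame(acrosome_fraction = 1,
                                                     vacuole_area = 0),
                             config = cfg, noise = FALSE)
  mask <- segment_head(im$brightfield, cfg$pixel_size_um)
  prof <- axial_gray_profile(im$brightfield, mask)
  acr <- measure_acrosome(prof, mask, im$brightfield)
  hm <- measure_head(mask)
  expect_equal(acr$AA, hm$A, tolerance = 0.05)
})

test_that("vacuole areas are recovered and additive", {
  cfg <- synth_config()
  base <- pi * 2.48 * 1.68
  # no vacuoles
  rs <- render_and_segment(make_record(AA = 0.35 * base), cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  acr <- measure_acrosome(prof, rs$mask, rs$images$brightfield)
  reg <- spermdfi:::acrosome_region(rs$mask, acr, rs$images$brightfield)
  expect_equal(measure_vacuoles(rs$images$brightfield, rs$mask, reg)$VA, 0)
  # one vacuole at the reference size 0.68 um^2
  rs <- render_and_segment(make_record(AA = 0.35 * base, VA = 0.68287),
                           cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  acr <- measure_acrosome(prof, rs$mask, rs$images$brightfield)
  reg <- spermdfi:::acrosome_region(rs$mask, acr, rs$images$brightfield)
  v1 <- measure_vacuoles(rs$images$brightfield, rs$mask, reg)
  expect_equal(v1$VA, 0.68287, tolerance = 0.10)
  # two vacuoles (rendered when VA > 1.1): areas add
  rs <- render_and_segment(make_record(L = 6.5, HW = 4.4, AA = 9, VA = 1.4),
                           cfg, noise = FALSE)
  prof <- axial_gray_profile(rs$images$brightfield, rs$mask)
  acr <- measure_acrosome(prof, rs$mask, rs$images$brightfield)
  reg <- spermdfi:::acrosome_region(rs$mask, acr, rs$images$brightfield)
  v2 <- measure_vacuoles(rs$images$brightfield, rs$mask, reg)
  expect_equal(v2$n_vacuoles, 2)
  expect_equal(v2$VA, 1.4, tolerance = 0.10)
})

test_that("midpiece width is recovered and scales with pixel size", {
  rec <- make_record(MW = 1.32059)
  for (px in c(0.05, 0.1)) {
    cfg <- synth_config(pixel_size_um = px)
    rs <- render_and_segment(rec, cfg, noise = FALSE)
    mw <- measure_midpiece(rs$images$brightfield, rs$mask)
    expect_equal(mw$flag, "ok")
    expect_equal(mw$MW, 1.32059, tolerance = 0.10)
  }
  # head-only image: flagged missing
  rs <- render_and_segment(make_record(MW = 0), synth_config(), noise = FALSE)
  mw <- measure_midpiece(rs$images$brightfield, rs$mask)
  expect_true(is.na(mw$MW))
  expect_equal(mw$flag, "no_midpiece")
})

test_that("measurements are invariant to rotation and translation", {
  cfg <- synth_config(n_cells = 1, seed = 8, shape_consistent = TRUE)
  ft <- generate_feature_table(cfg)
  ms <- lapply(list(c(0, 0, 0), c(90, 0, 0), c(0, 0.4, -0.3)), function(p) {
    im <- generate_cell_images(ft$table[1, ], ft$truth[1, ], cfg,
                               orientation_deg = p[1],
                               center_offset_px = p[2:3], noise = FALSE)
    suppressWarnings(measure_cell(im))
  })
  for (col in c("C", "HW", "L", "VA", "A", "P")) {
    vals <- vapply(ms, function(m) m[[col]], numeric(1))
    expect_lt(diff(range(vals)) / mean(vals), 0.02)
  }
  # MW and AA are quantization-limited on binary rasters: one pixel of
  # width (MW) and one axial slab of acrosome (AA) are the attainable floor
  px <- 0.05
  mw <- vapply(ms, function(m) m$MW, numeric(1))
  expect_lte(diff(range(mw)), 1.1 * px)
  aa <- vapply(ms, function(m) m$AA, numeric(1))
  slab_area <- px * max(vapply(ms, function(m) m$HW, numeric(1)))
  expect_lte(diff(range(aa)), 1.5 * slab_area)
})

test_that("re-measuring generator images recovers the features", {
  cfg <- synth_config(n_cells = 25, seed = 17, shape_consistent = TRUE)
  ds <- generate_image_dataset(cfg)
  meas <- do.call(rbind, lapply(ds$images, function(im) {
    suppressWarnings(measure_cell(im))
  }))
  for (col in c("C", "HW", "L", "MW", "VA", "AA")) {
    rel_err <- abs(meas[[col]] - ds$table[[col]]) / ds$table[[col]]
    expect_gte(mean(rel_err <= 0.05 | abs(meas[[col]] - ds$table[[col]]) < 0.05),
               0.95)
  }
})

test_that("contrast stretch maps the 1st and 99th percentiles to 0 and 1", {
  m <- matrix(runif(10000), 100, 100)
  s <- stretch_percentile(m)
  q <- quantile(m, c(0.01, 0.99))
  expect_equal(range(s), c(0, 1))
  expect_equal(s[m <= q[1]], rep(0, sum(m <= q[1])))
})
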