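# Shared fixtures: small records/configs and analytic oracles.

# Ramanujan's approximation to the ellipse perimeter (semi-axes a, b)
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# one-row feature record for image rendering; defaults are a plain ellipse
# head with no acrosome, no vacuole and no midpiece
make_record <- function(L = 4.9618, HW = 3.3639, C = NULL, MW = 0,
                        AA = 0, VA = 0, DFI = 0.1) {
  if (is.null(C)) C <- head_shape_metrics(L, HW, 0)$C  # plain ellipse
  data.frame(donor = 1L, cell_id = 1L, C = C, HW = HW, L = L, MW = MW,
             VA = VA, AA = AA, DFI = DFI, ln_dfi = log(DFI))
}

# render a record and return both the image set and its measured mask
render_and_segment <- function(record, cfg = synth_config(), ...) {
  im <- generate_cell_images(record, truth = NULL, config = cfg, ...)
  list(images = im,
       mask = segment_head(im$brightfield, im$pixel_size_um))
}

small_table <- function(n = 200, seed = 42, noise_sd = NULL) {
  cfg <- synth_config(n_cells = n, seed = seed)
  if (!is.null(noise_sd)) cfg$noise_sd <- noise_sd
  generate_feature_table(cfg)$table
}
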