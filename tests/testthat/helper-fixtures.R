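# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Six default-condition fields (noise and vignette on) with the
# session-wide illumination functions estimated across them.
fix_session <- function() fixture("session", {
  fields <- lapply(1:6, function(s) generate_field(scene_spec(seed = s)))
  fn_gfp <- estimate_illumination(lapply(fields, `[[`, "gfp"),
                                  smoothing_scale_px = 300)
  fn_dapi <- estimate_illumination(lapply(fields, `[[`, "dapi"),
                                   smoothing_scale_px = 300)
  list(fields = fields, fn_gfp = fn_gfp, fn_dapi = fn_dapi)
})

# A clean field: no noise, flat illumination.
clean_spec <- function(...) {
  scene_spec(noise_gaussian_sd = 0, noise_poisson_gain = 0,
             bias_amplitude = 0, ...)
}

fix_clean_field <- function() fixture("clean_field",
  generate_field(clean_spec(seed = 11)))

# Balanced labelled cytoprofile pool from truth masks (noise on),
# used by feature-separation and classifier tests.
fix_pool <- function() fixture("pool", {
  out <- lapply(1:8, function(s) {
    f <- generate_field(scene_spec(inclusion_prevalence = 0.5, seed = 300 + s))
    fn <- estimate_illumination(list(f$gfp), smoothing_scale_px = 300)
    pr <- compute_profiles(cells_from_truth(f$truth),
                           apply_illumination(f$gfp, fn))
    pr$field <- s
    pr
  })
  dplyr::bind_rows(out)
})

# Tiny perfectly separable two-class profile table (one informative
# feature), for classifier contract tests.
separable_profiles <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      cell_id = seq_len(2 * n_per_class),
      label = rep(c("inclusion", "no_inclusion"), each = n_per_class),
      int_mean = c(rnorm(n_per_class, 10), rnorm(n_per_class, 0)),
      int_sd = rnorm(2 * n_per_class),
      shp_area = rnorm(2 * n_per_class))
  })
}

# Segment + profile one generated field through the standard chain.
segment_field <- function(fld, fn_gfp, fn_dapi, ...) {
  g <- apply_illumination(fld$gfp, fn_gfp)
  d <- apply_illumination(fld$dapi, fn_dapi)
  segment_cells(g, segment_nuclei(d), ...)
}

# Disk-shaped constructed cell for closed-form feature checks.
disk_cell <- function(radius = 12, size = 2 * radius + 9, value = 1000,
                      background = 0) {
  img <- matrix(background, size, size)
  c0 <- (size + 1) / 2
  idx <- which(outer((seq_len(size) - c0)^2, (seq_len(size) - c0)^2, "+")
               <= radius^2)
  img[idx] <- value
  mask <- matrix(FALSE, size, size)
  mask[idx] <- TRUE
  cells <- tibble::tibble(
    cell_id = 1L, nucleus_id = NA_integer_,
    centroid_x = c0 - 1, centroid_y = c0 - 1,
    area_px = sum(mask), equiv_diameter_px = 2 * sqrt(sum(mask) / pi),
    mask = list(list(y0 = 1L, x0 = 1L, patch = mask)))
  attr(cells, "field_dim") <- c(size, size)
  class(cells) <- unique(c("cell_tbl", class(cells)))
  list(cells = cells, image = img, mask = mask)
}
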