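test_that("identical seeds give bit-identical fields", {
  a <- generate_field(scene_spec(seed = 7))
  b <- generate_field(scene_spec(seed = 7))
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$truth$cells, b$truth$cells)
  d <- generate_field(scene_spec(seed = 8))
  expect_false(identical(a$gfp, d$gfp))
})

test_that("an empty scene renders blank noise-only images with empty truth", {
  f <- generate_field(scene_spec(n_cells = 0, seed = 1))
  expect_equal(nrow(f$truth$cells), 0)
  expect_true(all(f$truth$cell_mask == 0))
  # only background + noise: nothing near a cell's brightness
  expect_lt(max(f$gfp), 2000)
})

test_that("inclusion labels are binomial draws at the set prevalence", {
  spec0 <- scene_spec(image_shape = c(256L, 256L), n_cells = 50,
                      inclusion_prevalence = 0.2,
                      cell_diameter = c(18, 2), nucleus_diameter = c(9, 1),
                      noise_gaussian_sd = 0, noise_poisson_gain = 0,
                      bias_amplitude = 0)
  k <- vapply(1:200, function(s) {
    spec0$seed <- s
    sum(generate_field(spec0)$truth$cells$label == "inclusion")
  }, numeric(1))
  expect_true(abs(mean(k) / 50 - 0.2) < 0.02)
})

test_that("label counts are conserved and masks stay disjoint and in-bounds", {
  f <- generate_field(scene_spec(seed = 3))
  cells <- f$truth$cells
  expect_equal(sum(table(cells$label)), nrow(cells))
  expect_equal(nrow(cells), 40)
  expect_setequal(unique(f$truth$cell_mask[f$truth$cell_mask > 0]),
                  cells$cell_id)
  # nucleus of cell i lies inside cell i's mask: disjointness across cells
  nz <- f$truth$nucleus_mask > 0
  expect_true(all(f$truth$cell_mask[nz] == f$truth$nucleus_mask[nz]))
})

test_that("rendered punctum peak sits at the specified contrast over diffuse", {
  ratios <- vapply(1:3, function(s) {
    f <- generate_field(scene_spec(
      n_cells = 1, inclusion_prevalence = 1, puncta_per_cell = c(1L, 1L),
      puncta_diameter = c(5, 0.001), puncta_contrast = 3,
      cell_diameter = c(36, 0.001), background = 0,
      noise_gaussian_sd = 0, noise_poisson_gain = 0, bias_amplitude = 0,
      seed = s))
    max(f$gfp) / stats::median(f$gfp[f$truth$cell_mask == 1])
  }, numeric(1))
  expect_true(all(abs(ratios - 3) / 3 < 0.01))
})

test_that("overdense scenes fail with a density error", {
  expect_error(generate_field(scene_spec(image_shape = c(128L, 128L),
                                         n_cells = 60, seed = 1)),
               "non-overlapping")
})

test_that("generate_plate writes the acquisition-scheme filenames and truth", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(image_shape = c(128L, 128L), n_cells = 4,
                   cell_diameter = c(20, 2), nucleus_diameter = c(9, 1))
  truth <- generate_plate(tibble::tibble(well = "B4", construct = "A4V"),
                          dir, spec = sp, fields_per_well = 4, seed = 2)
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_length(tifs, 8)  # 2 channels x 4 fields
  expect_true("B4_2_GFP_2.tif" %in% tifs)
  expect_true(all(c("well", "field", "cell_id", "label",
                    "centroid_x", "centroid_y") %in% names(truth)))
  expect_equal(unique(truth$construct), "A4V")
  expect_true(file.exists(file.path(dir, "truth.csv")))
})

test_that("a 5x5 tile scan yields 25 reporter fields for one well", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(image_shape = c(96L, 96L), n_cells = 1,
                   cell_diameter = c(20, 2), nucleus_diameter = c(9, 1))
  generate_plate(tibble::tibble(well = "A1"), dir, spec = sp,
                 fields_per_well = 25, seed = 1)
  expect_length(list.files(dir, pattern = "_GFP_.*\\.tif$"), 25)
})

test_that("checkerboard with zero offset and zero noise is an exact HSA surface", {
  cs <- combo_spec(synergy_offset = 0, noise_sd = 0, replicates = 1, seed = 1)
  cb <- generate_checkerboard(cs)
  ea <- inclusionprofiler:::hill_effect(cs$doses_a, cs$mono_a)
  eb <- inclusionprofiler:::hill_effect(cs$doses_b, cs$mono_b)
  expect_equal(cb$truth_effect, outer(ea, eb, pmax))
  m <- matrix(cb$observed$response, length(cs$doses_a))
  expect_equal(m, cs$baseline_pct * (100 - outer(ea, eb, pmax)) / 100)
})

test_that("a single-dose checkerboard is one control cell with zero effect", {
  cs <- combo_spec(doses_a = 0, doses_b = 0, noise_sd = 0, replicates = 1)
  cb <- generate_checkerboard(cs)
  expect_equal(nrow(cb$observed), 1)
  expect_equal(cb$observed$response, cs$baseline_pct)
  expect_equal(cb$truth_effect[1, 1], 0)
})

test_that("time series obey the deterministic mean model", {
  arms <- tibble::tibble(arm = c("ctrl", "mut"), death_rate = c(0, 0.02))
  ts <- generate_timeseries(arms, seed = 4)
  ctrl <- ts[ts$arm == "ctrl" & ts$replicate == 1, ]
  expect_true(all(ctrl$mean_count == ctrl$mean_count[1]))  # death rate 0
  mut <- ts[ts$arm == "mut" & ts$replicate == 1, ]
  rel <- mut$mean_count / ctrl$mean_count
  expect_true(all(diff(rel) < 0))  # mean relative survival declines
  expect_error(generate_timeseries(arms, timepoints = c(-1, 0)), "nonnegative")
})
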