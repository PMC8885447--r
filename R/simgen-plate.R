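#' Generate a ground-truthed synthetic plate on disk
#'
#' Renders every field of every well in `layout` with [generate_field()]
#' and writes 16-bit grayscale TIFFs named
#' `(WELL)_(FIELD)_(CHANNEL)_(IMAGE).tif` (e.g. `B4_2_GFP_2.tif`),
#' plus a `truth.csv` table with one row per simulated cell. Each field
#' gets a sub-seed derived from `seed`, so a plate is reproducible as a
#' whole without correlating fields.
#'
#' @param layout a data frame with a `well` column (e.g. "A1".."H12");
#'   optional columns `n_cells` and `inclusion_prevalence` override the
#'   scene spec per well, and any further columns (construct, dose_a,
#'   dose_b, replicate, ...) are carried into the truth table.
#' @param dir output directory (created if needed).
#' @param spec base [scene_spec()] shared by all wells.
#' @param fields_per_well number of tile-scan fields per well (e.g. 16 or
#'   25 for a 4 x 4 or 5 x 5 scan).
#' @param seed integer master seed for the plate.
#' @return (invisibly) the truth tibble: `well`, `field`, `cell_id`,
#'   `label`, `transfected`, `centroid_x`, `centroid_y`,
#'   `equiv_diameter_px` plus the carried layout columns.
#' @export
generate_plate <- function(layout, dir, spec = scene_spec(),
                           fields_per_well = 4L, seed = 1L) {
  layout <- as_tibble(layout)
  if (!"well" %in% names(layout)) abort("layout must have a `well` column")
  if (anyDuplicated(layout$well)) abort("duplicate wells in layout")
  if (fields_per_well < 1) abort("fields_per_well must be >= 1")
  bad <- !grepl("^[A-Pa-p][0-9]{1,2}$", layout$well)
  if (any(bad))
    abort(sprintf("invalid well name(s): %s",
                  paste(layout$well[bad], collapse = ", ")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  truths <- vector("list", nrow(layout) * fields_per_well)
  k <- 0L
  seen <- character(0)
  for (w in seq_len(nrow(layout))) {
    wspec <- spec
    if ("n_cells" %in% names(layout))
      wspec$n_cells <- as.integer(layout$n_cells[w])
    if ("inclusion_prevalence" %in% names(layout))
      wspec$inclusion_prevalence <- layout$inclusion_prevalence[w]
    for (f in seq_len(fields_per_well)) {
      wspec$seed <- derive_seed(seed, (w - 1L) * 1000L + f)
      fld <- generate_field(structure(wspec, class = "scene_spec"))
      for (ch in c("DAPI", "GFP")) {
        fname <- format_image_key(layout$well[w], f, ch, f)
        if (fname %in% seen)
          abort(sprintf("output filename collision: %s", fname))
        seen <- c(seen, fname)
        write_field(file.path(dir, fname),
                    if (ch == "DAPI") fld$dapi else fld$gfp,
                    bit_depth = wspec$bit_depth)
      }
      k <- k + 1L
      tr <- fld$truth$cells
      if (nrow(tr)) {
        truths[[k]] <- bind_cols(
          tibble(well = layout$well[w], field = f),
          tr,
          layout[w, setdiff(names(layout),
                            c("well", "n_cells", "inclusion_prevalence")),
                 drop = FALSE])
      }
    }
  }
  truth <- bind_rows(truths)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
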