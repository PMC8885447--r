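#' Segment and profile every field of a loaded plate
#'
#' Runs nucleus detection, size-gated cell segmentation and cytoprofile
#' computation per field and binds the results with their well/field
#' metadata. Combine with [correct_plate()] upstream and
#' [score_cells()] / [summarize_wells()] downstream for the full
#' image-to-percentages chain.
#'
#' @param plate a [load_plate()] (usually [correct_plate()]-ed) tibble.
#' @param min_diameter,max_diameter size gate passed to [segment_cells()].
#' @param gfp_only segment without nuclear seeds.
#' @param ... further arguments to [segment_cells()].
#' @return A profiles tibble with `well` and `field` columns.
#' @export
profile_plate <- function(plate, min_diameter = 17, max_diameter = 50,
                          gfp_only = FALSE, ...) {
  out <- vector("list", nrow(plate))
  for (i in seq_len(nrow(plate))) {
    gfp <- plate$gfp[[i]]
    nuc <- if (gfp_only || is.null(plate$dapi[[i]])) NULL
           else segment_nuclei(plate$dapi[[i]])
    cells <- segment_cells(gfp, nuc, min_diameter = min_diameter,
                           max_diameter = max_diameter, ...)
    if (!nrow(cells)) next
    prof <- compute_profiles(cells, gfp)
    out[[i]] <- bind_cols(tibble(well = plate$well[i], field = plate$field[i]),
                          prof)
  }
  bind_rows(out)
}

#' Count GFP-positive cells per field of a plate
#'
#' Live-cell counting mode: size-gated GFP-only segmentation, no
#' profiles. Used per timepoint for survival analyses.
#'
#' @inheritParams profile_plate
#' @return Tibble `well`, `field`, `n_cells`.
#' @export
count_gfp_cells <- function(plate, min_diameter = 17, max_diameter = 50, ...) {
  tibble(well = plate$well, field = plate$field,
         n_cells = vapply(plate$gfp, function(g)
           nrow(segment_cells(g, NULL, min_diameter = min_diameter,
                              max_diameter = max_diameter, ...)),
           integer(1)))
}

#' Simulate a labelled cytoprofile pool for classifier work
#'
#' Generates ground-truthed fields, runs the standard correction +
#' segmentation + profiling chain, and attaches the true phenotype label
#' of each detected cell (transferred from the simulator masks by IoU
#' matching). This is the supported way to build training pools: a
#' classifier should be trained on profiles measured on the same kind of
#' masks it will score - profiles computed on ideal truth masks differ
#' systematically from pipeline-segmented ones (thresholds trim the dim
#' cell rim) and transfer poorly. Set `segmentation = "truth"` to get
#' ideal-mask profiles for feature-level studies.
#'
#' @param n_fields number of fields to simulate.
#' @param prevalence inclusion prevalence of the simulated cells.
#' @param spec base [scene_spec()] (its seed is overridden per field).
#' @param seed master seed; field sub-seeds derive from it.
#' @param smoothing_scale_px illumination smoothing scale for the
#'   simulated session.
#' @param segmentation `"pipeline"` (default) or `"truth"`.
#' @return A labelled profiles tibble (`field`, metadata, features,
#'   `label`).
#' @export
simulate_labeled_profiles <- function(n_fields = 10, prevalence = 0.5,
                                      spec = scene_spec(), seed = 1L,
                                      smoothing_scale_px = 300,
                                      segmentation = c("pipeline", "truth")) {
  segmentation <- match.arg(segmentation)
  spec$inclusion_prevalence <- prevalence
  validate_scene_spec(spec)
  flds <- lapply(seq_len(n_fields), function(i) {
    spec$seed <- derive_seed(seed, i)
    generate_field(spec)
  })
  fn_g <- estimate_illumination(lapply(flds, `[[`, "gfp"), smoothing_scale_px)
  fn_d <- estimate_illumination(lapply(flds, `[[`, "dapi"), smoothing_scale_px)
  out <- lapply(seq_along(flds), function(i) {
    f <- flds[[i]]
    g <- apply_illumination(f$gfp, fn_g)
    if (segmentation == "truth") {
      cells <- cells_from_truth(f$truth)
      if (!nrow(cells)) return(NULL)
      pr <- compute_profiles(cells, g)
    } else {
      d <- apply_illumination(f$dapi, fn_d)
      cells <- segment_cells(g, segment_nuclei(d))
      if (!nrow(cells)) return(NULL)
      pr <- compute_profiles(cells, g)
      m <- match_to_truth(cells, f$truth$cell_mask)
      lb <- f$truth$cells$label[match(m$truth_id, f$truth$cells$cell_id)]
      pr$label <- lb[match(pr$cell_id, m$cell_id)]
      pr <- pr[!is.na(pr$label), ]
    }
    pr$field <- i
    pr
  })
  bind_rows(out)
}
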