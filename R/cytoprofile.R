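#' Compute per-cell cytoprofiles from a segmented field
#'
#' For each cell the five feature families used for phenotype
#' classification are measured on the masked reporter pixels only:
#'
#' * intensity: `int_mean`, `int_integrated`, `int_sd`, `int_max`,
#'   `int_min`, `int_median` (camera units);
#' * size/shape: `shp_area`, `shp_perimeter`, `shp_eccentricity`,
#'   `shp_form_factor` (4\eqn{\pi}A/P\eqn{^2}), `shp_solidity`,
#'   `shp_equiv_diameter`;
#' * texture: the 13 Haralick co-occurrence statistics, angle-averaged,
#'   at offsets 3 and 8 px (`tex_<stat>_s3`, `tex_<stat>_s8`);
#' * granularity: a 16-element granulometry spectrum `gran_01..gran_16`,
#'   the fraction of above-baseline intensity removed by successive
#'   disk openings of radius 1..16 px (background inside the patch is
#'   set to the cell minimum);
#' * radial intensity distribution over 4 concentric bins (1 = centre):
#'   `rad_frac_d1..4` (intensity fraction per bin, sums to 1),
#'   `rad_meanfrac_d1..4` (intensity fraction / pixel fraction),
#'   `rad_cv_d1..4` (coefficient of variation over 8 angular wedges).
#'
#' All features are finite and deterministic; undefined ratios (e.g.
#' texture correlation of a constant patch) are coerced to 0.
#'
#' @param cells a [segment_cells()] tibble (or [cells_from_truth()]).
#' @param gfp the corrected reporter field the cells were segmented from.
#' @param scales Haralick co-occurrence offsets in pixels.
#' @param granularity_radii disk radii of the granulometry openings.
#' @param radial_bins number of concentric bins.
#' @return A tibble: the metadata columns of `cells` (minus `mask`)
#'   followed by the feature columns.
#' @export
compute_profiles <- function(cells, gfp, scales = c(3, 8),
                             granularity_radii = 1:16, radial_bins = 4L) {
  assert_image(gfp)
  meta <- dplyr::select(as_tibble(cells), -dplyr::any_of("mask"))
  if (!nrow(cells)) return(meta)
  areas <- vapply(cells$mask, function(m) sum(m$patch), integer(1))
  if (any(areas < 9)) abort("cell mask of < 9 px: too degenerate for texture")

  lab <- rebuild_labels(cells, dim(gfp))
  # haralick on the full field, normalised by full-scale so binning is
  # comparable across cells and fields
  ref <- EBImage::Image(clamp(gfp / 65535, 0, 1))
  har <- EBImage::computeFeatures.haralick(EBImage::Image(lab), ref,
                                           haralick.scales = scales)
  har <- har[cells$cell_id, , drop = FALSE]
  colnames(har) <- sub("^h\\.", "tex_", colnames(har))
  colnames(har) <- sub("\\.s(\\d+)$", "_s\\1", colnames(har))
  shp <- EBImage::computeFeatures.shape(EBImage::Image(lab))
  shp <- shp[cells$cell_id, , drop = FALSE]
  mom <- EBImage::computeFeatures.moment(EBImage::Image(lab), ref)
  mom <- mom[cells$cell_id, , drop = FALSE]

  n <- nrow(cells)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    m <- cells$mask[[i]]
    patch <- gfp[m$y0 + seq_len(nrow(m$patch)) - 1L,
                 m$x0 + seq_len(ncol(m$patch)) - 1L, drop = FALSE]
    px <- patch[m$patch]
    ints <- c(int_mean = mean(px), int_integrated = sum(px),
              int_sd = if (length(px) > 1) stats::sd(px) else 0,
              int_max = max(px), int_min = min(px),
              int_median = stats::median(px))
    shape <- c(shp_area = unname(shp[i, "s.area"]),
               shp_perimeter = unname(shp[i, "s.perimeter"]),
               shp_eccentricity = unname(mom[i, "m.eccentricity"]),
               shp_form_factor = unname(4 * pi * shp[i, "s.area"] /
                                          max(shp[i, "s.perimeter"], 1)^2),
               shp_solidity = mask_solidity(m$patch),
               shp_equiv_diameter = equiv_diameter(unname(shp[i, "s.area"])))
    gran <- granularity_spectrum(patch, m$patch, granularity_radii)
    rad <- radial_distribution(patch, m$patch, radial_bins)
    feats[[i]] <- c(ints, shape, gran, rad)
  }
  fm <- do.call(rbind, feats)
  fm <- cbind(fm, har)
  fm[!is.finite(fm)] <- 0
  bind_cols(meta, as_tibble(fm))
}

mask_solidity <- function(patch) {
  idx <- which(patch, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  h <- grDevices::chull(idx)
  hx <- idx[h, 1]; hy <- idx[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  # pixel-area hull correction: polygon through pixel centres underestimates
  hull_area <- hull_area + nrow(idx[h, , drop = FALSE]) / 2 + 1
  min(sum(patch) / max(hull_area, sum(patch)), 1)
}

granularity_spectrum <- function(patch, mask, radii, denoise_sigma = 0.75) {
  # light denoise before the openings: single-pixel shot noise otherwise
  # contributes small-scale mass that mimics puncta, especially in small
  # cells; real puncta (several px FWHM) survive the smoothing. The
  # background is filled with the cell minimum first so the blur does
  # not bleed background into the cell rim.
  base <- min(patch[mask])
  patch[!mask] <- base
  if (denoise_sigma > 0 && min(dim(patch)) >= 5) {
    patch <- gaussian_smooth(patch, denoise_sigma)
    base <- min(patch[mask])
  }
  img <- (patch - base) * mask
  # EBImage morphology is grayscale only on [0,1]; the spectrum is a
  # ratio so rescaling does not change it
  if (max(img) > 0) img <- img / max(img)
  total <- sum(img)
  out <- numeric(length(radii))
  names(out) <- sprintf("gran_%02d", seq_along(radii))
  if (total <= 0) return(out)
  prev <- sum(img)
  for (k in seq_along(radii)) {
    op <- EBImage::opening(img, EBImage::makeBrush(2L * radii[k] + 1L, "disc"))
    # discrete disc elements are not perfectly nested; enforce the
    # monotone decline so the spectrum stays a partition of [0, 1]
    cur <- min(sum(op), prev)
    out[k] <- (prev - cur) / total
    prev <- cur
  }
  out
}

radial_distribution <- function(patch, mask, nbins = 4L) {
  d <- EBImage::distmap(mask)
  d <- as.matrix(EBImage::imageData(d))
  dmax <- max(d)
  out <- numeric(3 * nbins)
  names(out) <- c(sprintf("rad_frac_d%d", seq_len(nbins)),
                  sprintf("rad_meanfrac_d%d", seq_len(nbins)),
                  sprintf("rad_cv_d%d", seq_len(nbins)))
  if (dmax <= 0) return(out)
  f <- d / dmax                      # 1 at the medial centre, ~0 at the rim
  bin <- pmin(pmax((nbins + 1L) - ceiling(f * nbins), 1L), nbins)
  bin[!mask] <- 0L
  total <- sum(patch[mask])
  npx <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)
  wedge <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)
  binv <- bin[mask]; pxv <- patch[mask]
  for (b in seq_len(nbins)) {
    inb <- binv == b
    if (!any(inb)) next
    frac <- sum(pxv[inb]) / total
    out[b] <- frac
    out[nbins + b] <- frac / (sum(inb) / npx)
    wm <- tapply(pxv[inb], wedge[inb], mean)
    if (length(wm) > 1 && mean(wm) > 0)
      out[2L * nbins + b] <- stats::sd(wm) / mean(wm)
  }
  out
}

#' Convert simulator ground truth into a cell table
#'
#' Turns the exact truth masks of [generate_field()] into the same
#' `cell_tbl` shape that [segment_cells()] produces, so cytoprofiles can
#' be computed on noiseless-segmentation cells (useful for classifier
#' training and feature-level studies that should not be confounded by
#' segmentation error). Only transfected cells are returned.
#'
#' @param truth the `truth` element of a [generate_field()] result.
#' @return A `cell_tbl` tibble with the truth `label` column attached.
#' @export
cells_from_truth <- function(truth) {
  mask <- truth$cell_mask
  H <- nrow(mask); W <- ncol(mask)
  keep <- truth$cells$cell_id[truth$cells$transfected]
  rows <- vector("list", length(keep))
  j <- 0L
  for (id in keep) {
    idx <- which(mask == id)
    if (!length(idx)) next
    yy <- (idx - 1L) %% H + 1L; xx <- (idx - 1L) %/% H + 1L
    y0 <- min(yy); x0 <- min(xx)
    patch <- matrix(FALSE, max(yy) - y0 + 1L, max(xx) - x0 + 1L)
    patch[cbind(yy - y0 + 1L, xx - x0 + 1L)] <- TRUE
    j <- j + 1L
    rows[[j]] <- tibble(
      cell_id = j,
      nucleus_id = as.integer(id),
      label = truth$cells$label[truth$cells$cell_id == id],
      centroid_x = mean(xx) - 1, centroid_y = mean(yy) - 1,
      area_px = length(idx), equiv_diameter_px = equiv_diameter(length(idx)),
      mask = list(list(y0 = y0, x0 = x0, patch = patch)))
  }
  cell_tbl(bind_rows(rows[seq_len(j)]), dim = c(H, W))
}

profile_feature_cols <- function(profiles) {
  grep("^(int|shp|tex|gran|rad)_", names(profiles), value = TRUE)
}

#' Z-score cytoprofile features per batch
#'
#' Standardises every feature column to mean 0 and unit population
#' standard deviation within each batch (plate, imaging session, ...);
#' the population sd makes the transform invariant under duplicating a
#' batch. Zero-variance features cannot be
#' standardised; they are dropped with a warning. The per-feature
#' statistics are retained in the `"norm_stats"` attribute so the same
#' transform can be applied to new cells with [apply_normalization()].
#'
#' @param profiles a [compute_profiles()] tibble.
#' @param batch optional column name to standardise within; default one
#'   batch.
#' @return Tibble of the same shape (minus dropped features) with
#'   standardised feature columns; attribute `"norm_stats"` is a tibble
#'   `feature`, `mean`, `sd`, `batch`.
#' @export
normalize_profiles <- function(profiles, batch = NULL) {
  fc <- profile_feature_cols(profiles)
  if (!length(fc)) abort("no feature columns found")
  grp <- if (is.null(batch)) rep("all", nrow(profiles)) else profiles[[batch]]
  if (min(table(grp)) < 2) abort("each batch needs at least 2 cells")
  stats_all <- list()
  dropped <- character(0)
  # population sd: makes the z-scores invariant under duplicating the
  # batch, which the sample sd (n - 1) is not
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    mu <- vapply(profiles[rows, fc], mean, numeric(1))
    sdv <- vapply(profiles[rows, fc], pop_sd, numeric(1))
    zv <- sdv == 0
    dropped <- union(dropped, fc[zv])
    for (j in which(!zv))
      profiles[rows, fc[j]] <- (profiles[rows, fc[j], drop = TRUE] - mu[j]) / sdv[j]
    stats_all[[g]] <- tibble(feature = fc, mean = mu, sd = sdv, batch = g)
  }
  if (length(dropped)) {
    warn(sprintf("dropping %d zero-variance feature(s): %s", length(dropped),
                 paste(utils::head(dropped, 8), collapse = ", ")))
    profiles <- dplyr::select(profiles, -dplyr::all_of(dropped))
  }
  attr(profiles, "norm_stats") <- bind_rows(stats_all)
  profiles
}

#' Apply stored normalisation statistics to new profiles
#'
#' @param profiles raw [compute_profiles()] tibble.
#' @param stats a `norm_stats` tibble (single batch) as produced by
#'   [normalize_profiles()].
#' @return Standardised tibble restricted to the usable features.
#' @export
apply_normalization <- function(profiles, stats) {
  stats <- stats[stats$sd > 0, ]
  missing <- setdiff(stats$feature, names(profiles))
  if (length(missing))
    abort(sprintf("profiles lack feature(s): %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  for (j in seq_len(nrow(stats))) {
    f <- stats$feature[j]
    profiles[[f]] <- (profiles[[f]] - stats$mean[j]) / stats$sd[j]
  }
  drop <- setdiff(profile_feature_cols(profiles), stats$feature)
  if (length(drop)) profiles <- dplyr::select(profiles, -dplyr::all_of(drop))
  profiles
}
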