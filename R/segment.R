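#' Segment nuclei in a corrected nuclear-channel image
#'
#' Threshold (Otsu) after light smoothing, then split touching nuclei by
#' seeded watershed on the distance transform.
#'
#' @param dapi corrected nuclear-channel matrix.
#' @param min_area_px discard labelled specks below this area.
#' @param presmooth_sigma Gaussian sigma applied before thresholding.
#' @param tolerance watershed merge tolerance on the distance transform;
#'   lower splits more aggressively.
#' @return Integer label matrix (0 = background), one label per nucleus.
#' @export
segment_nuclei <- function(dapi, min_area_px = 25, presmooth_sigma = 2,
                           tolerance = 1) {
  assert_image(dapi)
  sm <- gaussian_smooth(dapi, presmooth_sigma)
  if (diff(range(sm)) <= 1e-8 * max(abs(sm), 1))
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = tolerance)
  lab <- drop_small(as.matrix(EBImage::imageData(lab)), min_area_px)
  lab
}

otsu_threshold <- function(x) {
  hi <- max(x)
  if (hi <= 0) return(0)
  EBImage::otsu(EBImage::Image(x / hi), range = c(0, 1), levels = 256L) * hi
}

# Two-threshold (three-class) Otsu by exhaustive search on a 256-bin
# histogram; returns the lower threshold (background vs dim foreground).
otsu3_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * nb) + 1L, nb), nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  cw <- cumsum(p); cm <- cumsum(p * mids)
  best <- -Inf; t1b <- 1L
  for (t1 in 1:(nb - 2L)) {
    w0 <- cw[t1]
    if (w0 == 0) next
    m0 <- cm[t1] / w0
    for (t2 in (t1 + 1L):(nb - 1L)) {
      w1 <- cw[t2] - cw[t1]; w2 <- 1 - cw[t2]
      if (w1 == 0 || w2 == 0) next
      m1 <- (cm[t2] - cm[t1]) / w1
      m2 <- (cm[nb] - cm[t2]) / w2
      mt <- cm[nb]
      v <- w0 * (m0 - mt)^2 + w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2
      if (v > best) { best <- v; t1b <- t1 }
    }
  }
  mids[t1b] + 0.5 / nb * diff(rng)
}

drop_small <- function(lab, min_area_px) {
  if (!any(lab > 0)) return(matrix(0L, nrow(lab), ncol(lab)))
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_area_px)
  relab <- integer(length(sz))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Segment GFP-positive (transfected) cells within the size gate
#'
#' Thresholds the corrected reporter image (Otsu with a configurable
#' absolute floor) and grows cell regions from nuclear seeds
#' (`propagate`); without nuclei (`nuclei = NULL`, GFP-only mode) the
#' thresholded regions are split by watershed instead. Retained objects
#' must have an equivalent diameter inside `[min_diameter, max_diameter]`
#' (default the 17--50 px analysis gate) and, by default, must not touch
#' the field border (tile scans are acquired without overlap, so border
#' objects are truncated duplicates-in-waiting).
#'
#' @param gfp corrected reporter-channel matrix.
#' @param nuclei label matrix from [segment_nuclei()], or `NULL`.
#' @param min_diameter,max_diameter equivalent-diameter gate in pixels.
#' @param threshold strategy for the GFP-positive mask: `"otsu3"`
#'   (default) is a three-class Otsu (background / dim cells / bright
#'   cells) whose lower split separates background from the dimmest
#'   transfected cells - a two-class Otsu is pulled into the
#'   heavy-tailed expression distribution and drops dim cells entirely;
#'   `"otsu"` is the classic bimodal split.
#' @param threshold_floor minimum absolute threshold in camera units;
#'   the applied threshold is `max(strategy threshold, threshold_floor)`.
#' @param discard_border drop objects touching the field border.
#' @return A `cell_tbl` tibble, one row per retained cell: `cell_id`,
#'   `nucleus_id`, `centroid_x`, `centroid_y` (0-based, x = column),
#'   `area_px`, `equiv_diameter_px`, and a `mask` list-column where each
#'   element is `list(y0, x0, patch)` - the 1-based top-left corner and
#'   logical patch of the cell mask. Masks are pairwise disjoint.
#' @export
segment_cells <- function(gfp, nuclei = NULL, min_diameter = 17,
                          max_diameter = 50,
                          threshold = c("otsu3", "otsu"),
                          threshold_floor = 0, discard_border = TRUE) {
  assert_image(gfp)
  threshold <- match.arg(threshold)
  H <- nrow(gfp); W <- ncol(gfp)
  sm <- gaussian_smooth(gfp, 1)
  thr <- switch(threshold,
    otsu3 = otsu3_threshold(sm),
    otsu = otsu_threshold(sm))
  thr <- max(thr, threshold_floor)
  mask <- sm > thr
  empty <- cell_tbl(tibble(cell_id = integer(), nucleus_id = integer(),
                           centroid_x = numeric(), centroid_y = numeric(),
                           area_px = integer(), equiv_diameter_px = numeric(),
                           mask = list()), dim = c(H, W))
  if (!any(mask)) return(empty)
  if (!is.null(nuclei)) {
    if (!identical(dim(nuclei), dim(gfp)))
      abort("nuclei and gfp shapes differ")
    seeds <- nuclei * mask
    lab <- as.matrix(EBImage::imageData(
      EBImage::propagate(EBImage::Image(gfp / max(gfp)),
                         EBImage::Image(seeds), mask = mask)))
  } else {
    lab <- as.matrix(EBImage::imageData(
      EBImage::watershed(EBImage::distmap(mask), tolerance = 3)))
  }
  lab <- drop_small(lab, ceiling(pi * (min_diameter / 2)^2 / 4))
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(empty)

  rows <- vector("list", length(ids))
  keep_n <- 0L
  for (id in ids) {
    idx <- which(lab == id)
    area <- length(idx)
    d <- equiv_diameter(area)
    if (d < min_diameter || d > max_diameter) next
    yy <- (idx - 1L) %% H + 1L
    xx <- (idx - 1L) %/% H + 1L
    if (discard_border &&
        (min(yy) == 1L || min(xx) == 1L || max(yy) == H || max(xx) == W))
      next
    y0 <- min(yy); x0 <- min(xx)
    patch <- matrix(FALSE, max(yy) - y0 + 1L, max(xx) - x0 + 1L)
    patch[cbind(yy - y0 + 1L, xx - x0 + 1L)] <- TRUE
    keep_n <- keep_n + 1L
    rows[[keep_n]] <- tibble(
      cell_id = keep_n,
      nucleus_id = if (is.null(nuclei)) NA_integer_ else as.integer(id),
      centroid_x = mean(xx) - 1, centroid_y = mean(yy) - 1,
      area_px = area, equiv_diameter_px = d,
      mask = list(list(y0 = y0, x0 = x0, patch = patch)))
  }
  out <- if (keep_n) bind_rows(rows[seq_len(keep_n)]) else empty
  cell_tbl(out, dim = c(H, W))
}

cell_tbl <- function(x, dim) {
  attr(x, "field_dim") <- as.integer(dim)
  class(x) <- unique(c("cell_tbl", class(x)))
  x
}

#' Rebuild the labelled cell image from a segmented cell table
#'
#' @param cells a [segment_cells()] tibble.
#' @param dim image dimensions `(H, W)`; defaults to the field the cells
#'   were segmented from.
#' @return Integer label matrix with `cell_id` labels.
#' @export
rebuild_labels <- function(cells, dim = attr(cells, "field_dim")) {
  if (is.null(dim)) abort("supply `dim`: cell table carries no field_dim")
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(cells))) {
    m <- cells$mask[[i]]
    sub <- lab[m$y0 + seq_len(nrow(m$patch)) - 1L,
               m$x0 + seq_len(ncol(m$patch)) - 1L, drop = FALSE]
    sub[m$patch] <- cells$cell_id[i]
    lab[m$y0 + seq_len(nrow(m$patch)) - 1L,
        m$x0 + seq_len(ncol(m$patch)) - 1L] <- sub
  }
  lab
}

#' Match detected cells to ground-truth masks
#'
#' Greedy one-to-one matching by intersection-over-union (IoU): each
#' truth object is matched to the detected cell with the largest IoU,
#' provided it reaches `min_iou` and is not already claimed.
#'
#' @param cells a [segment_cells()] tibble.
#' @param truth_mask labelled truth matrix (e.g. `truth$cell_mask` from
#'   [generate_field()]).
#' @param min_iou minimum IoU for a valid match.
#' @return Tibble with one row per truth object: `truth_id`, `cell_id`
#'   (NA if unmatched), `iou`, `matched`.
#' @export
match_to_truth <- function(cells, truth_mask, min_iou = 0.5) {
  lab <- rebuild_labels(cells, dim(truth_mask))
  t_ids <- sort(unique(truth_mask[truth_mask > 0]))
  t_area <- tabulate(truth_mask[truth_mask > 0])
  d_area <- if (nrow(cells)) tabulate(lab[lab > 0], max(cells$cell_id))
            else integer(0)
  both <- truth_mask > 0 & lab > 0
  res <- tibble(truth_id = t_ids, cell_id = NA_integer_, iou = 0)
  if (any(both)) {
    ov <- as.data.frame(table(truth = truth_mask[both], det = lab[both]),
                        stringsAsFactors = FALSE)
    ov$truth <- as.integer(ov$truth); ov$det <- as.integer(ov$det)
    ov$iou <- ov$Freq / (t_area[ov$truth] + d_area[ov$det] - ov$Freq)
    ov <- ov[order(-ov$iou), ]
    used <- integer(0)
    for (r in seq_len(nrow(ov))) {
      if (ov$iou[r] < min_iou) break
      ti <- match(ov$truth[r], res$truth_id)
      if (!is.na(res$cell_id[ti]) || ov$det[r] %in% used) next
      res$cell_id[ti] <- ov$det[r]
      res$iou[ti] <- ov$iou[r]
      used <- c(used, ov$det[r])
    }
  }
  res$matched <- !is.na(res$cell_id)
  res
}

#' Focus quality score for a field image
#'
#' Normalised variance-of-Laplacian: `var(laplacian(I)) / mean(I)^2`,
#' a standard autofocus figure of merit. Blur strictly lowers the score;
#' a constant image scores 0. The default use is reporting only - no
#' image is ever dropped by this function.
#'
#' @param image numeric matrix.
#' @param threshold score below which `pass` is `FALSE`.
#' @return Tibble with `score` and `pass`.
#' @export
qc_focus <- function(image, threshold = 1e-4) {
  assert_image(image)
  mu <- mean(image)
  if (mu <= 0 || max(image) == min(image))
    return(tibble(score = 0, pass = FALSE))
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- as.matrix(EBImage::filter2(image, k, boundary = "replicate"))
  score <- stats::var(as.vector(lap)) / mu^2
  tibble(score = score, pass = score >= threshold)
}
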