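#' Estimate a per-channel illumination function from an image set
#'
#' The illumination function summarises the smooth spatial variation in
#' illumination across one imaging session: the pixelwise aggregate of
#' the set (mean by default, median with `stat = "median"`) smoothed by a
#' wide Gaussian. The smoothing scale is expressed as an artifact
#' diameter (full width at half maximum), the convention of high-content
#' tools for the phrase "N pixel smoothing filter": the Gaussian sigma is
#' `smoothing_scale_px / 2.355`. Default scale 500 px.
#'
#' @param images list of numeric matrices (one channel), or a list-column
#'   from [load_plate()].
#' @param smoothing_scale_px smoothing FWHM in pixels.
#' @param stat pixelwise aggregate across images: `"mean"` or `"median"`.
#' @return An `illumination_function`: list with `surface` (nonnegative
#'   matrix, same shape as the fields), `smoothing_scale_px`, `stat`,
#'   `n_images`.
#' @export
estimate_illumination <- function(images, smoothing_scale_px = 500,
                                  stat = c("mean", "median")) {
  stat <- match.arg(stat)
  images <- images[!vapply(images, is.null, logical(1))]
  if (!length(images)) abort("need at least one image")
  lapply(images, assert_image, arg = "images[[i]]")
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    abort("all images must share one shape")
  agg <- if (length(images) == 1L) images[[1]] else {
    arr <- array(unlist(images, use.names = FALSE), c(shp, length(images)))
    apply(arr, c(1, 2), stat)
  }
  surface <- pmax(gaussian_smooth(agg, smoothing_scale_px / 2.355), 0)
  structure(list(surface = surface,
                 smoothing_scale_px = smoothing_scale_px,
                 stat = stat, n_images = length(images)),
            class = "illumination_function")
}

#' @export
print.illumination_function <- function(x, ...) {
  cat(sprintf(
    "<illumination_function> %d x %d, scale %g px (%s of %d image%s), range [%.1f, %.1f]\n",
    nrow(x$surface), ncol(x$surface), x$smoothing_scale_px, x$stat,
    x$n_images, if (x$n_images == 1) "" else "s",
    min(x$surface), max(x$surface)))
  invisible(x)
}

#' Correct a field image for illumination variation
#'
#' Subtracts the illumination function with a minimum-preserving offset:
#' `corrected = max(image - surface + min(surface), 0)`. The offset keeps
#' the dimmest region of the estimated illumination untouched, so a
#' perfectly flat set corrects to near-zero residual spatial variation
#' without nulling genuine signal; the zero clamp guarantees nonnegative
#' output.
#'
#' @param image numeric matrix in camera units.
#' @param fn an [estimate_illumination()] result.
#' @return Corrected matrix, same shape.
#' @export
apply_illumination <- function(image, fn) {
  assert_image(image)
  stopifnot(inherits(fn, "illumination_function"))
  if (!identical(dim(image), dim(fn$surface)))
    abort("image and illumination function shapes differ")
  pmax(image - fn$surface + min(fn$surface), 0)
}

#' Illumination-correct a loaded plate in place
#'
#' Estimates one illumination function per channel across all fields of
#' the plate (the fields stand in for "a set of images from one imaging
#' session") and corrects every field.
#'
#' @param plate a [load_plate()] tibble.
#' @param smoothing_scale_px,stat passed to [estimate_illumination()].
#' @return The plate tibble with corrected `dapi` / `gfp` list-columns;
#'   attribute `"illumination"` holds the per-channel functions.
#' @export
correct_plate <- function(plate, smoothing_scale_px = 500,
                          stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fns <- list()
  for (ch in c("dapi", "gfp")) {
    imgs <- plate[[ch]]
    if (all(vapply(imgs, is.null, logical(1)))) next
    fn <- estimate_illumination(imgs, smoothing_scale_px, stat)
    plate[[ch]] <- lapply(imgs, function(m)
      if (is.null(m)) NULL else apply_illumination(m, fn))
    fns[[ch]] <- fn
  }
  attr(plate, "illumination") <- fns
  plate
}
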