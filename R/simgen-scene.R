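#' Specify a synthetic two-channel field scene
#'
#' A `scene_spec` describes one microscope field of transfected cells:
#' how many cells, what fraction carry the inclusion phenotype, the size
#' and intensity distributions, the illumination vignette and the camera
#' noise model. [generate_field()] renders it into a DAPI/GFP image pair
#' plus exact ground truth (masks and per-cell labels).
#'
#' Defaults emulate 10x imaging of transfected neuron-like cells: cell
#' diameters straddle the 17--50 px analysis gate, diffuse GFP expression
#' is lognormal, inclusions are bright compact puncta, the vignette is a
#' smooth radial multiplicative bias, and noise is Poisson shot noise
#' plus Gaussian read noise on a 16-bit camera.
#'
#' @param image_shape integer (height, width) in pixels.
#' @param n_cells number of cells to place.
#' @param inclusion_prevalence probability in \[0,1\] that a transfected
#'   cell carries the inclusion phenotype.
#' @param frac_transfected fraction of cells expressing the GFP reporter;
#'   untransfected cells appear in DAPI only.
#' @param nucleus_diameter,cell_diameter length-2 numeric `(mean, sd)` of
#'   the object diameter in pixels.
#' @param diffuse_intensity length-2 numeric `(meanlog, sdlog)` of the
#'   per-cell lognormal diffuse GFP level, camera units.
#' @param puncta_per_cell length-2 integer `(min, max)`; inclusion cells
#'   receive a uniform count in this range.
#' @param puncta_diameter length-2 numeric `(mean, sd)` punctum FWHM, px.
#' @param puncta_contrast ratio of punctum peak intensity to the cell's
#'   diffuse mean.
#' @param bias_amplitude relative vignette depth (0 = flat illumination).
#' @param bias_scale vignette Gaussian scale as a fraction of the short
#'   image side.
#' @param background additive background level, camera units.
#' @param noise_gaussian_sd read-noise standard deviation, camera units.
#' @param noise_poisson_gain camera gain: shot-noise variance equals
#'   `gain * intensity`; 0 disables shot noise.
#' @param bit_depth camera bit depth; intensities saturate at
#'   `2^bit_depth - 1`.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return An object of class `scene_spec` (a validated list).
#' @export
#' @examples
#' fld <- generate_field(scene_spec(n_cells = 10, seed = 1))
#' dim(fld$gfp)
#' fld$truth$cells
scene_spec <- function(image_shape = c(512L, 512L),
                       n_cells = 40,
                       inclusion_prevalence = 0.2,
                       frac_transfected = 1,
                       nucleus_diameter = c(13, 1.5),
                       cell_diameter = c(30, 6),
                       diffuse_intensity = c(log(8000), 0.35),
                       puncta_per_cell = c(1L, 4L),
                       puncta_diameter = c(5, 1),
                       puncta_contrast = 3,
                       bias_amplitude = 0.25,
                       bias_scale = 0.8,
                       background = 300,
                       noise_gaussian_sd = 60,
                       noise_poisson_gain = 0.5,
                       bit_depth = 16L,
                       seed = NULL) {
  spec <- list(
    image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
    inclusion_prevalence = inclusion_prevalence,
    frac_transfected = frac_transfected,
    nucleus_diameter = nucleus_diameter, cell_diameter = cell_diameter,
    diffuse_intensity = diffuse_intensity,
    puncta_per_cell = as.integer(puncta_per_cell),
    puncta_diameter = puncta_diameter, puncta_contrast = puncta_contrast,
    bias_amplitude = bias_amplitude, bias_scale = bias_scale,
    background = background, noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson_gain = noise_poisson_gain,
    bit_depth = as.integer(bit_depth), seed = seed)
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(s) {
  if (length(s$image_shape) != 2 || any(s$image_shape < 16))
    abort("image_shape must be two integers >= 16")
  if (s$n_cells < 0) abort("n_cells must be >= 0")
  if (s$inclusion_prevalence < 0 || s$inclusion_prevalence > 1)
    abort("inclusion_prevalence must lie in [0, 1]")
  if (s$frac_transfected < 0 || s$frac_transfected > 1)
    abort("frac_transfected must lie in [0, 1]")
  for (nm in c("nucleus_diameter", "cell_diameter", "puncta_diameter"))
    if (s[[nm]][1] <= 0) abort(sprintf("%s mean must be > 0", nm))
  if (s$puncta_contrast <= 1) abort("puncta_contrast must exceed 1")
  if (s$bit_depth < 8 || s$bit_depth > 16) abort("bit_depth must be in 8..16")
  invisible(s)
}

# Rasterize a rotated ellipse; returns linear indices into an H x W matrix
# (rows = y, cols = x) or integer(0) if fully outside.
ellipse_indices <- function(cx, cy, a, b, theta, H, W) {
  r <- max(a, b)
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(integer(0))
  dy <- rep(ys - cy, times = length(xs))
  dx <- rep(xs - cx, each = length(ys))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u * u + v * v <= 1
  yy <- rep(ys, times = length(xs))[keep]
  xx <- rep(xs, each = length(ys))[keep]
  (xx - 1L) * H + yy
}

# Smooth radial vignette, 1 at centre falling to (1 - amplitude).
make_bias_field <- function(shape, amplitude, scale) {
  H <- shape[1]; W <- shape[2]
  if (amplitude == 0) return(matrix(1, H, W))
  sig <- scale * min(H, W) / 2
  y <- (seq_len(H) - (H + 1) / 2)
  x <- (seq_len(W) - (W + 1) / 2)
  r2 <- outer(y^2, x^2, "+")
  (1 - amplitude) + amplitude * exp(-r2 / (2 * sig^2))
}

place_cells <- function(n, radii, H, W, max_tries = 400L) {
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    m <- radii[i] + 3
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      px <- runif(1, m, W - m); py <- runif(1, m, H - m)
      if (i == 1L) { ok <- TRUE }
      else {
        j <- seq_len(i - 1L)
        ok <- all((cx[j] - px)^2 + (cy[j] - py)^2 >
                    (radii[j] + radii[i] + 2)^2)
      }
      if (ok) { cx[i] <- px; cy[i] <- py; break }
    }
    if (!ok)
      abort(sprintf(
        "could not place %d non-overlapping cells of mean radius %.1f px in a %d x %d field; reduce n_cells or cell_diameter",
        n, mean(radii), H, W))
  }
  list(cx = cx, cy = cy)
}

#' Render a synthetic DAPI/GFP field with ground truth
#'
#' Renders the scene described by a [scene_spec()]: cells are smoothed
#' ellipses with elliptical nuclei; inclusion-phenotype cells receive
#' bright 2-D Gaussian puncta clipped to the cell mask; the multiplicative
#' vignette is applied, then Poisson-Gaussian noise, then saturation at
#' the camera bit depth. The returned truth carries exact labelled masks,
#' per-cell phenotype labels and the generating parameters.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `dapi` and `gfp` (numeric matrices in
#'   camera units) and `truth`, itself a list of `cell_mask` and
#'   `nucleus_mask` (labelled integer matrices), `cells` (a tibble with
#'   one row per cell: `cell_id`, `label`, `transfected`, `centroid_x`,
#'   `centroid_y` (0-based), `equiv_diameter_px`, `n_puncta`,
#'   `diffuse_intensity`), `bias_field`, and `spec`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_rng(spec$seed, render_field(spec))
}

render_field <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  n <- spec$n_cells
  bias <- make_bias_field(spec$image_shape, spec$bias_amplitude, spec$bias_scale)

  cell_mask <- matrix(0L, H, W)
  nuc_mask <- matrix(0L, H, W)
  gfp_ideal <- matrix(spec$background, H, W)
  dapi_ideal <- matrix(spec$background, H, W)

  if (n > 0) {
    d_cell <- pmax(rnorm(n, spec$cell_diameter[1], spec$cell_diameter[2]), 10)
    d_nuc <- pmax(rnorm(n, spec$nucleus_diameter[1], spec$nucleus_diameter[2]), 5)
    d_nuc <- pmin(d_nuc, 0.8 * d_cell)
    aspect <- runif(n, 0.75, 1.3)
    theta <- runif(n, 0, pi)
    a_cell <- d_cell / 2 * sqrt(aspect); b_cell <- d_cell / 2 / sqrt(aspect)
    pos <- place_cells(n, pmax(a_cell, b_cell), H, W)
    transfected <- runif(n) < spec$frac_transfected
    inclusion <- transfected & (runif(n) < spec$inclusion_prevalence)
    diffuse <- exp(rnorm(n, spec$diffuse_intensity[1], spec$diffuse_intensity[2]))
    dapi_level <- exp(rnorm(n, log(15000), 0.25))
    n_puncta <- integer(n)
    puncta_xy <- vector("list", n)

    for (i in seq_len(n)) {
      ci <- ellipse_indices(pos$cx[i], pos$cy[i], a_cell[i], b_cell[i],
                            theta[i], H, W)
      ni <- ellipse_indices(pos$cx[i], pos$cy[i], d_nuc[i] / 2 * sqrt(aspect[i]),
                            d_nuc[i] / 2 / sqrt(aspect[i]), theta[i], H, W)
      cell_mask[ci] <- i
      nuc_mask[ni] <- i
      dapi_ideal[ni] <- dapi_ideal[ni] + dapi_level[i]
      if (transfected[i]) gfp_ideal[ci] <- gfp_ideal[ci] + diffuse[i]
      if (inclusion[i]) {
        k <- if (spec$puncta_per_cell[1] == spec$puncta_per_cell[2])
          spec$puncta_per_cell[1]
        else sample(spec$puncta_per_cell[1]:spec$puncta_per_cell[2], 1)
        n_puncta[i] <- k
        # punctum centres uniform over the cell interior, at least one
        # punctum radius from the rim (inclusions are intracellular
        # bodies; also keeps the rendered peak at the specified
        # contrast, undiluted by the smoothed cell edge)
        yy <- (ci - 1L) %% H + 1L; xx <- (ci - 1L) %/% H + 1L
        py0 <- min(yy); px0 <- min(xx)
        pm <- matrix(FALSE, max(yy) - py0 + 1L, max(xx) - px0 + 1L)
        pm[cbind(yy - py0 + 1L, xx - px0 + 1L)] <- TRUE
        dm <- as.matrix(EBImage::imageData(EBImage::distmap(pm)))
        dv <- dm[cbind(yy - py0 + 1L, xx - px0 + 1L)]
        elig <- ci[dv >= spec$puncta_diameter[1] / 2 + 1]
        if (!length(elig)) elig <- ci
        idx <- sample(elig, k, replace = k > length(elig))
        puncta_xy[[i]] <- cbind(x = (idx - 1L) %/% H + 1L,
                                y = (idx - 1L) %% H + 1L)
      }
    }

    # smooth the hard shape edges, then add already-smooth Gaussian puncta
    gfp_ideal <- gaussian_smooth(gfp_ideal, 1)
    dapi_ideal <- gaussian_smooth(dapi_ideal, 1)

    for (i in which(n_puncta > 0)) {
      d_p <- pmax(rnorm(n_puncta[i], spec$puncta_diameter[1],
                        spec$puncta_diameter[2]), 2)
      amp <- (spec$puncta_contrast - 1) * diffuse[i]
      for (j in seq_len(n_puncta[i])) {
        sig <- d_p[j] / 2.355
        px <- puncta_xy[[i]][j, "x"]; py <- puncta_xy[[i]][j, "y"]
        hw <- ceiling(3 * sig)
        ys <- max(1L, py - hw):min(H, py + hw)
        xs <- max(1L, px - hw):min(W, px + hw)
        blob <- amp * exp(-(outer((ys - py)^2, (xs - px)^2, "+")) / (2 * sig^2))
        inside <- cell_mask[ys, xs, drop = FALSE] == i
        gfp_ideal[ys, xs] <- gfp_ideal[ys, xs] + blob * inside
      }
    }

    cells <- tibble(
      cell_id = seq_len(n),
      label = ifelse(inclusion, "inclusion", "no_inclusion"),
      transfected = transfected,
      centroid_x = pos$cx - 1, centroid_y = pos$cy - 1,
      equiv_diameter_px = equiv_diameter(tabulate(cell_mask[cell_mask > 0], n)),
      n_puncta = n_puncta,
      diffuse_intensity = diffuse)
  } else {
    cells <- tibble(cell_id = integer(), label = character(),
                    transfected = logical(), centroid_x = numeric(),
                    centroid_y = numeric(), equiv_diameter_px = numeric(),
                    n_puncta = integer(), diffuse_intensity = numeric())
  }

  ceiling_dn <- 2^spec$bit_depth - 1
  corrupt <- function(ideal) {
    img <- ideal * bias
    if (spec$noise_poisson_gain > 0)
      img <- rpois(length(img), img / spec$noise_poisson_gain) *
        spec$noise_poisson_gain
    if (spec$noise_gaussian_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_gaussian_sd)
    matrix(clamp(round(img), 0, ceiling_dn), nrow(ideal), ncol(ideal))
  }

  list(dapi = corrupt(dapi_ideal), gfp = corrupt(gfp_ideal),
       truth = list(cell_mask = cell_mask, nucleus_mask = nuc_mask,
                    cells = cells, bias_field = bias, spec = spec))
}
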