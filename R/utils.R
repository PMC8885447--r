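#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest nest
#' @importFrom purrr map map_dbl map_int map_lgl map2 pmap imap list_rbind
NULL

# Gaussian smoothing that tolerates kernels wider than the image:
# the brush is truncated to the image and re-normalised to sum 1.
gaussian_smooth <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  size <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  cap <- 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L
  size <- min(size, cap)
  b <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  b <- b / sum(b)
  as.matrix(EBImage::filter2(x, b, boundary = "replicate"))
}

# Derive a per-stream sub-seed from a master seed, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 104729) %% 2147483647)
}

with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix of pixel intensities", arg))
  if (any(!is.finite(x)))
    abort(sprintf("`%s` contains non-finite pixels", arg))
  invisible(x)
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# equivalent diameter of a region from its pixel area
equiv_diameter <- function(area_px) 2 * sqrt(area_px / pi)
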