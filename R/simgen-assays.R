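#' Specify a synthetic checkerboard combination experiment
#'
#' Describes a two-drug factorial dose grid read out as "% cells with
#' inclusions". Monotherapy effects follow Hill curves; the combination
#' effect is the highest-single-agent (HSA) reference
#' `max(E_a, E_b)` plus an injectable `synergy_offset`, so with offset 0
#' the surface is an exact fixed point of the HSA model. Default doses
#' mirror a CuATSM-like 0--0.5 uM twofold series against an ebselen-like
#' 0--10 uM twofold series.
#'
#' @param doses_a,doses_b ascending dose vectors (uM), first element 0.
#' @param mono_a,mono_b named vectors `c(emax, ec50, hill)` of the
#'   monotherapy effect curves (percentage-point reduction at saturation,
#'   uM midpoint, slope).
#' @param synergy_offset percentage-point excess over the HSA reference:
#'   a scalar applied to every interior dose pair, or a full
#'   `length(doses_a) x length(doses_b)` matrix. Margins (either dose 0)
#'   are always 0: monotherapy defines the reference.
#' @param baseline_pct inclusion percentage of the no-drug control.
#' @param noise_sd Gaussian noise on the raw responses, percentage points.
#' @param replicates number of replicate plates.
#' @param seed integer seed.
#' @return A `combo_spec` list.
#' @export
combo_spec <- function(doses_a = c(0, 0.03125, 0.0625, 0.125, 0.25, 0.5),
                       doses_b = c(0, 1.25, 2.5, 5, 10),
                       mono_a = c(emax = 70, ec50 = 0.1, hill = 1.2),
                       mono_b = c(emax = 60, ec50 = 3, hill = 1.3),
                       synergy_offset = 0,
                       baseline_pct = 25,
                       noise_sd = 2,
                       replicates = 3L,
                       seed = NULL) {
  if (doses_a[1] != 0 || doses_b[1] != 0)
    abort("dose lists must start at 0 (the no-drug margins)")
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE))
    abort("doses must be strictly ascending")
  na <- length(doses_a); nb <- length(doses_b)
  off <- if (is.matrix(synergy_offset)) {
    if (!all(dim(synergy_offset) == c(na, nb)))
      abort("synergy_offset matrix must be doses_a x doses_b")
    synergy_offset
  } else matrix(synergy_offset, na, nb)
  off[1, ] <- 0; off[, 1] <- 0
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 mono_a = mono_a, mono_b = mono_b, synergy_offset = off,
                 baseline_pct = baseline_pct, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = seed),
            class = "combo_spec")
}

hill_effect <- function(dose, pars) {
  ifelse(dose <= 0, 0,
         pars[["emax"]] * dose^pars[["hill"]] /
           (pars[["ec50"]]^pars[["hill"]] + dose^pars[["hill"]]))
}

#' Simulate checkerboard inclusion responses with known synergy
#'
#' @param spec a [combo_spec()].
#' @return A list: `observed` - tibble `dose_a`, `dose_b`, `replicate`,
#'   `response` (raw "% cells with inclusions", the (0,0) cell being the
#'   no-drug control); `truth_effect` - the noiseless effect matrix
#'   (percentage-point reduction relative to control, doses_a in rows);
#'   `spec`.
#' @export
generate_checkerboard <- function(spec) {
  stopifnot(inherits(spec, "combo_spec"))
  ea <- hill_effect(spec$doses_a, spec$mono_a)
  eb <- hill_effect(spec$doses_b, spec$mono_b)
  E <- clamp(outer(ea, eb, pmax) + spec$synergy_offset, 0, 100)
  raw_mean <- spec$baseline_pct * (100 - E) / 100
  obs <- with_rng(spec$seed, {
    bind_rows(lapply(seq_len(spec$replicates), function(r) {
      noise <- if (spec$noise_sd > 0)
        matrix(rnorm(length(raw_mean), 0, spec$noise_sd), nrow(raw_mean))
      else 0
      m <- clamp(raw_mean + noise, 0, 100)
      tibble(dose_a = rep(spec$doses_a, times = length(spec$doses_b)),
             dose_b = rep(spec$doses_b, each = length(spec$doses_a)),
             replicate = r, response = as.vector(m))
    }))
  })
  list(observed = obs, truth_effect = E, spec = spec)
}

#' Simulate live-cell GFP-positive count series
#'
#' Counts decline (or hold) exponentially per treatment arm; observed
#' counts are Poisson draws around the deterministic mean curve
#' `n0 * exp(-death_rate * t)`, which is returned alongside.
#'
#' @param arms data frame with columns `arm`, `death_rate` (per hour;
#'   may be negative for growth) and optionally `n0` (starting GFP+
#'   count, default 200).
#' @param timepoints hours, nonnegative, strictly increasing.
#' @param replicates wells per arm.
#' @param seed integer seed.
#' @return Tibble: `arm`, `replicate`, `time_h`, `count` (stochastic),
#'   `mean_count` (deterministic truth).
#' @export
generate_timeseries <- function(arms, timepoints = seq(0, 48, by = 8),
                                replicates = 3L, seed = NULL) {
  arms <- as_tibble(arms)
  if (any(timepoints < 0)) abort("timepoints must be nonnegative")
  if (is.unsorted(timepoints, strictly = TRUE))
    abort("timepoints must be strictly increasing")
  if (any(!is.finite(arms$death_rate))) abort("death rates must be finite")
  if (!"n0" %in% names(arms)) arms$n0 <- 200
  if (any(arms$n0 <= 0)) abort("starting counts must be > 0")
  with_rng(seed, {
    tidyr::expand_grid(arms, replicate = seq_len(replicates),
                       time_h = timepoints) |>
      mutate(mean_count = .data$n0 * exp(-.data$death_rate * .data$time_h),
             count = stats::rpois(dplyr::n(), .data$mean_count)) |>
      dplyr::select("arm", "replicate", "time_h", "count", "mean_count")
  })
}
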