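#' Build a long checkerboard tibble from a response matrix
#'
#' @param doses_a,doses_b ascending dose vectors (uM), first element 0.
#' @param response matrix of "% cells with inclusions" with `doses_a` in
#'   rows, or a list of such matrices (one per replicate).
#' @return Tibble `dose_a`, `dose_b`, `replicate`, `response`.
#' @export
checkerboard_tbl <- function(doses_a, doses_b, response) {
  if (is.matrix(response)) response <- list(response)
  bind_rows(lapply(seq_along(response), function(r) {
    m <- response[[r]]
    if (!all(dim(m) == c(length(doses_a), length(doses_b))))
      abort("response matrix must be doses_a x doses_b")
    tibble(dose_a = rep(doses_a, times = length(doses_b)),
           dose_b = rep(doses_b, each = length(doses_a)),
           replicate = r, response = as.vector(m))
  }))
}

check_checkerboard <- function(cb) {
  need <- c("dose_a", "dose_b", "response")
  if (!all(need %in% names(cb)))
    abort("checkerboard needs columns dose_a, dose_b, response")
  if (!"replicate" %in% names(cb)) cb$replicate <- 1L
  if (any(cb$response < 0)) abort("responses must be nonnegative")
  cb
}

#' Normalise checkerboard responses to the no-drug control
#'
#' Each replicate is normalised to its own (0, 0) well as a percentage of
#' control: the control cell becomes exactly 100. Values above 100
#' (worsening under treatment) are retained. Replicates are normalised
#' individually - averaging happens after normalisation, downstream.
#'
#' @param cb checkerboard tibble (see [checkerboard_tbl()]).
#' @return The tibble with a `pct_control` column.
#' @export
normalize_checkerboard <- function(cb) {
  cb <- check_checkerboard(cb)
  cb |>
    group_by(.data$replicate) |>
    group_modify(function(d, key) {
      ctrl <- d$response[d$dose_a == 0 & d$dose_b == 0]
      if (length(ctrl) != 1)
        abort("each replicate needs exactly one (0, 0) control well")
      if (ctrl <= 0)
        abort("control response is 0: normalisation undefined")
      d$pct_control <- 100 * d$response / ctrl
      d
    }) |>
    ungroup()
}

#' Highest-single-agent (HSA) synergy matrix
#'
#' For each replicate the effect is the reduction relative to control,
#' `E(a,b) = 100 - pct_control`; the HSA reference is the best
#' monotherapy at that pair, `R(a,b) = max(E(a,0), E(0,b))`; the synergy
#' score is `S = E - R`. Monotherapy margins are the reference itself and
#' score exactly 0. Per-pair scores are averaged across replicates and
#' reported with their sd.
#'
#' @param norm a [normalize_checkerboard()] result.
#' @return A `synergy_matrix` tibble per dose pair: `dose_a`, `dose_b`,
#'   `effect` (mean E), `hsa_ref`, `score` (mean S), `score_sd`, `n_rep`.
#' @export
hsa_synergy <- function(norm) {
  if (!"pct_control" %in% names(norm))
    abort("input must be normalised first (normalize_checkerboard)")
  per_rep <- norm |>
    group_by(.data$replicate) |>
    group_modify(function(d, key) {
      d$effect <- 100 - d$pct_control
      ea <- d[d$dose_b == 0, c("dose_a", "effect")]
      eb <- d[d$dose_a == 0, c("dose_b", "effect")]
      d$hsa_ref <- pmax(ea$effect[match(d$dose_a, ea$dose_a)],
                        eb$effect[match(d$dose_b, eb$dose_b)])
      d$score <- d$effect - d$hsa_ref
      d$score[d$dose_a == 0 | d$dose_b == 0] <- 0
      d
    }) |>
    ungroup()
  out <- per_rep |>
    group_by(.data$dose_a, .data$dose_b) |>
    summarise(effect = mean(.data$effect), hsa_ref = mean(.data$hsa_ref),
              score_sd = stats::sd(.data$score), score = mean(.data$score),
              n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("score", .after = "hsa_ref")
  stopifnot(all(out$score[out$dose_a == 0 | out$dose_b == 0] == 0))
  class(out) <- unique(c("synergy_matrix", class(out)))
  out
}

#' Call synergy per dose pair
#'
#' A pair is `synergistic` if its mean score exceeds `threshold`
#' (strictly above - a score of exactly 10 is neutral), `antagonistic`
#' below `-threshold`, `neutral` otherwise.
#'
#' @param syn a [hsa_synergy()] matrix.
#' @param threshold synergy-call threshold in percentage points.
#' @return The tibble with a `call` factor column.
#' @export
call_synergy <- function(syn, threshold = 10) {
  syn$call <- factor(
    ifelse(syn$score > threshold, "synergistic",
           ifelse(syn$score < -threshold, "antagonistic", "neutral")),
    levels = c("antagonistic", "neutral", "synergistic"))
  syn
}
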