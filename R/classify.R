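#' Train the inclusion/no-inclusion random-forest classifier
#'
#' Fits a 100-tree random forest (sqrt-features per split) on z-scored
#' cytoprofiles. The normalisation statistics of the training batch are
#' stored in the model and re-applied at scoring time, so scores do not
#' depend on the composition of the plate being scored. Training is
#' deterministic given `seed`; out-of-bag (OOB) accuracy is reported.
#'
#' @param profiles raw [compute_profiles()] tibble with a label column.
#' @param label_col name of the label column; labels must be
#'   `"inclusion"` / `"no_inclusion"`.
#' @param n_trees number of trees.
#' @param threshold inclusion-class probability above which a cell is
#'   called `inclusion`; ties at the threshold resolve to
#'   `no_inclusion` (conservative for a prevalence readout).
#' @param seed integer seed.
#' @return An `inclusion_classifier` object: the forest, the bound
#'   feature schema, normalisation statistics, `threshold`,
#'   `oob_accuracy` and per-class OOB accuracy.
#' @export
train_inclusion_classifier <- function(profiles, label_col = "label",
                                       n_trees = 100L, threshold = 0.5,
                                       seed = 1L) {
  labs <- profiles[[label_col]]
  if (is.null(labs)) abort(sprintf("no `%s` column in profiles", label_col))
  tab <- table(labs)
  if (length(tab) < 2) abort("training set must contain both classes")
  if (min(tab) < 5) abort("need at least 5 training cells per class")
  if (anyDuplicated(interaction(profiles$cell_id,
                                profiles[["well"]] %||% 1,
                                profiles[["field"]] %||% 1)))
    abort("duplicate cell ids in training set")
  norm <- withCallingHandlers(
    normalize_profiles(profiles),
    warning = function(w) invokeRestart("muffleWarning"))
  stats <- attr(norm, "norm_stats")
  fc <- profile_feature_cols(norm)
  x <- as.data.frame(norm[fc])
  y <- factor(labs, levels = c("inclusion", "no_inclusion"))
  fit <- with_rng(seed,
    randomForest::randomForest(x, y, ntree = n_trees,
                               mtry = max(1L, floor(sqrt(length(fc))))))
  conf <- fit$confusion[, c("inclusion", "no_inclusion")]
  structure(list(forest = fit, feature_names = fc, norm_stats = stats,
                 levels = c("inclusion", "no_inclusion"),
                 threshold = threshold, n_trees = n_trees, seed = seed,
                 oob_accuracy = sum(diag(conf)) / sum(conf),
                 oob_class_accuracy = diag(conf) / rowSums(conf)),
            class = "inclusion_classifier")
}

#' @export
print.inclusion_classifier <- function(x, ...) {
  cat(sprintf(
    "<inclusion_classifier> %d trees on %d features; OOB accuracy %.1f%% (inclusion %.1f%%, no_inclusion %.1f%%)\n",
    x$n_trees, length(x$feature_names), 100 * x$oob_accuracy,
    100 * x$oob_class_accuracy["inclusion"],
    100 * x$oob_class_accuracy["no_inclusion"]))
  invisible(x)
}

#' Score cells with a trained classifier
#'
#' Normalises the incoming profiles with the model's stored statistics
#' and returns the inclusion-class probability and the thresholded call
#' for every cell. Profiles whose feature schema does not match the
#' fit-time schema are rejected.
#'
#' @param model an [train_inclusion_classifier()] model.
#' @param profiles raw profiles tibble.
#' @return The metadata columns of `profiles` plus `p_inclusion` and
#'   `pred_label`.
#' @export
score_cells <- function(model, profiles) {
  stopifnot(inherits(model, "inclusion_classifier"))
  meta <- dplyr::select(as_tibble(profiles),
                        -dplyr::any_of(profile_feature_cols(profiles)))
  if (!nrow(profiles))
    return(bind_cols(meta, tibble(p_inclusion = numeric(),
                                  pred_label = character())))
  norm <- apply_normalization(profiles, model$norm_stats)
  miss <- setdiff(model$feature_names, names(norm))
  if (length(miss))
    abort(sprintf("profile schema mismatch; missing: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  x <- as.data.frame(norm[model$feature_names])
  p <- stats::predict(model$forest, x, type = "prob")[, "inclusion"]
  bind_cols(meta, tibble(
    p_inclusion = unname(p),
    pred_label = ifelse(p > model$threshold, "inclusion", "no_inclusion")))
}

#' Accuracy-vs-training-size review protocol
#'
#' Emulates user-assisted training review: for increasing training-set
#' sizes, a classifier is trained on a balanced labelled sample, then
#' `batch` cells *predicted* as each bin are drawn from the held-out pool
#' and scored against the oracle labels (a precision-per-bin accuracy,
#' matching a reviewer requesting "100 cells of a bin" and counting the
#' misclassified); this draw is repeated `repeats` times and averaged.
#' The protocol stops at the first size whose mean inclusion-bin
#' accuracy reaches `target` (default 0.97).
#'
#' @param profiles labelled profile pool; the label column is the oracle
#'   (in tests, the simulator truth).
#' @param train_sizes increasing total training-set sizes (split evenly
#'   between the classes).
#' @param batch cells requested per bin per review round.
#' @param repeats review rounds per size.
#' @param target mean inclusion-bin accuracy at which to stop.
#' @param stop_at_target evaluate remaining sizes anyway if `FALSE`.
#' @param label_col training label column.
#' @param oracle_col column holding the oracle's truth used to score the
#'   review draws; defaults to `label_col` (simulator truth plays both
#'   the labelling user and the oracle).
#' @param seed integer seed.
#' @return A `review_protocol` tibble: `train_size`, `bin`, `round`,
#'   `n_scored`, `accuracy`. Attributes: `plateau_size` (first size
#'   meeting `target`, NA if never), `target`, `recall` (held-out
#'   per-class recall per size).
#' @export
review_protocol <- function(profiles, train_sizes = seq(10, 150, by = 10),
                            batch = 100L, repeats = 3L, target = 0.97,
                            stop_at_target = TRUE, label_col = "label",
                            oracle_col = label_col, seed = 1L) {
  labs <- profiles[[label_col]]
  res <- list(); recalls <- list()
  plateau <- NA_integer_
  with_rng(seed, {
    for (s in train_sizes) {
      per_class <- max(ceiling(s / 2), 5L)
      tr_idx <- unlist(lapply(c("inclusion", "no_inclusion"), function(cl) {
        cand <- which(labs == cl)
        sample(cand, min(per_class, length(cand)))
      }))
      model <- train_inclusion_classifier(profiles[tr_idx, ],
                                          label_col = label_col,
                                          seed = derive_seed(seed, s))
      hold <- profiles[-tr_idx, ]
      scored <- score_cells(model, hold)
      truth <- hold[[oracle_col]]
      for (bin in c("inclusion", "no_inclusion")) {
        in_bin <- which(scored$pred_label == bin)
        for (r in seq_len(repeats)) {
          take <- if (length(in_bin) > batch) sample(in_bin, batch) else in_bin
          if (length(take) < batch)
            inform(sprintf(
              "size %d, bin %s: only %d of %d requested cells available",
              s, bin, length(take), batch))
          acc <- if (length(take)) mean(truth[take] == bin) else NA_real_
          res[[length(res) + 1L]] <- tibble(
            train_size = s, bin = bin, round = r,
            n_scored = length(take), accuracy = acc)
        }
      }
      recalls[[length(recalls) + 1L]] <- tibble(
        train_size = s,
        class = c("inclusion", "no_inclusion"),
        recall = vapply(c("inclusion", "no_inclusion"), function(cl)
          mean(scored$pred_label[truth == cl] == cl), numeric(1)))
      mean_inc <- mean(vapply(res[(length(res) - 2 * repeats + 1):length(res)],
                              function(d)
                                if (d$bin == "inclusion") d$accuracy else NA_real_,
                              numeric(1)), na.rm = TRUE)
      if (is.na(plateau) && is.finite(mean_inc) && mean_inc >= target) {
        plateau <- s
        if (stop_at_target) break
      }
    }
  })
  out <- bind_rows(res)
  attr(out, "plateau_size") <- plateau
  attr(out, "target") <- target
  attr(out, "recall") <- bind_rows(recalls)
  class(out) <- unique(c("review_protocol", class(out)))
  out
}

#' Summarise per-well inclusion percentages
#'
#' @param scored a [score_cells()] result carrying a `well` column.
#' @param layout optional plate layout; every scored well must appear in
#'   it, and its metadata columns are joined onto the summary.
#' @param min_cells wells scoring fewer cells are flagged `low_n`.
#' @return A tibble per well: `n_cells_scored`, `n_with_inclusions`,
#'   `pct_with_inclusions` (0..100), `low_n`, plus layout columns.
#' @export
summarize_wells <- function(scored, layout = NULL, min_cells = 50L) {
  if (!"well" %in% names(scored)) abort("scored cells need a `well` column")
  if (!is.null(layout)) {
    orphan <- setdiff(unique(scored$well), layout$well)
    if (length(orphan))
      abort(sprintf("scored well(s) not in layout: %s",
                    paste(orphan, collapse = ", ")))
  }
  out <- scored |>
    group_by(.data$well) |>
    summarise(n_cells_scored = dplyr::n(),
              n_with_inclusions = sum(.data$pred_label == "inclusion"),
              .groups = "drop") |>
    mutate(pct_with_inclusions = 100 * .data$n_with_inclusions /
             .data$n_cells_scored,
           low_n = .data$n_cells_scored < min_cells)
  if (!is.null(layout))
    out <- left_join(out, as_tibble(layout), by = "well")
  out
}

#' Misclassification-corrected prevalence (Rogan-Gladen)
#'
#' Corrects an apparent inclusion percentage for known classifier
#' sensitivity and specificity:
#' `p = (apparent + specificity - 1) / (sensitivity + specificity - 1)`,
#' clipped to \[0, 100\].
#'
#' @param pct apparent percentage (0..100).
#' @param sensitivity,specificity per-class accuracies on fractions
#'   (0..1) measured on labelled data.
#' @return Corrected percentage.
#' @export
correct_prevalence <- function(pct, sensitivity, specificity) {
  denom <- sensitivity + specificity - 1
  if (denom <= 0) abort("sensitivity + specificity must exceed 1")
  clamp(100 * (pct / 100 + specificity - 1) / denom, 0, 100)
}
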