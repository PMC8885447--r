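test_that("a separable training set reaches perfect out-of-bag accuracy", {
  model <- train_inclusion_classifier(separable_profiles(30), seed = 1)
  expect_equal(model$oob_accuracy, 1)
  # training cells scored by their own model do at least as well as OOB
  sc <- score_cells(model, separable_profiles(30))
  expect_gte(mean(sc$pred_label == separable_profiles(30)$label),
             model$oob_accuracy)
})

test_that("training is deterministic given the seed", {
  pool <- fix_pool()
  tr <- pool[c(1:40, 200:239), ]
  m1 <- train_inclusion_classifier(tr, seed = 7)
  m2 <- train_inclusion_classifier(tr, seed = 7)
  expect_equal(score_cells(m1, pool[50:80, ])$p_inclusion,
               score_cells(m2, pool[50:80, ])$p_inclusion)
})

test_that("swapping class labels permutes predictions symmetrically", {
  prof <- separable_profiles(30)
  swapped <- prof
  swapped$label <- ifelse(prof$label == "inclusion", "no_inclusion",
                          "inclusion")
  m1 <- train_inclusion_classifier(prof, seed = 3)
  m2 <- train_inclusion_classifier(swapped, seed = 3)
  s1 <- score_cells(m1, prof)
  s2 <- score_cells(m2, prof)
  expect_true(all(s1$pred_label != s2$pred_label))
})

test_that("degenerate training sets are rejected", {
  prof <- separable_profiles(30)
  expect_error(train_inclusion_classifier(prof[prof$label == "inclusion", ]),
               "both classes")
  expect_error(train_inclusion_classifier(prof[c(1:3, 31:60), ]),
               "at least 5")
})

test_that("held-out per-class accuracy meets the screening bars", {
  pool <- fix_pool()
  withr::with_seed(11, {
    tr <- unlist(lapply(split(seq_len(nrow(pool)), pool$label), sample, 75))
  })
  model <- train_inclusion_classifier(pool[tr, ], seed = 5)
  sc <- score_cells(model, pool[-tr, ])
  truth <- pool$label[-tr]
  acc_inc <- mean(sc$pred_label[truth == "inclusion"] == "inclusion")
  acc_no <- mean(sc$pred_label[truth == "no_inclusion"] == "no_inclusion")
  expect_gte(acc_inc, 0.95)
  expect_gte(acc_no, 0.98)
})

test_that("scoring validates schema, bounds probabilities, handles empties", {
  pool <- fix_pool()
  model <- train_inclusion_classifier(pool[1:100, ], seed = 2)
  sc <- score_cells(model, pool[101:150, ])
  expect_true(all(sc$p_inclusion >= 0 & sc$p_inclusion <= 1))
  expect_true(all(sc$pred_label %in% c("inclusion", "no_inclusion")))
  expect_equal(nrow(score_cells(model, pool[0, ])), 0)
  broken <- dplyr::select(pool[101:110, ], -"gran_03")
  expect_error(score_cells(model, broken), "gran_03")
})

test_that("the review protocol converges immediately on separable data", {
  prof <- separable_profiles(150, seed = 9)
  rp <- review_protocol(prof, train_sizes = c(10, 20, 30), batch = 50,
                        repeats = 2, seed = 1)
  expect_equal(attr(rp, "plateau_size"), 10)
  expect_true(all(rp$accuracy[rp$train_size == 10] == 1))
})

test_that("a flipped oracle reports non-convergence with near-zero accuracy", {
  prof <- separable_profiles(150, seed = 9)
  prof$oracle <- ifelse(prof$label == "inclusion", "no_inclusion", "inclusion")
  rp <- review_protocol(prof, train_sizes = c(10, 20), batch = 50,
                        repeats = 2, oracle_col = "oracle", seed = 1)
  expect_true(is.na(attr(rp, "plateau_size")))
  expect_lt(mean(rp$accuracy, na.rm = TRUE), 0.1)
})

test_that("review accuracy on simulated cells plateaus under 100 labels", {
  pool <- fix_pool()
  rp <- review_protocol(pool, train_sizes = seq(10, 90, by = 20), batch = 50,
                        repeats = 3, seed = 4)
  expect_lt(attr(rp, "plateau_size"), 100)
})

test_that("well summaries compute percentages and flags correctly", {
  scored <- tibble::tibble(
    well = rep(c("A1", "A2"), c(30, 60)),
    pred_label = c(rep(c("inclusion", "no_inclusion"), c(3, 27)),
                   rep("no_inclusion", 60)))
  sm <- summarize_wells(scored, min_cells = 50)
  expect_equal(sm$pct_with_inclusions, c(10, 0))
  expect_equal(sm$low_n, c(TRUE, FALSE))
  layout <- tibble::tibble(well = c("A1", "A2"), construct = c("A4V", "WT"))
  sm2 <- summarize_wells(scored, layout)
  expect_equal(sm2$construct, c("A4V", "WT"))
  expect_error(summarize_wells(scored, layout[1, ]), "not in layout")
})

test_that("misclassification correction inverts known error rates", {
  expect_equal(correct_prevalence(27.7, 1, 1), 27.7)
  # apparent = sens * p + (1 - spec) * (1 - p), with p = 0.2
  apparent <- 100 * (0.95 * 0.2 + 0.02 * 0.8)
  expect_equal(correct_prevalence(apparent, 0.95, 0.98), 20)
  expect_error(correct_prevalence(10, 0.5, 0.5), "exceed 1")
})
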