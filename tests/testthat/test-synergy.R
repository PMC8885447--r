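test_that("normalisation is percentage-of-control arithmetic", {
  cb <- checkerboard_tbl(c(0, 1), c(0, 2),
                         matrix(c(24, 12, 24, 6), 2, 2))
  norm <- normalize_checkerboard(cb)
  expect_equal(norm$pct_control[norm$dose_a == 1 & norm$dose_b == 0], 50)
  expect_equal(norm$pct_control[norm$dose_a == 0 & norm$dose_b == 0], 100)
  # all-equal responses normalise to a flat 100
  flat <- normalize_checkerboard(checkerboard_tbl(c(0, 1), c(0, 2),
                                                  matrix(24, 2, 2)))
  expect_true(all(flat$pct_control == 100))
  zero <- checkerboard_tbl(c(0, 1), c(0, 2), matrix(c(0, 1, 1, 1), 2, 2))
  expect_error(normalize_checkerboard(zero), "control response is 0")
})

test_that("replicates are normalised individually before averaging", {
  # two replicates with different control levels: the order of
  # normalising and averaging matters, and per-replicate-first is used
  r1 <- matrix(c(20, 10, 20, 10), 2, 2)
  r2 <- matrix(c(40, 10, 40, 10), 2, 2)
  cb <- checkerboard_tbl(c(0, 1), c(0, 2), list(r1, r2))
  syn <- hsa_synergy(normalize_checkerboard(cb))
  eff_after <- syn$effect[syn$dose_a == 1 & syn$dose_b == 0]
  expect_equal(eff_after, mean(c(100 - 100 * 10 / 20, 100 - 100 * 10 / 40)))
  eff_before <- 100 - 100 * mean(c(10, 10)) / mean(c(20, 40))
  expect_false(isTRUE(all.equal(eff_after, eff_before)))
})

test_that("the HSA score is the excess over the best monotherapy", {
  # E(a,0)=30, E(0,b)=40, E(a,b)=60 -> S = 20
  resp <- matrix(c(100, 70, 60, 40), 2, 2) # % control: rows = doses_a
  cb <- checkerboard_tbl(c(0, 1), c(0, 2), resp)
  norm <- normalize_checkerboard(cb)
  syn <- hsa_synergy(norm)
  expect_equal(syn$score[syn$dose_a == 1 & syn$dose_b == 2], 20)
  expect_equal(syn$effect[syn$dose_a == 1 & syn$dose_b == 2], 60)
})

test_that("an HSA-additive surface scores zero everywhere", {
  cs <- combo_spec(synergy_offset = 0, noise_sd = 0, replicates = 3, seed = 2)
  syn <- hsa_synergy(normalize_checkerboard(generate_checkerboard(cs)$observed))
  expect_true(all(abs(syn$score) < 1e-9))
  expect_true(all(syn$n_rep == 3))
})

test_that("an injected synergy offset is returned exactly where injected", {
  doses_a <- c(0, 0.03125, 0.0625, 0.125, 0.25, 0.5)
  doses_b <- c(0, 0.625, 1.25, 2.5, 5, 10)
  off <- matrix(0, 6, 6); off[6, 6] <- 20
  cs <- combo_spec(doses_a = doses_a, doses_b = doses_b,
                   synergy_offset = off, noise_sd = 0, replicates = 1,
                   seed = 1)
  syn <- hsa_synergy(normalize_checkerboard(generate_checkerboard(cs)$observed))
  top <- syn$dose_a == 0.5 & syn$dose_b == 10
  expect_equal(syn$score[top], 20)
  expect_true(all(abs(syn$score[!top]) < 1e-9))
})

test_that("monotherapy margins always score exactly zero", {
  cs <- combo_spec(noise_sd = 4, replicates = 3, seed = 8)
  syn <- hsa_synergy(normalize_checkerboard(generate_checkerboard(cs)$observed))
  margins <- syn$dose_a == 0 | syn$dose_b == 0
  expect_true(all(syn$score[margins] == 0))
})

test_that("the score is invariant to rescaling all raw responses", {
  cs <- combo_spec(synergy_offset = 5, noise_sd = 3, replicates = 2, seed = 6)
  cb <- generate_checkerboard(cs)$observed
  s1 <- hsa_synergy(normalize_checkerboard(cb))
  cb$response <- cb$response * 3.7
  s2 <- hsa_synergy(normalize_checkerboard(cb))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("the score is equivariant under input row order", {
  cs <- combo_spec(synergy_offset = 5, noise_sd = 3, replicates = 2, seed = 6)
  cb <- generate_checkerboard(cs)$observed
  s1 <- hsa_synergy(normalize_checkerboard(cb))
  shuf <- cb[withr::with_seed(1, sample(nrow(cb))), ]
  s2 <- hsa_synergy(normalize_checkerboard(shuf))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("synergy calls use a strict threshold in both directions", {
  syn <- hsa_synergy(normalize_checkerboard(
    checkerboard_tbl(c(0, 1), c(0, 2), matrix(c(100, 70, 60, 40), 2, 2))))
  syn$score[syn$dose_a == 1 & syn$dose_b == 2] <- 20
  calls <- call_synergy(syn)
  expect_equal(as.character(calls$call[calls$dose_a == 1 & calls$dose_b == 2]),
               "synergistic")
  syn$score[syn$dose_a == 1 & syn$dose_b == 2] <- 10  # exactly 10: neutral
  expect_equal(as.character(call_synergy(syn)$call[syn$dose_a == 1 &
                                                     syn$dose_b == 2]),
               "neutral")
  syn$score[syn$dose_a == 1 & syn$dose_b == 2] <- -15
  expect_equal(as.character(call_synergy(syn)$call[syn$dose_a == 1 &
                                                     syn$dose_b == 2]),
               "antagonistic")
})
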