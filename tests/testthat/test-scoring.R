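test_that("peak score returns the maximum and its delay, ties to smallest", {
  p <- delay_profile(c(0, 0, 0.4, 0.1), 1:4)
  expect_equal(peak_score(p), list(value = 0.4, delay = 3L))
  flat <- delay_profile(rep(0.2, 6), 1:6)
  expect_equal(peak_score(flat)$delay, 1L)
})

test_that("coincidence window sizes reproduce the bin-width conventions", {
  expect_equal(window_bins_for(1), 5)
  expect_equal(window_bins_for(2), 3)
  expect_equal(window_bins_for(4), 1)
  expect_equal(window_bins_for(17), 1)
  expect_equal(window_bins_for(5), 1)  # 1 bin spans exactly 5 ms
})

test_that("coincidence index: delta profile gives 1, flat gives 5/30", {
  delta <- delay_profile(c(rep(0, 10), 1, rep(0, 19)), 1:30)
  expect_equal(coincidence_index(delta), 1)
  flat <- delay_profile(rep(0.3, 30), 1:30)
  expect_equal(coincidence_index(flat), 5 / 30)
})

test_that("coincidence window shifts inward at the delay-grid boundary", {
  # peak at delay 1: the 5-bin window becomes bins 1..5, never wrapping
  p <- delay_profile(c(10, 1, 1, 1, 1, 1), 1:6)
  expect_equal(coincidence_index(p, T_ms = 6), 14 / 15)
  # grid narrower than the window: the whole grid is the window
  p2 <- delay_profile(c(4, 1, 2), 1:3)
  expect_equal(coincidence_index(p2, T_ms = 30), 1)
})

test_that("coincidence index is scale invariant and bounded by delta case", {
  set.seed(301)
  v <- stats::runif(30)
  p1 <- delay_profile(v, 1:30)
  p2 <- delay_profile(5 * v, 1:30)
  ci <- coincidence_index(p1)
  expect_equal(ci, coincidence_index(p2))
  expect_lte(ci, 1)
  expect_gt(ci, 0)
})

test_that("coincidence index needs a curve, not a single delay", {
  expect_error(coincidence_index(delay_profile(0.5, 1)), "at least two")
})

test_that("score_matrix agrees with per-profile scoring", {
  set.seed(302)
  mats <- lapply(1:3, function(q) rbin(5000, 0.05))
  raster <- spike_raster(do.call(rbind, mats))
  ps <- te_profiles(raster, 1, 1, delays = 1:30)
  pk <- score_matrix(ps, "pk")
  ci <- score_matrix(ps, "ci")
  for (p in seq_len(nrow(ps$pairs))) {
    prof <- delay_profile(ps$values[p, ], ps$delays)
    expect_equal(pk$score[p], peak_score(prof)$value)
    expect_equal(pk$peak_delay[p], peak_score(prof)$delay)
    expect_equal(ci$score[p], coincidence_index(prof))
  }
})

test_that("CI is refused for single-delay profile sets (D1TE)", {
  set.seed(303)
  raster <- spike_raster(rbind(rbin(1000, 0.1), rbin(1000, 0.1)))
  ps <- te_profiles(raster, 1, 1, delays = 1)
  expect_error(score_matrix(ps, "ci"), "at least two delays")
})

test_that("NCC profiles are scored on absolute values", {
  set.seed(304)
  j <- rbin(3000, 0.4)
  i <- 1 - j
  raster <- spike_raster(rbind(i, j))
  ps <- cc_profiles(raster, "ncc", delays = 0:10)
  pk <- score_matrix(ps, "pk", absolute = TRUE)
  expect_true(all(pk$score >= 0))
  row <- which(pk$pre == 2 & pk$post == 1)
  expect_equal(pk$peak_delay[row], 0L)  # anti-correlation peaks at lag 0
})

test_that("missing profiles yield missing scores ranked out of the way", {
  raster <- spike_raster(rbind(rbin(500, 0.2), rep(0, 500), rbin(500, 0.2)))
  ps <- cc_profiles(raster, "ncc", delays = 1:10)
  pk <- score_matrix(ps, "pk", absolute = TRUE)
  silent <- pk$pre == 2 | pk$post == 2
  expect_true(all(is.na(pk$score[silent])))
  expect_true(all(!is.na(pk$score[!silent])))
})
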