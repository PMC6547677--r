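test_that("the ratio flagger follows the short-against-successor rule", {
  const <- flag_improbable_ibis(beat_series(rep(800, 50)))
  expect_equal(sum(const$flags), 0)

  b <- flag_improbable_ibis(beat_series(c(800, 400, 810, 800)))
  expect_equal(which(b$flags), 2L)  # 400 <= 0.6 * 810; 800 > 0.6 * 400

  # last interval has no successor and is never flagged
  tail_short <- flag_improbable_ibis(beat_series(c(800, 800, 100)))
  expect_false(tail_short$flags[3])

  expect_error(flag_improbable_ibis(beat_series(numeric(0))), "empty")
})

test_that("flagging is invariant to rescaling the series", {
  set.seed(10)
  ib <- 800 + cumsum(rnorm(200, 0, 60))
  ib <- pmax(ib, 200)
  f1 <- flag_improbable_ibis(beat_series(ib))$flags
  f2 <- flag_improbable_ibis(beat_series(ib * 3.7))$flags
  expect_identical(f1, f2)
})

test_that("merge correction restores split beats and conserves duration", {
  # spec example: flagged short pair merges back to the local beat length
  b <- beat_series(c(800, 390, 410, 800))
  b$flags <- c(FALSE, TRUE, FALSE, FALSE)
  out <- correct_flagged(b, "merge_adjacent")
  expect_equal(out$ibis_ms, c(800, 800, 800))
  expect_equal(sum(out$ibis_ms), sum(b$ibis_ms))
  expect_identical(out$provenance, "corrected")

  # no flags: output identical
  clean <- flag_improbable_ibis(beat_series(rep(800, 30)))
  expect_identical(correct_flagged(clean, "merge_adjacent")$ibis_ms,
                   clean$ibis_ms)

  expect_error(correct_flagged(clean, "zap"), "strategy")
})

test_that("flag + merge restores nearly all true intervals", {
  beats <- beat_series(rep(800, 300) + sin(seq_len(300) / 5) * 30)
  inj <- inject_artifacts(beats, 0.05, seed = 7)
  fl <- flag_improbable_ibis(inj)
  fixed <- correct_flagged(fl, "merge_adjacent")
  # duration is conserved to machine precision
  expect_equal(sum(fixed$ibis_ms), sum(beats$ibis_ms), tolerance = 1e-12)
  expect_gte(restored_fraction(beats, fixed), 0.95)
  # and on this fixture every injected split is actually merged back
  n_splits <- nrow(attr(inj, "splits"))
  restored <- length(inj$ibis_ms) - length(fixed$ibis_ms)
  expect_equal(restored, n_splits)
})

test_that("interpolate and drop strategies behave as documented", {
  b <- beat_series(c(800, 300, 820, 810))
  fl <- flag_improbable_ibis(b)
  expect_equal(which(fl$flags), 2L)
  ip <- correct_flagged(fl, "interpolate")
  expect_equal(ip$ibis_ms[2], mean(c(800, 820)))
  dr <- correct_flagged(fl, "drop")
  expect_equal(dr$ibis_ms, c(800, 820, 810))
})

test_that("segmentation yields padded windows whose cores tile the task", {
  beats <- beat_series(rep(1000, 700), t0_s = -50)
  segs <- segment_epochs(beats, c(0, 300), epoch_s = 30, pad_s = 12)
  expect_length(segs, 10)
  for (k in seq_len(10)) {
    s <- segs[[k]]
    expect_equal(diff(s$window), 54)
    expect_equal(s$effective_window, c((k - 1) * 30, k * 30))
    expect_equal(s$epoch_index, k - 1)
    # constant 1000 ms intervals: 54 +/- 1 beats per padded window
    expect_lte(abs(length(s$ibis_ms) - 54), 1)
  }
  # every in-task beat lands in exactly one effective window
  tt <- beat_times(beats)
  in_task <- sum(tt >= 0 & tt < 300)
  counted <- sum(vapply(segs, function(s)
    sum(s$times_s >= s$effective_window[1] &
          s$times_s < s$effective_window[2]), numeric(1)))
  expect_equal(counted, in_task)
})

test_that("zero padding gives disjoint tiling windows", {
  beats <- beat_series(rep(1000, 400), t0_s = 0)
  segs <- segment_epochs(beats, c(0, 300), epoch_s = 30, pad_s = 0)
  wins <- t(vapply(segs, function(s) s$window, numeric(2)))
  expect_equal(wins[, 1], seq(0, 270, by = 30))
  expect_equal(wins[, 2], seq(30, 300, by = 30))
})

test_that("missing margins error by name or degrade by reflection", {
  beats <- beat_series(rep(1000, 310), t0_s = 0)  # no baseline margin
  expect_error(segment_epochs(beats, c(0, 300)), "epoch 0")
  segs <- segment_epochs(beats, c(0, 300), allow_degraded = TRUE)
  expect_true(segs[[1]]$degraded)
  expect_false(segs[[5]]$degraded)
})

test_that("the IBI text format round-trips", {
  b <- beat_series(c(812.25, 797.5, 803), t0_s = -12.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibi(b, path)
  back <- read_ibi(path)
  expect_equal(back$ibis_ms, b$ibis_ms)
  expect_equal(back$t0_s, b$t0_s)
})

test_that("qc report tabulates flags per participant", {
  s <- list(a = beat_series(c(800, 390, 410, 800, 805)),
            b = beat_series(rep(750, 5)))
  qc <- qc_beat_series(s)
  expect_equal(qc$report$participant_id, c("a", "b"))
  expect_equal(qc$report$n_flags, c(1, 0))
})
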