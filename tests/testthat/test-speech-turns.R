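test_that("turn merging follows the strict 150-ms rule", {
  rec <- annotations(c("mother", "mother"), c("vocalization", "vocalization"),
                     c(0, 1100), c(1000, 2000))
  tl <- merge_turns(rec, duration_ms = 3000)
  expect_equal(nrow(tl$turns), 1) # 100-ms gap < 150: one turn
  expect_equal(tl$turns$offset_ms, 2000)

  rec2 <- annotations(c("mother", "mother"),
                      c("vocalization", "vocalization"),
                      c(0, 1150), c(1000, 2000))
  expect_equal(nrow(merge_turns(rec2, 3000)$turns), 2) # gap exactly 150

  # categories never merge across each other
  rec3 <- annotations(c("mother", "mother"), c("vocalization", "other_noise"),
                      c(0, 1050), c(1000, 2000))
  expect_equal(nrow(merge_turns(rec3, 3000)$turns), 2)
})

test_that("merging equals the transitive-closure oracle on random soups", {
  set.seed(19)
  for (rep in 1:20) {
    rec <- random_annotations(sample(5:40, 1), duration_ms = 30000)
    tl <- merge_turns(rec, duration_ms = 30000)
    want <- oracle_merge(rec, 150)
    got <- cbind(tl$turns$onset_ms, tl$turns$offset_ms,
                 match(tl$turns$speaker, c("mother", "infant")))
    got <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("speaker pauses are the exact complement of vocal time", {
  rec <- annotations(c("mother", "infant"), c("vocalization", "vocalization"),
                     c(0, 12000), c(10000, 15000))
  tl <- merge_turns(rec, duration_ms = 20000)
  sp <- speaker_pauses(tl, "mother")
  expect_equal(sp$ratio, 0.5)
  # silent speaker: one full-duration pause
  only_m <- merge_turns(annotations("mother", "vocalization", 0, 5000),
                        duration_ms = 20000)
  inf <- speaker_pauses(only_m, "infant")
  expect_equal(inf$ratio, 1)
  expect_equal(nrow(inf$intervals), 1)
  # complement identity on random timelines
  set.seed(3)
  for (rep in 1:10) {
    tl <- merge_turns(random_annotations(30, 40000), duration_ms = 40000)
    for (spk in c("mother", "infant")) {
      occ <- sum(dyadimaging:::speaker_union(tl, spk)[, "offset"] -
                 dyadimaging:::speaker_union(tl, spk)[, "onset"]) / 40000
      expect_equal(speaker_pauses(tl, spk)$ratio + occ, 1, tolerance = 1e-12)
    }
  }
})

test_that("dyadic silences need strictly more than 150 ms", {
  rec <- annotations(c("mother", "infant"), c("vocalization", "vocalization"),
                     c(0, 10000), c(10000, 20000))
  expect_equal(silences(merge_turns(rec, 20000))$silenceRatio, 0)

  rec2 <- annotations(c("mother", "infant"),
                      c("vocalization", "vocalization"),
                      c(0, 10000), c(10000, 15000))
  s <- silences(merge_turns(rec2, 20000))
  expect_equal(s$silenceRatio, 0.25) # [15, 20) s silent
  expect_equal(nrow(s$intervals), 1)

  # a 100-ms joint gap is not a silence
  rec3 <- annotations(c("mother", "mother"),
                      c("vocalization", "other_noise"),
                      c(0, 10100), c(10000, 20000))
  expect_equal(silences(merge_turns(rec3, 20000))$silenceRatio, 0)
})

test_that("overlap ratio equals interval arithmetic and the ms-grid oracle", {
  rec <- annotations(c("mother", "infant"), c("vocalization", "vocalization"),
                     c(0, 5000), c(10000, 15000))
  expect_equal(overlap_ratio(merge_turns(rec, 20000)), 0.25)

  disj <- annotations(c("mother", "infant"),
                      c("vocalization", "vocalization"),
                      c(0, 6000), c(5000, 9000))
  expect_equal(overlap_ratio(merge_turns(disj, 20000)), 0)

  set.seed(27)
  for (rep in 1:10) {
    tl <- merge_turns(random_annotations(25, 20000), duration_ms = 20000)
    expect_equal(overlap_ratio(tl), oracle_overlap_ratio(tl),
                 tolerance = 1e-12)
  }
})

test_that("synchrony ratio counts responses in (offset, offset + 3 s]", {
  rec <- annotations(
    c("mother", "mother", "mother", "infant", "infant"),
    rep("vocalization", 5),
    c(0, 4000, 8000, 2000, 20000),
    c(1000, 5000, 9000, 2500, 20500))
  tl <- merge_turns(rec, duration_ms = 30000)
  expect_equal(synchrony_ratio(tl), 1 / 3)
  expect_equal(synchrony_ratio(tl, window_ms = 0), 0)

  # every mother turn answered
  rec2 <- annotations(c("mother", "infant", "mother", "infant"),
                      rep("vocalization", 4),
                      c(0, 1500, 6000, 7500), c(1000, 2000, 7000, 8000))
  expect_equal(synchrony_ratio(merge_turns(rec2, 20000)), 1)

  # an onset inside the mother turn (overlap) is not a response
  rec3 <- annotations(c("mother", "infant"), rep("vocalization", 2),
                      c(0, 500), c(1000, 900))
  expect_equal(synchrony_ratio(merge_turns(rec3, 20000)), 0)
})

test_that("one infant onset answers at most one mother vocalization", {
  # two mother turns 1 s apart, one infant onset in both windows
  rec <- annotations(c("mother", "mother", "infant"),
                     rep("vocalization", 3),
                     c(0, 2000, 3500), c(1000, 3000, 4000))
  expect_equal(synchrony_ratio(merge_turns(rec, 10000)), 0.5)
})

test_that("the 16 STT features are complete and conserve occupancy", {
  empty <- merge_turns(annotations(), duration_ms = 20000)
  f <- stt_features(empty)
  expect_length(f, 16)
  expect_equal(unname(f["motherVocCount"]), 0)
  expect_equal(unname(f["silenceRatio"]), 1)
  expect_true(is.na(f["infantSynchronyRatio"]))
  expect_error(stt_features(merge_turns(annotations(), duration_ms = 0)),
               "zero-duration")

  # constructed occupancy: mother 30%, infant 20%, overlap 5% of 20 s
  rec <- annotations(c("mother", "infant"), rep("vocalization", 2),
                     c(0, 5000), c(6000, 9000))
  f2 <- stt_features(merge_turns(rec, duration_ms = 20000))
  expect_equal(unname(f2["motherVocRatio"]), 0.3)
  expect_equal(unname(f2["infantVocRatio"]), 0.2)
  expect_equal(unname(f2["overlapRatio"]), 0.05)

  set.seed(41)
  for (rep in 1:10) {
    tl <- merge_turns(random_annotations(30, 60000), duration_ms = 60000)
    f3 <- stt_features(tl)
    expect_equal(unname(f3["motherVocRatio"] + f3["motherNoiseRatio"] +
                        f3["motherPauseRatio"]), 1, tolerance = 1e-12)
    expect_equal(unname(f3["infantVocRatio"] + f3["infantAtypicalRatio"] +
                        f3["infantPauseRatio"]), 1, tolerance = 1e-12)
    # overall ratio between the two motherese-subset ratios
    subs <- c(synchrony_ratio(tl, subset = "motherese"),
              synchrony_ratio(tl, subset = "non_motherese"))
    if (!anyNA(subs)) {
      all_r <- synchrony_ratio(tl)
      expect_gte(all_r, min(subs) - 1e-12)
      expect_lte(all_r, max(subs) + 1e-12)
    }
  }
})

test_that("synchrony ratio is an unbiased estimator of p_sync", {
  set.seed(2)
  est <- vapply(1:50, function(s) {
    tl <- make_timeline(timeline_params(p_sync = 0.35, infant_voc_rate = 0,
                                        mother_voc_rate = 12,
                                        other_noise_fraction = 0),
                        duration_ms = 180000, seed = 5000 + s)
    synchrony_ratio(merge_turns(tl, duration_ms = 180000))
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.35), 3 * se)
})
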