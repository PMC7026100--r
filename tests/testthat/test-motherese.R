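test_that("cepstral frames follow the 25/10-ms windowing arithmetic", {
  sr <- 8000
  wave <- sin(2 * pi * 200 * seq(0, 1, length.out = sr))
  seg <- extract_segmental(wave, sr)
  expect_equal(dim(seg), c(98, 13)) # floor((8000-200)/80)+1
  expect_identical(extract_segmental(wave, sr), seg)
  expect_error(extract_segmental(wave[1:100], sr), "100 ms")

  # gain change moves only the energy-like coefficient 0
  seg2 <- extract_segmental(2 * wave, sr)
  expect_gt(mean(abs(seg2[, 1] - seg[, 1])), 0.1)
  expect_lt(max(abs(seg2[, -1] - seg[, -1])), 1e-8)
})

test_that("prosodic features recover pitch, glides and silence", {
  sr <- 8000
  t <- seq(0, 1, length.out = sr)
  tone <- extract_suprasegmental(sin(2 * pi * 220 * t), sr)
  expect_lt(abs(tone["f0_mean"] - 220), 2)
  expect_lt(tone["f0_sd"], 2)

  t2 <- seq(0, 2, length.out = 2 * sr)
  f0 <- 200 + 100 * t2 # linear glide 200 -> 400 Hz
  glide <- sin(2 * pi * cumsum(f0) / sr)
  g <- extract_suprasegmental(glide, sr)
  expect_lt(abs(g["f0_range"] - 200) / 200, 0.05)
  expect_gt(g["f0_slope"], 50)

  sil <- extract_suprasegmental(rep(0, sr), sr)
  expect_equal(unname(sil["voiced_fraction"]), 0)
  expect_true(is.na(sil["f0_mean"]))
})

test_that("EM fits are exact for M=1 and recover separated clusters", {
  set.seed(10)
  x <- matrix(rnorm(200), 100, 2)
  g1 <- fit_gmm(x, 1, seed = 1)
  expect_equal(as.vector(g1$means), colMeans(x), tolerance = 1e-9)
  expect_equal(sum(g1$weights), 1)

  x2 <- rbind(cbind(rnorm(150, -4, 0.4), rnorm(150)),
              cbind(rnorm(150, 4, 0.4), rnorm(150)))
  g2 <- fit_gmm(x2, 2, seed = 2)
  expect_lt(max(abs(sort(g2$means[, 1]) - c(-4, 4))), 0.1)
  expect_error(fit_gmm(x[1:3, ], 5), "at least")
})

test_that("EM log-likelihood is monotone on arbitrary inputs", {
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 3, sd = runif(1, 0.5, 3)), 60, 3)
    g <- fit_gmm(x, sample(2:4, 1), seed = rep)
    expect_true(all(diff(g$loglik) >= -1e-6 * abs(g$loglik[-1])))
    expect_equal(sum(g$weights), 1, tolerance = 1e-9)
  }
})

test_that("fitted mixtures agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(12)
  x <- rbind(cbind(rnorm(120, -3, 0.5), rnorm(120, 2, 0.5)),
             cbind(rnorm(120, 3, 0.5), rnorm(120, -2, 0.5)))
  mine <- fit_gmm(x, 2, seed = 3)
  ref <- mclust::Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(sort(mine$means[, 1]), sort(ref$parameters$mean[1, ]),
               tolerance = 0.05)
  # and the achieved log-likelihoods match
  expect_equal(tail(mine$loglik, 1), ref$loglik, tolerance = 1e-3)
})

test_that("score fusion is affine in lambda and falls back without prosody", {
  corpus <- make_motherese_corpus(n_per_class = 16, duration_s = 0.5,
                                  seed = 40)
  cfg <- run_config(gmm_components_segmental = 4,
                    gmm_components_suprasegmental = 4)
  m <- suppressMessages(train_motherese_model(corpus, cfg))
  s <- make_voice_segment("motherese", seed = 77)
  seg <- extract_segmental(s$wave, s$sample_rate)
  sup <- extract_suprasegmental(s$wave, s$sample_rate)
  f0 <- fused_score(m, seg, sup, lambda = 0)
  f1 <- fused_score(m, seg, sup, lambda = 1)
  for (lam in c(0.25, 0.4, 0.8)) {
    expect_equal(fused_score(m, seg, sup, lambda = lam),
                 lam * f1 + (1 - lam) * f0, tolerance = 1e-9)
  }
  sup_na <- sup; sup_na["f0_mean"] <- NA
  expect_equal(suppressMessages(fused_score(m, seg, sup_na)), f1)
})

test_that("the detector separates glide from flat prosody on held-out data", {
  corpus <- make_motherese_corpus(n_per_class = 30, duration_s = 0.5,
                                  seed = 50)
  train <- corpus[c(1:20, 31:50)]
  test <- corpus[c(21:30, 51:60)]
  cfg <- run_config(gmm_components_segmental = 6,
                    gmm_components_suprasegmental = 5)
  m <- suppressMessages(train_motherese_model(train, cfg))
  pred <- vapply(test, function(s) {
    classify_motherese(m, s$wave, s$sample_rate)$label
  }, "")
  truth <- vapply(test, function(s) s$label, "")
  expect_gte(mean(pred == truth), 0.9)

  # model JSON round-trip preserves every score
  f <- withr::local_tempfile(fileext = ".json")
  save_motherese_model(m, f)
  m2 <- load_motherese_model(f)
  s <- test[[1]]
  expect_equal(classify_motherese(m2, s$wave, s$sample_rate)$score,
               classify_motherese(m, s$wave, s$sample_rate)$score,
               tolerance = 1e-9)
})

test_that("classifier-truth agreement is high on a 100-vs-100 corpus", {
  # mirrors a rater-validation design: 100 motherese vs 100 other-speech
  # segments, ICC between the classifier's labels and the ground truth
  corpus <- make_motherese_corpus(n_per_class = 100, duration_s = 0.5,
                                  seed = 90)
  train <- corpus[c(1:50, 101:150)]
  heldout <- corpus[c(51:100, 151:200)]
  m <- suppressMessages(train_motherese_model(train, run_config()))
  pred <- vapply(heldout, function(s) {
    as.integer(classify_motherese(m, s$wave, s$sample_rate)$label ==
               "motherese")
  }, 0L)
  truth <- vapply(heldout, function(s) {
    as.integer(s$label == "motherese")
  }, 0L)
  agreement <- icc(pred, truth)
  expect_gte(unname(agreement["icc"]), 0.75)
})

test_that("timeline labeling touches only mother vocalizations with audio", {
  corpus <- make_motherese_corpus(n_per_class = 16, duration_s = 0.5,
                                  seed = 60)
  cfg <- run_config(gmm_components_segmental = 4,
                    gmm_components_suprasegmental = 4)
  m <- suppressMessages(train_motherese_model(corpus, cfg))
  rec <- annotations(c("mother", "mother", "infant"),
                     c("vocalization", "other_noise", "vocalization"),
                     c(0, 2000, 4000), c(1000, 3000, 5000))
  tl <- merge_turns(rec, duration_ms = 6000)
  mo <- make_voice_segment("motherese", 0.5, seed = 61)
  waves <- list(list(wave = mo$wave, sample_rate = mo$sample_rate),
                NULL, NULL)
  out <- label_timeline(m, tl, waves)
  expect_true(out$turns$motherese[1] %in% c("motherese", "other_speech"))
  expect_equal(out$turns$motherese[2:3], c("unlabeled", "unlabeled"))
  out2 <- label_timeline(m, tl, waves)
  expect_identical(out$turns, out2$turns)
  # missing waveform on a mother vocalization leaves it unlabeled
  out3 <- label_timeline(m, tl, list(NULL, NULL, NULL))
  expect_equal(out3$turns$motherese[1], "unlabeled")
})

test_that("ICC(2,1) matches the variance-component oracle values", {
  expect_equal(unname(icc(c(1, 2, 3, 4), c(1, 2, 3, 4))["icc"]), 1)
  # frozen from an independent implementation of two-way random
  # absolute-agreement single-rater ICC on the same table
  v <- icc(c(1, 2, 3, 4, 6, 8), c(2, 1, 4, 4, 5, 9))
  expect_equal(unname(v["icc"]), 0.9422632794457273, tolerance = 1e-9)
  expect_equal(unname(v["ci_low"]), 0.66, tolerance = 0.01)
  expect_equal(unname(v["ci_high"]), 0.99, tolerance = 0.01)

  # absolute agreement penalizes a constant shift
  a <- c(1, 2, 3, 4, 6, 8)
  shifted <- icc(a, a + 1)
  expect_lt(unname(shifted["icc"]), 1)
  expect_equal(unname(shifted["icc"]), 0.9315068493150684, tolerance = 1e-9)

  # independent ratings: ICC concentrates near zero
  set.seed(70)
  nul <- icc(rnorm(200), rnorm(200))
  expect_lt(abs(unname(nul["icc"])), 0.15)

  expect_warning(icc(rep(1, 5), rep(1, 5)), "between-target")
})
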