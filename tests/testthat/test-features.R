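tone <- function(freq, dur = 1, sr = 20000, amp = 0.5)
  amp * sin(2 * pi * freq * seq(0, dur, by = 1 / sr))

test_that("log_mel_spectrogram: band layout and tone localization", {
  sg <- log_mel_spectrogram(tone(1000), sr = 20000)
  expect_s3_class(sg, "feature_space")
  expect_identical(ncol(sg$data), 31L)
  expect_equal(sg$rate, 100)

  # oracle: mel-spaced centers with printed end points; argmax channel for
  # a 1 kHz tone must be the band whose center is nearest 1 kHz
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  centers <- imel(seq(mel(124.1), mel(7284.1), length.out = 31))
  expected_band <- which.min(abs(centers - 1000))
  mean_energy <- colMeans(sg$data)
  expect_identical(unname(which.max(mean_energy)), expected_band)

  # silence hits the log floor everywhere
  sil <- log_mel_spectrogram(numeric(20000), sr = 20000)
  expect_equal(max(sil$data) - min(sil$data), 0)

  expect_error(log_mel_spectrogram(tone(100, sr = 8000), sr = 8000), "2\\*fmax")
})

test_that("envelope and half-wave derivative", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)   # rows [1,2],[3,4]
  fs <- feature_space(m, 40, "Sg")
  expect_equal(envelope(fs)$data[, 1], c(3, 7))

  cfs <- feature_space(matrix(2.5, 10, 31), 40, "Sg")
  expect_equal(envelope(cfs)$data[, 1], rep(31 * 2.5, 10))

  expect_true(all(halfwave_derivative(cfs)$data == 0))
  dec <- feature_space(matrix(10:1, 10, 1), 40, "Sg")
  expect_true(all(halfwave_derivative(dec)$data == 0))
  ramp <- feature_space(matrix(seq(0, 27, by = 3), 10, 1), 40, "Sg")
  d <- halfwave_derivative(ramp)$data[, 1]
  expect_equal(d[1], 0)
  expect_true(all(d[-1] == 3))
  expect_identical(nrow(halfwave_derivative(ramp)$data), 10L)
  expect_error(halfwave_derivative(feature_space(matrix(1, 1, 2), 40)),
               "2 time samples")

  rnd <- feature_space(matrix(rnorm(200), 20), 40, "Sg")
  expect_true(all(halfwave_derivative(rnd)$data >= 0))
  expect_equal(envelope(rnd)$data[, 1], rowSums(rnd$data))
})

test_that("gabor_filterbank: cardinality and ripple selectivity", {
  expect_identical(gabor_bank_size(31L), 455L)

  # zero spectrogram -> zero output
  gz <- gabor_filterbank(feature_space(matrix(0, 120, 31), 100, "Sg"))
  expect_identical(ncol(gz$data), 455L)
  expect_lt(max(abs(gz$data)), 1e-12)

  # pure spectral ripple at the Omega ~ 0.06 cyc/channel center frequency:
  # among purely spectral filters (omega = 0), that Omega group responds
  # most strongly
  ripple_omega <- 0.3761  # radians/channel, third spectral center
  rip <- outer(rep(1, 300), cos(ripple_omega * (1:31)))
  g <- gabor_filterbank(feature_space(rip, 100, "Sg"))
  nm <- colnames(g$data)
  temporal_dc <- grepl("_n0\\.000_", nm)
  k_of <- abs(as.numeric(sub("gb_k([+-][0-9.]+)_.*", "\\1", nm)))
  pw <- colMeans(g$data^2)
  groups <- sort(unique(round(k_of[temporal_dc], 3)))
  grp_pw <- vapply(groups, function(k)
    max(pw[temporal_dc & round(k_of, 3) == k]), numeric(1))
  expect_equal(groups[which.max(grp_pw)], round(ripple_omega, 3))

  expect_error(gabor_filterbank(g, spectral_mods = c(-1, 4)), "unknown")
})

test_that("hilbert_spectrogram16: band structure and compression", {
  x <- tone(250, dur = 0.8)
  fs <- hilbert_spectrogram16(x, sr = 20000)
  expect_identical(ncol(fs$data), 16L)
  expect_identical(unname(which.max(colMeans(fs$data))), 1L)

  # a 2888 Hz tone lands in channel 10
  f10 <- hilbert_spectrogram16(tone(2888, dur = 0.8), sr = 20000)
  expect_identical(unname(which.max(colMeans(f10$data))), 10L)

  sil <- hilbert_spectrogram16(numeric(16000), sr = 20000, compress = TRUE)
  expect_identical(sil$name, "Sg16c")
  expect_true(all(sil$data == 0))

  expect_error(hilbert_spectrogram16(x, sr = 16000), "band edge")
})

test_that("event_features: impulse placement and articulatory channels", {
  ev <- event_table(c(0.5, 1.0, 1.5), c("AH", "P", "S"),
                    c("vowel", "plosive", "fricative"))
  art <- event_features(ev, "Art", 40, 100)
  expect_identical(ncol(art$data), 23L)
  # AH carries voiced + sonorant + central = 3 features
  expect_equal(sum(art$data[21, ]), 3)   # 0.5 s -> 0-based sample 20
  phon <- event_features(ev, "PhOn", 40, 100)
  expect_identical(ncol(phon$data), 1L)
  expect_equal(sum(phon$data), 3)
  expect_equal(which(phon$data[, 1] == 1), c(21L, 41L, 61L))

  empty <- event_table(numeric(0), character(0))
  expect_true(all(event_features(empty, "Art", 40, 50)$data == 0))

  late <- event_table(5, "AH", "vowel")
  expect_error(event_features(late, "PhOn", 40, 100), "rows")
})

test_that("preprocess: resampling and z-scoring", {
  fs <- feature_space(matrix(rnorm(24000), 24000, 1), 400, "x")
  out <- preprocess(fs, 40)
  expect_identical(nrow(out$data), 2400L)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_lt(max(abs(apply(out$data, 2, sd) - 1)), 1e-10)

  at40 <- feature_space(matrix(rexp(400), 400, 1), 40, "x")
  out40 <- preprocess(at40, 40)
  expect_identical(rank(out40$data[, 1]), rank(at40$data[, 1]))

  cst <- feature_space(cbind(rnorm(100), 1), 40, "x")
  expect_warning(pc <- preprocess(cst, 40), "constant")
  expect_true(all(pc$data[, 2] == 0))
})

test_that("concat_subspaces: the joint feature-space dimensionalities", {
  mk <- function(nch, nm) feature_space(matrix(rnorm(100 * nch), 100), 40, nm)
  sg <- mk(31, "Sg"); dv <- mk(31, "Deriv"); art <- mk(23, "Art")
  sd2 <- concat_subspaces(list(sg, dv))
  expect_identical(ncol(sd2$data), 62L)
  expect_identical(names(sd2$subspaces), c("Sg", "Deriv"))
  ctrl <- concat_subspaces(list(sg, dv, art), name = "Control")
  expect_identical(ncol(ctrl$data), 85L)
  expect_identical(ctrl$name, "Control")
  expect_identical(concat_subspaces(list(sg)), sg)
  expect_error(concat_subspaces(list(sg, mk(5, "x")[["data"]] |>
    (\(m) feature_space(m[1:50, ], 40, "short"))())), "length mismatch")
  expect_error(concat_subspaces(list(sg, feature_space(matrix(1:200, 100), 20))),
               "rate mismatch")
})
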