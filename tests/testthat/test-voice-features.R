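test_that("pitch is recovered on pure tones and noise stays unvoiced", {
  rate <- 16000
  t <- (0:15999) / rate
  tr <- estimate_pitch(sin(2 * pi * 200 * t), rate)
  expect_true(all(tr$voiced))
  expect_true(all(abs(tr$f0 - 200) < 1))

  set.seed(8)
  trn <- estimate_pitch(rnorm(rate), rate)
  expect_gte(mean(!trn$voiced), 0.95)
})

test_that("pure-tone F0 relative error is below 1% across 80-450 Hz", {
  rate <- 16000
  t <- (0:15999) / rate
  for (f in seq(80, 450, by = 37)) {
    tr <- estimate_pitch(sin(2 * pi * f * t), rate)
    expect_lt(abs(median(tr$f0, na.rm = TRUE) - f) / f, 0.01)
  }
})

test_that("a harmonic-rich 120 Hz tone is not halved or doubled", {
  rate <- 16000
  t <- (0:15999) / rate
  h <- rowSums(sapply(1:5, function(k) sin(2 * pi * 120 * k * t) / k))
  tr <- estimate_pitch(h, rate)
  expect_lt(abs(median(tr$f0, na.rm = TRUE) - 120), 2)
})

test_that("period extraction finds 5 ms cycles in a 200 Hz voice", {
  w <- synthesize_voice(200, 0, 0, 40, 1, 16000, seed = 4)
  tr <- estimate_pitch(w, 16000)
  ps <- extract_periods(w, 16000, tr)
  allT <- unlist(lapply(ps$stretches, `[[`, "periods"))
  expect_gt(length(allT), 150)
  expect_true(all(abs(allT - 0.005) < 2e-4))

  # unvoiced input: empty sequence
  set.seed(10)
  nz <- rnorm(16000)
  ps2 <- extract_periods(nz, 16000, estimate_pitch(nz, 16000))
  expect_equal(length(ps2$stretches), 0)
})

test_that("alternating amplitude modulation appears in extracted amplitudes", {
  rate <- 16000
  f0 <- 160
  w <- synthesize_voice(f0, 0, 0, 60, 1, rate, seed = 2)
  # impose exact alternating +-10% amplitude on alternating cycles
  tt <- (0:(length(w) - 1)) / rate
  cyc <- floor(tt * f0 + 0.5)  # pulse index (pulses peak at cycle bounds)
  am <- ifelse(cyc %% 2 == 0, 1.1, 1.0)
  wam <- w * am
  ps <- extract_periods(wam, rate, estimate_pitch(wam, rate))
  A <- unlist(lapply(ps$stretches, `[[`, "amplitudes"))
  ratio <- exp(abs(mean(diff(log(A)) * rep_len(c(1, -1), length(A) - 1))))
  expect_equal(ratio, 1.1, tolerance = 0.01)
})

test_that("jitter formulas match hand evaluation", {
  expect_equal(unname(jitter_measures(rep(0.005, 20))),
               rep(0, 5))
  # alternating 5.0 / 5.1 ms
  T <- rep(c(5.0, 5.1), 10) / 1000
  j <- jitter_measures(T)
  expect_equal(unname(j["jitter_local"]), 0.1 / 5.05 / 10 * 10,
               tolerance = 1e-10)
  expect_equal(unname(j["jitter_local_abs"]), 0.1e-3, tolerance = 1e-12)
  # rap by hand: interior deviation |T_i - mean3| = 0.1/1.5 ms
  expect_equal(unname(j["jitter_rap"]), (0.1 / 1.5) / 5.05, tolerance = 1e-10)
  expect_equal(unname(j["jitter_ddp"]), 3 * unname(j["jitter_rap"]))
  # ddp = 3 * rap on arbitrary sequences
  set.seed(3)
  Tr <- 0.005 * (1 + rnorm(30, 0, 0.02))
  jr <- jitter_measures(Tr)
  expect_equal(unname(jr["jitter_ddp"]), 3 * unname(jr["jitter_rap"]))
  expect_true(all(is.na(jitter_measures(c(0.005, 0.005)))))
})

test_that("shimmer formulas match hand evaluation", {
  expect_equal(unname(shimmer_measures(rep(0.8, 20))), rep(0, 6))
  A <- rep(c(1, 1.1), 10)
  s <- shimmer_measures(A)
  expect_equal(unname(s["shimmer_local"]), 0.1 / 1.05, tolerance = 1e-10)
  expect_equal(unname(s["shimmer_local_db"]), abs(20 * log10(1.1)),
               tolerance = 1e-10)
  expect_equal(unname(s["shimmer_dda"]), 3 * unname(s["shimmer_apq3"]))
  expect_error(shimmer_measures(c(1, -1, 1)), "positive")
  # apq11 needs 11 cycles
  expect_true(is.na(shimmer_measures(rep(c(1, 1.1), 4))["shimmer_apq11"]))
})

test_that("time scaling moves only absolute jitter; amplitude scaling moves nothing", {
  set.seed(5)
  T <- 0.004 * (1 + rnorm(40, 0, 0.02))
  j1 <- jitter_measures(T)
  j2 <- jitter_measures(T * 2)
  expect_equal(j1[c("jitter_local", "jitter_rap", "jitter_ppq5", "jitter_ddp")],
               j2[c("jitter_local", "jitter_rap", "jitter_ppq5", "jitter_ddp")])
  expect_equal(unname(j2["jitter_local_abs"]),
               2 * unname(j1["jitter_local_abs"]))
  A <- 1 + abs(rnorm(40, 0, 0.05))
  expect_equal(shimmer_measures(A), shimmer_measures(A * 3.7))
})

test_that("HNR follows the r/(1-r) relation and decreases with noise", {
  mk_track <- function(r) {
    structure(data.frame(time = 1:5 / 100, f0 = 200, voiced = TRUE,
                         harmonicity_r = r),
              class = c("pitch_track", "data.frame"), frame = 0.04)
  }
  expect_equal(unname(hnr_stats(mk_track(0.5))["hnr_mean"]), 0)
  expect_equal(unname(hnr_stats(mk_track(10 / 11))["hnr_mean"]), 10,
               tolerance = 1e-10)
  expect_equal(unname(hnr_stats(mk_track(1 - 1e-9))["hnr_mean"]), 40)

  hnrs <- sapply(c(25, 15, 5), function(h) {
    w <- synthesize_voice(180, 0, 0, h, 1, 16000, seed = 6)
    hnr_stats(estimate_pitch(w, 16000))["hnr_mean"]
  })
  expect_true(all(diff(hnrs) < 0))
})

test_that("the DCT matrix is orthonormal and inverts the truncation-free transform", {
  C <- dct_matrix(64)
  expect_equal(t(C) %*% C, diag(64), tolerance = 1e-10)
  set.seed(2)
  x <- rnorm(64)
  expect_equal(as.numeric(t(C) %*% (C %*% x)), x, tolerance = 1e-6)
})

test_that("MFCCs behave under degenerate input and amplitude scaling", {
  z <- mfcc_mean(rep(0, 4000), 16000)
  expect_length(z, 40)
  expect_true(all(is.finite(z)))

  w <- synthesize_voice(150, 0.01, 0.03, 20, 1, 16000, seed = 9)
  m1 <- mfcc_mean(w, 16000)
  m2 <- mfcc_mean(2 * w, 16000)
  expect_gt(abs(m2[1] - m1[1]), 1e-3)         # c0 absorbs the gain change
  expect_lt(max(abs(m2[-1] - m1[-1])), 1e-6)  # higher coefficients do not
  expect_error(mfcc_mean(w, 16000, n_coeff = 80, n_mel = 64), "n_mel")
})

test_that("voice_summary composes the 57-field vector with closed-form checks", {
  rate <- 16000
  a <- 0.25
  w <- a * sin(2 * pi * 220 * (0:(2 * rate - 1)) / rate)
  vs <- voice_summary(w, rate)
  expect_length(vs, 57)
  expect_equal(unname(vs["rms_energy"]), a / sqrt(2), tolerance = 1e-3)
  expect_equal(unname(vs["f0_mean"]), 220, tolerance = 220 * 0.005)
  expect_lt(unname(vs["jitter_local"]), 0.005)
  expect_lt(unname(vs["shimmer_local"]), 0.005)
})

test_that("injected voice parameters are recovered by the extractor", {
  vs <- voice_summary(synthesize_voice(200, 0, 0, 40, 2, 16000, seed = 1),
                      16000)
  expect_equal(unname(vs["f0_mean"]), 200, tolerance = 2 / 200)
  expect_lt(unname(vs["jitter_local"]), 0.005)
  expect_lt(unname(vs["shimmer_local"]), 0.005)
  expect_gt(unname(vs["hnr_mean"]), 30)

  vj <- voice_summary(synthesize_voice(150, 0.02, 0, 40, 2, 16000, seed = 2),
                      16000)
  expect_equal(unname(vj["jitter_local"]), 0.02, tolerance = 0.15)
  vsh <- voice_summary(synthesize_voice(150, 0, 0.05, 40, 2, 16000, seed = 3),
                       16000)
  expect_equal(unname(vsh["shimmer_local"]), 0.05, tolerance = 0.15)
})
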