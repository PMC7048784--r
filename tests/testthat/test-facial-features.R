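test_that("AU summaries are plain means of presence and intensity", {
  sched <- toy_schedule()
  ft <- make_ft(c(1, 4, 6, 8, 12, 15),
                AU12_c = c(1L, 0L, 1L, 1L, 0L, 1L),
                AU12_r = c(0.2, 0.4, 0.1, 0.3, 1.0, 0.6))
  s <- au_segment_summary(ft, sched, aus = "AU12")
  seg_a <- s[s$segment == "a", ]
  expect_equal(seg_a$occurrence, 0.75)
  expect_equal(seg_a$intensity, mean(c(0.2, 0.4, 0.1, 0.3)))
  seg_b <- s[s$segment == "b", ]
  expect_equal(seg_b$occurrence, 0.5)
  expect_equal(seg_b$intensity, 0.8)
  whole <- s[s$segment == "whole", ]
  expect_equal(whole$occurrence, 4 / 6)
  expect_error(au_segment_summary(ft, sched, aus = "AU99"), "unknown AU")
})

test_that("empty segments yield NA, never zero", {
  sched <- toy_schedule()
  ft <- make_ft(c(1, 2, 3), AU12_c = c(1L, 1L, 0L))  # nothing in segment b
  s <- au_segment_summary(ft, sched, aus = "AU12")
  expect_true(is.na(s$occurrence[s$segment == "b"]))
  expect_false(is.na(s$occurrence[s$segment == "a"]))
})

test_that("summary means are bounded by the channel range", {
  set.seed(11)
  sched <- toy_schedule()
  ft <- make_ft(seq(0, 19.5, by = 0.5),
                AU06_r = runif(40, 0, 3),
                AU06_c = sample(0:1, 40, replace = TRUE))
  s <- au_segment_summary(ft, sched, aus = "AU06")
  expect_true(all(s$intensity >= min(ft$AU06_r) & s$intensity <= max(ft$AU06_r)))
  expect_true(all(s$occurrence >= 0 & s$occurrence <= 1))
})

test_that("social smiling reports the whole-conversation AU12/AU6 values", {
  sched <- toy_schedule()
  n <- 20
  ft <- make_ft(seq(0.5, 19.5, by = 1),
                AU12_c = rep(c(1L, 0L), n / 2),
                AU06_c = rep(1L, n),
                AU06_r = rep(0.4, n))
  sm <- social_smiling(ft, sched)
  expect_equal(sm$AU12_occ, 0.5)
  expect_equal(sm$AU6_occ, 1)
  expect_equal(sm$AU6_int, 0.4)
  expect_equal(sm$AU12_int, 0)
  # consistency with the generic summary
  s <- au_segment_summary(ft, sched, aus = c("AU12", "AU06"))
  expect_equal(sm$AU12_occ,
               s$occurrence[s$segment == "whole" & s$au == "AU12"])

  zero <- make_ft(seq(0.5, 19.5, by = 1))
  smz <- social_smiling(zero, sched)
  expect_equal(unlist(smz), c(AU12_occ = 0, AU12_int = 0,
                              AU6_occ = 0, AU6_int = 0))
})

test_that("a perfect copy gives mimicry 1 at lag 0 and inversion gives -1", {
  set.seed(3)
  t <- seq(0, 59.9, by = 1 / 10)
  x <- abs(sin(t / 3)) + 0.1 * sin(t)
  actress <- make_ft(t, AU06_r = x, person_id = "actress")
  self <- make_ft(t, AU06_r = x, person_id = "p")
  m <- mimicry_correlation(self, actress, "AU06", lag_grid = c(0, 0.5, 1))
  expect_equal(m$score, 1, tolerance = 1e-10)
  expect_equal(m$lag_selected, 0)
  anti <- make_ft(t, AU06_r = max(x) - x, person_id = "p")
  m2 <- mimicry_correlation(anti, actress, "AU06", lag_grid = 0)
  expect_equal(m2$score, -1, tolerance = 1e-10)
})

test_that("a constructed delay is recovered by the lag search", {
  set.seed(5)
  fps <- 10
  t <- seq(0, 79.9, by = 1 / fps)
  base <- as.numeric(stats::filter(rnorm(length(t) + 20), rep(1, 15) / 15,
                                   sides = 1))[-(1:20)]
  base <- base - min(base)
  actress <- make_ft(t, AU12_r = base, person_id = "actress")
  lag_frames <- 10  # exactly 1.0 s
  delayed <- c(rep(0, lag_frames), base)[seq_along(base)]
  participant <- make_ft(t, AU12_r = delayed, person_id = "p")
  m <- mimicry_correlation(participant, actress, "AU12",
                           lag_grid = seq(0, 2, by = 0.25))
  expect_equal(m$lag_selected, 1.0)
  expect_gt(m$score, 0.99)
  # direct-computation oracle at the true lag: on identical uniform grids,
  # shifting the participant back one second aligns actress frame i with
  # participant frame i + lag_frames; 10-s windows then hold 100 frames
  n_align <- length(t) - lag_frames
  win <- floor(t[seq_len(n_align)] / 10)
  zs <- vapply(unique(win), function(w) {
    i <- which(win == w)
    if (length(i) < 10) return(NA_real_)
    atanh(min(cor(base[i], delayed[i + lag_frames]), 1 - 1e-12))
  }, numeric(1))
  oracle <- tanh(mean(zs[!is.na(zs)]))
  expect_equal(m$score, oracle, tolerance = 1e-6)
})

test_that("mimicry is invariant to positive affine rescaling", {
  set.seed(9)
  t <- seq(0, 59.9, by = 0.1)
  a <- cumsum(rnorm(length(t), 0, 0.05)); a <- a - min(a)
  p <- pmax(0.5 * a + rnorm(length(t), 0, 0.1), 0)
  actress <- make_ft(t, AU04_r = a, person_id = "actress")
  p1 <- make_ft(t, AU04_r = p, person_id = "p")
  p2 <- make_ft(t, AU04_r = 3.2 * p + 0.7, person_id = "p")
  m1 <- mimicry_correlation(p1, actress, "AU04", lag_grid = c(0, 0.5))
  m2 <- mimicry_correlation(p2, actress, "AU04", lag_grid = c(0, 0.5))
  expect_equal(m1$score, m2$score, tolerance = 1e-10)
})

test_that("independent white-noise signals have mean mimicry near zero", {
  set.seed(123)
  t <- seq(0, 39.9, by = 0.1)
  scores <- replicate(200, {
    a <- make_ft(t, AU09_r = rnorm(length(t)) + 5, person_id = "a")
    p <- make_ft(t, AU09_r = rnorm(length(t)) + 5, person_id = "p")
    mimicry_correlation(p, a, "AU09", lag_grid = 0)$score
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 0.01)
})

test_that("degenerate input reports no usable windows", {
  t <- seq(0, 19.9, by = 0.1)
  a <- make_ft(t, AU06_r = rep(1, length(t)), person_id = "a")
  p <- make_ft(t, AU06_r = rep(2, length(t)), person_id = "p")
  m <- mimicry_correlation(p, a, "AU06", lag_grid = 0)
  expect_true(is.na(m$score))
  expect_equal(m$n_windows_used, 0)
})
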