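test_that("the actress reference is deterministic and segment-structured", {
  sched <- default_schedule()
  a1 <- actress_reference(sched, seed = 5)
  a2 <- actress_reference(sched, seed = 5)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  a3 <- actress_reference(sched, seed = 6)
  expect_false(identical(a1$AU12_r, a3$AU12_r))

  # smile intensity higher while she talks about liked food than disliked
  pos <- slice_segment(a1, sched, "positive_listen")
  neg <- slice_segment(a1, sched, "negative_listen")
  expect_gt(mean(pos$AU12_r), mean(neg$AU12_r))
  # disgust AUs the other way around
  expect_gt(mean(neg$AU04_r), mean(pos$AU04_r))
  # frame-table invariants hold (constructor validates)
  expect_s3_class(a1, "frame_table")
})

test_that("synthesized waves are seed-deterministic", {
  w1 <- synthesize_voice(180, 0.01, 0.03, 15, 1, 8000, seed = 3)
  w2 <- synthesize_voice(180, 0.01, 0.03, 15, 1, 8000, seed = 3)
  expect_identical(w1, w2)
  expect_true(all(abs(w1) <= 1))
  expect_error(synthesize_voice(30, 0, 0, 10, 1, 8000), "f0")
  expect_error(synthesize_voice(200, 0, 0, 10, 0.1, 8000), "duration")
})

test_that("full mimicry coupling reproduces the actress track at lag zero", {
  sched <- default_schedule()
  spec <- cohort_spec(n_per_group = 2, seed = 1, fps = 15,
                      modalities = "face")
  spec$mimicry_lag <- 0
  spec$groups$NT$mimicry[] <- 0.95  # ceiling coupling
  act <- actress_reference(sched, seed = 1, fps = 15)
  p <- simulate_participant(spec, "NT", 1, act, seed = 2, person_id = "x")
  m <- mimicry_correlation(p$frames, act, "AU12", lag_grid = 0)
  expect_gt(m$score, 0.5)

  spec0 <- cohort_spec(n_per_group = 2, seed = 1, fps = 15,
                       modalities = "face")
  spec0$groups$NT$mimicry[] <- 0
  scores <- vapply(1:8, function(s) {
    p0 <- simulate_participant(spec0, "NT", 1, act, seed = 100 + s,
                               person_id = "x")
    mimicry_correlation(p0$frames, act, "AU12", lag_grid = 0)$score
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.1)
})

test_that("occurrence targets are hit in expectation", {
  sched <- default_schedule()
  spec <- cohort_spec(n_per_group = 2, seed = 1, fps = 15,
                      modalities = "face", aus = c("AU12", "AU06"))
  act <- actress_reference(sched, seed = 1, fps = 15)
  occ <- vapply(1:12, function(s) {
    p <- simulate_participant(spec, "NT", 0, act, seed = 400 + s,
                              person_id = "x")
    w <- slice_segment(p$frames, sched, "whole")
    mean(w$AU12_c)
  }, numeric(1))
  expect_lt(abs(mean(occ) - 0.40), 0.05)
})

test_that("simulated cohorts are reproducible and carry coherent metadata", {
  spec <- fast_cohort_spec(3, seed = 9, modalities = c("face", "gaze"))
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(as.data.frame(c1$frames[[2]]),
                   as.data.frame(c2$frames[[2]]))
  expect_equal(nrow(c1$metadata), 6)
  expect_equal(sort(unique(c1$metadata$label)), c("ASD", "NT"))
  expect_true(all(c1$metadata$severity[c1$metadata$label == "ASD"] >
                    mean(c1$metadata$severity[c1$metadata$label == "NT"])))
})

test_that("cohorts round-trip through a directory", {
  spec <- fast_cohort_spec(2, seed = 4)
  coh <- simulate_cohort(spec)
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "schedule.yaml")))
  back <- read_cohort(dir)
  expect_equal(back$metadata$subject_id, coh$metadata$subject_id)
  expect_equal(nrow(back$frames[[1]]), nrow(coh$frames[[1]]))
  expect_equal(back$waves[[1]]$rate, spec$audio_rate)
  expect_equal(back$waves[[1]]$wave, coh$waves[[1]]$wave, tolerance = 1e-4)
  expect_equal(back$schedule, coh$schedule)
})

test_that("the null preset equalizes the group profiles", {
  spec <- cohort_spec(n_per_group = 2, seed = 1, preset = "null")
  expect_identical(spec$groups$NT, spec$groups$ASD)
})

test_that("injected prosody targets survive the voice extractor", {
  spec <- fast_cohort_spec(2, seed = 21)
  act <- actress_reference(spec$schedule, seed = 21, fps = spec$fps)
  p <- simulate_participant(spec, "ASD", 1, act, seed = 33, person_id = "a1")
  vs <- voice_summary(p$wave, p$rate)
  expect_equal(unname(vs["f0_mean"]), p$voice_params$f0,
               tolerance = 4 / p$voice_params$f0)
  expect_equal(unname(vs["hnr_mean"]), p$voice_params$hnr, tolerance = 0.35)
})
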