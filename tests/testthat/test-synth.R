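test_that("generation is deterministic and substream-stable", {
  cfg <- synth_config(n_subjects = 3, seed = 5,
                      phase_durations = short_durations)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(generate_scores(cfg), generate_scores(cfg))

  # enlarging the cohort must not perturb existing subjects
  cfg5 <- synth_config(n_subjects = 5, seed = 5,
                       phase_durations = short_durations)
  c5 <- generate_cohort(cfg5)
  expect_identical(c5[1:3], unclass(c1)[1:3])
})

test_that("configured nose-tip effects appear in the generated means", {
  cfg <- synth_config(n_subjects = 4, seed = 6,
                      phase_durations = short_durations,
                      nose_effect = c(BL = 0, Forward = 0, Backward = -0.5,
                                      ImmR = 0, DelR = 0, Rec = 0),
                      artifact_rate = 0)
  coh <- generate_cohort(cfg)
  for (rec in coh) {
    drop <- mean(rec$thermal$nosetip$Backward$values) -
      mean(rec$thermal$nosetip$BL$values)
    expect_equal(drop, -0.5, tolerance = 0.3)  # noise + oscillation slack
  }
})

test_that("ground-truth beats are increasing with physiological gaps", {
  coh <- shared_cohort()
  for (rec in coh) {
    for (beats in rec$truth$beat_times) {
      expect_true(all(diff(beats) > 0))
      expect_true(all(diff(beats) >= 0.250))
    }
  }
})

test_that("a phase too short for two beats names itself in the error", {
  cfg <- synth_config(n_subjects = 2, seed = 1,
                      phase_durations = c(BL = 120, Forward = 1,
                                          Backward = 120, ImmR = 120,
                                          DelR = 120, Rec = 120))
  expect_error(generate_cohort(cfg), "Forward")
})

test_that("artifact counts follow the configured Poisson rate", {
  counts <- unlist(lapply(1:10, function(s) {
    cfg <- synth_config(n_subjects = 2, seed = s,
                        phase_durations = short_durations)
    coh <- generate_cohort(cfg)
    unlist(lapply(coh, function(r)
      lengths(c(r$truth$artifacts$nosetip, r$truth$artifacts$glabella))))
  }))
  # rate 2/min over 1- and 2-minute phases: mean count per series
  durations <- rep(short_durations, length.out = length(counts))
  expect_equal(mean(counts), mean(2 * short_durations / 60),
               tolerance = 0.2)
})

test_that("null mode removes phase effects from extracted summaries", {
  rejections <- sapply(1:20, function(s) {
    cfg <- synth_config(n_subjects = 20, seed = s, null_mode = TRUE,
                        phase_durations = c(BL = 60, Forward = 60,
                                            Backward = 60, ImmR = 60,
                                            DelR = 60, Rec = 60))
    coh <- generate_cohort(cfg)
    fwd <- sapply(coh, function(r) mean(r$thermal$nosetip$Forward$values))
    bwd <- sapply(coh, function(r) mean(r$thermal$nosetip$Backward$values))
    wilcox.test(fwd, bwd)$p.value < 0.01
  })
  expect_lt(mean(rejections), 0.5)
})

test_that("score generation honors size, means and the type-I error rate", {
  cfg <- synth_config(n_subjects = 26, seed = 2)
  sc <- generate_scores(cfg)
  expect_equal(nrow(sc), 26)
  expect_named(sc, c("subject_id", "Forward", "Backward", "ImmR", "DelR",
                     "Rec"))

  # equal configured means: paired t rejects at about the nominal 5%
  rej <- sapply(1:1000, function(s) {
    cfgs <- synth_config(n_subjects = 26, seed = s)
    d <- generate_scores(cfgs, means = c(a = 5, b = 5), sds = c(a = 1, b = 1))
    t.test(d$a, d$b, paired = TRUE)$p.value < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.4)  # within ~2% absolute

  # difference 1.0 with paired-difference sd 1.0 at n = 26: power > 0.99
  pow <- power.t.test(n = 26, delta = 1, sd = 1, type = "paired")$power
  expect_gt(pow, 0.99)
  hits <- sapply(1:100, function(s) {
    cfgs <- synth_config(n_subjects = 26, seed = s + 2000)
    d <- generate_scores(cfgs, means = c(a = 1, b = 0), sds = c(a = 1, b = 1),
                         correlation = 0.5)  # sd of difference = 1
    t.test(d$a, d$b, paired = TRUE)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_subjects = 1), "n_subjects")
  expect_error(synth_config(phase_durations = c(BL = -1, Forward = 10)),
               "durations|> 0")
  cfg <- synth_config(n_subjects = 2, null_mode = TRUE)
  expect_true(all(cfg$rr_mean == cfg$rr_mean[["BL"]]))
  expect_true(all(cfg$nose_effect == 0))
})
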