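# Synthetic-data generator: forward-sampling fidelity, the reference
# preset, and reaction-time attachment with its discretization round trip.

test_that("forward sampling is seeded and deterministic CPTs give hand-derivable data", {
  m <- build_model("mathews")
  # deterministic: E/V always on, detectors copy stimuli, response by rule
  tabs <- list(E = cbind(0, 1), V = cbind(0, 1),
               DT = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
               DD = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)),
               R = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 0, 1)))
  p <- dbn_params(m, tabs)
  des <- build_group_design(1, 1, 8, seed = 2)
  dat <- forward_sample(m, p, des, seed = 3)
  expect_equal(dat$state_DT, as.integer(dat$target_valence == "threat"))
  expect_equal(dat$state_DD, as.integer(dat$distractor_valence == "threat"))
  expected_r <- ifelse(dat$state_DT == 1 & dat$state_DD == 1, "error",
                ifelse(dat$state_DT == 0 & dat$state_DD == 0, "fast", "slow"))
  expect_equal(dat$response_class, expected_r)
  # byte-identical reproducibility
  dat2 <- forward_sample(m, p, des, seed = 3)
  expect_identical(dat, dat2)
  # different seeds diverge once sampling is stochastic
  ps <- sharp_mathews_mod()
  ms <- build_model("mathews_mod")
  des2 <- build_group_design(2, 1, 16, seed = 2)
  expect_false(identical(forward_sample(ms, ps, des2, seed = 3),
                         forward_sample(ms, ps, des2, seed = 4)))
})

test_that("empirical conditional frequencies converge to the configured CPT entries", {
  m <- build_model("mathews_mod")
  p <- sharp_mathews_mod()
  des <- build_group_design(20, 16, 32, seed = 5)  # 20 * 16 * 64 = 20480 trials
  dat <- forward_sample(m, p, des, seed = 6)
  within3se <- function(phat, p0, n) abs(phat - p0) <= 3 * sqrt(p0 * (1 - p0) / n) + 1e-9
  # response CPT row (DT neutral, DD threat): P(slow) = 0.8
  i <- dat$state_DT == 0 & dat$state_DD == 1
  expect_true(within3se(mean(dat$response_class[i] == "slow"), 0.8, sum(i)))
  # distractor detector: P(DD = threat | Dv = threat, V = on) = 0.9
  j <- dat$distractor_valence == "threat" & dat$state_V == 1
  expect_true(within3se(mean(dat$state_DD[j] == 1), 0.9, sum(j)))
  # cross-trial: P(E = on | prev DT = threat, prev DD = neutral) = 0.75
  ord <- order(dat$subject_id, dat$run, dat$trial_index)
  d2 <- dat[ord, ]
  same <- c(FALSE, d2$subject_id[-1] == d2$subject_id[-nrow(d2)] &
                     d2$run[-1] == d2$run[-nrow(d2)])
  pDT <- c(NA, d2$state_DT[-nrow(d2)]); pDD <- c(NA, d2$state_DD[-nrow(d2)])
  k <- same & !is.na(pDT) & pDT == 1 & pDD == 0
  expect_true(within3se(mean(d2$state_E[k] == 1), 0.75, sum(k)))
})

test_that("the reference preset carries the reported entries with provenance flags", {
  p <- preset_params()
  expect_equal(p$cpts$R$table[1, 1], 0.90)    # fast | both detectors neutral
  expect_equal(p$cpts$R$table[3, 1], 0.73)    # fast | threat target, neutral distractor
  expect_equal(p$cpts$R$table[2, 2], 0.83)    # slow | neutral target, threat distractor
  expect_equal(p$cpts$V$table[4, 2], 0.94)    # threat evaluation after dual threat
  expect_equal(p$cpts$E$table[2, 2], 0.74)    # effort after threat distractor
  expect_equal(p$cpts$E$table[3, 2], 0.68)    # effort after threat target
  expect_equal(p$cpts$DD$table[4, 2], 0.725)  # DD hit, threat evaluation high
  expect_equal(p$cpts$DD$table[3, 2], 0.463)  # DD hit, threat evaluation low
  for (f in p$cpts) {
    expect_true(all(abs(rowSums(f$table) - 1) < 1e-12))
    expect_false(is.null(f$flags))
  }
  expect_equal(p$cpts$V$flags[4, 2], "reported")
  expect_equal(p$cpts$V$flags[1, 2], "default")
  expect_true(all(p$cpts$DT$flags == "ambiguous"))
  expect_equal(p$cpts$E$table[c(1, 4), 2], c(0.5, 0.5))  # unreported rows stay neutral
  # both readings of the ambiguous target-detector sentence are available
  p2 <- preset_params(target_reading = "literal")
  expect_equal(p2$cpts$DT$table[1, 1], 0.83)
  expect_false(identical(p$cpts$DT$table, p2$cpts$DT$table))
})

test_that("attached RTs discretize back to the generating classes", {
  dat <- simulate_study(6, 2, 16, seed = 61)
  # simulate_study stores the sampled classes, attaches RTs, re-discretizes:
  # response_class must equal the round trip of itself
  rt <- attach_rts(dat, rt_model(), seed = 62)
  rt2 <- discretize_responses(rt)
  expect_equal(rt2$response_class, dat$response_class)
  # all-fast input stays at or below the nominal median
  allfast <- data.frame(subject_id = "s1", run = 1, trial_index = 1:10,
                        response_class = "fast", stringsAsFactors = FALSE)
  af <- attach_rts(allfast, rt_model(median_ms = 600, spread_ms = 100), seed = 63)
  expect_true(all(af$rt_ms <= 600))
  expect_true(all(discretize_responses(af)$response_class == "fast"))
  # error trials are incorrect and may have missing RTs; seeding is exact
  errs <- data.frame(subject_id = "s1", run = 1, trial_index = 1:50,
                     response_class = c(rep("fast", 30), rep("error", 20)),
                     stringsAsFactors = FALSE)
  e1 <- attach_rts(errs, rt_model(), seed = 64)
  expect_true(all(!e1$correct[41:50]))
  expect_identical(e1, attach_rts(errs, rt_model(), seed = 64))
})
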