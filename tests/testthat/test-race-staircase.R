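test_that("deterministic parameters make the race order exact", {
  det <- subject_params(mu = 500, sigma = 0, tau = 0, stop_mean = 200,
                        stop_sd = 0)
  # stop finishes at 200 + 200 = 400 < 500: inhibition wins
  r1 <- race_trial(det, soa_ms = 200, stop_relevant = TRUE, seed = 1)
  expect_false(r1$responded)
  expect_true(is.na(r1$rt_ms))
  # stop finishes at 350 + 200 = 550 > 500: response wins with RT 500
  r2 <- race_trial(det, soa_ms = 350, stop_relevant = TRUE, seed = 1)
  expect_true(r2$responded)
  expect_equal(r2$rt_ms, 500)
  expect_error(race_trial(det, soa_ms = -1, stop_relevant = TRUE), "non-negative")
})

test_that("Monte-Carlo response probability matches the quadrature oracle", {
  params <- subject_params()
  n <- 100000
  for (soa in c(150, 300)) {
    sim <- race_trial(params, soa_ms = soa, stop_relevant = TRUE, n = n,
                      seed = 42 + soa)
    p_hat <- mean(sim$responded)
    p_true <- oracle_p_respond(params, soa)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("P(respond | soa) is non-decreasing in the delay", {
  params <- subject_params()
  grid <- seq(64, 928, by = 96)
  p <- vapply(grid, function(soa) {
    mean(race_trial(params, soa, TRUE, n = 4000, seed = 7)$responded)
  }, numeric(1))
  # allow Monte-Carlo wiggle of 2 x binomial SE between neighbouring delays
  tol <- 2 * sqrt(0.25 / 4000) * sqrt(2)
  expect_true(all(diff(p) > -tol))
})

test_that("staircase updates match the tracking rule and clamp at the bounds", {
  s <- staircase_state()
  expect_equal(s$soa_ms, c(128, 128, 128))
  s1 <- update_staircase(s, 1, stop_success = TRUE)
  expect_equal(s1$soa_ms, c(144, 128, 128))
  s2 <- update_staircase(s1, 2, stop_success = FALSE)
  expect_equal(s2$soa_ms, c(144, 64, 128)) # 128 - 64 = 64, at the floor
  s3 <- staircase_state(init_ms = 928)
  expect_equal(update_staircase(s3, 3, TRUE)$soa_ms[3], 928)   # ceiling clamp
  s4 <- staircase_state(init_ms = 100, bounds_ms = c(64, 928))
  expect_equal(update_staircase(s4, 1, FALSE)$soa_ms[1], 64)   # floor clamp
})

test_that("sessions track only on stop-relevant trials and stay in bounds", {
  sched <- generate_schedule(tiny_config(), seed = 21)
  rec <- simulate_session(subject_params(), sched, seed = 3)
  expect_equal(nrow(rec), nrow(sched))
  expect_true(all(is.na(rec$soa_ms[rec$stimulus == "go"])))
  soas <- rec$soa_ms[!is.na(rec$soa_ms)]
  expect_true(all(soas >= 64 & soas <= 928))
  expect_true(all(is.na(rec$rt_ms) != rec$responded))
  expect_true(all(rec$rt_ms[rec$responded] <= 1350))
  # a schedule with no stop-relevant trials never moves the staircase
  go_only <- generate_schedule(design_config(go = 32, stim1 = 0, stim2 = 0),
                               seed = 21)
  rec0 <- simulate_session(subject_params(), go_only, seed = 3)
  expect_equal(attr(rec0, "final_staircase")$soa_ms, c(128, 128, 128))
})

test_that("context staircases evolve independently", {
  sched <- generate_schedule(design_config(), seed = 8)
  base <- subject_params()
  shifted <- subject_params(context_mu_shift = c(0, 150, 0))
  r1 <- simulate_session(base, sched, seed = 99)
  r2 <- simulate_session(shifted, sched, seed = 99)
  # altering context-2 behaviour must not touch the context-1 (or 3) delays
  expect_identical(r1$soa_ms[r1$context == 1], r2$soa_ms[r2$context == 1])
  expect_identical(r1$soa_ms[r1$context == 3], r2$soa_ms[r2$context == 3])
  expect_false(identical(r1$soa_ms[r1$context == 2], r2$soa_ms[r2$context == 2]))
})

test_that("the staircase equilibrates near the 16/(16+64) = 20% failure rate", {
  # ~35 sessions x 296 stop trials > 10,000 staircase-tracked trials
  rec <- simulate_cohort(n_subjects = 35, seed = 123)
  stop_trials <- rec[rec$stop_relevant, ]
  expect_gte(nrow(stop_trials), 10000)
  rr <- mean(stop_trials$responded)
  expect_lt(abs(rr - 0.20), 0.02)
})

test_that("failed-stop RTs are faster than go RTs (race censoring)", {
  rec <- simulate_cohort(n_subjects = 5, seed = 31)
  for (cx in 1:3) {
    d <- rec[rec$context == cx, ]
    expect_lt(mean(d$rt_ms[d$outcome == "stop_fail"]),
              mean(d$rt_ms[d$outcome == "go_correct"]))
  }
})

test_that("cohorts are shaped and seeded as requested", {
  rec <- simulate_cohort(n_subjects = 3, config = tiny_config(), seed = 4)
  expect_equal(dplyr::count(rec, subject)$n, rep(96L, 3))
  expect_length(attr(rec, "schedules"), 3L)
  expect_warning(
    simulate_cohort(n_subjects = 2, config = tiny_config(),
                    subject_seeds = c(7, 7)),
    "duplicate"
  )
  again <- simulate_cohort(n_subjects = 3, config = tiny_config(), seed = 4)
  expect_identical(as.data.frame(rec), as.data.frame(again))
})
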