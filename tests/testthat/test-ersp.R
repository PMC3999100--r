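null_records <- function(n, stimulus = rep(c("go", "stim1"), length.out = n)) {
  tibble::tibble(
    trial = seq_len(n), context = 1L, stimulus = stimulus,
    stop_relevant = FALSE, soa_ms = NA_real_, responded = TRUE,
    rt_ms = 500, outcome = "go_correct"
  )
}

fc6 <- function() dplyr::filter(eoi_sets(), eoi == "frontocentral")

test_that("band, EOI and grid defaults are well-formed", {
  bw <- band_windows()
  expect_equal(bw$band, c("delta", "theta", "low_beta", "high_beta"))
  expect_true(all(bw$f_lo < bw$f_hi) && all(bw$t_lo < bw$t_hi))
  eo <- eoi_sets()
  expect_false(any(duplicated(paste(eo$eoi, eo$electrode))))
  expect_setequal(eo$electrode[eo$eoi == "frontocentral"],
                  c("F1", "F2", "FC1", "FC2", "FCz", "Cz"))
  expect_setequal(eo$electrode[eo$eoi == "left_motor"], c("C5", "C3", "CP3"))
  an <- ersp_analysis()
  expect_length(an$freqs, 100L)
  expect_lte(max(an$freqs), 35)
  expect_error(ersp_analysis(times = seq(-700, 1200, 20)), "epoch")
})

test_that("a pure sinusoid peaks at its own frequency bin", {
  an <- ersp_analysis()
  times <- seq(an$t_lim[1], an$t_lim[2], by = 1000 / an$srate)
  x <- array(sin(2 * pi * 10 * times / 1000), c(1, 1, length(times)))
  dimnames(x)[[2]] <- "Cz"
  p <- compute_ersp(x, an)
  peak <- an$freqs[which.max(apply(p$power[1, 1, , ], 1, mean))]
  expect_lt(abs(peak - 10), diff(an$freqs[1:2]) + 1e-9)
})

test_that("white-noise power is flat across frequencies", {
  an <- ersp_analysis()
  rec <- null_records(40)
  ep <- synthesize_epochs(rec, channels = "Cz",
                          noise = noise_spec(alpha = 0), analysis = an,
                          seed = 5)
  p <- compute_ersp(ep)
  by_freq <- apply(p$power[, 1, , ], 2, mean)
  # statistical flatness: extremes over 100 bins stay within sampling noise
  expect_lt(max(by_freq) / min(by_freq), 1.6)
})

test_that("a chirp's power ridge follows the instantaneous frequency", {
  an <- ersp_analysis()
  times <- seq(an$t_lim[1], an$t_lim[2], by = 1000 / an$srate) / 1000
  f0 <- 8; rate <- 8 # 8 Hz/s, analytic instantaneous frequency f0 + rate*t
  x <- array(cos(2 * pi * (f0 * (times - times[1]) +
                             rate * (times - times[1])^2 / 2)),
             c(1, 1, length(times)))
  dimnames(x)[[2]] <- "Cz"
  p <- compute_ersp(x, an)
  mid <- which(an$times > -100 & an$times < 600)
  ridge <- an$freqs[apply(p$power[1, 1, , mid], 2, which.max)]
  inst <- f0 + rate * (an$times[mid] / 1000 - times[1])
  expect_lt(max(abs(ridge - inst)), 1.5)
})

test_that("dB conversion obeys the log identities", {
  # power grid where the post-stimulus ratio to baseline is exactly known
  freqs <- c(3, 6); times <- c(-300, -200, 100, 200); chans <- c("Cz", "FCz")
  pw <- array(1, c(1, 2, 2, 4))
  pw[1, , , 3] <- 10   # 10x baseline
  pw[1, , , 4] <- 0.5  # half baseline
  x <- baseline_normalize(ersp_power(pw, freqs, times, chans))
  expect_equal(unname(x$db[1, 1, 1, 1]), 0)            # ratio 1 -> 0 dB
  expect_equal(unname(x$db[1, 1, 1, 3]), 10)           # ratio 10 -> +10 dB
  expect_equal(unname(x$db[1, 2, 2, 4]), 10 * log10(0.5)) # -3.0103 dB
  pw0 <- pw; pw0[1, 1, 1, 1:2] <- 0
  expect_error(baseline_normalize(ersp_power(pw0, freqs, times, chans)),
               "zero baseline")
})

test_that("feature extraction equals the brute-force bin average", {
  set.seed(4)
  freqs <- c(3, 5, 7); times <- c(-300, -200, 100, 200, 300)
  chans <- c("Cz", "FCz")
  pw <- array(rexp(1 * 2 * 3 * 5) + 0.1, c(1, 2, 3, 5))
  x <- baseline_normalize(ersp_power(pw, freqs, times, chans))
  bands <- tibble::tibble(band = "b", f_lo = 2, f_hi = 6, t_lo = 50, t_hi = 250)
  eois <- tibble::tibble(eoi = c("e", "e"), electrode = c("Cz", "FCz"))
  got <- extract_features(x, bands, eois)$db
  want <- mean(x$db[1, 1:2, 1:2, 3:4]) # channels Cz,FCz x bins 3,5 x 100,200
  expect_equal(got, want)
  # single-electrode EOI equals that electrode's own window mean
  one <- extract_features(x, bands, tibble::tibble(eoi = "z", electrode = "FCz"))
  expect_equal(one$db, mean(x$db[1, 2, 1:2, 3:4]))
  # constant field: every feature equals the constant
  pc <- array(1, c(1, 2, 3, 5)); pc[, , , 3:5] <- 10^(2 / 10)
  xc <- baseline_normalize(ersp_power(pc, freqs, times, chans))
  expect_equal(extract_features(xc, bands, eois)$db, 2)
  expect_error(
    extract_features(x, bands, tibble::tibble(eoi = "q", electrode = "Oz")),
    "Oz")
})

test_that("epoch synthesis is deterministic in the seed", {
  rec <- null_records(3)
  a <- synthesize_epochs(rec, channels = c("Cz", "FCz"), seed = 9)
  b <- synthesize_epochs(rec, channels = c("Cz", "FCz"), seed = 9)
  expect_identical(a$data, b$data)
  ef <- ersp_effect("theta", "frontocentral", 3, stimulus = "stim1")
  a2 <- synthesize_epochs(rec, ef, seed = 9)
  b2 <- synthesize_epochs(rec, ef, seed = 9)
  expect_identical(a2$data, b2$data)
  expect_error(synthesize_epochs(rec, ersp_effect("theta", "nope", 3)),
               "unknown EOI")
  expect_error(synthesize_epochs(rec, ef, channels = c("Cz", "FCz")),
               "not synthesized")
})

test_that("the null generator is calibrated at 0 dB", {
  rec <- null_records(80)
  ep <- synthesize_epochs(rec, effects = NULL,
                          channels = fc6()$electrode, seed = 11)
  fe <- extract_features(baseline_normalize(compute_ersp(ep)),
                         eois = fc6(), average_by = rep("all", 80))
  # 99% CI of the mean condition-average feature, from per-trial spread
  per <- extract_features(baseline_normalize(compute_ersp(ep)), eois = fc6())
  for (b in unique(fe$band)) {
    ci <- 2.58 * sd(per$db[per$band == b]) / sqrt(80)
    expect_lt(abs(fe$db[fe$band == b]), max(ci, 0.2))
  }
})

test_that("an injected +3 dB theta effect is recovered as a condition contrast", {
  n <- 240 # 120 trials per condition
  rec <- null_records(n)
  ef <- ersp_effect("theta", "frontocentral", 3, stimulus = "stim1")
  ep <- synthesize_epochs(rec, ef, channels = fc6()$electrode, seed = 13)
  fe <- extract_features(baseline_normalize(compute_ersp(ep)),
                         eois = fc6(), average_by = rec$stimulus)
  wide <- tidyr::pivot_wider(fe, names_from = "group", values_from = "db")
  theta <- wide[wide$band == "theta", ]
  expect_lt(abs((theta$stim1 - theta$go) - 3), 0.5)
  # spectrally distant bands stay clean; the adjacent delta band may carry a
  # small resolution-limited remnant
  beta <- wide[wide$band %in% c("low_beta", "high_beta"), ]
  expect_true(all(abs(beta$stim1 - beta$go) < 0.35))
  delta <- wide[wide$band == "delta", ]
  expect_lt(abs(delta$stim1 - delta$go), 0.25 * 3)
})

test_that("configured condition orderings are recovered in the features", {
  # stop > go in delta and theta; the context-2 stop effect is attenuated
  n_per <- 60
  rec <- tibble::tibble(
    trial = 1:(3 * n_per),
    context = rep(c(1L, 1L, 2L), each = n_per),
    stimulus = rep(c("go", "stim1", "stim1"), each = n_per),
    stop_relevant = FALSE, soa_ms = NA_real_, responded = TRUE, rt_ms = 500,
    outcome = "go_correct"
  )
  ef <- dplyr::bind_rows(
    ersp_effect("delta", "frontocentral", 2, stimulus = "stim1", context = 1),
    ersp_effect("theta", "frontocentral", 3, stimulus = "stim1", context = 1),
    ersp_effect("delta", "frontocentral", 1, stimulus = "stim1", context = 2),
    ersp_effect("theta", "frontocentral", 1.5, stimulus = "stim1", context = 2)
  )
  ep <- synthesize_epochs(rec, ef, channels = fc6()$electrode, seed = 17)
  grp <- paste(rec$stimulus, rec$context, sep = "_c")
  fe <- extract_features(baseline_normalize(compute_ersp(ep)),
                         eois = fc6(), average_by = grp)
  for (b in c("delta", "theta")) {
    v <- fe[fe$band == b, ]
    go1 <- v$db[v$group == "go_c1"]
    s1c1 <- v$db[v$group == "stim1_c1"]
    s1c2 <- v$db[v$group == "stim1_c2"]
    expect_gt(s1c1, go1)   # stop > go
    expect_gt(s1c2, go1)
    expect_gt(s1c1, s1c2)  # context-2 attenuation
  }
})
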