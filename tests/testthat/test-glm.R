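toy_events <- function() {
  tibble::tibble(onset = c(6, 26, 50), condition = "stop")
}

test_that("the canonical HRF has the right shape", {
  expect_equal(hrf_canonical(0), 0)
  grid <- seq(0, 32, by = 0.001)
  h <- hrf_canonical(grid)
  # numeric maximization oracle: peak location of the double-gamma
  expect_lt(abs(grid[which.max(h)] - 5.0), 0.1)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_lt(abs(h[grid == 32]), 0.01)          # back to ~0 at the support end
  expect_lt(min(h), 0)                         # undershoot exists
  expect_error(hrf_canonical(-1), "non-negative")
})

test_that("design columns equal a brute-force convolution oracle", {
  n_scans <- 40; tr <- 2; dt <- 0.1
  des <- build_design(toy_events(), n_scans = n_scans, tr = tr,
                      highpass_s = 128, microtime = dt)
  # oracle: add a shifted HRF per event on the microtime grid, read scans
  grid <- seq(0, n_scans * tr - dt, by = dt)
  h <- hrf_canonical(seq(0, 32, by = dt))
  y <- numeric(length(grid))
  for (on in toy_events()$onset) {
    i0 <- floor(on / dt) + 1
    span <- i0:min(length(grid), i0 + length(h) - 1)
    y[span] <- y[span] + h[seq_along(span)]
  }
  oracle <- y[round((0:(n_scans - 1)) * tr / dt) + 1]
  expect_lt(max(abs(des$X[, "stop"] - oracle)), 1e-10)
  # drift count: periods above 128 s -> floor(2*80/128) = 1 drift column
  expect_equal(sum(des$columns$kind == "drift"), 1L)
  expect_equal(unname(des$X[, "constant"]), rep(1, n_scans))
})

test_that("degenerate designs error informatively", {
  ev <- toy_events()
  expect_error(build_design(ev, n_scans = 10, tr = 2), "within the scanned")
  # zero events: drift + constant only
  d0 <- build_design(ev[0, ], n_scans = 100, tr = 2)
  expect_setequal(unique(d0$columns$kind), c("drift", "constant"))
  # constant modulator has no z-score
  expect_error(
    build_design(ev, modulators = data.frame(theta = c(1, 1, 1)),
                 n_scans = 60, tr = 2),
    "constant or missing")
  # duplicated column makes the design rank deficient
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, condition = "stop2"))
  expect_error(build_design(ev2, n_scans = 60, tr = 2), "collinear")
})

test_that("modulated columns are orthogonal to their companions", {
  set.seed(2)
  ev <- tibble::tibble(onset = sort(runif(40, 0, 560)), condition = "stop")
  mods <- data.frame(delta = rnorm(40), theta = rnorm(40), high_beta = rnorm(40))
  des <- build_design(ev, mods, n_scans = 300, tr = 2)
  X <- des$X
  for (m in c("delta", "theta", "high_beta")) {
    expect_lt(abs(cor(X[, "stop"], X[, paste0("stop:", m)])), 1e-12)
  }
  # serial orthogonalization also decorrelates the modulators in order
  expect_lt(abs(cor(X[, "stop:delta"], X[, "stop:theta"])), 1e-12)
  expect_lt(abs(cor(X[, "stop:theta"], X[, "stop:high_beta"])), 1e-12)
})

test_that("noiseless data are fit exactly and AR noise has the right moments", {
  set.seed(3)
  ev <- tibble::tibble(onset = sort(runif(30, 0, 360)), condition = "stop")
  des <- build_design(ev, n_scans = 200, tr = 2)
  betas <- rnorm(ncol(des$X))
  y <- synthesize_bold(des, betas, sigma = 0)
  expect_equal(unname(y), unname(as.numeric(des$X %*% betas)))
  fit <- fit_glm(y, des, prewhiten = FALSE)
  expect_lt(max(abs(fit$coefficients - betas)), 1e-8)
  # white noise: sample sd close to sigma
  y0 <- synthesize_bold(des, betas * 0, sigma = 2, ar1_rho = 0, seed = 4)
  expect_lt(abs(sd(y0) - 2), 0.15)
  # AR(1) moment oracle at long n
  long <- build_design(ev[0, ], n_scans = 10000, tr = 2)
  e <- synthesize_bold(long, numeric(ncol(long$X)), sigma = 1, ar1_rho = 0.4,
                       seed = 5)
  r1 <- cor(e[-1], e[-length(e)])
  expect_lt(abs(r1 - 0.4), 0.03)
})

test_that("prewhitening estimates rho and keeps estimates unbiased", {
  set.seed(6)
  ev <- tibble::tibble(onset = sort(runif(100, 0, 1180)), condition = "stop")
  mods <- data.frame(theta = rnorm(100))
  des <- build_design(ev, mods, n_scans = 600, tr = 2)
  bet <- c(stop = 1, `stop:theta` = 0.8)
  ests <- replicate(60, {
    y <- synthesize_bold(des, bet, sigma = 1, ar1_rho = 0.4)
    f <- fit_glm(y, des, prewhiten = TRUE)
    c(f$coefficients["stop:theta"], f$rho)
  })
  expect_lt(abs(mean(ests[1, ]) - 0.8), 0.05)
  expect_lt(abs(mean(ests[2, ]) - 0.4), 0.1)
  expect_error(fit_glm(numeric(10), des), "length")
})

test_that("tidy and glance expose the fit in broom shape", {
  ev <- toy_events()
  des <- build_design(ev, n_scans = 60, tr = 2)
  y <- synthesize_bold(des, rep(0.5, ncol(des$X)), sigma = 0.5, seed = 7)
  fit <- fit_glm(y, des, contrasts = list(stop = c(stop = 1)))
  td <- tidy(fit)
  expect_equal(names(td), c("term", "kind", "estimate", "std.error", "statistic"))
  expect_equal(nrow(td), ncol(des$X))
  gl <- glance(fit)
  expect_equal(gl$df.residual, 60 - ncol(des$X))
  expect_equal(fit$contrasts$estimate, unname(fit$coefficients["stop"]))
  expect_equal(fit$contrasts$t,
               td$statistic[td$term == "stop"], tolerance = 1e-12)
})

test_that("coupling is attributed to the generating band's modulator", {
  set.seed(8)
  n_ev <- 100
  ev <- tibble::tibble(onset = sort(runif(n_ev, 0, 1180)), condition = "stop")
  # weakly correlated single-trial band features
  mods <- data.frame(delta = rnorm(n_ev), theta = rnorm(n_ev),
                     high_beta = rnorm(n_ev))
  des <- build_design(ev, mods, n_scans = 600, tr = 2)
  # BOLD amplitude scales with the single-trial theta feature only
  y <- synthesize_bold(des, c(stop = 1, `stop:theta` = 0.8), sigma = 1,
                       ar1_rho = 0.3, seed = 9)
  fit <- fit_glm(y, des, prewhiten = TRUE)
  td <- tidy(fit)
  t_theta <- abs(td$statistic[td$term == "stop:theta"])
  t_other <- abs(td$statistic[td$term %in% c("stop:delta", "stop:high_beta")])
  expect_gt(t_theta, 5)
  expect_true(all(t_other < 3))
})
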