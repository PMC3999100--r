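# Small designs and closed-form oracles shared across tests.

# A reduced design whose per-context total (32) still partitions into 13-18
# runs (16 + 16), for fast schedule-level tests.
tiny_config <- function() {
  design_config(go = 20, stim1 = 6, stim2 = 6)
}

# Ex-Gaussian CDF (normal mu/sigma + exponential tau), used as the
# independent oracle for race probabilities.
pexgauss <- function(q, mu, sigma, tau) {
  if (tau == 0) return(pnorm(q, mu, sigma))
  z <- (q - mu) / sigma
  k <- sigma / tau
  pnorm(z) - exp(-(q - mu) / tau + k^2 / 2 + pnorm(z - k, log.p = TRUE))
}

# Oracle for P(respond | soa): P(go FT < soa + stop latency), integrating the
# truncated-at-zero normal stop-latency density numerically.
oracle_p_respond <- function(params, soa, response_window = 1350) {
  p_win <- function(s) {
    pexgauss(pmin(soa + s, response_window), params$mu, params$sigma, params$tau)
  }
  if (params$stop_sd == 0) {
    p <- p_win(max(params$stop_mean, 0))
  } else {
    p0 <- pnorm(0, params$stop_mean, params$stop_sd)
    f <- function(s) {
      stats::dnorm(s, params$stop_mean, params$stop_sd) / (1 - p0) * p_win(s)
    }
    p <- stats::integrate(f, 0, params$stop_mean + 10 * params$stop_sd)$value
  }
  # races the subject loses outright to the response window still count as
  # non-responses
  p_trig <- 1 - params$p_trigger_failure
  p_no_trig_respond <- pexgauss(response_window, params$mu, params$sigma,
                                params$tau)
  p_trig * p + (1 - p_trig) * p_no_trig_respond
}
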