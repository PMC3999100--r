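#' Subject parameters for the independent horse-race model
#'
#' Go-process finishing times are ex-Gaussian (normal with mean `mu` and sd
#' `sigma`, plus an independent exponential with mean `tau`); stop-process
#' latencies are normal truncated at zero. The go and stop processes race
#' independently: a response is emitted iff the go process finishes first.
#' `context_mu_shift` lets the go-RT mean differ across the three
#' stimulus-response contexts (default: no context effect).
#'
#' @param mu,sigma,tau Ex-Gaussian go-RT parameters in ms.
#' @param stop_mean,stop_sd Stop-latency (SSRT) distribution in ms, truncated
#'   at 0.
#' @param p_trigger_failure Probability that the stop process never starts on
#'   a stop-relevant trial.
#' @param p_go_omission Probability that the go process never produces a
#'   response.
#' @param context_mu_shift Numeric length-3 additive shift of `mu` per context.
#' @return A list of class `subject_params`.
#' @export
subject_params <- function(mu = 450, sigma = 60, tau = 120,
                           stop_mean = 200, stop_sd = 30,
                           p_trigger_failure = 0, p_go_omission = 0,
                           context_mu_shift = c(0, 0, 0)) {
  if (sigma < 0 || tau < 0 || stop_sd < 0) {
    abort_input("sigma, tau and stop_sd must be non-negative")
  }
  if (p_trigger_failure < 0 || p_trigger_failure > 1 ||
      p_go_omission < 0 || p_go_omission > 1) {
    abort_input("probabilities must lie in [0, 1]")
  }
  if (length(context_mu_shift) != 3L) {
    abort_input("context_mu_shift must have length 3")
  }
  structure(
    list(mu = mu, sigma = sigma, tau = tau,
         stop_mean = stop_mean, stop_sd = stop_sd,
         p_trigger_failure = p_trigger_failure,
         p_go_omission = p_go_omission,
         context_mu_shift = as.numeric(context_mu_shift)),
    class = "subject_params"
  )
}

#' Per-context adaptive staircase state for the stop-signal delay
#'
#' One delay (SOA) is tracked per context. Successful inhibition increases
#' the delay by `step_up_ms` (making stopping harder), a failed stop
#' decreases it by `step_down_ms`; the delay is clamped to `bounds_ms`. With
#' the default asymmetric 16/64 steps the staircase equilibrates at a failure
#' rate of 16/(16+64) = 20%.
#'
#' @param init_ms Initial delay for every context.
#' @param step_up_ms,step_down_ms Step sizes in ms.
#' @param bounds_ms Two-element clamp range.
#' @return A list of class `staircase_state` with element `soa_ms` (length 3).
#' @export
staircase_state <- function(init_ms = 128, step_up_ms = 16, step_down_ms = 64,
                            bounds_ms = c(64, 928)) {
  if (init_ms < bounds_ms[1] || init_ms > bounds_ms[2]) {
    abort_input("initial SOA outside bounds")
  }
  structure(
    list(soa_ms = rep(init_ms, 3), step_up_ms = step_up_ms,
         step_down_ms = step_down_ms, bounds_ms = bounds_ms),
    class = "staircase_state"
  )
}

#' Update the staircase after a stop-relevant trial
#'
#' @param state A [staircase_state()].
#' @param context Context (1-3) of the trial just run.
#' @param stop_success Was inhibition successful (no response emitted)?
#' @return The updated state; only the given context's delay changes.
#' @export
#' @examples
#' s <- staircase_state()
#' update_staircase(s, 1, stop_success = TRUE)$soa_ms # 144 128 128
update_staircase <- function(state, context, stop_success) {
  stopifnot(inherits(state, "staircase_state"))
  if (!context %in% 1:3) abort_input("context must be 1, 2 or 3")
  soa <- state$soa_ms[context] +
    if (isTRUE(stop_success)) state$step_up_ms else -state$step_down_ms
  state$soa_ms[context] <- min(max(soa, state$bounds_ms[1]), state$bounds_ms[2])
  state
}

# Truncated-at-zero normal via inverse CDF so that exactly one uniform is
# consumed per draw (keeps RNG streams aligned across parameter changes).
rtnorm0 <- function(u, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), length(u)))
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + u * (1 - p0)) * sd + mean
}

# Per-trial random draws for one session; drawn up-front so the draw used by
# trial i never depends on other trials' parameters or outcomes.
session_draws <- function(n) {
  list(
    z_go = rnorm(n),
    e_go = rexp(n),
    u_stop = runif(n),
    u_trig = runif(n),
    u_omit = runif(n)
  )
}

race_core <- function(params, context, soa_ms, stop_relevant, draws, i,
                      response_window_ms) {
  mu_c <- params$mu + params$context_mu_shift[context]
  go_ft <- max(mu_c + params$sigma * draws$z_go[i] + params$tau * draws$e_go[i], 0)
  if (draws$u_omit[i] < params$p_go_omission) go_ft <- Inf
  stop_ft <- Inf
  if (stop_relevant && draws$u_trig[i] >= params$p_trigger_failure) {
    stop_ft <- soa_ms + rtnorm0(draws$u_stop[i], params$stop_mean, params$stop_sd)
  }
  responded <- is.finite(go_ft) && go_ft < stop_ft && go_ft <= response_window_ms
  list(responded = responded, rt_ms = if (responded) go_ft else NA_real_)
}

#' Run independent race trials at a fixed stop-signal delay
#'
#' Simulates `n` one-shot trials (no staircase): the go finishing time is
#' drawn ex-Gaussian; on stop-relevant trials a stop finishing time
#' `soa_ms + stop latency` races it. A response is emitted iff the go process
#' wins and finishes within the response window.
#'
#' @param params A [subject_params()].
#' @param soa_ms Stop-signal delay in ms (ignored when `stop_relevant` is
#'   FALSE).
#' @param stop_relevant Does the trial carry a stop signal to be obeyed?
#' @param n Number of trials.
#' @param context Context used for `context_mu_shift`.
#' @param response_window_ms Response-active window.
#' @param seed Optional seed.
#' @return Tibble with columns `responded`, `rt_ms`.
#' @export
race_trial <- function(params, soa_ms, stop_relevant, n = 1, context = 1,
                       response_window_ms = 1350, seed = NULL) {
  stopifnot(inherits(params, "subject_params"))
  if (soa_ms < 0) abort_input("soa_ms must be non-negative")
  with_seed(seed, {
    draws <- session_draws(n)
    out <- lapply(seq_len(n), function(i) {
      race_core(params, context, soa_ms, stop_relevant, draws, i,
                response_window_ms)
    })
    tibble(
      responded = vapply(out, `[[`, logical(1), "responded"),
      rt_ms = vapply(out, `[[`, numeric(1), "rt_ms")
    )
  })
}

classify_outcome <- function(stimulus, stop_relevant, responded) {
  if (stop_relevant) {
    if (responded) "stop_fail" else "stop_success"
  } else if (stimulus == "go") {
    if (responded) "go_correct" else "go_omission"
  } else {
    if (responded) "irrelevant_response" else "irrelevant_omission"
  }
}

#' Simulate one subject's session with adaptive SOA tracking
#'
#' Iterates the schedule in order. Every deviant (Stim1/Stim2) trial is
#' presented at the current delay of its context's staircase; the staircase
#' is updated only after stop-relevant trials (in context 1 both deviant
#' stimuli update the same staircase). Stop-irrelevant deviants engage no
#' stop process: the subject responds from the go process alone.
#'
#' @param params A [subject_params()].
#' @param schedule A `stop_schedule` tibble from [generate_schedule()].
#' @param staircase Initial [staircase_state()].
#' @param seed Optional seed; the session is fully reproducible from it.
#' @return A tibble of behavioural records: `trial`, `context`, `stimulus`,
#'   `stop_relevant`, `soa_ms` (NA on pure go trials), `responded`, `rt_ms`,
#'   `outcome`.
#' @export
simulate_session <- function(params, schedule, staircase = staircase_state(),
                             seed = NULL) {
  stopifnot(inherits(params, "subject_params"))
  cfg <- attr(schedule, "config")
  rw <- if (!is.null(cfg)) cfg$response_window_ms else 1350
  n <- nrow(schedule)
  with_seed(seed, {
    draws <- session_draws(n)
    soa_used <- rep(NA_real_, n)
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    outcome <- character(n)
    st <- staircase
    for (i in seq_len(n)) {
      cx <- schedule$context[i]
      stim <- schedule$stimulus[i]
      rel <- schedule$stop_relevant[i]
      soa <- if (stim == "go") NA_real_ else st$soa_ms[cx]
      res <- race_core(params, cx, if (is.na(soa)) 0 else soa, rel, draws, i, rw)
      soa_used[i] <- soa
      responded[i] <- res$responded
      rt[i] <- res$rt_ms
      outcome[i] <- classify_outcome(stim, rel, res$responded)
      if (rel) st <- update_staircase(st, cx, stop_success = !res$responded)
    }
    out <- tibble(
      trial = schedule$trial,
      context = schedule$context,
      stimulus = schedule$stimulus,
      stop_relevant = schedule$stop_relevant,
      soa_ms = soa_used,
      responded = responded,
      rt_ms = rt,
      outcome = outcome
    )
    attr(out, "final_staircase") <- st
    out
  })
}

#' Simulate one subject over many sessions with continuous SOA tracking
#'
#' Runs `n_sessions` freshly randomized schedules back to back, carrying the
#' staircase state from one session into the next, so the delay tracker
#' reaches and stays at its equilibrium. This is the cleanest way to measure
#' the tracking rule's long-run failure rate: with re-starts, each session's
#' climb from the 128 ms initial delay toward equilibrium deflates the rate
#' slightly (as it does in real sessions).
#'
#' @param params A [subject_params()].
#' @param n_sessions Number of consecutive sessions.
#' @param config A [design_config()].
#' @param seed Master seed.
#' @return Records tibble with a `session` column; final staircase state in
#'   attribute `"final_staircase"`.
#' @export
simulate_long_run <- function(params = subject_params(), n_sessions = 10,
                              config = design_config(), seed = NULL) {
  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max - 2L, n_sessions)
  } else {
    derive_seeds(seed, n_sessions)
  }
  st <- staircase_state()
  recs <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sched <- generate_schedule(config, seed = seeds[s])
    r <- simulate_session(params, sched, staircase = st, seed = seeds[s] + 1L)
    st <- attr(r, "final_staircase")
    recs[[s]] <- mutate(r, session = s, .before = 1)
  }
  out <- bind_rows(recs)
  attr(out, "final_staircase") <- st
  out
}

#' Simulate a cohort of subjects
#'
#' Each subject runs a freshly randomized schedule from `config` with an
#' independent seed derived from `seed`. Per-subject parameter overrides can
#' be supplied as a list of [subject_params()].
#'
#' @param n_subjects Number of subjects.
#' @param params A single [subject_params()] shared by all subjects, or a
#'   list of length `n_subjects`.
#' @param config A [design_config()].
#' @param seed Master seed for the cohort.
#' @param subject_seeds Optional explicit per-subject seeds; duplicates
#'   trigger a warning.
#' @return Tibble of records with a leading `subject` column; the schedules
#'   are attached as attribute `"schedules"`.
#' @export
simulate_cohort <- function(n_subjects = 21, params = subject_params(),
                            config = design_config(), seed = NULL,
                            subject_seeds = NULL) {
  if (n_subjects < 1) abort_input("need at least one subject")
  if (inherits(params, "subject_params")) {
    params <- rep(list(params), n_subjects)
  }
  if (length(params) != n_subjects) {
    abort_input("params must be one subject_params or a list of n_subjects")
  }
  if (is.null(subject_seeds)) {
    subject_seeds <- if (is.null(seed)) {
      sample.int(.Machine$integer.max - 1L, n_subjects)
    } else {
      derive_seeds(seed, n_subjects)
    }
  }
  if (anyDuplicated(subject_seeds)) {
    warning("duplicate subject seeds: subjects will produce identical data",
            call. = FALSE)
  }
  schedules <- vector("list", n_subjects)
  recs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    schedules[[s]] <- generate_schedule(config, seed = subject_seeds[s])
    recs[[s]] <- simulate_session(params[[s]], schedules[[s]],
                                  seed = subject_seeds[s] + 1L) %>%
      mutate(subject = s, .before = 1)
  }
  out <- bind_rows(recs)
  attr(out, "schedules") <- schedules
  out
}
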