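#' Configure the three-context stop-signal design
#'
#' The default design presents, per context, 236 pure go trials, 48 trials on
#' which Stim1 follows the go signal, and 100 trials on which Stim2 follows
#' the go signal (1152 trials in total across the three contexts). Trials of
#' the same context are presented in consecutive runs of 13 to 18 trials, and
#' each trial's onset is jittered uniformly within `jitter_range_ms` to
#' improve temporal sampling of the haemodynamic response.
#'
#' @param go,stim1,stim2 Per-context trial counts for the pure go trials and
#'   the two infrequently presented (deviant) stimuli.
#' @param stimulus_duration_ms Presentation duration of each stimulus.
#' @param response_window_ms Length of the response-active window that starts
#'   at go-signal onset; responses after it count as omissions.
#' @param jitter_range_ms Two-element range (inclusive, integer milliseconds)
#'   of the uniform onset jitter.
#' @param base_iti_ms Fixed inter-trial gap added after the response window.
#' @param run_range Allowed lengths of consecutive same-context runs.
#'
#' @return A list of class `design_config`.
#' @export
#' @examples
#' cfg <- design_config()
#' cfg$n_trials_total
design_config <- function(go = 236, stim1 = 48, stim2 = 100,
                          stimulus_duration_ms = 100,
                          response_window_ms = 1350,
                          jitter_range_ms = c(0, 2000),
                          base_iti_ms = 0,
                          run_range = c(13L, 18L)) {
  counts <- c(go = go, stim1 = stim1, stim2 = stim2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_input("per-context trial counts must be non-negative integers")
  }
  if (stimulus_duration_ms <= 0 || response_window_ms <= 0) {
    abort_input("durations must be positive")
  }
  if (length(jitter_range_ms) != 2L || jitter_range_ms[1] > jitter_range_ms[2] ||
      jitter_range_ms[1] < 0) {
    abort_input("jitter_range_ms must be a non-negative increasing range")
  }
  if (base_iti_ms < 0) abort_input("base_iti_ms must be non-negative")
  run_range <- as.integer(run_range)
  if (length(run_range) != 2L || run_range[1] < 1L || run_range[1] > run_range[2]) {
    abort_input("run_range must be an increasing pair of positive integers")
  }
  structure(
    list(
      go = as.integer(go), stim1 = as.integer(stim1), stim2 = as.integer(stim2),
      n_per_context = as.integer(sum(counts)),
      n_trials_total = as.integer(3L * sum(counts)),
      stimulus_duration_ms = stimulus_duration_ms,
      response_window_ms = response_window_ms,
      jitter_range_ms = as.integer(jitter_range_ms),
      base_iti_ms = base_iti_ms,
      run_range = run_range
    ),
    class = "design_config"
  )
}

#' Context-dependent stop relevance of a stimulus
#'
#' In context 1 both deviant stimuli are stop signals; in context 2 only
#' Stim1 must be stopped (Stim2 requires a response); in context 3 the
#' mapping is reversed. The pure go stimulus never requires stopping.
#'
#' @param context Integer vector with values in 1:3.
#' @param stimulus Character vector with values `"go"`, `"stim1"`, `"stim2"`.
#' @return Logical vector: must the response be withheld?
#' @export
#' @examples
#' stop_relevance(1, "stim2") # TRUE
#' stop_relevance(2, "stim2") # FALSE
stop_relevance <- function(context, stimulus) {
  if (!all(context %in% 1:3)) abort_input("context must be 1, 2 or 3")
  if (!all(stimulus %in% c("go", "stim1", "stim2"))) {
    abort_input("stimulus must be 'go', 'stim1' or 'stim2'")
  }
  (context == 1 & stimulus != "go") |
    (context == 2 & stimulus == "stim1") |
    (context == 3 & stimulus == "stim2")
}

# Partition `total` trials into run lengths within run_range by rejection
# sampling: draw uniformly until the remainder is short, fold it into the
# final run when allowed, otherwise redraw.
partition_runs <- function(total, run_range, max_tries = 1000L) {
  lo <- run_range[1]; hi <- run_range[2]
  if (total == 0L) return(integer(0))
  if (total < lo) {
    abort_input(sprintf(
      "cannot partition %d trials into runs of %d-%d trials", total, lo, hi))
  }
  for (i in seq_len(max_tries)) {
    lens <- integer(0)
    left <- total
    while (left >= lo) {
      l <- sample(lo:hi, 1L)
      if (l > left) l <- left
      lens <- c(lens, l)
      left <- left - l
    }
    if (left == 0L) return(lens)
    if (lens[length(lens)] + left <= hi) {
      lens[length(lens)] <- lens[length(lens)] + left
      return(lens)
    }
  }
  abort_input(sprintf(
    "cannot partition %d trials into runs of %d-%d trials", total, lo, hi))
}

# Order runs from the three contexts so that no two consecutive runs share a
# context (otherwise the observed run length would exceed the allowed range).
interleave_runs <- function(n_runs, max_tries = 1000L) {
  ctx <- rep(1:3, n_runs)
  for (i in seq_len(max_tries)) {
    left <- n_runs
    out <- integer(sum(n_runs))
    prev <- 0L
    ok <- TRUE
    for (k in seq_along(out)) {
      avail <- which(left > 0L)
      avail <- setdiff(avail, prev)
      if (length(avail) == 0L) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else {
        sample(avail, 1L, prob = left[avail])
      }
      out[k] <- pick
      left[pick] <- left[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  abort_input("could not interleave context runs without adjacent repeats")
}

#' Generate a context-blocked stop-signal trial schedule
#'
#' Produces the full ordered trial plan: per-context stimulus counts are met
#' exactly, same-context trials come in consecutive runs whose lengths lie in
#' `config$run_range`, stimulus order within each context is randomized, and
#' onsets accumulate the response window, the base inter-trial interval and a
#' uniform integer-millisecond jitter.
#'
#' @param config A [design_config()].
#' @param seed Optional integer seed; the same seed reproduces the schedule
#'   exactly.
#' @return A tibble of class `stop_schedule` with columns `trial`, `context`,
#'   `stimulus`, `stop_relevant`, `run`, `jitter_ms`, `onset_s`, `duration_s`.
#' @export
#' @examples
#' sched <- generate_schedule(design_config(), seed = 1)
#' dplyr::count(sched, context, stimulus)
generate_schedule <- function(config = design_config(), seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  with_seed(seed, {
    run_lens <- lapply(1:3, function(cx) {
      partition_runs(config$n_per_context, config$run_range)
    })
    run_ctx <- interleave_runs(vapply(run_lens, length, integer(1)))
    # shuffled per-context stimulus pools, dealt into that context's runs
    pools <- lapply(1:3, function(cx) {
      sample(rep(c("go", "stim1", "stim2"),
                 times = c(config$go, config$stim1, config$stim2)))
    })
    taken <- integer(3)
    next_run <- integer(3)
    rows <- vector("list", length(run_ctx))
    for (r in seq_along(run_ctx)) {
      cx <- run_ctx[r]
      next_run[cx] <- next_run[cx] + 1L
      len <- run_lens[[cx]][next_run[cx]]
      stim <- pools[[cx]][taken[cx] + seq_len(len)]
      taken[cx] <- taken[cx] + len
      rows[[r]] <- tibble(context = cx, stimulus = stim, run = r)
    }
    sched <- bind_rows(rows)
    n <- nrow(sched)
    jit <- if (n) {
      sample(seq.int(config$jitter_range_ms[1], config$jitter_range_ms[2]),
             n, replace = TRUE)
    } else integer(0)
    iti_s <- (config$response_window_ms + config$base_iti_ms) / 1000
    onset <- cumsum(jit / 1000 + c(0, rep(iti_s, max(n - 1L, 0L))))
    sched <- sched %>%
      mutate(
        trial = row_number(),
        stop_relevant = stop_relevance(.data$context, .data$stimulus),
        jitter_ms = as.integer(jit),
        onset_s = round(onset, 3),
        duration_s = config$stimulus_duration_ms / 1000
      ) %>%
      select("trial", "context", "stimulus", "stop_relevant", "run",
             "jitter_ms", "onset_s", "duration_s")
    attr(sched, "config") <- config
    class(sched) <- c("stop_schedule", class(sched))
    validate_schedule(sched)
    sched
  })
}

#' Validate schedule invariants
#'
#' Checks exact per-(context, stimulus) tallies, run lengths, jitter bounds,
#' stop-relevance mapping and strictly increasing onsets. Called by
#' [generate_schedule()] and [write_events()].
#'
#' @param schedule A `stop_schedule` tibble.
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  cfg <- attr(schedule, "config")
  if (nrow(schedule) > 1 && any(diff(schedule$onset_s) <= 0)) {
    abort_input("schedule onsets must be strictly increasing")
  }
  if (!all(schedule$stop_relevant ==
           stop_relevance(schedule$context, schedule$stimulus))) {
    abort_input("stop_relevant column contradicts the context x stimulus mapping")
  }
  if (!is.null(cfg)) {
    if (any(schedule$jitter_ms < cfg$jitter_range_ms[1]) ||
        any(schedule$jitter_ms > cfg$jitter_range_ms[2])) {
      abort_input("jitter outside the configured range")
    }
    tal <- schedule %>% count(.data$context, .data$stimulus)
    for (cx in 1:3) {
      for (st in c("go", "stim1", "stim2")) {
        want <- cfg[[st]]
        got <- tal$n[tal$context == cx & tal$stimulus == st]
        got <- if (length(got)) got else 0L
        if (got != want) {
          abort_input(sprintf("context %d has %d %s trials, expected %d",
                              cx, got, st, want))
        }
      }
    }
    runs <- schedule_runs(schedule)
    if (nrow(runs) &&
        (any(runs$length < cfg$run_range[1]) | any(runs$length > cfg$run_range[2]))) {
      abort_input("context run lengths outside the allowed range")
    }
  }
  invisible(schedule)
}

#' Observed context runs of a schedule
#'
#' @param schedule A `stop_schedule` tibble (or any tibble with a `context`
#'   column in trial order).
#' @return Tibble with one row per maximal same-context run: `run`, `context`,
#'   `length`.
#' @export
schedule_runs <- function(schedule) {
  ctx <- schedule$context
  if (!length(ctx)) return(tibble(run = integer(), context = integer(),
                                  length = integer()))
  id <- cumsum(c(1L, as.integer(diff(ctx) != 0)))
  tibble(context = ctx, id = id) %>%
    count(.data$id, .data$context, name = "length") %>%
    rename(run = "id")
}

#' Tally trials by context and stimulus
#'
#' @param schedule A `stop_schedule` tibble.
#' @return Tibble with `context`, `stimulus`, `stop_relevant`, `n`.
#' @export
schedule_counts <- function(schedule) {
  schedule %>% count(.data$context, .data$stimulus, .data$stop_relevant)
}

#' Write and read schedule event tables
#'
#' `write_events()` writes a BIDS-events-style tab-separated file with columns
#' `onset`, `duration`, `trial_type`, `context`, `stop_relevant` (plus
#' `soa_ms` when the schedule carries assigned stop-signal delays);
#' `read_events()` reads it back into a `stop_schedule` tibble so that the
#' pair round-trips losslessly.
#'
#' @param schedule A validated `stop_schedule` tibble.
#' @param path File path of the TSV.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   the schedule tibble.
#' @export
write_events <- function(schedule, path) {
  validate_schedule(schedule)
  out <- tibble(
    onset = schedule$onset_s,
    duration = schedule$duration_s,
    trial_type = schedule$stimulus,
    context = schedule$context,
    stop_relevant = schedule$stop_relevant
  )
  if ("soa_ms" %in% names(schedule)) out$soa_ms <- schedule$soa_ms
  if ("jitter_ms" %in% names(schedule)) out$jitter_ms <- schedule$jitter_ms
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sched <- tibble(
    trial = seq_len(nrow(ev)),
    context = as.integer(ev$context),
    stimulus = ev$trial_type,
    stop_relevant = as.logical(ev$stop_relevant),
    run = {
      ctx <- as.integer(ev$context)
      if (length(ctx)) cumsum(c(1L, as.integer(diff(ctx) != 0))) else integer(0)
    },
    jitter_ms = if ("jitter_ms" %in% names(ev)) as.integer(ev$jitter_ms) else
      NA_integer_,
    onset_s = ev$onset,
    duration_s = ev$duration
  )
  if ("soa_ms" %in% names(ev)) sched$soa_ms <- ev$soa_ms
  class(sched) <- c("stop_schedule", class(sched))
  sched
}
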