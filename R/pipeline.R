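#' Default EEG effect pattern for the pipeline generator
#'
#' Qualitative pattern used by the end-to-end simulation: stop-relevant
#' deviants in context 1 raise frontocentral delta and theta power relative
#' to go trials, the same stimulus in context 2 shows an attenuated theta
#' effect, and stop trials carry a left-motor high-beta increase.
#'
#' @return Effect tibble for [synthesize_epochs()].
#' @export
default_effect_spec <- function() {
  bind_rows(
    ersp_effect("delta", "frontocentral", 2.0, stimulus = "stim1", context = 1),
    ersp_effect("theta", "frontocentral", 3.0, stimulus = "stim1", context = 1),
    ersp_effect("theta", "frontocentral", 1.5, stimulus = "stim1", context = 2),
    ersp_effect("high_beta", "left_motor", 1.0, stimulus = "stim1", context = 1)
  )
}

#' Assemble a full pipeline configuration
#'
#' One configuration drives schedule generation, behavioural simulation,
#' summary statistics, EEG synthesis + ERSP features, and the EEG-informed
#' GLM. All stage seeds are derived deterministically from the master seed
#' given to [run_pipeline()].
#'
#' @param design A [design_config()].
#' @param params A [subject_params()] (shared across subjects).
#' @param n_subjects Cohort size.
#' @param staircase A [staircase_state()] template.
#' @param effects EEG effect table ([ersp_effect()] rows).
#' @param bands Band/window table used for features and validation.
#' @param eeg List: `trials` (maximum epochs synthesized, stratified over
#'   conditions), `channels`, `trial_sdlog`, `noise`, `analysis`.
#' @param glm List: `tr`, `sigma`, `ar1_rho`, `coupling` (named vector of
#'   true modulation betas, e.g. `c(theta = 0.8)`), `highpass_s`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            params = subject_params(),
                            n_subjects = 21,
                            staircase = staircase_state(),
                            effects = default_effect_spec(),
                            bands = band_windows(),
                            eeg = list(),
                            glm = list()) {
  eeg <- modifyList(
    list(trials = 240, channels = ersp_channels(), trial_sdlog = 0.5,
         noise = noise_spec(), analysis = ersp_analysis()),
    eeg)
  glm <- modifyList(
    list(tr = 2, sigma = 1, ar1_rho = 0.3, coupling = c(theta = 0.8),
         highpass_s = 128),
    glm)
  structure(
    list(design = design, params = params, n_subjects = n_subjects,
         staircase = staircase, effects = effects, bands = bands,
         eeg = eeg, glm = glm),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Returns a tibble of findings (`level` is `"error"` or `"warning"`): trial
#' counts that cannot be partitioned into allowed run lengths, feature
#' windows outside the analysable epoch, degenerate probability parameters,
#' and staircase steps whose implied equilibrium failure rate
#' `step_up / (step_up + step_down)` differs from the conventional 20%
#' target.
#'
#' @param config A [pipeline_config()].
#' @return Tibble with columns `level`, `message`; zero rows when the
#'   configuration is clean.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- list()
  add <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- tibble(level = level, message = msg)
  }
  # run partition feasibility: some a with 13a <= total <= 18a
  total <- config$design$n_per_context
  rr <- config$design$run_range
  feasible <- total == 0 ||
    floor(total / rr[1]) >= ceiling(total / rr[2])
  if (!feasible) {
    add("error", sprintf(
      "per-context total %d cannot be split into runs of %d-%d trials",
      total, rr[1], rr[2]))
  }
  an <- config$eeg$analysis
  for (i in seq_len(nrow(config$bands))) {
    bw <- config$bands[i, ]
    if (bw$t_hi > max(an$times) || bw$t_lo < min(an$times)) {
      add("error", sprintf(
        "band %s window [%g, %g] ms lies outside the analysable frames [%g, %g] ms",
        bw$band, bw$t_lo, bw$t_hi, min(an$times), max(an$times)))
    }
    if (bw$f_hi <= min(an$freqs)) {
      add("error", sprintf("band %s lies below the analysis frequency grid",
                           bw$band))
    }
  }
  if (config$params$p_go_omission >= 0.5) {
    add("warning", "p_go_omission >= 0.5: go RT distribution mostly censored")
  }
  if (config$params$p_trigger_failure >= 0.5) {
    add("warning", "p_trigger_failure >= 0.5: staircase tracking will stall")
  }
  st <- config$staircase
  eq <- st$step_up_ms / (st$step_up_ms + st$step_down_ms)
  if (abs(eq - 0.2) > 1e-9) {
    add("warning", sprintf(
      "staircase steps imply an equilibrium failure rate of %.3f, not the conventional 0.20",
      eq))
  }
  if (!is.null(config$effects) && nrow(config$effects)) {
    bad <- setdiff(config$effects$band, config$bands$band)
    if (length(bad)) add("error", paste("effects name unknown band:", bad[1]))
  }
  if (length(findings)) bind_rows(findings) else
    tibble(level = character(), message = character())
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes schedule generation, behavioural simulation with adaptive SOA
#' tracking, behavioural summaries, EEG epoch synthesis + ERSP feature
#' extraction, and the EEG-informed GLM, writing tabular outputs and a JSON
#' run log into `out_dir`. Everything is reproducible from `seed`.
#'
#' Written files: one BIDS-style events TSV per subject, `records.tsv` (all
#' behavioural records), `behavior_summary.csv`, `ersp_features.csv`
#' (per-trial), `ersp_condition_means.csv`, `glm_results.csv`, and
#' `run_log.json` (stage seeds, file checksums, versions).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param stages Subset of `c("behavior", "eeg", "glm")` to run (later stages
#'   need earlier ones).
#' @return Invisibly, a list with the in-memory results (`records`,
#'   `summary`, `features`, `condition_features`, `fit`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1,
                         stages = c("behavior", "eeg", "glm")) {
  stages <- match.arg(stages, several.ok = TRUE)
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid pipeline config:\n  ",
         paste(findings$message[findings$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  for (w in findings$message[findings$level == "warning"]) warning(w, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 3L)
  paths <- character(0)
  out <- list()

  # --- behaviour ---------------------------------------------------------
  records <- stage_try("behavior", {
    simulate_cohort(n_subjects = config$n_subjects, params = config$params,
                    config = config$design, seed = seeds[1])
  })
  schedules <- attr(records, "schedules")
  for (s in seq_along(schedules)) {
    sched <- schedules[[s]]
    rec_s <- records[records$subject == s, ]
    sched$soa_ms <- rec_s$soa_ms
    p <- file.path(out_dir, sprintf("sub-%02d_events.tsv", s))
    write_events(sched, p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "records.tsv")
  readr::write_tsv(records, p); paths <- c(paths, p)
  summary_tbl <- summarize_behavior(records)
  p <- file.path(out_dir, "behavior_summary.csv")
  readr::write_csv(summary_tbl, p); paths <- c(paths, p)
  out$records <- records
  out$summary <- summary_tbl

  # --- EEG ---------------------------------------------------------------
  if ("eeg" %in% stages) {
    eegres <- stage_try("eeg", {
      rec1 <- records[records$subject == 1, ]
      rec1 <- select(rec1, -"subject")
      # stratified trial subset: deviants first, go trials fill the rest
      dev <- which(rec1$stimulus != "go")
      go <- which(rec1$stimulus == "go")
      n_total <- min(config$eeg$trials, nrow(rec1))
      keep <- if (length(dev) >= n_total) {
        with_seed(seeds[2] + 1L, sort(sample(dev, n_total)))
      } else {
        with_seed(seeds[2] + 1L,
                  sort(c(dev, sample(go, n_total - length(dev)))))
      }
      rec_eeg <- rec1[keep, ]
      ep <- synthesize_epochs(rec_eeg, effects = config$effects,
                              channels = config$eeg$channels,
                              noise = config$eeg$noise,
                              trial_sdlog = config$eeg$trial_sdlog,
                              analysis = config$eeg$analysis,
                              seed = seeds[2])
      db <- baseline_normalize(compute_ersp(ep))
      # only EOIs fully covered by the synthesized channels are extractable
      eois <- eoi_sets() %>%
        group_by(.data$eoi) %>%
        filter(all(.data$electrode %in% config$eeg$channels)) %>%
        ungroup()
      if (!nrow(eois)) abort_input("no EOI fully covered by eeg$channels")
      feats <- extract_features(db, bands = config$bands, eois = eois)
      grp <- paste(rec_eeg$stimulus, rec_eeg$context, sep = "_c")
      cond <- extract_features(db, bands = config$bands, eois = eois,
                               average_by = grp)
      list(rec_eeg = rec_eeg, feats = feats, cond = cond)
    })
    feats <- left_join(eegres$feats,
                       mutate(eegres$rec_eeg,
                              row = row_number())[, c("row", "trial", "context",
                                                      "stimulus", "outcome")] %>%
                         rename(schedule_trial = "trial"),
                       by = c(trial = "row"))
    p <- file.path(out_dir, "ersp_features.csv")
    readr::write_csv(feats, p); paths <- c(paths, p)
    p <- file.path(out_dir, "ersp_condition_means.csv")
    readr::write_csv(eegres$cond, p); paths <- c(paths, p)
    out$features <- feats
    out$condition_features <- eegres$cond
  }

  # --- GLM ---------------------------------------------------------------
  if ("glm" %in% stages && "eeg" %in% stages) {
    fit <- stage_try("glm", {
      rec_eeg <- eegres$rec_eeg
      sched1 <- schedules[[1]]
      onsets <- sched1$onset_s[match(rec_eeg$trial, sched1$trial)]
      feats_w <- eegres$feats %>%
        filter((.data$band %in% c("delta", "theta") &
                  .data$eoi == "frontocentral") |
                 (.data$band == "high_beta" & .data$eoi == "left_motor")) %>%
        select("trial", "band", "db") %>%
        tidyr::pivot_wider(names_from = "band", values_from = "db")
      mods <- as.data.frame(feats_w[, c("delta", "theta", "high_beta")])
      ev <- tibble(onset = onsets,
                   condition = paste0(rec_eeg$stimulus, "_c", rec_eeg$context))
      # desk scale: one event regressor + its three band modulators
      ev$condition <- "event"
      tr <- config$glm$tr
      n_scans <- ceiling((max(onsets) + 32) / tr)
      des <- build_design(ev, mods, n_scans = n_scans, tr = tr,
                          highpass_s = config$glm$highpass_s)
      true_b <- c(event = 1)
      for (nm in names(config$glm$coupling)) {
        true_b[paste0("event:", nm)] <- config$glm$coupling[[nm]]
      }
      y <- synthesize_bold(des, true_b, sigma = config$glm$sigma,
                           ar1_rho = config$glm$ar1_rho, seed = seeds[3])
      fit_glm(y, des, prewhiten = TRUE)
    })
    p <- file.path(out_dir, "glm_results.csv")
    readr::write_csv(tidy(fit), p); paths <- c(paths, p)
    out$fit <- fit
  }

  log <- list(
    package = "contextstop",
    version = as.character(utils::packageVersion("contextstop")),
    master_seed = seed,
    stage_seeds = list(behavior = seeds[1], eeg = seeds[2], glm = seeds[3]),
    stages = stages,
    n_subjects = config$n_subjects,
    outputs = lapply(stats::setNames(paths, basename(paths)),
                     function(p) unname(tools::md5sum(p)))
  )
  p <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, p, auto_unbox = TRUE, pretty = TRUE)
  out$paths <- c(paths, p)
  invisible(out)
}
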