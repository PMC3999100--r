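#' Stop-trial response rate
#'
#' The fraction of stop-relevant trials on which a response was emitted
#' (failed stops / all stop trials) — the stop-signal task's accuracy
#' measure, tracked toward ~20% by the adaptive staircase.
#'
#' @param records Behavioural records from [simulate_session()] (optionally
#'   filtered).
#' @param context Optional context (1-3) to restrict to.
#' @return A proportion in \[0, 1\].
#' @export
response_rate <- function(records, context = NULL) {
  if (!is.null(context)) records <- records[records$context == context, ]
  stop_trials <- records[records$stop_relevant, ]
  if (nrow(stop_trials) == 0L) {
    abort_input("response rate undefined: no stop-relevant trials")
  }
  mean(stop_trials$responded)
}

#' Integration-method estimate of the stop-signal reaction time
#'
#' Under the horse-race model the stop process's finishing time corresponds
#' to the go-RT at position `n` of the ascending go-RT distribution, where
#' `n` is the number of go RTs multiplied by the stop-trial response rate.
#' The SSRT is that quantile minus the mean stop-signal delay. Go omissions
#' (`NA` RTs) are replaced by the maximum observed RT before taking the
#' quantile, the standard guard that keeps the quantile honest when slow
#' responses are censored.
#'
#' @param go_rts Numeric go reaction times in ms; `NA` marks omissions.
#' @param rr Response rate on stop trials, strictly between 0 and 1.
#' @param mean_soa_ms Mean stop-signal delay over stop-relevant trials.
#' @param rounding How to turn `N * rr` into a rank: `"ceiling"`
#'   (conservative nth-fastest, default) or `"nearest"`.
#' @return SSRT in ms.
#' @export
#' @examples
#' ssrt_integration(c(400, 450, 500, 550, 600), rr = 0.4, mean_soa_ms = 150)
ssrt_integration <- function(go_rts, rr, mean_soa_ms,
                             rounding = c("ceiling", "nearest")) {
  rounding <- match.arg(rounding)
  if (length(go_rts) == 0L) abort_input("go_rts must be non-empty")
  if (!is.finite(rr) || rr <= 0 || rr >= 1) {
    abort_input("SSRT undefined: response rate must lie strictly in (0, 1)")
  }
  if (all(is.na(go_rts))) abort_input("go_rts contains no observed RTs")
  rts <- go_rts
  rts[is.na(rts)] <- max(rts, na.rm = TRUE)
  rts <- sort(rts)
  n_rank <- switch(rounding,
    ceiling = ceiling(length(rts) * rr),
    nearest = round(length(rts) * rr)
  )
  n_rank <- min(max(n_rank, 1L), length(rts))
  rts[n_rank] - mean_soa_ms
}

summarise_one_context <- function(records) {
  go <- records[records$outcome == "go_correct", ]
  go_all <- records[records$stimulus == "go", ]
  stop_rel <- records[records$stop_relevant, ]
  irrel <- records[!records$stop_relevant & records$stimulus != "go", ]
  failed <- records[records$outcome == "stop_fail", ]

  rr <- if (nrow(stop_rel)) mean(stop_rel$responded) else NA_real_
  mean_soa <- if (nrow(stop_rel)) mean(stop_rel$soa_ms) else NA_real_
  ssrt <- if (nrow(stop_rel) && nrow(go_all) && is.finite(rr) &&
              rr > 0 && rr < 1 && any(!is.na(go_all$rt_ms))) {
    ssrt_integration(go_all$rt_ms, rr, mean_soa)
  } else NA_real_

  tibble(
    n_go = nrow(go_all),
    n_stop = nrow(stop_rel),
    go_rt = if (nrow(go)) mean(go$rt_ms) else NA_real_,
    go_rt_sem = if (nrow(go) > 1) sd(go$rt_ms) / sqrt(nrow(go)) else NA_real_,
    rr = rr,
    mean_soa = mean_soa,
    ssrt = ssrt,
    failed_stop_rt = if (nrow(failed)) mean(failed$rt_ms) else NA_real_,
    irrelevant_accuracy = if (nrow(irrel)) mean(irrel$responded) else NA_real_,
    irrelevant_rt = if (any(irrel$responded)) {
      mean(irrel$rt_ms[irrel$responded])
    } else NA_real_
  )
}

#' Per-context behavioural summary
#'
#' Computes, per context, the go-RT mean and SEM (correct pure-go trials
#' only), the stop-trial response rate, the mean stop-signal delay, the
#' integration-method SSRT, the mean RT on failed stop trials, and accuracy
#' and RT on stop-irrelevant deviant trials. With a `subject` column the
#' statistics are computed per subject and then averaged, and the SEM is the
#' between-subject SEM; otherwise SEMs are across trials. Contexts missing
#' from the records appear as rows of `NA`.
#'
#' @param records Behavioural records, optionally with a `subject` column.
#' @return A tibble of class `behavior_summary`, one row per context.
#' @export
summarize_behavior <- function(records) {
  by_subject <- "subject" %in% names(records) &&
    length(unique(records$subject)) > 1L
  ctxs <- 1:3
  if (by_subject) {
    per <- records %>%
      group_by(.data$subject, .data$context) %>%
      group_modify(~ summarise_one_context(.x)) %>%
      ungroup()
    out <- lapply(ctxs, function(cx) {
      d <- per[per$context == cx, ]
      if (!nrow(d)) {
        return(tibble(context = cx, summarise_one_context(records[0, ])))
      }
      sem <- function(x) {
        x <- x[is.finite(x)]
        if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
      }
      m <- function(x) mean(x[is.finite(x)])
      tibble(
        context = cx,
        n_go = sum(d$n_go), n_stop = sum(d$n_stop),
        go_rt = m(d$go_rt), go_rt_sem = sem(d$go_rt),
        rr = m(d$rr), mean_soa = m(d$mean_soa),
        ssrt = m(d$ssrt), failed_stop_rt = m(d$failed_stop_rt),
        irrelevant_accuracy = m(d$irrelevant_accuracy),
        irrelevant_rt = m(d$irrelevant_rt)
      )
    })
    out <- bind_rows(out)
    attr(out, "sem_basis") <- "between-subject"
  } else {
    out <- bind_rows(lapply(ctxs, function(cx) {
      tibble(context = cx,
             summarise_one_context(records[records$context == cx, ]))
    }))
    attr(out, "sem_basis") <- "between-trial"
  }
  class(out) <- c("behavior_summary", class(out))
  out
}
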