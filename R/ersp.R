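#' Frequency-band and time-window definitions for ERSP feature extraction
#'
#' Defaults follow the stop-signal time-frequency literature: delta (0-4 Hz)
#' in the 300-400 ms window of the P3 complex, theta (4-8 Hz) in the 150-250
#' ms window of the N2, and low/high beta (12-21 / 21-30 Hz) between 220 and
#' 500 ms. Times are ms post stimulus onset.
#'
#' @return Tibble with columns `band`, `f_lo`, `f_hi`, `t_lo`, `t_hi`.
#' @export
band_windows <- function() {
  tibble(
    band = c("delta", "theta", "low_beta", "high_beta"),
    f_lo = c(0, 4, 12, 21),
    f_hi = c(4, 8, 21, 30),
    t_lo = c(300, 150, 220, 220),
    t_hi = c(400, 250, 500, 500)
  )
}

#' Electrode sites of interest (EOIs)
#'
#' Clusters of 10-10 electrodes whose ERSP values are averaged: frontocentral
#' and centroparietal midline clusters (delta/theta), left and right inferior
#' frontal, and left and right motor clusters (beta).
#'
#' @return Long tibble with columns `eoi`, `electrode`.
#' @export
eoi_sets <- function() {
  sets <- list(
    frontocentral = c("F1", "F2", "FC1", "FC2", "FCz", "Cz"),
    centroparietal = c("C1", "C2", "CP1", "CP2", "CPz", "Pz"),
    left_frontal = c("F7", "F5", "AF3", "AF7"),
    right_frontal = c("F6", "F4", "AF4", "AF8"),
    left_motor = c("C5", "C3", "CP3"),
    right_motor = c("C4", "C6", "CP4")
  )
  tibble(
    eoi = rep(names(sets), lengths(sets)),
    electrode = unlist(sets, use.names = FALSE)
  )
}

#' All channels required by the default EOI sets
#' @return Character vector of 10-10 electrode labels.
#' @export
ersp_channels <- function() unique(eoi_sets()$electrode)

#' Analysis grid and estimator settings for the time-frequency decomposition
#'
#' The decomposition is a Morlet-wavelet (Gaussian-windowed complex
#' exponential) filter bank with a constant spectral bandwidth `sigma_f`,
#' equivalent to a Gabor transform with temporal sd `1/(2*pi*sigma_f)`
#' (~227 ms at the default 0.7 Hz). `freqs` is a linear grid of 100 steps; 0
#' Hz itself is unattainable for a finite epoch, so the grid starts at 2 Hz,
#' the lowest frequency whose wavelet fits the 800 ms pre-stimulus interval.
#' Frame `times` (ms) are spaced 20 ms apart and restricted so the wavelet's
#' +/-2 sd support stays inside the epoch.
#'
#' @param freqs Analysis frequencies in Hz.
#' @param times Frame centres in ms relative to stimulus onset.
#' @param sigma_f Spectral bandwidth (Gaussian sd) in Hz.
#' @param srate Sampling rate in Hz.
#' @param t_lim Epoch span in ms.
#' @return List of class `ersp_analysis`.
#' @export
ersp_analysis <- function(freqs = seq(2, 35, length.out = 100),
                          times = seq(-344, 756, by = 20),
                          sigma_f = 0.7, srate = 250,
                          t_lim = c(-800, 1212)) {
  sigma_t <- 1000 / (2 * pi * sigma_f) # ms
  if (any(times - 2 * sigma_t < t_lim[1]) || any(times + 2 * sigma_t > t_lim[2])) {
    abort_input("frame times leave less than 2 wavelet sds inside the epoch")
  }
  if (min(freqs) < 2.5 * sigma_f) {
    abort_input("lowest analysis frequency must exceed 2.5 x sigma_f")
  }
  structure(list(freqs = freqs, times = times, sigma_f = sigma_f,
                 sigma_t = sigma_t, srate = srate, t_lim = t_lim),
            class = "ersp_analysis")
}

#' Background-noise spectrum of the synthetic EEG
#'
#' Power spectral density `scale^2 / (f + knee)^alpha`: 1/f ("pink")
#' background with a low-frequency knee, the standard first-order description
#' of resting scalp EEG.
#'
#' @param scale Amplitude scale in microvolts.
#' @param alpha Spectral exponent.
#' @param knee Knee frequency in Hz.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(scale = 5, alpha = 1, knee = 1) {
  if (scale <= 0 || alpha < 0 || knee <= 0) abort_input("invalid noise spectrum")
  structure(list(scale = scale, alpha = alpha, knee = knee),
            class = "noise_spec")
}

# Two-sided circular PSD on the n-point DFT grid (per-bin variance
# convention: E|FFT(x)_k|^2 = n * S_k).
psd_grid <- function(noise, n, srate) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * srate / n
  noise$scale^2 / (f + noise$knee)^noise$alpha
}

# Real Gaussian signals (columns) with circular PSD S; fixed RNG consumption.
rnoise_spec <- function(n_signals, S) {
  n <- length(S)
  w <- matrix(rnorm(n * n_signals), n, n_signals)
  X <- mvfft(w) * sqrt(S)
  Re(mvfft(X, inverse = TRUE)) / n
}

# Raised-cosine-edged envelope: plateau over [t_on, t_off] ms with ramps.
burst_envelope <- function(times_ms, t_on, t_off, ramp_ms = 50) {
  e <- numeric(length(times_ms))
  core <- times_ms >= t_on & times_ms <= t_off
  e[core] <- 1
  up <- times_ms >= t_on - ramp_ms & times_ms < t_on
  e[up] <- 0.5 * (1 + cos(pi * (t_on - times_ms[up]) / ramp_ms))
  dn <- times_ms > t_off & times_ms <= t_off + ramp_ms
  e[dn] <- 0.5 * (1 + cos(pi * (times_ms[dn] - t_off) / ramp_ms))
  e
}

# Complex Morlet kernel at frequency f (Hz), unit L2 norm, support +/-3 sd.
morlet_kernel <- function(f, analysis) {
  sig_t <- analysis$sigma_t / 1000
  half <- ceiling(3 * sig_t * analysis$srate)
  t <- (-half:half) / analysis$srate
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sig_t^2))
  k / sqrt(sum(Mod(k)^2))
}

# Wavelet coefficients of the columns of x (samples x signals) at one
# frequency, evaluated at all epoch samples, energy-corrected at the edges.
wavelet_coef <- function(x, f, analysis, npad = NULL) {
  n <- nrow(x)
  k <- morlet_kernel(f, analysis)
  half <- (length(k) - 1L) / 2L
  npad <- npad %||% 2^ceiling(log2(n + length(k)))
  kp <- complex(length.out = npad)
  kp[1:(half + 1L)] <- k[(half + 1L):length(k)]        # offsets 0..half
  kp[(npad - half + 1L):npad] <- k[1:half]             # offsets -half..-1
  xp <- rbind(x, matrix(0, npad - n, ncol(x)))
  K <- Conj(fft(kp))
  W <- mvfft(mvfft(xp) * K, inverse = TRUE)[1:n, , drop = FALSE] / npad
  # in-epoch kernel energy per centre position (edge correction)
  ones <- matrix(1, n, 1)
  Kq <- Conj(fft({
    kq <- complex(length.out = npad)
    kq[1:(half + 1L)] <- Mod(k[(half + 1L):length(k)])^2
    kq[(npad - half + 1L):npad] <- Mod(k[1:half])^2
    kq
  }))
  onesp <- rbind(ones, matrix(0, npad - n, 1))
  q <- Re(mvfft(mvfft(onesp) * Kq, inverse = TRUE)[1:n, 1]) / npad
  list(coef = W, q = pmax(q, 1e-12))
}

#' Synthesize stimulus-locked EEG epochs with calibrated band-power effects
#'
#' Generates, for every trial in `records`, multichannel epochs of 1/f
#' Gaussian background noise (250 Hz, -800..1212 ms) and adds band-limited
#' noise bursts to the trials, channels, bands and time windows named in
#' `effects`. Burst amplitudes are calibrated against the analytic expected
#' wavelet power of the background so that the condition-averaged ERSP
#' feature of affected trials exceeds that of unaffected trials by the
#' requested dB — the calibration is computed from the analysis parameters
#' before any data are drawn. Trial-to-trial burst power varies lognormally
#' (`trial_sdlog`) around unit mean; realized per-trial power scales are
#' stored as ground truth in attribute `"truth"`.
#'
#' @param records Behavioural records ([simulate_session()]); one epoch per
#'   row.
#' @param effects Effect table from [ersp_effect()] (or `NULL` for pure
#'   noise).
#' @param channels Channel labels to synthesize.
#' @param noise A [noise_spec()].
#' @param trial_sdlog Lognormal sd of the per-trial burst power scale.
#' @param analysis The [ersp_analysis()] the calibration should target.
#' @param seed Optional seed.
#' @return Object of class `eeg_epochs`: list with `data` (trials x channels
#'   x samples array, microvolts), `times` (ms), `srate`, `channels`,
#'   `records`, `effects`.
#' @export
synthesize_epochs <- function(records, effects = NULL,
                              channels = ersp_channels(),
                              noise = noise_spec(), trial_sdlog = 0.5,
                              analysis = ersp_analysis(), seed = NULL) {
  srate <- analysis$srate
  times <- seq(analysis$t_lim[1], analysis$t_lim[2], by = 1000 / srate)
  n_s <- length(times)
  n_t <- nrow(records)
  n_c <- length(channels)
  S <- psd_grid(noise, n_s, srate)
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects))
    bad <- setdiff(eoi_sets()$electrode[eoi_sets()$eoi %in% effects$eoi],
                   channels)
    unknown_eoi <- setdiff(effects$eoi, unique(eoi_sets()$eoi))
    if (length(unknown_eoi)) {
      abort_input(paste("unknown EOI in effects:", unknown_eoi[1]))
    }
    if (length(bad)) {
      abort_input(paste("effect electrode(s) not synthesized:",
                        paste(bad, collapse = ", ")))
    }
  }
  with_seed(seed, {
    data <- array(0, dim = c(n_t, n_c, n_s),
                  dimnames = list(NULL, channels, NULL))
    for (i in seq_len(n_t)) {
      data[i, , ] <- t(rnoise_spec(n_c, S))
    }
    truth <- NULL
    if (!is.null(effects) && nrow(effects)) {
      bands <- band_windows()
      eois <- eoi_sets()
      truth <- vector("list", nrow(effects))
      for (j in seq_len(nrow(effects))) {
        ef <- effects[j, ]
        bw <- bands[bands$band == ef$band, ]
        if (!nrow(bw)) abort_input(paste("unknown band:", ef$band))
        sel <- rep(TRUE, n_t)
        if (!is.na(ef$stimulus)) sel <- sel & records$stimulus == ef$stimulus
        if (!is.na(ef$context)) sel <- sel & records$context == ef$context
        if ("outcome" %in% names(ef) && !is.na(ef$outcome)) {
          sel <- sel & records$outcome == ef$outcome
        }
        idx <- which(sel)
        if (!length(idx)) { truth[[j]] <- NULL; next }
        chans <- eois$electrode[eois$eoi == ef$eoi]
        g2 <- calibrate_burst_gain(ef$db, bw, noise, analysis)
        env <- burst_envelope(times, bw$t_lo - analysis$sigma_t,
                              bw$t_hi + analysis$sigma_t)
        mask <- burst_band_mask(bw, n_s, srate, analysis)
        L <- rlnorm(n_t, meanlog = -trial_sdlog^2 / 2, sdlog = trial_sdlog)
        for (i in idx) {
          b <- rnoise_spec(length(chans), S * mask)
          data[i, chans, ] <- data[i, chans, , drop = FALSE][1, , ] +
            t(sqrt(g2 * L[i]) * env * b)
        }
        truth[[j]] <- tibble(
          trial = idx, band = ef$band, eoi = ef$eoi, db_nominal = ef$db,
          power_scale = g2 * L[idx]
        )
      }
      truth <- bind_rows(truth)
    }
    structure(
      list(data = data, times = times, srate = srate, channels = channels,
           records = records, effects = effects, noise = noise,
           analysis = analysis),
      truth = truth,
      class = "eeg_epochs"
    )
  })
}

# Spectral support of an injected burst: the analyzable part of the band,
# with a 0.5 Hz guard inside each edge to limit spill into neighbours.
burst_band_mask <- function(bw, n, srate, analysis, guard = 0.5) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * srate / n
  lo <- max(bw$f_lo, min(analysis$freqs)) + guard
  hi <- bw$f_hi - guard
  if (hi <= lo) { # degenerate narrow band: centre line only
    mid <- (max(bw$f_lo, min(analysis$freqs)) + bw$f_hi) / 2
    return(as.numeric(abs(f - mid) <= srate / n))
  }
  as.numeric(f >= lo & f <= hi)
}

# Expected wavelet power of (masked, enveloped) unit-scale burst noise and of
# the background at frame centres `centres_ms`, for one frequency.
expected_powers <- function(f, centres_ms, env, S, mask, analysis, times_ms) {
  n <- length(times_ms)
  k <- morlet_kernel(f, analysis)
  half <- (length(k) - 1L) / 2L
  srate <- analysis$srate
  vapply(centres_ms, function(cm) {
    ci <- which.min(abs(times_ms - cm))
    lo <- max(1L, ci - half); hi <- min(n, ci + half)
    psi <- complex(length.out = n)
    psi[lo:hi] <- k[(lo - ci + half + 1L):(hi - ci + half + 1L)]
    u_burst <- env * Conj(psi)
    u_bg <- Conj(psi)
    a <- sum(S * mask * Mod(fft(u_burst))^2) / n
    b <- sum(S * Mod(fft(u_bg))^2) / n
    c(a, b)
  }, numeric(2))
}

# Solve for the burst power gain g^2 such that the expected condition-average
# feature contrast (affected minus unaffected trials) equals `db_target`.
calibrate_burst_gain <- function(db_target, bw, noise, analysis) {
  if (db_target == 0) return(0)
  times_ms <- seq(analysis$t_lim[1], analysis$t_lim[2],
                  by = 1000 / analysis$srate)
  n <- length(times_ms)
  S <- psd_grid(noise, n, analysis$srate)
  mask <- burst_band_mask(bw, n, analysis$srate, analysis)
  env <- burst_envelope(times_ms, bw$t_lo - analysis$sigma_t,
                        bw$t_hi + analysis$sigma_t)
  bins <- analysis$freqs[analysis$freqs > bw$f_lo & analysis$freqs <= bw$f_hi]
  frames <- analysis$times[analysis$times >= bw$t_lo &
                             analysis$times <= bw$t_hi]
  if (!length(bins) || !length(frames)) {
    abort_input("band window lies outside the analysis grid")
  }
  ab <- lapply(bins, function(f) {
    expected_powers(f, frames, env, S, mask, analysis, times_ms)
  })
  ratio <- unlist(lapply(ab, function(m) m[1, ] / m[2, ])) # a/b per (f, frame)
  fdb <- function(g2) mean(10 * log10(1 + g2 * ratio)) - db_target
  if (db_target > 0) {
    uniroot(fdb, c(1e-9, 1e9), tol = 1e-10)$root
  } else {
    abort_input("negative dB effects are expressed by boosting the other condition")
  }
}

#' Time-frequency power decomposition of EEG epochs
#'
#' Applies the Morlet filter bank of [ersp_analysis()] to every trial and
#' channel and returns power at each analysis frequency and frame time.
#' Coefficients near the epoch edges are energy-corrected for the truncated
#' part of the wavelet.
#'
#' @param epochs An `eeg_epochs` object (or a plain trials x channels x
#'   samples array with matching `analysis`).
#' @param analysis An [ersp_analysis()]; defaults to the one the epochs were
#'   synthesized for.
#' @return Object of class `ersp_power`: list with `power` (trials x channels
#'   x freqs x times, microvolts squared), `freqs`, `times`, `channels`.
#' @export
compute_ersp <- function(epochs, analysis = NULL) {
  if (inherits(epochs, "eeg_epochs")) {
    analysis <- analysis %||% epochs$analysis
    data <- epochs$data
    channels <- epochs$channels
    times_ms <- epochs$times
  } else {
    if (is.null(analysis)) abort_input("analysis parameters required")
    data <- epochs
    channels <- dimnames(data)[[2]] %||% paste0("ch", seq_len(dim(data)[2]))
    times_ms <- seq(analysis$t_lim[1], analysis$t_lim[2],
                    by = 1000 / analysis$srate)
  }
  if (dim(data)[3] != length(times_ms)) {
    abort_input("epoch length does not match the analysis epoch span")
  }
  lowest_ok <- min(analysis$freqs) >= 2.5 * analysis$sigma_f
  if (!lowest_ok) abort_input("epoch too short for the lowest frequency")
  frame_idx <- vapply(analysis$times, function(tm) {
    which.min(abs(times_ms - tm))
  }, integer(1))
  n_t <- dim(data)[1]; n_c <- dim(data)[2]
  nf <- length(analysis$freqs); nt <- length(frame_idx)
  power <- array(NA_real_, dim = c(n_t, n_c, nf, nt),
                 dimnames = list(NULL, channels, NULL, NULL))
  n_s <- dim(data)[3]
  for (ch in seq_len(n_c)) {
    x <- t(matrix(data[, ch, ], n_t, n_s)) # samples x trials
    for (fi in seq_len(nf)) {
      wc <- wavelet_coef(x, analysis$freqs[fi], analysis)
      p <- (Mod(wc$coef)^2 / wc$q)[frame_idx, , drop = FALSE]
      power[, ch, fi, ] <- t(p)
    }
  }
  structure(list(power = power, freqs = analysis$freqs,
                 times = analysis$times, channels = channels,
                 analysis = analysis),
            class = "ersp_power")
}

#' Construct an `ersp_power` object from a power array
#'
#' Mainly for building small synthetic test cases; [compute_ersp()] is the
#' normal constructor.
#'
#' @param power Trials x channels x freqs x times array of non-negative power.
#' @param freqs,times,channels Grid labels matching the array dimensions.
#' @return An `ersp_power` object.
#' @export
ersp_power <- function(power, freqs, times, channels) {
  stopifnot(length(dim(power)) == 4, dim(power)[2] == length(channels),
            dim(power)[3] == length(freqs), dim(power)[4] == length(times))
  dimnames(power)[[2]] <- channels
  structure(list(power = power, freqs = freqs, times = times,
                 channels = channels, analysis = NULL),
            class = "ersp_power")
}

#' Baseline-normalize time-frequency power to dB (ERSP)
#'
#' Divides power by the frequency- and channel-specific mean power over the
#' pre-stimulus baseline window (averaged over all trials and baseline
#' frames, condition-blind) and converts to decibels, `10*log10(ratio)`.
#'
#' @param x An `ersp_power` object.
#' @param baseline Two-element window in ms (default -800 to -100).
#' @return Object of class `ersp_db`: like `ersp_power` but with a `db` array
#'   and the `baseline_power` (channels x freqs) retained.
#' @export
baseline_normalize <- function(x, baseline = c(-800, -100)) {
  stopifnot(inherits(x, "ersp_power"))
  bidx <- which(x$times >= baseline[1] & x$times <= baseline[2])
  if (!length(bidx)) abort_input("no analysis frames inside the baseline window")
  bp <- apply(x$power[, , , bidx, drop = FALSE], c(2, 3), mean)
  if (any(bp <= 0) || any(!is.finite(bp))) {
    abort_input("degenerate input: zero baseline power")
  }
  db <- 10 * log10(sweep(x$power, c(2, 3), bp, "/"))
  structure(list(db = db, power = x$power, baseline_power = bp,
                 freqs = x$freqs, times = x$times, channels = x$channels,
                 baseline = baseline, analysis = x$analysis),
            class = "ersp_db")
}

#' Extract band x window x EOI ERSP features
#'
#' Per-trial features average the dB values over the band's frequency bins
#' (`f_lo < f <= f_hi`), the window's frame times and the EOI's electrodes.
#' With `average_by`, trials are first averaged in the power domain within
#' each group (the condition-average ERSP), converted to dB against the same
#' all-trial baseline, and then averaged over bins, frames and electrodes.
#'
#' @param x An `ersp_db` object from [baseline_normalize()].
#' @param bands Band/window table, see [band_windows()].
#' @param eois EOI table, see [eoi_sets()].
#' @param average_by Optional grouping vector (length = number of trials).
#' @return Tidy tibble: (`trial` | `group`), `band`, `eoi`, `db`.
#' @export
extract_features <- function(x, bands = band_windows(), eois = eoi_sets(),
                             average_by = NULL) {
  stopifnot(inherits(x, "ersp_db"))
  missing_el <- setdiff(unique(eois$electrode), x$channels)
  if (length(missing_el)) {
    abort_input(paste("electrode(s) missing from the data:",
                      paste(missing_el, collapse = ", ")))
  }
  n_t <- dim(x$db)[1]
  sel <- function(bw) {
    fi <- which(x$freqs > bw$f_lo & x$freqs <= bw$f_hi)
    ti <- which(x$times >= bw$t_lo & x$times <= bw$t_hi)
    if (!length(fi) || !length(ti)) {
      abort_input(sprintf("band %s has no bins/frames on the analysis grid",
                          bw$band))
    }
    list(fi = fi, ti = ti)
  }
  out <- list()
  for (bi in seq_len(nrow(bands))) {
    bw <- bands[bi, ]
    s <- sel(bw)
    for (e in unique(eois$eoi)) {
      chans <- eois$electrode[eois$eoi == e]
      ci <- match(chans, x$channels)
      if (is.null(average_by)) {
        v <- apply(x$db[, ci, s$fi, s$ti, drop = FALSE], 1, mean)
        out[[length(out) + 1L]] <- tibble(trial = seq_len(n_t), band = bw$band,
                                          eoi = e, db = v)
      } else {
        stopifnot(length(average_by) == n_t)
        for (g in unique(average_by)) {
          rows <- which(average_by == g)
          pw <- x$power[rows, ci, s$fi, s$ti, drop = FALSE]
          pbar <- apply(pw, c(2, 3, 4), mean)
          dbb <- 10 * log10(sweep(pbar, c(1, 2),
                                  x$baseline_power[ci, s$fi, drop = FALSE], "/"))
          out[[length(out) + 1L]] <- tibble(group = g, band = bw$band, eoi = e,
                                            db = mean(dbb))
        }
      }
    }
  }
  bind_rows(out)
}

#' Helper to build ERSP effect tables for the epoch generator
#'
#' Each row requests one condition-specific band-power increase: trials
#' matching `stimulus`/`context` (NA matches anything) receive a burst in
#' `band` at the electrodes of `eoi` whose size is calibrated so the
#' condition-average feature exceeds non-matching trials by `db` decibels.
#'
#' @param band Band name from [band_windows()].
#' @param eoi EOI name from [eoi_sets()].
#' @param db Effect size in dB (> 0).
#' @param stimulus,context Optional trial selectors.
#' @return One-row tibble; combine rows with [dplyr::bind_rows()].
#' @export
ersp_effect <- function(band, eoi, db, stimulus = NA, context = NA) {
  tibble(band = band, eoi = eoi, db = db,
         stimulus = as.character(stimulus), context = as.numeric(context))
}
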