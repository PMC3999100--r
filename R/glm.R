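#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak delay 6 s, undershoot
#' delay 16 s, unit dispersions, peak:undershoot ratio 6), evaluated on a
#' time grid and normalized to unit peak. The response is treated as zero
#' beyond 32 s.
#'
#' @param t Time grid in seconds, all non-negative.
#' @param peak_delay,undershoot_delay Gamma shape parameters (dispersion 1 s).
#' @param dispersion,u_dispersion Gamma scale parameters in s.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Support length; values beyond it are zero.
#' @return Numeric response values, max 1.
#' @export
#' @examples
#' hrf_canonical(0)            # 0 at the origin
#' which.max(hrf_canonical(seq(0, 32, 0.01))) # peak near 5 s
hrf_canonical <- function(t, peak_delay = 6, undershoot_delay = 16,
                          dispersion = 1, u_dispersion = 1, ratio = 6,
                          length_s = 32) {
  if (any(t < 0)) abort_input("HRF is defined for non-negative times only")
  h <- dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    dgamma(t, shape = undershoot_delay / u_dispersion, scale = u_dispersion) /
    ratio
  h[t > length_s] <- 0
  ref <- seq(0, length_s, by = 0.001)
  peak <- max(dgamma(ref, shape = peak_delay / dispersion, scale = dispersion) -
                dgamma(ref, shape = undershoot_delay / u_dispersion,
                       scale = u_dispersion) / ratio)
  h / peak
}

# Discrete-cosine drift basis with periods longer than `highpass_s`.
dct_drifts <- function(n_scans, tr, highpass_s = 128) {
  order <- floor(2 * n_scans * tr / highpass_s)
  if (order < 1) return(NULL)
  t <- 0:(n_scans - 1)
  X <- vapply(seq_len(order), function(k) {
    sqrt(2 / n_scans) * cos(pi * k * (2 * t + 1) / (2 * n_scans))
  }, numeric(n_scans))
  colnames(X) <- paste0("drift_", seq_len(order))
  X
}

convolve_sticks <- function(onsets, weights, n_scans, tr, microtime, hrf_fun) {
  n_micro <- ceiling(n_scans * tr / microtime)
  h <- hrf_fun(seq(0, 32, by = microtime))
  conv <- numeric(n_micro + length(h))
  idx <- floor(onsets / microtime) + 1L
  for (i in seq_along(idx)) {
    span <- idx[i]:(idx[i] + length(h) - 1L)
    conv[span] <- conv[span] + weights[i] * h
  }
  scan_idx <- round((0:(n_scans - 1)) * tr / microtime) + 1L
  conv[scan_idx]
}

#' Build a first-level fMRI design matrix with EEG parametric modulation
#'
#' Each condition in `events` gets a stick-function regressor convolved with
#' the canonical HRF (at 100 ms microtime resolution, sampled at the scan
#' times). For every modulator column the per-event values are z-scored
#' across that condition's events, used as stick weights, convolved, and then
#' residualized against the unmodulated regressor and any earlier modulated
#' companions (serial orthogonalization in the column order of `modulators`),
#' so that modulated columns carry only trial-by-trial amplitude variation.
#' Discrete-cosine drift regressors with periods above `highpass_s` and a
#' constant complete the design.
#'
#' @param events Tibble with columns `onset` (s), `condition`; one row per
#'   event.
#' @param modulators Optional data frame (one row per event) of per-trial
#'   modulator values, e.g. single-trial EEG band power; column names become
#'   regressor suffixes. Modulation order follows column order.
#' @param n_scans Number of volumes.
#' @param tr Repetition time in seconds.
#' @param highpass_s High-pass cutoff period in seconds.
#' @param microtime Microtime resolution in seconds.
#' @param nuisance Optional matrix of nuisance regressors (e.g. movement
#'   parameters), appended unmodified.
#' @return Object of class `fmri_design`: the numeric matrix is in `$X`, with
#'   metadata columns in `$columns`.
#' @export
build_design <- function(events, modulators = NULL, n_scans, tr = 2,
                         highpass_s = 128, microtime = 0.1, nuisance = NULL) {
  stopifnot(is.data.frame(events), all(c("onset", "condition") %in% names(events)))
  if (nrow(events) && any(events$onset < 0 | events$onset > n_scans * tr)) {
    abort_input("event onsets must lie within the scanned interval")
  }
  if (!is.null(modulators)) {
    modulators <- as.data.frame(modulators)
    if (nrow(modulators) != nrow(events)) {
      abort_input("modulators must have one row per event")
    }
  }
  cols <- list()
  names_out <- character(0)
  kinds <- character(0)
  for (cond in unique(events$condition)) {
    rows <- which(events$condition == cond)
    unmod <- convolve_sticks(events$onset[rows], rep(1, length(rows)),
                             n_scans, tr, microtime, hrf_canonical)
    block <- matrix(unmod, ncol = 1)
    blk_names <- cond
    blk_kinds <- "event"
    if (!is.null(modulators)) {
      for (m in names(modulators)) {
        v <- modulators[rows, m]
        if (length(rows) < 2 || sd(v) == 0 || anyNA(v)) {
          abort_input(sprintf(
            "modulator '%s' is constant or missing for condition '%s': z-score undefined",
            m, cond))
        }
        z <- (v - mean(v)) / sd(v)
        mod <- convolve_sticks(events$onset[rows], z, n_scans, tr, microtime,
                               hrf_canonical)
        # residualize against the unmodulated column and earlier modulators
        qrb <- qr(cbind(1, block))
        mod <- qr.resid(qrb, mod)
        block <- cbind(block, mod)
        blk_names <- c(blk_names, paste(cond, m, sep = ":"))
        blk_kinds <- c(blk_kinds, "modulator")
      }
    }
    cols[[length(cols) + 1L]] <- block
    names_out <- c(names_out, blk_names)
    kinds <- c(kinds, blk_kinds)
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), n_scans, 0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    nm <- colnames(nuisance) %||% paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    names_out <- c(names_out, nm)
    kinds <- c(kinds, rep("nuisance", ncol(nuisance)))
  }
  drifts <- dct_drifts(n_scans, tr, highpass_s)
  if (!is.null(drifts)) {
    X <- cbind(X, drifts)
    names_out <- c(names_out, colnames(drifts))
    kinds <- c(kinds, rep("drift", ncol(drifts)))
  }
  X <- cbind(X, constant = 1)
  names_out <- c(names_out, "constant")
  kinds <- c(kinds, "constant")
  colnames(X) <- names_out
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    abort_input(paste("design is rank deficient; collinear column(s):",
                      paste(dropped, collapse = ", ")))
  }
  structure(
    list(X = X, tr = tr, n_scans = n_scans,
         columns = tibble(name = names_out, kind = kinds),
         highpass_s = highpass_s, microtime = microtime),
    class = "fmri_design"
  )
}

#' Synthesize BOLD data from a design with AR(1) noise
#'
#' `y = X beta + e`, with `e` a stationary AR(1) Gaussian process of marginal
#' standard deviation `sigma` and lag-1 autocorrelation `ar1_rho`.
#'
#' @param design An [build_design()] object (or bare matrix).
#' @param betas Coefficient per design column (recycled names are matched
#'   when named).
#' @param sigma Marginal noise sd.
#' @param ar1_rho AR(1) coefficient, `0 <= ar1_rho < 1`.
#' @param seed Optional seed.
#' @return Numeric vector of scans.
#' @export
synthesize_bold <- function(design, betas, sigma = 1, ar1_rho = 0,
                            seed = NULL) {
  X <- if (inherits(design, "fmri_design")) design$X else as.matrix(design)
  if (ar1_rho < 0 || ar1_rho >= 1) abort_input("ar1_rho must lie in [0, 1)")
  b <- numeric(ncol(X))
  if (!is.null(names(betas))) {
    stopifnot(all(names(betas) %in% colnames(X)))
    b[match(names(betas), colnames(X))] <- betas
  } else {
    stopifnot(length(betas) == ncol(X))
    b <- betas
  }
  n <- nrow(X)
  with_seed(seed, {
    innov_sd <- sigma * sqrt(1 - ar1_rho^2)
    e <- numeric(n)
    e[1] <- rnorm(1, sd = sigma)
    if (n > 1) {
      z <- rnorm(n - 1, sd = innov_sd)
      for (i in 2:n) e[i] <- ar1_rho * e[i - 1] + z[i - 1]
    }
    as.numeric(X %*% b) + e
  })
}

#' Fit a first-level GLM with optional AR(1) prewhitening
#'
#' Ordinary least squares; with `prewhiten = TRUE` the AR(1) coefficient is
#' estimated from the OLS residuals' lag-1 autocorrelation, data and design
#' are transformed once by the Prais-Winsten quasi-differencing, and the
#' model is refit (one-step Cochrane-Orcutt). Contrast t-statistics are
#' `c'b / se(c'b)`.
#'
#' @param y Scan time series.
#' @param design An [build_design()] object.
#' @param prewhiten Estimate and remove AR(1) serial correlation?
#' @param contrasts Optional named list of contrast vectors (length = number
#'   of columns, or named numeric vectors over column names).
#' @return Object of class `eegfmri_glm` with elements `coefficients`,
#'   `sigma2`, `df_residual`, `rho`, `contrasts` (tibble), `design`.
#' @export
fit_glm <- function(y, design, prewhiten = TRUE, contrasts = NULL) {
  stopifnot(inherits(design, "fmri_design"))
  X <- design$X
  if (length(y) != nrow(X)) abort_input("y length must equal the scan count")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) abort_input("design is rank deficient")
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  rho <- 0
  Xcur <- X
  if (prewhiten) {
    rho <- sum(res[-1] * res[-length(res)]) / sum(res^2)
    w1 <- sqrt(1 - rho^2)
    Xcur <- rbind(X[1, ] * w1,
                  X[-1, , drop = FALSE] - rho * X[-nrow(X), , drop = FALSE])
    yw <- c(y[1] * w1, y[-1] - rho * y[-length(y)])
    qrx <- qr(Xcur)
    beta <- qr.coef(qrx, yw)
    res <- qr.resid(qrx, yw)
  }
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(chol(crossprod(Xcur)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  ctab <- NULL
  if (!is.null(contrasts)) {
    ctab <- purrr::imap(contrasts, function(cv, nm) {
      cvec <- numeric(p)
      if (!is.null(names(cv))) {
        stopifnot(all(names(cv) %in% colnames(X)))
        cvec[match(names(cv), colnames(X))] <- cv
      } else {
        stopifnot(length(cv) == p)
        cvec <- cv
      }
      est <- sum(cvec * beta)
      se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
      tibble(contrast = nm, estimate = est, se = se, t = est / se)
    }) %>% list_rbind()
  }
  structure(
    list(coefficients = beta, sigma2 = sigma2, df_residual = n - p,
         rho = rho, vcov_unscaled = XtXinv, contrasts = ctab,
         design = design, residuals = res, n = n),
    class = "eegfmri_glm"
  )
}

#' @export
tidy.eegfmri_glm <- function(x, ...) {
  se <- sqrt(x$sigma2 * diag(x$vcov_unscaled))
  tibble(
    term = names(x$coefficients),
    kind = x$design$columns$kind,
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se)
  )
}

#' @export
glance.eegfmri_glm <- function(x, ...) {
  tibble(sigma = sqrt(x$sigma2), df.residual = x$df_residual, rho = x$rho,
         n = x$n)
}

#' Broom-style generics for fitted objects
#'
#' `tidy()` returns one row per design column with estimate, standard error
#' and t-statistic; `glance()` returns one row of fit-level summaries
#' (residual sd, residual df, the AR(1) coefficient used, scan count).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
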