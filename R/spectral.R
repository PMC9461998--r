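#' Welch averaged-periodogram power spectral density
#'
#' Hann-windowed overlapping segments, one-sided density scaling
#' (microvolts squared per Hz), so that `sum(power) * df` approximates the
#' signal variance (Parseval).
#'
#' @param x Numeric signal vector (or a matrix, one channel per column, in
#'   which case per-channel PSDs are averaged).
#' @param fs_hz Sampling rate.
#' @param nperseg Segment length in samples (default: 4 s rounded down to a
#'   power of two, capped at the signal length).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `psd_estimate`: list with `freqs_hz`, `power`, `fs`,
#'   `nperseg`, `overlap`.
#' @export
welch_psd <- function(x, fs_hz, nperseg = NULL, overlap = 0.5) {
  if (is.matrix(x)) {
    psds <- lapply(seq_len(ncol(x)), function(j)
      welch_psd(x[, j], fs_hz, nperseg, overlap))
    out <- psds[[1L]]
    out$power <- rowMeans(do.call(cbind, lapply(psds, `[[`, "power")))
    return(out)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(2^floor(log2(fs_hz * 4)), n)
  nperseg <- as.integer(nperseg)
  if (n < nperseg || nperseg < 8L) stop("signal too short for Welch estimate")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  if (length(starts) < 2L) stop("signal too short for Welch estimate: ",
                                "need at least 2 windows")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0L, nperseg - 1L) / (nperseg - 1L)) # Hann
  scale <- fs_hz * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  pow <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  dbl <- seq(2L, nfreq - if (nperseg %% 2L == 0L) 1L else 0L)
  pow[dbl] <- 2 * pow[dbl]
  structure(list(freqs_hz = seq(0L, nfreq - 1L) * fs_hz / nperseg,
                 power = pow, fs = fs_hz, nperseg = nperseg,
                 overlap = overlap),
            class = "psd_estimate")
}

#' Individual alpha frequency from a PSD
#'
#' Peak alpha frequency (PAF) is found on the *background-corrected*
#' spectrum: a log-log line is fitted to the PSD over `background_hz`
#' excluding the alpha search window (the aperiodic trend), the in-window
#' log-power residual is smoothed with a Savitzky-Golay filter, and PAF is
#' the frequency of the highest interior local maximum whose smoothed
#' residual exceeds `min_log10_prom` (log10-power units above the
#' background). When no such peak exists — e.g. a purely aperiodic
#' spectrum — PAF is `NA` and a quality flag is set; a missing estimate is
#' data, not an error. Centre of gravity (COG) is the power-weighted mean
#' frequency over the raw in-window spectrum.
#'
#' @param psd A `psd_estimate`.
#' @param window_hz Alpha search window, default `c(7, 13)` Hz.
#' @param sg_window Savitzky-Golay window length in bins (odd, default 11).
#' @param sg_order Savitzky-Golay polynomial order (default 5).
#' @param min_log10_prom Minimum smoothed peak elevation above the aperiodic
#'   background, in log10 power units (default 0.15, i.e. ~40% above
#'   background).
#' @param background_hz Range used for the aperiodic background fit
#'   (default `c(2, 30)`, clipped to the PSD support).
#' @return An `iaf_estimate`: list with `paf_hz` (possibly `NA`), `cog_hz`,
#'   `search_window_hz`, `no_peak` flag.
#' @export
estimate_iaf <- function(psd, window_hz = c(7, 13), sg_window = 11L,
                         sg_order = 5L, min_log10_prom = 0.15,
                         background_hz = c(2, 30)) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (window_hz[1L] < min(psd$freqs_hz) || window_hz[2L] > max(psd$freqs_hz)) {
    stop("search window outside PSD support")
  }
  fr <- psd$freqs_hz
  inw <- fr >= window_hz[1L] & fr <= window_hz[2L]
  f <- fr[inw]
  p <- psd$power[inw]
  bg <- fr >= max(background_hz[1L], min(fr[fr > 0])) &
    fr <= min(background_hz[2L], max(fr)) & !inw & psd$power > 0
  fit <- stats::lm.fit(cbind(1, log10(fr[bg])), log10(psd$power[bg]))
  resid <- log10(pmax(p, .Machine$double.xmin)) -
    (fit$coefficients[[1L]] + fit$coefficients[[2L]] * log10(f))
  sg_window <- min(sg_window, if (length(p) %% 2L == 1L) length(p)
                   else length(p) - 1L)
  rs <- if (length(p) > sg_window && sg_window > sg_order) {
    as.numeric(signal::sgolayfilt(resid, p = sg_order, n = sg_window))
  } else resid
  i <- which(diff(sign(diff(rs))) == -2L) + 1L    # interior local maxima
  i <- i[rs[i] >= min_log10_prom]
  paf <- if (length(i) > 0L) f[i[which.max(rs[i])]] else NA_real_
  cog <- sum(f * p) / sum(p)
  structure(list(paf_hz = paf, cog_hz = cog, search_window_hz = window_hz,
                 no_peak = is.na(paf)),
            class = "iaf_estimate")
}

#' Separate aperiodic and oscillatory spectra by irregular resampling
#'
#' Irregular-resampling auto-spectral analysis: for each resampling factor
#' `h` the signal is resampled by `h` and `1/h` (polyphase FIR), the two
#' Welch PSDs are combined by their geometric mean, and the median across
#' the `hset` yields the aperiodic spectrum (oscillatory peaks, displaced to
#' `f/h` and `f*h`, are suppressed by the median while a power law is
#' invariant). The aperiodic intercept and slope come from an ordinary
#' least-squares fit of log power on log frequency over `fit_range_hz`;
#' `slope` is reported positive for 1/f-decaying spectra (`slope_raw` keeps
#' the signed regression coefficient).
#'
#' @param x Numeric signal (or matrix, channels in columns: PSDs averaged
#'   across channels before fitting).
#' @param fs_hz Sampling rate.
#' @param hset Resampling factors, default `seq(1.1, 1.9, by = 0.05)`.
#' @param fit_range_hz Frequency range of the log-log fit, default
#'   `c(2, 25)` Hz.
#' @param nperseg Welch segment length (see [welch_psd()]).
#' @return An `aperiodic_fit`: `intercept` (log10 power at log10 f = 0),
#'   `slope`, `slope_raw`, `fit_range_hz`, `hset`, `freqs_hz`,
#'   `aperiodic_power`, `oscillatory_power` (original minus aperiodic),
#'   `psd` (the original-spectrum `psd_estimate`).
#' @export
irasa <- function(x, fs_hz, hset = seq(1.1, 1.9, by = 0.05),
                  fit_range_hz = c(2, 25), nperseg = NULL) {
  if (is.matrix(x)) {
    fits <- welch_psd(x, fs_hz, nperseg)   # averaged original PSD
    per <- lapply(seq_len(ncol(x)), function(j)
      irasa(x[, j], fs_hz, hset, fit_range_hz, nperseg))
    ap <- rowMeans(do.call(cbind, lapply(per, `[[`, "aperiodic_power")))
    return(finish_irasa(fits, ap, hset, fit_range_hz))
  }
  psd0 <- welch_psd(x, fs_hz, nperseg)
  n_h <- length(hset)
  ap_mat <- matrix(NA_real_, length(psd0$power), n_h)
  for (j in seq_len(n_h)) {
    h <- hset[[j]]
    frac <- rational_factor(h)
    up <- signal::resample(x, frac[1L], frac[2L])
    dn <- signal::resample(x, frac[2L], frac[1L])
    p_up <- welch_psd(up, fs_hz, psd0$nperseg)$power
    p_dn <- welch_psd(dn, fs_hz, psd0$nperseg)$power
    ap_mat[, j] <- sqrt(p_up * p_dn)
  }
  ap <- apply(ap_mat, 1L, stats::median)
  finish_irasa(psd0, ap, hset, fit_range_hz)
}

finish_irasa <- function(psd0, ap, hset, fit_range_hz) {
  f <- psd0$freqs_hz
  if (fit_range_hz[1L] < min(f[f > 0]) || fit_range_hz[2L] > max(f)) {
    stop("fit_range_hz outside PSD support")
  }
  sel <- f >= fit_range_hz[1L] & f <= fit_range_hz[2L] & ap > 0
  fit <- stats::lm.fit(cbind(1, log10(f[sel])), log10(ap[sel]))
  slope_raw <- fit$coefficients[[2L]]
  structure(list(intercept = fit$coefficients[[1L]],
                 slope = -slope_raw, slope_raw = slope_raw,
                 fit_range_hz = fit_range_hz, hset = hset,
                 freqs_hz = f, aperiodic_power = ap,
                 oscillatory_power = psd0$power - ap,
                 psd = psd0),
            class = "aperiodic_fit")
}

# express a resampling factor as a reduced integer ratio p/q
rational_factor <- function(h, denom = 20L) {
  p <- as.integer(round(h * denom))
  g <- gcd_int(p, denom)
  c(p %/% g, denom %/% g)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat("IRASA aperiodic fit over", x$fit_range_hz[1L], "-", x$fit_range_hz[2L],
      "Hz: slope =", format(x$slope, digits = 4),
      ", intercept =", format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' Combine pre- and post-session metric estimates
#'
#' The per-participant metric is the mean of the pre- and post-task
#' estimates when both are available; when one session yields no estimate
#' the other session's value is used alone; when both are missing the
#' participant is flagged for downstream exclusion.
#'
#' @param pre,post Numeric scalars or `NA`.
#' @return List with `value` (numeric or `NA`), `provenance` (one of
#'   `"mean_of_pre_post"`, `"pre_only"`, `"post_only"`, `"missing"`),
#'   `exclude` (logical).
#' @export
combine_sessions <- function(pre, post) {
  pre_ok <- length(pre) == 1L && is.finite(pre)
  post_ok <- length(post) == 1L && is.finite(post)
  if (pre_ok && post_ok) {
    list(value = (pre + post) / 2, provenance = "mean_of_pre_post",
         exclude = FALSE)
  } else if (pre_ok) {
    list(value = pre, provenance = "pre_only", exclude = FALSE)
  } else if (post_ok) {
    list(value = post, provenance = "post_only", exclude = FALSE)
  } else {
    list(value = NA_real_, provenance = "missing", exclude = TRUE)
  }
}

#' Posterior electrode set used for alpha-frequency estimation
#' @return Character vector of channel names.
#' @export
iaf_electrodes <- function() {
  c("P1", "Pz", "P2", "PO3", "POz", "PO4", "O1", "Oz", "O2")
}

#' Fronto-centro-parietal electrode set used for aperiodic-slope estimation
#' @return Character vector of channel names.
#' @export
slope_electrodes <- function() {
  c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8", "O1", "Oz", "O2")
}

#' Compute per-participant resting metrics from one or two sessions
#'
#' Convenience wrapper: estimates IAF (PAF by default — the covariate used
#' in the moderation analyses — plus COG) and the IRASA aperiodic
#' intercept/slope for each available session, then applies the
#' session-combination rule of [combine_sessions()].
#'
#' @param subject Subject identifier.
#' @param pre,post Numeric signal vectors/matrices for the pre- and
#'   post-task eyes-closed recordings (`NULL` if unavailable).
#' @param fs_hz Sampling rate.
#' @param ... Passed to [estimate_iaf()] / [irasa()].
#' @return One-row data.frame: `subject, iaf, cog, slope, intercept,
#'   iaf_provenance, slope_provenance, exclude`.
#' @export
participant_metrics <- function(subject, pre = NULL, post = NULL, fs_hz,
                                ...) {
  one <- function(x) {
    if (is.null(x)) return(list(paf = NA_real_, cog = NA_real_,
                                slope = NA_real_, intercept = NA_real_))
    psd <- welch_psd(x, fs_hz)
    ia <- estimate_iaf(psd, ...)
    ap <- irasa(x, fs_hz)
    list(paf = ia$paf_hz, cog = ia$cog_hz,
         slope = ap$slope, intercept = ap$intercept)
  }
  a <- one(pre); b <- one(post)
  iaf <- combine_sessions(a$paf, b$paf)
  cog <- combine_sessions(a$cog, b$cog)
  slp <- combine_sessions(a$slope, b$slope)
  itc <- combine_sessions(a$intercept, b$intercept)
  data.frame(subject = subject,
             iaf = iaf$value, cog = cog$value,
             slope = slp$value, intercept = itc$value,
             iaf_provenance = iaf$provenance,
             slope_provenance = slp$provenance,
             exclude = iaf$exclude || slp$exclude,
             stringsAsFactors = FALSE)
}
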