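#' Centro-parietal region of interest for N400 analyses
#' @return Character vector of channel names.
#' @export
cp_roi <- function() {
  c("C3", "C1", "Cz", "C2", "C4", "P3", "P1", "Pz", "P2", "P4",
    "CP3", "CP1", "CPz", "CP2", "CP4")
}

#' Epoch/window configuration for single-trial feature extraction
#'
#' Defaults follow the auditory-comprehension pipeline: epochs span -200 to
#' 1000 ms around critical-word onset; the prestimulus window is
#' [-200, 0) ms and the N400 window [300, 500) ms (half-open in sample
#' space, onset sample included in post-stimulus time 0).
#'
#' @param epoch_span_ms Two-element epoch span in ms.
#' @param prestim_ms Prestimulus window in ms.
#' @param n400_ms N400 window in ms.
#' @param roi Channel names to extract (default the centro-parietal set).
#' @return An `epoch_window_config` list.
#' @export
epoch_window_config <- function(epoch_span_ms = c(-200, 1000),
                                prestim_ms = c(-200, 0),
                                n400_ms = c(300, 500),
                                roi = cp_roi()) {
  stopifnot(length(roi) >= 1L,
            prestim_ms[1L] >= epoch_span_ms[1L],
            n400_ms[2L] <= epoch_span_ms[2L])
  structure(list(epoch_span_ms = epoch_span_ms, prestim_ms = prestim_ms,
                 n400_ms = n400_ms, roi = roi),
            class = "epoch_window_config")
}

#' Preprocess continuous multichannel EEG
#'
#' Average re-reference (subtract the instantaneous channel mean),
#' resampling to `fs_out`, and a zero-phase Butterworth band-pass: a
#' second-order 0.1 Hz high-pass cascaded with a fourth-order 30 Hz
#' low-pass, each applied forward-backward.
#'
#' @param x Numeric matrix, samples x channels, with channel names as
#'   column names.
#' @param fs_in Input sampling rate in Hz (must exceed twice the low-pass
#'   edge).
#' @param fs_out Output rate, default 500 Hz.
#' @param band Band edges in Hz, default `c(0.1, 30)`.
#' @return Matrix at `fs_out` with attribute `fs`.
#' @export
preprocess_eeg <- function(x, fs_in, fs_out = 500, band = c(0.1, 30)) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("average reference needs at least 2 channels")
  if (fs_in < 2 * band[2L]) stop("fs_in below twice the low-pass edge")
  x <- x - rowMeans(x)
  if (fs_out != fs_in) {
    r <- rational_factor(fs_out / fs_in, denom = 1000L)
    x <- apply(x, 2L, function(ch) signal::resample(ch, r[1L], r[2L]))
  }
  ny <- fs_out / 2
  hp <- signal::butter(2, band[1L] / ny, type = "high")
  lp <- signal::butter(4, band[2L] / ny, type = "low")
  x <- apply(x, 2L, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  })
  attr(x, "fs") <- fs_out
  x
}

#' Extract single-trial window means around events
#'
#' For each event onset and each ROI channel, returns the mean amplitude in
#' the prestimulus and N400 windows. Windows are half-open `[start, end)`
#' in sample space with 0-based offsets from the onset sample. Events whose
#' full epoch span does not fit inside the recording are dropped (counted
#' and messaged, not silently).
#'
#' @param x Preprocessed samples x channels matrix with column names.
#' @param fs_hz Sampling rate of `x`.
#' @param events data.frame with columns `sample` (1-based onset sample)
#'   and `trial_id`.
#' @param cfg An `epoch_window_config`.
#' @param pool_roi Average ROI channels into a single row per trial?
#'   Default `FALSE` (long format, one row per trial x channel, so channel
#'   can enter the model as a random effect).
#' @return data.frame `trial_id, channel, prestim_uv, n400_uv` with
#'   attribute `n_dropped`.
#' @export
epoch_features <- function(x, fs_hz, events, cfg = epoch_window_config(),
                           pool_roi = FALSE) {
  stopifnot(inherits(cfg, "epoch_window_config"),
            all(c("sample", "trial_id") %in% names(events)))
  chans <- intersect(cfg$roi, colnames(x))
  if (length(chans) == 0L) stop("no ROI channels present in the recording")
  ms2samp <- function(ms) as.integer(round(ms / 1000 * fs_hz))
  span <- ms2samp(cfg$epoch_span_ms)
  pre <- ms2samp(cfg$prestim_ms)
  n4 <- ms2samp(cfg$n400_ms)
  n <- nrow(x)
  onset <- as.integer(events$sample)
  ok <- (onset + span[1L]) >= 1L & (onset + span[2L] - 1L) <= n
  n_drop <- sum(!ok)
  if (n_drop > 0L) {
    message(n_drop, " event(s) too close to the recording edge; dropped")
  }
  rows <- vector("list", sum(ok))
  kept <- which(ok)
  win_mean <- function(on, w, ch) {
    idx <- (on + w[1L]):(on + w[2L] - 1L)   # half-open [start, end)
    mean(x[idx, ch])
  }
  for (r in seq_along(kept)) {
    ev <- kept[r]
    rows[[r]] <- data.frame(
      trial_id = events$trial_id[ev],
      channel = chans,
      prestim_uv = unname(vapply(chans, function(ch)
        win_mean(onset[ev], pre, ch), numeric(1L))),
      n400_uv = unname(vapply(chans, function(ch)
        win_mean(onset[ev], n4, ch), numeric(1L))),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out) && pool_roi) {
    agg <- stats::aggregate(cbind(prestim_uv, n400_uv) ~ trial_id, data = out,
                            FUN = mean)
    agg$channel <- "ROI"
    out <- agg[, c("trial_id", "channel", "prestim_uv", "n400_uv")]
  }
  if (is.null(out)) {
    out <- data.frame(trial_id = character(0L), channel = character(0L),
                      prestim_uv = numeric(0L), n400_uv = numeric(0L))
  }
  attr(out, "n_dropped") <- n_drop
  out
}
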