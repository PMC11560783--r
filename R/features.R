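#' EEG recording container
#'
#' Bundles a multichannel EEG signal with its sampling rate and metadata.
#' The signal is stored channels x time, in microvolts.
#'
#' @param signal numeric matrix, channels x time samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names optional character vector of channel labels.
#' @param label emotion category id in `0..C-1`, or `NA` if unknown.
#' @param subject,session optional identifiers carried through feature
#'   extraction.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_names = NULL, label = NA,
                          subject = NA, session = NA) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || nrow(signal) < 1L || ncol(signal) < 1L)
    stop("`signal` must be a non-empty numeric channels x time matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar sampling rate in Hz")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("`channel_names` length must equal the number of channels")
  structure(
    list(signal = signal, fs = fs, channel_names = channel_names,
         label = label, subject = subject, session = session),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Frequency band definition
#'
#' @param name band label, e.g. `"alpha"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return an object of class `band_definition`.
#' @export
band_definition <- function(name, low, high) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' The five canonical EEG bands
#'
#' delta (1-3 Hz), theta (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz) and
#' gamma (31-50 Hz) -- the band decomposition used for differential-entropy
#' emotion features.
#'
#' @return a named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(delta = band_definition("delta", 1, 3),
       theta = band_definition("theta", 4, 7),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 14, 30),
       gamma = band_definition("gamma", 31, 50))
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), so filtered windows stay time-aligned with the
#' raw signal.
#'
#' @param recording an [eeg_recording()].
#' @param band a [band_definition()]; the upper edge must lie below the
#'   Nyquist frequency.
#' @return the filtered recording, same shape and metadata.
#' @export
bandpass <- function(recording, band) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(band, "band_definition"))
  nyq <- recording$fs / 2
  if (band$high >= nyq)
    stop(sprintf("invalid band: upper edge %g Hz >= Nyquist %g Hz",
                 band$high, nyq))
  flt <- signal::butter(4, c(band$low, band$high) / nyq, type = "pass")
  out <- recording
  out$signal <- t(apply(recording$signal, 1L, function(ch) {
    if (all(ch == 0)) ch else signal::filtfilt(flt, ch)
  }))
  out
}

#' Segment a recording into non-overlapping windows
#'
#' Windows are returned in temporal order; a trailing partial window is
#' discarded. A window longer than the signal yields an empty list.
#'
#' @param recording an [eeg_recording()].
#' @param window_seconds window length in seconds; `window_seconds * fs`
#'   must be at least 2 samples.
#' @return list of [eeg_recording()] windows.
#' @export
segment_windows <- function(recording, window_seconds) {
  stopifnot(inherits(recording, "eeg_recording"))
  w <- as.integer(round(window_seconds * recording$fs))
  if (w < 2L) stop("window must span at least 2 samples")
  n <- ncol(recording$signal)
  k <- n %/% w
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    out <- recording
    out$signal <- recording$signal[, ((i - 1L) * w + 1L):(i * w), drop = FALSE]
    out
  })
}

#' Differential entropy of a signal window
#'
#' For a window modelled as Gaussian, the differential entropy is
#' `0.5 * log(2 * pi * e * sigma^2)` nats, with `sigma^2` the
#' maximum-likelihood (divide-by-n) window variance. The variance is floored
#' at `eps` before the log so a constant window returns a finite value.
#'
#' @param x numeric vector, one channel of one window (length >= 2).
#' @param eps variance floor (default `1e-12`).
#' @return differential entropy in nats.
#' @export
differential_entropy <- function(x, eps = 1e-12) {
  if (length(x) < 2L) stop("window must contain at least 2 samples")
  v <- mean((x - mean(x))^2)
  0.5 * log(2 * pi * exp(1) * max(v, eps))
}

#' Extract differential-entropy band features
#'
#' Band-pass filters the recording once per band (zero-phase), cuts it into
#' non-overlapping windows, and computes the differential entropy of every
#' channel in every band, yielding one channels x bands feature matrix per
#' window. With 62 channels and the 5 canonical bands each sample is
#' 62 x 5 = 310-dimensional once flattened.
#'
#' @param recording an [eeg_recording()].
#' @param bands list of [band_definition()]s (default [default_bands()]).
#' @param window_seconds window length in seconds (default 1).
#' @param domain_id domain identifier attached to the output.
#' @return a [domain_dataset()] with `m = n_channels`, `d = n_bands` and one
#'   row per window; labels replicate the recording's trial label.
#' @export
extract_features <- function(recording, bands = default_bands(),
                             window_seconds = 1, domain_id = 1L) {
  stopifnot(inherits(recording, "eeg_recording"), length(bands) >= 1L)
  m <- nrow(recording$signal)
  d <- length(bands)
  band_names <- vapply(bands, function(b) b$name, character(1))

  # filter first, then window: zero-phase filtering keeps windows aligned
  per_band <- lapply(bands, function(b) {
    segment_windows(bandpass(recording, b), window_seconds)
  })
  k <- length(per_band[[1]])
  if (k == 0L) {
    feats <- matrix(numeric(0), nrow = 0L, ncol = m * d)
  } else {
    feats <- t(vapply(seq_len(k), function(i) {
      vals <- vapply(seq_len(d), function(b) {
        apply(per_band[[b]][[i]]$signal, 1L, differential_entropy)
      }, numeric(m))  # m x d
      as.vector(vals)
    }, numeric(m * d)))
  }
  colnames(feats) <- paste(rep(recording$channel_names, times = d),
                           rep(band_names, each = m), sep = "_")
  labels <- if (is.na(recording$label)) NULL else rep.int(as.integer(recording$label), k)
  domain_dataset(feats, labels = labels, domain_id = domain_id,
                 m = m, d = d,
                 subject = recording$subject, session = recording$session)
}

#' Z-score features per channel-band coordinate
#'
#' Normalizes every feature column (one channel x band coordinate) to zero
#' mean and unit standard deviation across the samples of the dataset,
#' typically one subject-session. Constant coordinates map to all zeros
#' (the sd is floored at `eps`).
#'
#' @param dataset a [domain_dataset()] with at least 2 samples.
#' @param eps standard-deviation floor.
#' @return the dataset with normalized features.
#' @export
normalize_channels <- function(dataset, eps = 1e-12) {
  stopifnot(inherits(dataset, "domain_dataset"))
  X <- dataset$features
  if (nrow(X) < 2L) {
    warning("fewer than 2 samples: normalization skipped (identity)")
    return(dataset)
  }
  mu <- colMeans(X)
  sd_ml <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  dataset$features <- sweep(sweep(X, 2L, mu), 2L, pmax(sd_ml, eps), "/")
  dataset
}
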