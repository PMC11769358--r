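# Preprocessing of continuous paired recordings: zero-phase high-pass and
# power-line notch filtering of both streams, common average referencing of
# the scalp only, per-recording amplitude normalization, and fixed-length
# segmentation around annotated IED onsets with matched non-IED sampling.

#' Preprocessing configuration
#'
#' The defaults implement 1 Hz high-pass, 50 Hz notch, common average
#' reference on the scalp, and 320 ms segments (64 samples at 200 Hz) spanning
#' 160 ms before and after the IED onset.
#'
#' @param highpass_cutoff high-pass cutoff in Hz
#' @param notch_freq power-line frequency in Hz
#' @param segment_length segment length in samples
#' @param pre_onset,post_onset window extent around the onset in seconds
#' @param apply_car_to_scalp apply common average reference to the scalp
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(highpass_cutoff = 1, notch_freq = 50,
                              segment_length = 64, pre_onset = 0.160,
                              post_onset = 0.160, apply_car_to_scalp = TRUE) {
  structure(list(highpass_cutoff = highpass_cutoff, notch_freq = notch_freq,
                 segment_length = segment_length, pre_onset = pre_onset,
                 post_onset = post_onset,
                 apply_car_to_scalp = apply_car_to_scalp),
            class = "preprocess_config")
}

# forward-backward filtering with odd-reflection padding so edge transients
# die out in the discarded pad rather than in the signal
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_ref <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a), c(head_ref, x, tail_ref))
  y[pad + seq_len(n)]
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward-backward (via [signal::filtfilt()]),
#' so spike morphology suffers no phase distortion.
#'
#' @param x numeric matrix, time by sensors (vectors are treated as one
#'   sensor)
#' @param cutoff cutoff frequency in Hz
#' @param rate sampling rate in Hz
#' @return filtered array of the same shape
#' @export
highpass <- function(x, cutoff = 1, rate = 200) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency ",
                               rate / 2, " Hz")
  x <- as.matrix(x)
  bf <- signal::butter(4, cutoff / (rate / 2), type = "high")
  pad <- ceiling(8 * rate / cutoff)
  apply(x, 2, function(col) filtfilt_padded(bf$b, bf$a, col, pad))
}

# RBJ biquad notch coefficients
design_notch <- function(freq, rate, q = 30) {
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase power-line notch filter
#'
#' 2nd-order IIR notch (quality factor 30) applied forward-backward.
#'
#' @inheritParams highpass
#' @param freq notch center frequency in Hz
#' @return filtered array of the same shape
#' @export
notch <- function(x, freq = 50, rate = 200) {
  if (freq >= rate / 2) stop("notch frequency must be below the Nyquist ",
                             "frequency ", rate / 2, " Hz")
  x <- as.matrix(x)
  co <- design_notch(freq, rate)
  pad <- ceiling(3 * rate) # notch transients ring for ~Q cycles
  apply(x, 2, function(col) filtfilt_padded(co$b, co$a, col, pad))
}

#' Common average reference
#'
#' Subtracts the across-sensor mean at every time sample; after referencing
#' the mean over sensors is exactly zero everywhere.
#'
#' @param x numeric matrix, time by sensors (at least 2 sensors)
#' @return referenced matrix
#' @export
common_average_reference <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("common average reference requires at least 2 sensors")
  x - rowMeans(x)
}

# per-recording min-max scaling to [-1, 1] preserving zero
normalize_recording <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' Filter and reference a continuous paired recording
#'
#' Applies the high-pass and notch filters to both streams, the common average
#' reference to the scalp only, then per-recording amplitude normalization to
#' `[-1, 1]`.
#'
#' @param recording list with `scalp`, `intracranial` (time x sensors) and
#'   `sampling_rate`, as returned by [import_edf()] or
#'   [simulate_continuous()]
#' @param cfg a [preprocess_config()]
#' @return the recording with filtered, normalized streams
#' @export
preprocess_recording <- function(recording, cfg = preprocess_config()) {
  rate <- recording$sampling_rate
  fs <- function(x) notch(highpass(x, cfg$highpass_cutoff, rate),
                          cfg$notch_freq, rate)
  sc <- fs(recording$scalp)
  ic <- fs(recording$intracranial)
  if (cfg$apply_car_to_scalp) sc <- common_average_reference(sc)
  recording$scalp <- normalize_recording(sc)
  recording$intracranial <- normalize_recording(ic)
  recording
}

#' Cut fixed-length paired segments around IED onsets
#'
#' Each onset yields one IED segment covering `[onset - L/2, onset + L/2)`
#' samples; an equal number of non-IED segments is drawn (seeded) from
#' onset-free stretches, never overlapping any IED window. Onsets too close
#' to the recording edges are skipped with a warning.
#'
#' @param recording preprocessed continuous paired recording
#' @param onsets IED onset sample indices
#' @param cfg a [preprocess_config()]
#' @param subject_id identifier stamped on the segments
#' @param seed RNG seed for non-IED placement
#' @return list of [paired_segment()]s (IED segments first)
#' @export
extract_segments <- function(recording, onsets, cfg = preprocess_config(),
                             subject_id = "S1", seed = 1) {
  rate <- recording$sampling_rate
  pre <- round(cfg$pre_onset * rate)
  post <- round(cfg$post_onset * rate)
  L <- cfg$segment_length
  if (pre + post != L)
    stop("pre_onset + post_onset (", pre + post, " samples) must equal ",
         "segment_length (", L, ")")
  Tn <- nrow(recording$scalp)
  ok <- onsets - pre >= 1 & onsets + post - 1 <= Tn
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) too close to the recording edge; skipped")
    onsets <- onsets[ok]
  }
  windows <- lapply(onsets, function(o) (o - pre):(o + post - 1))
  cut_one <- function(idx, label) {
    paired_segment(
      scalp_segment(recording$scalp[idx, , drop = FALSE], rate,
                    onset_index = if (label == "IED") pre + 1L else NULL),
      intracranial_segment(recording$intracranial[idx, , drop = FALSE]),
      label = label, subject_id = subject_id)
  }
  ied_segs <- lapply(windows, cut_one, label = "IED")
  # candidate non-IED starts: windows fully disjoint from every IED window
  blocked <- rep(FALSE, Tn)
  for (w in windows) blocked[w] <- TRUE
  cand <- which(vapply(seq_len(Tn - L + 1),
                       function(s) !any(blocked[s:(s + L - 1)]), logical(1)))
  if (length(cand) < length(onsets))
    stop("not enough onset-free signal to draw ", length(onsets),
         " non-IED segments")
  set.seed(seed %% 2147483647)
  starts <- sample(cand, length(onsets))
  non_segs <- lapply(starts, function(s) cut_one(s:(s + L - 1), "nonIED"))
  c(ied_segs, non_segs)
}
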