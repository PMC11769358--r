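# Synthetic concurrent scalp/intracranial cohort simulator.
#
# Emulates the statistical structure of paired foramen-ovale/scalp recordings
# in temporal lobe epilepsy: intracranial channels carry interictal
# epileptiform discharges (a biphasic spike followed by a damped slow
# oscillation) on top of 1/f-like background; each scalp channel observes a
# nonlinearly mixed, attenuated and noisy combination of the intracranial
# sources, so that only a minority of discharges remain visible at the scalp.
# The scalp-visible fraction is calibrated against a fixed peak-threshold
# detector (a stand-in for the neurologist's reading that defined visibility
# in the clinical tables).

#' IED waveform template
#'
#' @param spike_width width of the biphasic spike in seconds
#' @param spike_amplitude peak amplitude in units of the background RMS
#' @param oscillation_frequency frequency (Hz) of the post-spike slow wave
#' @param oscillation_decay exponential decay time constant in seconds
#' @param polarity `+1` or `-1`
#' @return an object of class `ied_template`
#' @export
ied_template <- function(spike_width = 0.06, spike_amplitude = 8,
                         oscillation_frequency = 8, oscillation_decay = 0.08,
                         polarity = 1) {
  stopifnot(spike_width > 0, oscillation_decay > 0, polarity %in% c(-1, 1))
  structure(list(spike_width = spike_width, spike_amplitude = spike_amplitude,
                 oscillation_frequency = oscillation_frequency,
                 oscillation_decay = oscillation_decay, polarity = polarity),
            class = "ied_template")
}

#' Render an IED template into a sampled waveform
#'
#' The spike is the biphasic second derivative of a Gaussian (peak magnitude
#' equal to `spike_amplitude` at the onset sample); it is followed by an
#' exponentially damped sinusoid whose envelope decays with time constant
#' `oscillation_decay`.
#'
#' @param template an [ied_template()]
#' @param L segment length in samples
#' @param rate sampling rate in Hz
#' @param onset onset sample index (1-based position of the spike peak)
#' @return numeric vector of length `L`
#' @export
render_ied_template <- function(template, L = 64, rate = 200, onset = 32) {
  w <- template$spike_width
  if (4 * w * rate > L) stop("template wider than segment")
  t <- (seq_len(L) - onset) / rate
  s <- w / 4 # Gaussian width parameter; +/- 2w covers the biphasic lobes
  mexh <- (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))
  spike <- template$spike_amplitude * mexh
  tail_t <- t[t > 0]
  osc <- numeric(L)
  osc[t > 0] <- -0.4 * template$spike_amplitude *
    sin(2 * pi * template$oscillation_frequency * tail_t) *
    exp(-tail_t / template$oscillation_decay)
  ramp <- pmin(1, pmax(0, t / (w / 2))) # oscillation fades in after the spike
  template$polarity * (spike + osc * ramp)
}

#' Forward model from intracranial sources to scalp sensors
#'
#' Scalp = attenuation * F(intracranial %*% t(mixing)) + noise, with F either
#' the identity or a saturating tanh; IED transients are additionally scaled
#' by `spike_leakage` (deep spike sources attenuate more than ongoing
#' background), the knob used to calibrate scalp visibility.
#'
#' @param mixing_matrix numeric `M x Mbar` weight matrix
#' @param nonlinearity `"identity"` or `"saturating"`
#' @param noise_sd scalp sensor noise standard deviation (ignored when
#'   `snr_db` is supplied at simulation time)
#' @param attenuation scalar gain in (0, 1]
#' @param spike_leakage relative transmission of spike transients
#' @param saturation_gain input gain of the tanh when saturating
#' @return an object of class `forward_model`
#' @export
forward_model <- function(mixing_matrix, nonlinearity = c("saturating", "identity"),
                          noise_sd = 0.1, attenuation = 0.5, spike_leakage = 1,
                          saturation_gain = 0.25) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(all(is.finite(mixing_matrix)), noise_sd >= 0,
            attenuation > 0 || noise_sd > 0)
  structure(list(mixing_matrix = mixing_matrix, nonlinearity = nonlinearity,
                 noise_sd = noise_sd, attenuation = attenuation,
                 spike_leakage = spike_leakage,
                 saturation_gain = saturation_gain),
            class = "forward_model")
}

#' Default scalp sensitivity profiles
#'
#' Smooth nonnegative mixing weights: each scalp sensor is dominated by a few
#' nearby intracranial contacts. Smaller `width` gives sharper (better
#' conditioned) profiles.
#'
#' @param M,Mb scalp / intracranial sensor counts
#' @param width Gaussian profile width in contact units
#' @return `M x Mb` row-normalized weight matrix
#' @export
default_mixing <- function(M, Mb, width = 1.5) {
  w <- matrix(0, M, Mb)
  centers <- seq(1, Mb, length.out = M)
  for (m in seq_len(M)) {
    w[m, ] <- exp(-((seq_len(Mb) - centers[m])^2) / (2 * width^2))
  }
  w / rowSums(w)
}

#' Simulation configuration
#'
#' Defaults mirror the recording geometry of concurrent scalp/foramen-ovale
#' monitoring: 64-sample (320 ms) windows at 200 Hz, 20 scalp and 12
#' intracranial sensors, balanced IED/non-IED labels.
#'
#' @param n_subjects number of subjects
#' @param segments_per_subject paired segments per subject
#' @param L,M,M_bar segment geometry (time samples, scalp sensors,
#'   intracranial sensors)
#' @param sampling_rate Hz
#' @param ied_fraction fraction of segments labeled IED (exact count)
#' @param target_visible_fraction scalp-visible IED fraction the forward model
#'   is calibrated to (`NULL` to skip calibration)
#' @param snr_db scalp signal-to-noise ratio in dB
#' @param seed master seed; the cohort is a pure function of the configuration
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_subjects = 5, segments_per_subject = 100,
                              L = 64, M = 20, M_bar = 12, sampling_rate = 200,
                              ied_fraction = 0.5,
                              target_visible_fraction = 0.188,
                              snr_db = 6, seed = 1) {
  stopifnot(L > 0, M > 1, M_bar > 0, ied_fraction >= 0, ied_fraction <= 1)
  structure(list(n_subjects = n_subjects,
                 segments_per_subject = segments_per_subject, L = L, M = M,
                 M_bar = M_bar, sampling_rate = sampling_rate,
                 ied_fraction = ied_fraction,
                 target_visible_fraction = target_visible_fraction,
                 snr_db = snr_db, seed = seed),
            class = "simulation_config")
}

default_templates <- function(n = 3) {
  lapply(seq_len(n), function(i) {
    ied_template(spike_width = 0.05 + 0.01 * (i - 1),
                 spike_amplitude = 8,
                 oscillation_frequency = 6 + 2 * (i - 1),
                 oscillation_decay = 0.06 + 0.02 * (i - 1),
                 polarity = c(1, -1, 1)[(i - 1) %% 3 + 1])
  })
}

# pink-ish background: white noise shaped by a leaky integrator cascade,
# standardized to unit RMS, with weak common-mode channel correlation
sim_background <- function(L, n_ch, common = 0.3) {
  raw <- matrix(stats::rnorm(L * n_ch), L, n_ch)
  cm <- stats::rnorm(L)
  raw <- sqrt(1 - common^2) * raw + common * cm
  shaped <- apply(raw, 2, function(x) {
    y <- stats::filter(x, 0.9, method = "recursive")
    as.numeric(y)
  })
  shaped <- sweep(shaped, 2, apply(shaped, 2, stats::sd), "/")
  shaped
}

sim_ied_segment <- function(L, Mb, rate, templates, onset = L / 2) {
  bg <- sim_background(L, Mb)
  tmpl <- templates[[sample.int(length(templates), 1)]]
  n_active <- sample(4:min(8, Mb), 1)
  active <- sample.int(Mb, n_active)
  gains <- stats::runif(n_active, 0.6, 1.4)
  wave <- render_ied_template(tmpl, L, rate, onset)
  spikes <- matrix(0, L, Mb)
  for (j in seq_along(active)) spikes[, active[j]] <- gains[j] * wave
  list(background = bg, spikes = spikes)
}

scalp_mix <- function(bg, spikes, fwd) {
  mixed_bg <- bg %*% t(fwd$mixing_matrix)
  mixed_sp <- spikes %*% t(fwd$mixing_matrix)
  pre <- mixed_bg + fwd$spike_leakage * mixed_sp
  if (fwd$nonlinearity == "saturating")
    pre <- tanh(fwd$saturation_gain * pre) / fwd$saturation_gain
  fwd$attenuation * pre
}

#' Simulate one subject's paired segments
#'
#' Intracranial segments are 1/f-like background plus (for IED segments) a
#' spike/damped-oscillation transient on a random sensor subset; scalp
#' segments are the forward-mixed, optionally saturated, attenuated signals
#' plus Gaussian noise at `cfg$snr_db`. The same `subject_seed` always
#' reproduces the subject bit-exactly.
#'
#' @param cfg a [simulation_config()]
#' @param fwd a [forward_model()] (default mixing if `NULL`)
#' @param templates list of [ied_template()]s
#' @param subject_seed integer seed for this subject
#' @param subject_id identifier stamped on the segments
#' @return a [subject_record()]; attribute `components` stores the simulator's
#'   own signal/noise decomposition (per-segment scalp signal and noise parts)
#' @export
simulate_subject <- function(cfg, fwd = NULL, templates = default_templates(),
                             subject_seed = 1, subject_id = "S1") {
  if (is.null(fwd)) fwd <- forward_model(default_mixing(cfg$M, cfg$M_bar))
  set.seed(subject_seed %% 2147483647)
  n <- cfg$segments_per_subject
  n_ied <- round(cfg$ied_fraction * n)
  labels <- c(rep("IED", n_ied), rep("nonIED", n - n_ied))
  L <- cfg$L
  rate <- cfg$sampling_rate
  sc_sig <- array(0, c(n, L, cfg$M))
  sc_noise <- array(0, c(n, L, cfg$M))
  ic <- array(0, c(n, L, cfg$M_bar))
  for (i in seq_len(n)) {
    if (labels[i] == "IED") {
      parts <- sim_ied_segment(L, cfg$M_bar, rate, templates)
    } else {
      parts <- list(background = sim_background(L, cfg$M_bar),
                    spikes = matrix(0, L, cfg$M_bar))
    }
    ic[i, , ] <- parts$background + parts$spikes
    sc_sig[i, , ] <- scalp_mix(parts$background, parts$spikes, fwd)
  }
  p_sig <- mean(sc_sig^2)
  if (p_sig == 0) stop("zero scalp signal power; snr_db is undefined")
  noise_sd <- sqrt(p_sig / 10^(cfg$snr_db / 10))
  if (fwd$noise_sd == 0) noise_sd <- 0
  sc_noise[] <- stats::rnorm(length(sc_noise), sd = noise_sd)
  sc <- sc_sig + sc_noise
  # one normalization per subject recording, as applied before training
  scale_sc <- max(abs(sc))
  scale_ic <- max(abs(ic))
  segs <- arrays_to_segments(sc / scale_sc, ic / scale_ic, labels, subject_id,
                             rate)
  onset <- L / 2
  for (i in which(labels == "IED")) segs[[i]]$scalp$onset_index <- onset
  rec <- subject_record(subject_id, segs, n_ied_total = n_ied)
  attr(rec, "components") <- list(signal = sc_sig / scale_sc,
                                  noise = sc_noise / scale_sc,
                                  scalp_scale = scale_sc,
                                  intracranial_scale = scale_ic,
                                  onset = onset)
  rec
}

#' Fraction of IED segments visible at the scalp
#'
#' A fixed peak-threshold detector: an IED segment counts as scalp-visible
#' when, on any scalp channel, the peak absolute amplitude inside the onset
#' window exceeds `detector_threshold` times that channel's robust (MAD)
#' amplitude outside the window.
#'
#' @param record a [subject_record()] (or list of paired segments)
#' @param detector_threshold peak-to-background ratio required for visibility
#' @return fraction in `[0, 1]`
#' @export
measure_visible_fraction <- function(record, detector_threshold = 6) {
  segments <- if (inherits(record, "subject_record")) record$segments else record
  ied <- Filter(function(s) s$label == "IED", segments)
  if (!length(ied)) stop("record contains no IED segments")
  vis <- vapply(ied, function(s) {
    x <- s$scalp$samples
    L <- nrow(x)
    onset <- if (!is.null(s$scalp$onset_index)) s$scalp$onset_index else L / 2
    win <- max(1, onset - 8):min(L, onset + 8)
    ratios <- vapply(seq_len(ncol(x)), function(ch) {
      bg <- stats::mad(x[-win, ch])
      if (bg == 0) return(Inf * max(abs(x[win, ch])))
      max(abs(x[win, ch])) / bg
    }, numeric(1))
    max(ratios) > detector_threshold
  }, logical(1))
  mean(vis)
}

# choose spike_leakage by bisection so the threshold detector reproduces the
# target scalp-visible fraction on a dedicated calibration subject
calibrate_leakage <- function(cfg, fwd, templates, target, seed,
                              n_probe = 800, tol = 0.008) {
  probe_cfg <- cfg
  probe_cfg$segments_per_subject <- n_probe
  probe_cfg$ied_fraction <- 1
  frac_at <- function(leak) {
    f <- fwd
    f$spike_leakage <- leak
    rec <- simulate_subject(probe_cfg, f, templates, subject_seed = seed,
                            subject_id = "CAL")
    measure_visible_fraction(rec)
  }
  lo <- 0.01
  hi <- 4
  flo <- frac_at(lo)
  fhi <- frac_at(hi)
  if (flo >= target) return(lo)
  if (fhi <= target) return(hi)
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    fm <- frac_at(mid)
    if (abs(fm - target) < tol) return(mid)
    if (fm < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a full annotated cohort
#'
#' When `cfg$target_visible_fraction` is set, the forward model's spike
#' transmission is first calibrated so the peak-threshold detector reproduces
#' that scalp-visible IED fraction, then per-subject recordings are generated
#' with seeds derived deterministically from `cfg$seed`. Per-subject records
#' carry total and scalp-visible IED counts.
#'
#' @param cfg a [simulation_config()]
#' @param fwd optional [forward_model()]
#' @param templates list of [ied_template()]s
#' @return a [subject_cohort()]; attribute `forward_model` holds the
#'   (possibly calibrated) model used
#' @export
simulate_cohort <- function(cfg, fwd = NULL, templates = default_templates()) {
  if (is.null(fwd)) fwd <- forward_model(default_mixing(cfg$M, cfg$M_bar))
  if (!is.null(cfg$target_visible_fraction)) {
    fwd$spike_leakage <- calibrate_leakage(cfg, fwd, templates,
                                           cfg$target_visible_fraction,
                                           seed = (as.numeric(cfg$seed) * 1000) %% 2147483629)
  }
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
    rec <- simulate_subject(cfg, fwd, templates,
                            subject_seed = (cfg$seed + 7919L * i) %% 2147483647,
                            subject_id = paste0("S", i))
    rec$n_ied_visible <- round(measure_visible_fraction(rec) * rec$n_ied_total)
    rec
  })
  cohort <- subject_cohort(subjects)
  attr(cohort, "forward_model") <- fwd
  cohort
}

#' Simulate a continuous paired recording with annotated IED onsets
#'
#' Produces the continuous analogue of [simulate_subject()]: background with
#' IED transients inserted at spaced random onsets, mixed to the scalp through
#' the same forward model. Intended as input to [preprocess_recording()] and
#' [extract_segments()].
#'
#' @param duration_s recording duration in seconds
#' @param cfg a [simulation_config()] (geometry and SNR are used)
#' @param fwd optional [forward_model()]
#' @param templates list of [ied_template()]s
#' @param n_ieds number of IED events to insert
#' @param seed RNG seed
#' @return list with `scalp`, `intracranial` (T x sensors matrices),
#'   `onsets` (sample indices) and `sampling_rate`
#' @export
simulate_continuous <- function(duration_s = 60, cfg = simulation_config(),
                                fwd = NULL, templates = default_templates(),
                                n_ieds = 20, seed = 1) {
  if (is.null(fwd)) fwd <- forward_model(default_mixing(cfg$M, cfg$M_bar))
  set.seed(seed %% 2147483647)
  rate <- cfg$sampling_rate
  Tn <- as.integer(duration_s * rate)
  bg <- sim_background(Tn, cfg$M_bar)
  guard <- cfg$L
  slots <- seq(guard + 1, Tn - guard, by = max(2 * cfg$L, (Tn - 2 * guard) %/% max(n_ieds, 1)))
  onsets <- sort(sample(slots, min(n_ieds, length(slots))))
  spikes <- matrix(0, Tn, cfg$M_bar)
  for (o in onsets) {
    seg <- sim_ied_segment(cfg$L, cfg$M_bar, rate, templates, onset = cfg$L / 2)
    idx <- (o - cfg$L / 2 + 1):(o + cfg$L / 2)
    spikes[idx, ] <- spikes[idx, ] + seg$spikes
  }
  sc_sig <- scalp_mix(bg, spikes, fwd)
  p_sig <- mean(sc_sig^2)
  noise_sd <- if (fwd$noise_sd == 0) 0 else sqrt(p_sig / 10^(cfg$snr_db / 10))
  sc <- sc_sig + matrix(stats::rnorm(length(sc_sig), sd = noise_sd), Tn, cfg$M)
  list(scalp = sc, intracranial = bg + spikes, onsets = onsets,
       sampling_rate = rate)
}
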