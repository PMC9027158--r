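#' Configuration for the surrogate EEG generator
#'
#' Two balanced classes of subjects, each subject a multichannel
#' recording.  Every channel is a second-order autoregressive resonance
#' (a damped stochastic oscillator) plus white measurement noise: a
#' deliberately simple surrogate whose class signal is a shift of the
#' spectral peak, sufficient to exercise textural features without
#' claiming physiological realism.  Class 0 peaks at \code{f0} Hz and
#' class 1 at \code{f0 + effect_size * delta_f} Hz, so
#' \code{effect_size = 0} makes the classes exchangeable.
#' \code{subject_sd} adds a per-subject random offset to the peak
#' frequency (in Hz), emulating individual-rhythm variation: segments of
#' one subject share a spectral fingerprint with no class information,
#' which is the mechanism that lets segment-level cross-validation
#' overestimate accuracy while leave-one-subject-out stays honest.  The
#' sign-comparison features are invariant to positive affine transforms
#' of the signal, so a plain amplitude offset would be invisible to the
#' pipeline; the offset therefore acts on the spectral parameter.
#'
#' @param n_subjects_per_class subjects per class (default 14).
#' @param n_channels channels per recording (default 19, standard 10-20
#'   montage names).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s recording length per subject in seconds (default 50,
#'   i.e. two 25 s segments).
#' @param effect_size nonnegative spectral separation multiplier
#'   (default 1).
#' @param subject_sd standard deviation in Hz of the per-subject peak
#'   frequency offset (default 0).
#' @param f0 class-0 peak frequency in Hz (default 9, an alpha-band
#'   rhythm).
#' @param delta_f peak shift in Hz per unit effect size (default 2).
#' @param ar_r pole radius of the AR(2) resonance, in (0, 1); closer to 1
#'   means a sharper spectral peak (default 0.97).
#' @param osc_amp oscillation amplitude relative to unit-variance noise
#'   (default 2).
#' @param seed integer seed.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects_per_class = 14L, n_channels = 19L,
                       fs = 250, duration_s = 50, effect_size = 1,
                       subject_sd = 0, f0 = 9, delta_f = 2, ar_r = 0.97,
                       osc_amp = 2, seed = 1L) {
  cfg <- list(n_subjects_per_class = as.integer(n_subjects_per_class),
              n_channels = as.integer(n_channels), fs = fs,
              duration_s = duration_s, effect_size = effect_size,
              subject_sd = subject_sd, f0 = f0, delta_f = delta_f,
              ar_r = ar_r, osc_amp = osc_amp, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects_per_class >= 1L, n_channels >= 1L, fs > 0,
              duration_s > 0, effect_size >= 0, subject_sd >= 0,
              f0 > 0, delta_f >= 0, ar_r > 0, ar_r < 1, osc_amp >= 0)
  })
  structure(cfg, class = "sim_config")
}

# standard 10-20 montage labels used by the 19-channel default
montage_10_20 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                   "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Simulate a two-class multichannel surrogate EEG dataset
#'
#' @param cfg a [sim_config()].
#' @return list with \code{records} (list of [signal_record()]) and
#'   \code{manifest} (data frame with subject_id, label, fs, n_samples,
#'   n_channels).  Fully reproducible from \code{cfg$seed}.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_samp <- round(cfg$fs * cfg$duration_s)
  if (cfg$n_channels <= length(montage_10_20)) {
    ch_names <- montage_10_20[seq_len(cfg$n_channels)]
  } else {
    ch_names <- paste0("ch", seq_len(cfg$n_channels))
  }
  records <- list()
  for (cl in 0:1) {
    f_peak <- cfg$f0 + cl * cfg$effect_size * cfg$delta_f
    for (s in seq_len(cfg$n_subjects_per_class)) {
      f_subj <- f_peak + stats::rnorm(1L, 0, cfg$subject_sd)
      f_subj <- min(max(f_subj, 1), cfg$fs / 2 - 1)  # keep below Nyquist
      x <- vapply(seq_len(cfg$n_channels), function(ch) {
        ar2_oscillation(n_samp, f_subj, cfg$fs, cfg$ar_r) * cfg$osc_amp +
          stats::rnorm(n_samp)
      }, numeric(n_samp))
      records[[length(records) + 1L]] <- signal_record(
        x, fs = cfg$fs,
        subject_id = sprintf("S%d_%02d", cl, s),
        label = cl, channel_names = ch_names)
    }
  }
  manifest <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    label = vapply(records, function(r) r$label, integer(1)),
    fs = cfg$fs, n_samples = n_samp, n_channels = cfg$n_channels,
    stringsAsFactors = FALSE)
  list(records = records, manifest = manifest)
}

# unit-variance AR(2) resonance with spectral peak near f_peak Hz
ar2_oscillation <- function(n, f_peak, fs, r) {
  phi <- c(2 * r * cos(2 * pi * f_peak / fs), -r^2)
  burn <- 200L
  x <- stats::filter(stats::rnorm(n + burn), phi, method = "recursive")
  x <- as.numeric(x)[(burn + 1L):(burn + n)]
  x / stats::sd(x)
}
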