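# Synthetic annotated ECG records with the four AAMI beat morphologies.
#
# Beats are sums of five Gaussian deflections (P, Q, R, S, T); the generator
# is a morphological stand-in for real ambulatory recordings whose contract
# is separability of the four classes plus realistic noise and inter-patient
# variability, not physiological fidelity.

.wave_names <- c("P", "Q", "R", "S", "T")
.wave_cols <- c("amp", "center", "width")

# Default (amplitude mV, center ms relative to R, Gaussian sd ms) per class.
# N: dominant narrow R, normal P and upright T.
# S (APC-like): flattened/ectopic P, otherwise near-normal QRS; the premature
#   timing cue is added by synth_record (shortened preceding RR).
# V (PVC-like): absent P, wide tall QRS with deep S and discordant T.
.class_wave_defaults <- function(aami_class) {
  tab <- switch(aami_class,
    N = rbind(
      P = c(0.15, -170, 22),
      Q = c(-0.12, -25, 9),
      R = c(1.00, 0, 11),
      S = c(-0.25, 28, 10),
      T = c(0.35, 220, 45)
    ),
    S = rbind(
      P = c(0.05, -150, 30),
      Q = c(-0.10, -25, 9),
      R = c(0.95, 0, 11),
      S = c(-0.22, 28, 10),
      T = c(0.30, 200, 42)
    ),
    V = rbind(
      P = c(0.00, -170, 22),
      Q = c(-0.28, -50, 16),
      R = c(1.40, 0, 30),
      S = c(-0.45, 60, 20),
      T = c(-0.40, 240, 55)
    ),
    stop("unknown AAMI class: ", aami_class, call. = FALSE)
  )
  colnames(tab) <- .wave_cols
  tab
}

#' Beat template for one AAMI class
#'
#' Builds the five-deflection (P, Q, R, S, T) Gaussian parameter set for one
#' of the four AAMI classes used as classification targets. Class `"F"`
#' (fusion) is the convex blend, weight 1/2, of an `"N"` and a `"V"`
#' template. `jitter_sd > 0` perturbs amplitudes and widths multiplicatively
#' (log-normal factors drawn from the current RNG stream), emulating
#' morphology variability; wave centers are left at the class defaults.
#'
#' @param aami_class one of `"N"`, `"S"`, `"V"`, `"F"`.
#' @param jitter_sd standard deviation (log scale) of the multiplicative
#'   jitter applied to wave amplitudes and widths; `0` is deterministic.
#' @return an object of class `beat_template`: a list with `aami_class` and
#'   `waves`, a 5 x 3 matrix (rows P, Q, R, S, T; columns amp \[mV\],
#'   center \[ms relative to R\], width \[ms\]).
#' @examples
#' tpl <- beat_template("V")
#' tpl$waves["P", "amp"] # ventricular beats carry no P wave
#' @export
beat_template <- function(aami_class, jitter_sd = 0) {
  stopifnot(length(aami_class) == 1, jitter_sd >= 0)
  if (!aami_class %in% aami_classes()) {
    stop("unknown AAMI class: ", aami_class, call. = FALSE)
  }
  if (aami_class == "F") {
    n <- beat_template("N", jitter_sd)
    v <- beat_template("V", jitter_sd)
    waves <- 0.5 * n$waves + 0.5 * v$waves
  } else {
    waves <- .class_wave_defaults(aami_class)
    if (jitter_sd > 0) {
      fac_amp <- exp(stats::rnorm(nrow(waves), 0, jitter_sd))
      fac_width <- exp(stats::rnorm(nrow(waves), 0, jitter_sd))
      waves[, "amp"] <- waves[, "amp"] * fac_amp
      waves[, "width"] <- waves[, "width"] * fac_width
    }
  }
  structure(list(aami_class = aami_class, waves = waves),
            class = "beat_template")
}

#' QRS span of a beat template
#'
#' Span in ms from one Gaussian width before the Q center to one width after
#' the S center, the convention used by the class invariants (ventricular
#' templates span at least 120 ms).
#'
#' @param template a [beat_template()].
#' @return span in ms.
#' @export
qrs_span <- function(template) {
  w <- template$waves
  (w["S", "center"] + w["S", "width"]) - (w["Q", "center"] - w["Q", "width"])
}

#' Render a beat template to a sampled waveform
#'
#' Evaluates the sum of the five Gaussian deflections on a sample grid
#' spanning `-round(0.3 fs) .. +round(0.4 fs)` samples around the R center
#' (the segmentation window plus one sample).
#'
#' @param template a [beat_template()].
#' @param fs sampling rate in Hz.
#' @return numeric waveform in mV with attribute `r_index`, the 1-based
#'   sample at the R center (t = 0).
#' @export
render_beat <- function(template, fs) {
  stopifnot(fs > 0)
  pre <- round(0.3 * fs)
  post <- round(0.4 * fs)
  t_ms <- (seq(-pre, post) / fs) * 1000
  w <- template$waves
  y <- rep(0, length(t_ms))
  for (i in seq_len(nrow(w))) {
    y <- y + w[i, "amp"] * exp(-(t_ms - w[i, "center"])^2 / (2 * w[i, "width"]^2))
  }
  attr(y, "r_index") <- pre + 1L
  y
}

#' Synthesize an annotated single-lead ECG record
#'
#' Places rendered beats at (jittered) RR intervals, shortening the RR
#' preceding a premature beat (classes S and V) by `premature_factor`, then
#' adds baseline wander and powerline sinusoids and white noise. Annotations
#' carry the true R sample (1-based) of every beat.
#'
#' @param class_sequence character vector of AAMI classes (N, S, V, F), one
#'   per beat, in time order.
#' @param mean_rr_ms mean RR interval in ms; must exceed the 700 ms
#'   segmentation window.
#' @param rr_jitter_sd standard deviation (ms) of Gaussian RR jitter.
#' @param premature_factor factor applied to the RR preceding an S or V beat.
#' @param baseline_amp,baseline_freq baseline-wander sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param powerline_amp,powerline_freq powerline sinusoid amplitude (mV) and
#'   frequency (Hz); 60 Hz matches the MIT-BIH recording environment.
#' @param noise_sd standard deviation (mV) of additive white noise.
#' @param fs sampling rate in Hz (MIT-BIH convention: 360).
#' @param jitter_sd per-record template morphology jitter, passed to
#'   [beat_template()] when `templates` is `NULL`.
#' @param templates optional named list of `beat_template`s (names among
#'   N, S, V, F) to use instead of freshly built ones.
#' @param patient_id identifier stored with the record.
#' @return an object of class `synth_record`: list with `signal` (mV),
#'   `fs`, `annotations` (data.frame `sample`, `aami_class`), `templates`,
#'   `patient_id`.
#' @examples
#' set.seed(1)
#' rec <- synth_record(c("N", "N", "V", "N"), noise_sd = 0)
#' nrow(rec$annotations)
#' @export
synth_record <- function(class_sequence,
                         mean_rr_ms = 800,
                         rr_jitter_sd = 20,
                         premature_factor = 0.7,
                         baseline_amp = 0.15,
                         baseline_freq = 0.3,
                         powerline_amp = 0.05,
                         powerline_freq = 60,
                         noise_sd = 0.02,
                         fs = 360,
                         jitter_sd = 0,
                         templates = NULL,
                         patient_id = "synthetic") {
  if (length(class_sequence) == 0) {
    stop("class_sequence must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(class_sequence), aami_classes())
  if (length(bad) > 0) {
    stop("unknown AAMI class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (mean_rr_ms <= 700) {
    stop("mean_rr_ms must exceed the 700 ms segmentation window", call. = FALSE)
  }
  if (is.null(templates)) {
    templates <- stats::setNames(
      lapply(aami_classes(), beat_template, jitter_sd = jitter_sd),
      aami_classes()
    )
  }
  n_beats <- length(class_sequence)
  rr <- mean_rr_ms + stats::rnorm(n_beats, 0, rr_jitter_sd)
  rr <- pmax(rr, 250)
  premature <- class_sequence %in% c("S", "V")
  rr[premature] <- rr[premature] * premature_factor
  r_ms <- 500 + cumsum(c(0, rr[-1]))
  r_samples <- round(r_ms * fs / 1000) + 1L
  n <- max(r_samples) + round(0.5 * fs)

  signal <- rep(0, n)
  pre <- round(0.3 * fs)
  for (i in seq_len(n_beats)) {
    beat <- render_beat(templates[[class_sequence[i]]], fs)
    idx <- seq(r_samples[i] - pre, length.out = length(beat))
    keep <- idx >= 1 & idx <= n
    signal[idx[keep]] <- signal[idx[keep]] + beat[keep]
  }
  t <- (seq_len(n) - 1) / fs
  signal <- signal +
    baseline_amp * sin(2 * pi * baseline_freq * t) +
    powerline_amp * sin(2 * pi * powerline_freq * t)
  if (noise_sd > 0) signal <- signal + stats::rnorm(n, 0, noise_sd)

  structure(
    list(
      signal = signal,
      fs = fs,
      annotations = data.frame(
        sample = r_samples,
        aami_class = class_sequence,
        stringsAsFactors = FALSE
      ),
      templates = templates,
      patient_id = patient_id
    ),
    class = "synth_record"
  )
}

#' Synthesize a cohort of patients with inter-patient morphology variability
#'
#' Each patient receives its own jittered beat templates (shared across that
#' patient's beats, distinct across patients), giving the inter-/intra-patient
#' structure needed to exercise patient-specific adaptation. Beat classes are
#' drawn independently from `class_mix`.
#'
#' @param n_patients number of patients (at least 2).
#' @param beats_per_patient beats per record.
#' @param class_mix named numeric vector of class probabilities over
#'   N, S, V, F; must sum to 1.
#' @param patient_shift_sd log-scale SD of the per-patient multiplicative
#'   template jitter (amplitudes and widths). The default 0.3 emulates the
#'   large amplitude variability seen across subjects and electrode
#'   placements.
#' @param ... further arguments passed to [synth_record()] (noise levels,
#'   `fs`, RR parameters, ...).
#' @return list of [synth_record()] objects.
#' @export
synth_cohort <- function(n_patients = 10,
                         beats_per_patient = 400,
                         class_mix = c(N = 0.70, S = 0.10, V = 0.15, F = 0.05),
                         patient_shift_sd = 0.3,
                         ...) {
  stopifnot(n_patients >= 2, beats_per_patient >= 1)
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), aami_classes())) {
    stop("class_mix must be named with exactly N, S, V, F", call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1", call. = FALSE)
  }
  lapply(seq_len(n_patients), function(i) {
    templates <- stats::setNames(
      lapply(aami_classes(), beat_template, jitter_sd = patient_shift_sd),
      aami_classes()
    )
    classes <- sample(names(class_mix), beats_per_patient,
                      replace = TRUE, prob = class_mix)
    synth_record(classes, templates = templates,
                 patient_id = sprintf("P%02d", i), ...)
  })
}
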