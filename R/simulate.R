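#' Default SSEP microstate scripts
#'
#' Builds the scripted sequence of quasi-stable scalp topographies that the
#' simulator plants in synthetic recordings. The median-nerve script has
#' K = 4 states with boundaries at 6, 12.8, 15.2, 25.6 and 50 ms
#' post-stimulus; the tibial-nerve script has K = 3 states starting at
#' 10.8 ms and ending at 60 ms. Each state's template is the
#' average-referenced, unit-GFP scalp map of a planted dipole computed with
#' the 3-shell sphere forward model: a deep posterior source for the
#' brainstem-like first state (left-side stimulation, so later sources sit
#' in the right hemisphere for the median script and near the midline for
#' the tibial script), and a polarity reversal between the last two states.
#' The placements are stylized, not anatomically validated. The per-state
#' GFP envelope is a raised-cosine bump peaking near the classical component
#' latencies (brainstem-like ~6.9 ms, main cortical ~17.9 ms) on a floor of
#' 30 % of the state's peak, mimicking a GFP waveform that stays well above
#' zero between components so state transitions remain crisp.
#'
#' @param kind `"median"` or `"tibial"` (left-side stimulation layout)
#' @param montage an `ssep_montage`
#' @param head an `ssep_head`
#' @return an `ssep_script` with elements `kind`, `K`, `boundaries` (ms),
#'   `peak_ms`, `peak_gfp` (uV), `floor`, `dipoles`, `templates`
#'   (electrodes x K, zero-mean, unit GFP), `montage`, `head`
#' @export
make_default_script <- function(kind = c("median", "tibial"),
                                montage = macaque33_montage(),
                                head = head_model()) {
  kind <- match.arg(kind)
  rb <- brain_radius(head)
  sc <- rb / 27.2   # placements below are tuned for the default geometry
  if (kind == "median") {
    boundaries <- c(6, 12.8, 15.2, 25.6, 50)
    peak_ms <- c(6.9, 13.8, 17.9, 32)
    peak_gfp <- c(1.2, 2.0, 3.0, 2.0)
    dipoles <- list(
      list(pos = sc * c(2, -15, -12),  mom = c(0, 5, 4)),    # brainstem-like
      list(pos = sc * c(10, 5, 16),    mom = c(4, 6, 2)),    # contralateral fronto-parietal
      list(pos = sc * c(12, -2, 18),   mom = c(2, 0, 5)),    # contralateral parietal
      list(pos = sc * c(10, -6, 18),   mom = -c(2, 0, 5)))   # voltage inversion of state 3
  } else {
    boundaries <- c(10.8, 16.4, 29.2, 60)
    peak_ms <- c(12.7, 21.6, 40)
    peak_gfp <- c(1.0, 2.5, 1.5)
    dipoles <- list(
      list(pos = sc * c(0, 0, 18),   mom = c(0, 5, -4)),     # midline fronto-central
      list(pos = sc * c(0, -4, 20),  mom = c(0, 1, 5)),      # midline central positivity
      list(pos = sc * c(0, -7, 19),  mom = -c(0, 1, 5)))     # reversal of state 2
  }
  templates <- script_templates(dipoles, montage, head)
  structure(list(kind = kind, K = length(dipoles), boundaries = boundaries,
                 peak_ms = peak_ms, peak_gfp = peak_gfp, floor = 0.3,
                 dipoles = dipoles, templates = templates,
                 montage = montage, head = head),
            class = "ssep_script")
}

# average-referenced unit-GFP template of each planted dipole for a given
# (possibly perturbed) montage
script_templates <- function(dipoles, montage, head) {
  tm <- vapply(dipoles, function(d)
    forward_topography(head, montage, d$pos, d$mom), numeric(length(montage$labels)))
  tm <- sweep(tm, 2, colMeans(tm))
  tm <- sweep(tm, 2, apply(tm, 2, gfp), "/")
  rownames(tm) <- montage$labels
  tm
}

#' @export
print.ssep_script <- function(x, ...) {
  cat("<ssep_script> ", x$kind, " nerve, K = ", x$K, ", boundaries ",
      paste(x$boundaries, collapse = "/"), " ms\n", sep = "")
  invisible(x)
}

#' Per-frame state label and GFP envelope of a script
#'
#' State intervals are half-open `[onset, offset)`; frames outside every
#' state get label `NA` and envelope 0.
#' @param script an `ssep_script`
#' @param times frame times in ms
#' @return `script_labels`: integer vector (NA outside states);
#'   `script_envelope`: target GFP (uV) per frame
#' @export
script_labels <- function(script, times) {
  lab <- rep(NA_integer_, length(times))
  for (k in seq_len(script$K)) {
    lab[times >= script$boundaries[k] & times < script$boundaries[k + 1]] <- k
  }
  lab
}

#' @rdname script_labels
#' @export
script_envelope <- function(script, times) {
  env <- numeric(length(times))
  for (k in seq_len(script$K)) {
    on <- script$boundaries[k]; off <- script$boundaries[k + 1]
    pk <- script$peak_ms[k]
    sel <- times >= on & times < off
    t <- times[sel]
    half <- ifelse(t <= pk, (t - on) / max(pk - on, 1e-9),
                   (off - t) / max(off - pk, 1e-9))
    bump <- 0.5 - 0.5 * cos(pi * pmin(pmax(half, 0), 1))
    env[sel] <- script$peak_gfp[k] *
      (script$floor + (1 - script$floor) * bump)
  }
  env
}

#' Noise-free script signal
#'
#' The planted multichannel signal: at each frame, the active state's
#' template scaled to the envelope GFP. `reference = "vertex"` returns the
#' recorded-channel view (reference potential subtracted, reference row
#' dropped), which is what an amplifier referenced at the vertex measures.
#' @param script an `ssep_script`
#' @param times frame times (ms)
#' @param montage montage to evaluate the planted dipoles on (defaults to
#'   the script's); the session synthesizer passes the perturbed cap here
#' @param reference `"average"` (all electrodes, zero-mean maps) or
#'   `"vertex"` (recorded channels only)
#' @return channels x frames matrix (uV)
#' @export
script_signal <- function(script, times, montage = script$montage,
                          reference = c("average", "vertex"),
                          templates = NULL) {
  reference <- match.arg(reference)
  tm <- if (!is.null(templates)) templates
        else if (identical(montage, script$montage)) script$templates
        else script_templates(script$dipoles, montage, script$head)
  lab <- script_labels(script, times)
  env <- script_envelope(script, times)
  X <- matrix(0, nrow(tm), length(times))
  ok <- !is.na(lab)
  X[, ok] <- tm[, lab[ok], drop = FALSE] *
    rep(env[ok], each = nrow(tm))
  rownames(X) <- montage$labels
  if (reference == "vertex") {
    X <- sweep(X, 2, X[montage$reference, ])
    X <- X[rownames(X) != montage$reference, , drop = FALSE]
  }
  X
}

#' Trial noise specification
#'
#' All values are free choices of the simulator (no quantitative single-trial
#' SNR was ever published for this preparation); the defaults give a
#' single-trial SNR well below 0 dB that recovers clean evoked responses
#' after ~80-sweep averaging, with session-to-session variability dominated
#' by the trial latency jitter.
#' The session-level stability they produce (mean per-map SC about 0.9,
#' onset-latency SDs of a few tenths of a millisecond after ~80-sweep
#' averaging) matches the stability reported for real repeated SSEP
#' sessions in this preparation.
#' @param sensor_sd white sensor noise SD per channel (uV)
#' @param background_amp RMS of spatially correlated brain background (uV)
#' @param latency_jitter_sd trial latency jitter SD (ms)
#' @param amplitude_jitter_sd multiplicative trial amplitude jitter SD
#' @param line_amp 50 Hz line interference amplitude (uV; 0 = off)
#' @param artifact_fraction fraction of trials carrying a planted artifact
#' @param artifact_amp artifact amplitude (uV; must exceed the rejection
#'   threshold to be detectable)
#' @return an `ssep_noise` list
#' @export
noise_spec <- function(sensor_sd = 3, background_amp = 2,
                       latency_jitter_sd = 0.5, amplitude_jitter_sd = 0.1,
                       line_amp = 0, artifact_fraction = 0,
                       artifact_amp = 150) {
  structure(list(sensor_sd = sensor_sd, background_amp = background_amp,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 line_amp = line_amp, artifact_fraction = artifact_fraction,
                 artifact_amp = artifact_amp),
            class = "ssep_noise")
}

# spatially correlated background: a few random interior dipole maps driven
# by AR(1)-smoothed noise, scaled to a target per-channel RMS
background_noise <- function(n_ch, n_t, montage, head, amp, n_gen = 5) {
  if (amp <= 0) return(matrix(0, n_ch, n_t))
  rb <- brain_radius(head)
  dirs <- matrix(stats::rnorm(n_gen * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- dirs * (0.7 * rb * stats::runif(n_gen)^(1 / 3))
  mom <- matrix(stats::rnorm(n_gen * 3), ncol = 3)
  maps <- forward_gain(head, montage, pos, moments = mom, reference = "raw")
  maps <- sweep(maps, 2, sqrt(colMeans(maps^2)), "/")
  ref <- montage$reference
  maps <- sweep(maps, 2, maps[ref, ])[rownames(maps) != ref, , drop = FALSE]
  tc <- matrix(stats::rnorm(n_gen * n_t), n_gen, n_t)
  for (g in seq_len(n_gen))
    tc[g, ] <- as.numeric(stats::filter(tc[g, ], 0.95, method = "recursive"))
  x <- maps %*% tc
  x * amp / sqrt(mean(x^2))
}

#' Synthesize an epoch set directly (no continuous carrier)
#'
#' The efficient generation path used for multi-session experiments: each
#' trial is the script signal with seeded latency and amplitude jitter plus
#' spatially correlated background and white sensor noise, on the recorded
#' (vertex-referenced) channels. Planted artifact trials get a square pulse
#' on 3 random channels. Returns the epoch set together with the ground
#' truth that generated it.
#'
#' @param script an `ssep_script`
#' @param noise an `ssep_noise`
#' @param n_trials number of trials (default 90, i.e. 3 min at 0.5 Hz)
#' @param window epoch window `c(t0, t1)` ms
#' @param rate sampling rate (Hz)
#' @param seed RNG seed (required; all randomness is reproducible)
#' @param montage session montage override (perturbed cap); defaults to the
#'   script's montage
#' @return list with `epochs` (`ssep_epochs`) and `truth` (list: script,
#'   labels per frame, dipoles, artifact trials, jitter draws, snr_db)
#' @export
synthesize_epochs <- function(script, noise = noise_spec(), n_trials = 90,
                              window = c(-100, 200), rate = 5000, seed,
                              montage = script$montage) {
  set.seed(seed)
  times <- epoch_times(window, rate)
  n_t <- length(times)
  rec_ch <- recorded_channels(montage)
  n_ch <- length(rec_ch)
  tm <- if (identical(montage, script$montage)) script$templates
        else script_templates(script$dipoles, montage, script$head)
  jit <- stats::rnorm(n_trials, 0, noise$latency_jitter_sd)
  amp <- 1 + stats::rnorm(n_trials, 0, noise$amplitude_jitter_sd)
  n_art <- floor(noise$artifact_fraction * n_trials)
  art_trials <- if (n_art > 0) sort(sample(n_trials, n_art)) else integer(0)
  dat <- array(0, dim = c(n_trials, n_ch, n_t))
  base_sig <- NULL
  p_sig <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    sig <- script_signal(script, times - jit[i], montage,
                         reference = "vertex", templates = tm) * amp[i]
    p_sig[i] <- mean(sig^2)
    x <- sig +
      background_noise(n_ch, n_t, montage, script$head,
                       noise$background_amp) +
      matrix(stats::rnorm(n_ch * n_t, 0, noise$sensor_sd), n_ch, n_t)
    if (noise$line_amp > 0) {
      gains <- stats::runif(n_ch, 0.5, 1.5)
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + outer(gains, noise$line_amp *
                       sin(2 * pi * 50 * times / 1000 + ph))
    }
    if (i %in% art_trials) {
      ch <- sample(n_ch, 3)
      t0 <- sample(which(times >= 0 & times < window[2] - 25), 1)
      span <- t0:(t0 + round(20 * rate / 1000))
      x[ch, span] <- x[ch, span] +
        sample(c(-1, 1), 1) * noise$artifact_amp
    }
    dat[i, , ] <- x
  }
  if (noise$artifact_fraction > 0 && noise$artifact_amp <= 100)
    warning("artifact amplitude <= 100 uV: planted artifacts will not be rejected")
  p_noise <- noise$sensor_sd^2 + noise$background_amp^2
  snr_db <- 10 * log10(p_sig / max(p_noise, 1e-12))
  ep <- new_epochset(dat, window, rate, montage)
  truth <- list(script = script, labels = script_labels(script, times),
                times = times, dipoles = script$dipoles,
                artifact_trials = art_trials, latency_jitter = jit,
                amplitude_jitter = amp, snr_db = snr_db)
  list(epochs = ep, truth = truth)
}

#' Synthesize a continuous recording of one stimulation run
#'
#' Emulates the acquisition protocol: stimuli every `1/stim_hz` seconds for
#' `duration_min` minutes (90 stimuli for 3 min at 0.5 Hz), sampled at
#' 5 kHz on the recorded channels, with one second of silent pre-roll before
#' the first stimulus so the first epoch window fits.
#'
#' @inheritParams synthesize_epochs
#' @param duration_min stimulation duration in minutes
#' @param stim_hz stimulation rate (Hz)
#' @param nerve,side event tags
#' @return list with `recording` (`ssep_recording`) and `truth`
#' @export
synthesize_session <- function(script, noise = noise_spec(),
                               duration_min = 3, rate = 5000, stim_hz = 0.5,
                               seed, montage = script$montage,
                               nerve = script$kind, side = "left",
                               window = c(-100, 200)) {
  n_trials <- floor(duration_min * 60 * stim_hz)
  syn <- synthesize_epochs(script, noise, n_trials, window, rate, seed,
                           montage)
  pre_roll <- rate                      # 1 s
  n_total <- pre_roll + round(duration_min * 60 * rate)
  rec_ch <- recorded_channels(montage)
  x <- matrix(stats::rnorm(length(rec_ch) * n_total, 0, noise$sensor_sd),
              length(rec_ch), n_total)
  onsets <- as.integer(pre_roll + 1 +
                         round((seq_len(n_trials) - 1) * rate / stim_hz))
  w0 <- round(window[1] * rate / 1000)
  n_win <- dim(syn$epochs$data)[3]
  for (i in seq_len(n_trials)) {
    idx <- onsets[i] + w0 + seq_len(n_win) - 1
    # epoch already contains sensor noise; replace rather than add
    x[, idx] <- syn$epochs$data[i, , ]
  }
  events <- data.frame(sample = onsets, nerve = nerve, side = side)
  rec <- new_recording(x, rate = rate, events = events, montage = montage)
  list(recording = rec, truth = syn$truth)
}

#' Synthesize a multi-session study
#'
#' Re-draws the noise per session and applies a small seeded rigid rotation
#' (|angle| <= `max_rotation_deg`) of the electrode cap about a random axis,
#' emulating imperfect cap repositioning between sessions. Templates are
#' re-derived from the planted dipoles on the rotated cap, so the session
#' topographies vary slightly around the nominal script.
#'
#' @inheritParams synthesize_epochs
#' @param n_sessions number of recording sessions
#' @param rotation_sd_deg SD of the per-session cap rotation angle (deg)
#' @param max_rotation_deg hard cap on the rotation angle (deg)
#' @param level `"evoked"` returns preprocessed average-referenced evokeds
#'   (epochs averaged, baseline-corrected, re-referenced); `"epochs"`
#'   returns the raw epoch sets
#' @param baseline baseline window (ms) used when `level = "evoked"`
#' @return list with `sessions` (list of evokeds or epoch sets) and
#'   `truths`
#' @export
synthesize_study <- function(script, noise = noise_spec(), n_sessions = 9,
                             n_trials = 90, window = c(-100, 200),
                             rate = 5000, seed, rotation_sd_deg = 1.5,
                             max_rotation_deg = 3,
                             level = c("evoked", "epochs"),
                             baseline = c(-80, -30)) {
  level <- match.arg(level)
  set.seed(seed)
  session_seeds <- sample.int(2^31 - 2, n_sessions)
  axes <- matrix(stats::rnorm(3 * n_sessions), ncol = 3)
  angles <- pmin(abs(stats::rnorm(n_sessions, 0, rotation_sd_deg)),
                 max_rotation_deg)
  sessions <- vector("list", n_sessions)
  truths <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    mont_s <- rotate_montage(script$montage, axes[s, ], angles[s])
    syn <- synthesize_epochs(script, noise, n_trials, window, rate,
                             seed = session_seeds[s], montage = mont_s)
    syn$truth$rotation <- list(axis = axes[s, ], angle_deg = angles[s])
    truths[[s]] <- syn$truth
    sessions[[s]] <- if (level == "epochs") syn$epochs
      else average_reference(average_epochs(syn$epochs, baseline = baseline))
  }
  list(sessions = sessions, truths = truths)
}

#' Synthesize a grand-average-level evoked directly
#'
#' Generates an average-referenced evoked equal to the script signal plus
#' average-referenced white noise at a prescribed signal-to-noise ratio,
#' bypassing trial-level synthesis. `snr` is the ratio of the mean script
#' GFP over the active states to the expected noise GFP.
#'
#' @inheritParams synthesize_epochs
#' @param snr GFP signal-to-noise ratio (`Inf` = noise-free)
#' @return an `ssep_evoked` (average reference, all montage electrodes)
#' @export
synthesize_evoked <- function(script, snr = Inf, window = c(-100, 200),
                              rate = 5000, seed = NULL,
                              montage = script$montage) {
  if (!is.null(seed)) set.seed(seed)
  times <- epoch_times(window, rate)
  S <- script_signal(script, times, montage, reference = "average")
  if (is.finite(snr)) {
    env <- script_envelope(script, times)
    sd_n <- mean(env[env > 0]) / snr
    N <- matrix(stats::rnorm(length(S), 0, sd_n), nrow(S))
    N <- sweep(N, 2, colMeans(N))
    S <- S + N
  }
  new_evoked(S, window, rate, montage, n_sweeps = NA_integer_,
             reference_mode = "average")
}
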