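#' Continuous recording, epoch set and evoked containers
#'
#' `new_recording()` builds a validated continuous multichannel recording:
#' a channels x samples matrix of voltages in microvolts (recorded channels
#' only, vertex-referenced), a sampling rate in Hz, a table of stimulus
#' events and the electrode montage. Events carry the stimulated nerve
#' (`"median"`/`"tibial"`) and side (`"left"`/`"right"`); all analyses are
#' per-tag. Sample indices are 1-based and must lie within the data.
#'
#' @param data numeric matrix, channels x samples (microvolts)
#' @param rate sampling rate in Hz (default 5000)
#' @param events data.frame with columns `sample`, `nerve`, `side`
#' @param montage an `ssep_montage`; `nrow(data)` must equal the number of
#'   recorded (non-reference) channels
#' @return an `ssep_recording`
#' @export
new_recording <- function(data, rate = 5000, events, montage) {
  stopifnot(is.matrix(data), rate > 0)
  rec_ch <- recorded_channels(montage)
  if (nrow(data) != length(rec_ch))
    stop("channel count (", nrow(data), ") does not match montage recorded channels (",
         length(rec_ch), ")")
  rownames(data) <- rec_ch
  events <- as.data.frame(events)
  stopifnot(all(c("sample", "nerve", "side") %in% names(events)))
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data)))
    stop("event sample indices outside the data")
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(data = data, rate = rate, events = events, montage = montage),
            class = "ssep_recording")
}

#' @export
print.ssep_recording <- function(x, ...) {
  cat("<ssep_recording> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$rate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Sample times of an epoch window
#'
#' Epoch windows are half-open `[t0, t1)` in milliseconds with stimulus onset
#' at 0 ms; frame 1 is the first sample of the epoch.
#' @param window `c(t0, t1)` ms
#' @param rate Hz
#' @return vector of frame times in ms
#' @export
epoch_times <- function(window, rate) {
  step <- 1000 / rate
  n <- round((window[2] - window[1]) / step)
  window[1] + (seq_len(n) - 1) * step
}

#' @rdname new_recording
#' @param ep_data trials x channels x samples array (microvolts)
#' @param window epoch window `c(t0, t1)` ms, must contain 0
#' @param kept per-trial logical keep mask
#' @param baseline_applied has baseline correction been applied
#' @param reference_mode `"vertex"` or `"average"`
#' @export
new_epochset <- function(ep_data, window, rate, montage,
                         kept = rep(TRUE, dim(ep_data)[1]),
                         baseline_applied = FALSE, reference_mode = "vertex") {
  stopifnot(length(dim(ep_data)) == 3, window[1] <= 0, window[2] > 0)
  structure(list(data = ep_data, window = window, rate = rate,
                 times = epoch_times(window, rate), montage = montage,
                 kept = kept, baseline_applied = baseline_applied,
                 reference_mode = reference_mode),
            class = "ssep_epochs")
}

#' @export
print.ssep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<ssep_epochs> ", d[1], " trials (", sum(x$kept), " kept) x ", d[2],
      " ch x ", d[3], " frames, window [", x$window[1], ", ", x$window[2],
      ") ms, ", x$reference_mode, " reference\n", sep = "")
  invisible(x)
}

#' @rdname new_recording
#' @param ev_data channels x samples matrix (microvolts)
#' @param n_sweeps number of averaged trials
#' @export
new_evoked <- function(ev_data, window, rate, montage, n_sweeps = NA_integer_,
                       reference_mode = "vertex") {
  stopifnot(is.matrix(ev_data))
  if (reference_mode == "average") {
    if (nrow(ev_data) != length(montage$labels))
      stop("average-referenced evoked must include the reference channel")
    if (max(abs(colMeans(ev_data))) > 1e-8)
      stop("average-referenced evoked must have zero channel mean per frame")
  }
  structure(list(data = ev_data, window = window, rate = rate,
                 times = epoch_times(window, rate), montage = montage,
                 n_sweeps = n_sweeps, reference_mode = reference_mode),
            class = "ssep_evoked")
}

#' @export
print.ssep_evoked <- function(x, ...) {
  cat("<ssep_evoked> ", nrow(x$data), " ch x ", ncol(x$data),
      " frames, window [", x$window[1], ", ", x$window[2], ") ms, ",
      x$n_sweeps, " sweeps, ", x$reference_mode, " reference\n", sep = "")
  invisible(x)
}

#' Frame selector for a half-open time window
#' @param times frame times (ms)
#' @param window `c(t0, t1)` ms
#' @return logical frame mask for `t0 <= t < t1`
#' @export
in_window <- function(times, window) times >= window[1] & times < window[2]
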