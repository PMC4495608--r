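#' Band-pass filter a continuous recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass between `lo` and `hi`
#' Hz with per-channel DC removal, and an optional zero-phase 50 Hz notch
#' (biquad, Q = 35). The band-pass is realized as a cascade of a 2nd-order
#' high-pass and a 4th-order low-pass section: at a 5 kHz rate the 8 Hz edge
#' sits at 0.3 % of Nyquist, where a single high-order band-pass recursion
#' is numerically fragile while the cascaded form is robust. Zero-phase
#' filtering preserves component latencies, which the downstream latency
#' statistics depend on. Events are preserved.
#'
#' @param rec an `ssep_recording`
#' @param lo,hi band edges in Hz
#' @param notch50 apply the 50 Hz notch
#' @return filtered `ssep_recording`
#' @export
filter_recording <- function(rec, lo = 8, hi = 300, notch50 = FALSE) {
  rate <- rec$rate
  if (hi >= rate / 2) stop("hi must be below the Nyquist frequency")
  if (lo >= hi) stop("lo must be below hi")
  if (rate <= 2 * hi) stop("sampling rate too low for this band")
  hp <- signal::butter(2, lo / (rate / 2), type = "high")
  lp <- signal::butter(4, hi / (rate / 2), type = "low")
  ntc <- NULL
  if (notch50) {
    # RBJ biquad notch at 50 Hz, Q = 35
    w0 <- 2 * pi * 50 / rate
    alpha <- sin(w0) / (2 * 35)
    ntc <- list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
                a = c(1, -2 * cos(w0) / (1 + alpha),
                      (1 - alpha) / (1 + alpha)))
  }
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    x <- rec$data[ch, ] - mean(rec$data[ch, ])     # DC removal
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    if (!is.null(ntc)) x <- signal::filtfilt(signal::Arma(b = ntc$b, a = ntc$a), x)
    out$data[ch, ] <- x
  }
  out
}

#' Re-reference to the average reference
#'
#' Appends the (implicitly zero) vertex reference channel as an explicit
#' data row and subtracts each frame's mean across all electrodes, so every
#' frame becomes a zero-mean scalp map and the original reference electrode
#' is recovered as a 33rd data channel.
#'
#' @param x an `ssep_evoked` or `ssep_epochs` in `"vertex"` reference mode
#' @return same type, `"average"` reference mode, channel count + 1
#' @export
average_reference <- function(x) {
  if (x$reference_mode != "vertex") stop("already average-referenced")
  labels <- x$montage$labels
  ref <- x$montage$reference
  if (inherits(x, "ssep_evoked")) {
    full <- matrix(0, length(labels), ncol(x$data),
                   dimnames = list(labels, NULL))
    full[rownames(x$data), ] <- x$data
    full <- sweep(full, 2, colMeans(full))
    out <- x
    out$data <- full
    out$reference_mode <- "average"
    return(out)
  }
  if (inherits(x, "ssep_epochs")) {
    d <- dim(x$data)
    full <- array(0, dim = c(d[1], length(labels), d[3]))
    idx <- match(recorded_channels(x$montage), labels)
    full[, idx, ] <- x$data
    mu <- apply(full, c(1, 3), mean)
    full <- full - aperm(array(mu, dim = c(d[1], d[3], length(labels))),
                         c(1, 3, 2))
    out <- x
    out$data <- full
    out$reference_mode <- "average"
    return(out)
  }
  stop("unsupported input")
}

#' Cut epochs around stimulus events and reject high-amplitude trials
#'
#' Extracts the `window` (default -100..+200 ms, a superset of all analysis
#' windows) around every event whose window fits inside the recording
#' (events too close to an edge are dropped and counted). A trial is marked
#' rejected when any channel's absolute amplitude within the window is
#' strictly greater than `threshold` microvolts; a trial peaking at exactly
#' the threshold is kept.
#'
#' @param rec an `ssep_recording`
#' @param window epoch window `c(t0, t1)` ms
#' @param threshold rejection threshold (uV)
#' @return an `ssep_epochs` with `kept` mask; attributes `n_dropped_edge`
#'   and `n_rejected` summarize the bookkeeping
#' @export
epoch_and_reject <- function(rec, window = c(-100, 200), threshold = 100) {
  if (!nrow(rec$events)) stop("recording has no events")
  rate <- rec$rate
  w0 <- round(window[1] * rate / 1000)
  n_win <- length(epoch_times(window, rate))
  starts <- rec$events$sample + w0
  fits <- starts >= 1 & (starts + n_win - 1) <= ncol(rec$data)
  n_ch <- nrow(rec$data)
  dat <- array(NA_real_, dim = c(sum(fits), n_ch, n_win))
  for (i in seq_along(which(fits))) {
    s <- starts[which(fits)[i]]
    dat[i, , ] <- rec$data[, s:(s + n_win - 1)]
  }
  peak <- apply(abs(dat), 1, max)
  kept <- peak <= threshold            # strictly-greater rejection
  ep <- new_epochset(dat, window, rate, rec$montage, kept = kept)
  attr(ep, "n_dropped_edge") <- sum(!fits)
  attr(ep, "n_rejected") <- sum(!kept)
  ep
}

#' Average kept epochs and baseline-correct
#'
#' Means the kept trials and subtracts each channel's mean over the
#' pre-stimulus baseline window (default -80..-30 ms).
#' @param ep an `ssep_epochs`
#' @param baseline baseline window `c(t0, t1)` ms; must lie inside the
#'   epoch window
#' @return an `ssep_evoked` with `n_sweeps` = number of averaged trials
#' @export
average_epochs <- function(ep, baseline = c(-80, -30)) {
  if (!any(ep$kept)) stop("no kept trials to average")
  if (baseline[1] < ep$window[1] || baseline[2] > ep$window[2])
    stop("baseline outside the epoch window")
  kept <- which(ep$kept)
  avg <- apply(ep$data[kept, , , drop = FALSE], c(2, 3), mean)
  bsel <- in_window(ep$times, baseline)
  avg <- avg - rowMeans(avg[, bsel, drop = FALSE])
  rownames(avg) <- recorded_channels(ep$montage)
  new_evoked(avg, ep$window, ep$rate, ep$montage, n_sweeps = length(kept),
             reference_mode = ep$reference_mode)
}

#' Full preprocessing chain for one recording
#'
#' filter -> epoch/reject -> average -> baseline -> average reference,
#' the fixed pipeline order.
#' @param rec an `ssep_recording`
#' @param cfg an `ssep_config`
#' @return list with `evoked` (average-referenced), `epochs`, and `report`
#'   (rejection bookkeeping)
#' @export
preprocess_recording <- function(rec, cfg = default_config()) {
  f <- filter_recording(rec, cfg$filter_lo, cfg$filter_hi, cfg$notch50)
  ep <- epoch_and_reject(f, cfg$epoch_ms, cfg$reject_uV)
  ev <- average_reference(average_epochs(ep, cfg$baseline_ms))
  list(evoked = ev, epochs = ep,
       report = list(n_trials = dim(ep$data)[1],
                     n_kept = sum(ep$kept),
                     n_rejected = attr(ep, "n_rejected"),
                     n_dropped_edge = attr(ep, "n_dropped_edge")))
}
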