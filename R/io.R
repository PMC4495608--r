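#' Read and write continuous recordings
#'
#' Two on-disk dialects are supported and chosen by file extension:
#' \itemize{
#'   \item `.edf` — standard 16-bit EDF. Recorded channels are stored as EDF
#'     signals at 0.1 uV resolution; stimulus events are carried by an extra
#'     `TRIG` signal whose nonzero samples mark onsets (1 = median/left,
#'     2 = median/right, 3 = tibial/left, 4 = tibial/right). The true sample
#'     count is kept in the reserved header field since EDF pads the last
#'     one-second data record.
#'   \item anything else — a whitespace-delimited samples x channels matrix
#'     with a header row of channel labels, plus a JSON sidecar
#'     (`<path>.json`) holding the rate and event table and a montage file
#'     (`<path>.montage`).
#' }
#'
#' @param path input file
#' @param montage optional `ssep_montage` override; for EDF the builtin
#'   `"macaque33"` layout is assumed when labels match, for the text dialect
#'   the sidecar montage file is used.
#' @return an `ssep_recording`
#' @export
read_recording <- function(path, montage = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    read_edf(path, montage = montage)
  else
    read_recording_text(path, montage = montage)
}

#' @rdname read_recording
#' @param rec an `ssep_recording`
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) write_edf(rec, path)
  else write_recording_text(rec, path)
  invisible(path)
}

write_recording_text <- function(rec, path) {
  tab <- t(rec$data)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = rownames(rec$data))
  jsonlite::write_json(list(rate = rec$rate, events = rec$events),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write_montage(rec$montage, paste0(path, ".montage"))
  invisible(path)
}

read_recording_text <- function(path, montage = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$rate) || meta$rate <= 0) stop("sidecar rate invalid")
  if (is.null(montage)) montage <- load_montage(paste0(path, ".montage"))
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  data <- t(as.matrix(tab))
  ev <- as.data.frame(meta$events)
  if (!nrow(ev)) ev <- data.frame(sample = integer(), nerve = character(),
                                  side = character())
  new_recording(data, rate = meta$rate, events = ev, montage = montage)
}

## ---- minimal EDF (16-bit, one-second data records) ----

edf_pad <- function(x, n) {
  s <- substr(paste0(x, strrep(" ", n)), 1, n)
  s
}

EDF_PHYS <- 3276.7  # uV full scale -> 0.1 uV per digital unit

write_edf <- function(rec, path) {
  ns_sig <- nrow(rec$data) + 1L        # + TRIG
  rate <- rec$rate
  n_total <- ncol(rec$data)
  n_rec <- ceiling(n_total / rate)
  labels <- c(rownames(rec$data), "TRIG")
  trig <- integer(n_total)
  if (nrow(rec$events)) {
    code <- ifelse(rec$events$nerve == "median", 1L, 3L) +
      ifelse(rec$events$side == "left", 0L, 1L)
    trig[rec$events$sample] <- code
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (ns_sig + 1)), 8),
    edf_pad(paste0("NSAMP=", n_total), 44),
    edf_pad(as.character(n_rec), 8), edf_pad("1", 8),
    edf_pad(as.character(ns_sig), 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, n) writeChar(paste0(vapply(vals, edf_pad, "", n),
                                            collapse = ""), con, eos = NULL)
  fld(labels, 16)
  fld(rep("", ns_sig), 80)                                   # transducer
  fld(c(rep("uV", ns_sig - 1), ""), 8)                       # dimension
  fld(c(rep(as.character(-EDF_PHYS), ns_sig - 1), "-32767"), 8)
  fld(c(rep(as.character(EDF_PHYS), ns_sig - 1), "32767"), 8)
  fld(rep("-32767", ns_sig), 8)
  fld(rep("32767", ns_sig), 8)
  fld(rep("", ns_sig), 80)                                   # prefiltering
  fld(rep(as.character(rate), ns_sig), 8)
  fld(rep("", ns_sig), 32)                                   # reserved
  dig <- round(rec$data / EDF_PHYS * 32767)
  if (any(abs(dig) > 32767)) {
    warning("EDF voltage clipped at +/-", EDF_PHYS, " uV")
    dig <- pmin(pmax(dig, -32767), 32767)
  }
  pad <- n_rec * rate - n_total
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):min(r * rate, n_total)
    block <- rbind(dig[, idx, drop = FALSE], trig[idx])
    if (r == n_rec && pad > 0)
      block <- cbind(block, matrix(0L, ns_sig, pad))
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns_sig <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns_sig), function(i) rd(16), ""))
  rd(80 * ns_sig); rd(8 * ns_sig)
  pmin_ <- as.numeric(vapply(seq_len(ns_sig), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns_sig), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns_sig), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns_sig), function(i) rd(8), ""))
  rd(80 * ns_sig)
  nspr <- as.integer(vapply(seq_len(ns_sig), function(i) rd(8), ""))
  rd(32 * ns_sig)
  stopifnot(length(unique(nspr)) == 1)
  rate <- nspr[1] / dur
  raw <- readBin(con, "integer", n = n_rec * sum(nspr), size = 2,
                 endian = "little")
  mat <- matrix(NA_real_, ns_sig, n_rec * nspr[1])
  off <- 0
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[off + seq_len(ns_sig * nspr[1])], nrow = nspr[1])
    mat[, ((r - 1) * nspr[1] + 1):(r * nspr[1])] <- t(block)
    off <- off + ns_sig * nspr[1]
  }
  n_total <- n_rec * nspr[1]
  m <- regmatches(reserved, regexpr("NSAMP=[0-9]+", reserved))
  if (length(m)) n_total <- as.integer(sub("NSAMP=", "", m))
  mat <- mat[, seq_len(n_total), drop = FALSE]
  i_trig <- which(labels == "TRIG")
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- mat[-i_trig, , drop = FALSE] * scale[-i_trig]
  trig <- mat[i_trig, ]
  onsets <- which(trig != 0)
  code <- trig[onsets]
  events <- data.frame(sample = onsets,
                       nerve = ifelse(code <= 2, "median", "tibial"),
                       side = ifelse(code %% 2 == 1, "left", "right"))
  if (is.null(montage)) montage <- macaque33_montage()
  if (!identical(labels[-i_trig], recorded_channels(montage)))
    stop("EDF channel labels do not match the montage")
  new_recording(data, rate = rate, events = events, montage = montage)
}

#' Write an evoked potential as a delimited table
#'
#' The table has one row per frame (first column `time_ms`) and one column
#' per channel; header comment lines (`# key: value`) carry the sampling
#' rate, window, sweep count and reference mode.
#' @param ev an `ssep_evoked`
#' @param path output path
#' @export
write_evoked <- function(ev, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rate: ", ev$rate),
               paste0("# window: ", ev$window[1], " ", ev$window[2]),
               paste0("# n_sweeps: ", ev$n_sweeps),
               paste0("# reference_mode: ", ev$reference_mode)), con)
  tab <- data.frame(time_ms = ev$times, t(ev$data), check.names = FALSE)
  names(tab) <- c("time_ms", rownames(ev$data))
  utils::write.table(tab, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_evoked
#' @param montage montage to attach on read
#' @export
read_evoked <- function(path, montage) {
  lines <- readLines(path, n = 10)
  meta <- lines[startsWith(lines, "# ")]
  get <- function(key) sub(paste0("# ", key, ": "), "",
                           meta[startsWith(meta, paste0("# ", key, ":"))])
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           check.names = FALSE, sep = "\t")
  data <- t(as.matrix(tab[, -1, drop = FALSE]))
  win <- as.numeric(strsplit(get("window"), " ")[[1]])
  new_evoked(data, window = win, rate = as.numeric(get("rate")),
             montage = montage, n_sweeps = as.integer(get("n_sweeps")),
             reference_mode = get("reference_mode"))
}
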