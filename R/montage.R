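#' Electrode montage
#'
#' A montage holds the ordered electrode labels, their positions on the unit
#' sphere (scaled to the scalp radius only when a head model is attached),
#' the identity of the recording reference, and per-electrode midline flags.
#' The builtin `"macaque33"` layout is a 10-10-inspired approximation for a
#' macaque cap: 32 recorded electrodes (2 on the midline, 15 per hemisphere)
#' referenced to a 33rd vertex electrode. The true cap coordinates were never
#' published, so this layout is stylized: symmetric about the midsagittal
#' plane and covering the whole scalp, but not anatomically validated.
#'
#' Coordinate convention: x points right, y anterior, z up; all positions are
#' unit vectors (head-centered).
#'
#' @param path path to a 4-column delimited electrode file
#'   (label, x, y, z; whitespace or comma separated), or the builtin token
#'   `"macaque33"`.
#' @param reference label of the reference electrode (default `"ref"`).
#' @return an object of class `ssep_montage` with elements `labels`,
#'   `pos` (n x 3 unit-norm matrix), `reference`, `midline` (logical),
#'   and `roles` (named list tagging the deep-posterior `"e32"`-like and
#'   right-sensorimotor `"e12"`-like channels).
#' @export
load_montage <- function(path, reference = "ref") {
  if (identical(path, "macaque33")) return(macaque33_montage())
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("electrode file must have 4 columns: label x y z")
  labels <- as.character(tab$label)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  if (anyDuplicated(labels)) stop("duplicate electrode labels")
  if (!all(is.finite(pos))) stop("non-finite electrode coordinates")
  if (!reference %in% labels) stop("missing reference row '", reference, "'")
  new_montage(labels, pos, reference)
}

new_montage <- function(labels, pos, reference, roles = NULL) {
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("electrode at origin")
  pos <- pos / nrm
  dimnames(pos) <- list(labels, c("x", "y", "z"))
  midline <- abs(pos[, 1]) < 1e-8
  structure(list(labels = labels, pos = pos, reference = reference,
                 midline = midline, roles = roles),
            class = "ssep_montage")
}

#' @rdname load_montage
#' @export
macaque33_montage <- function() {
  deg <- pi / 180
  sph <- function(theta, phi) {  # theta: polar from vertex; phi: azimuth from +x toward +y
    c(sin(theta * deg) * cos(phi * deg),
      sin(theta * deg) * sin(phi * deg),
      cos(theta * deg))
  }
  # right-hemisphere sites (x > 0); mirrored for the left hemisphere
  right <- rbind(
    t(sapply(c(-60, -20, 20, 60),            function(p) sph(36, p))),
    t(sapply(c(-72, -36, 0, 36, 72),         function(p) sph(69, p))),
    t(sapply(c(-75, -45, -15, 15, 45, 75),   function(p) sph(100, p))))
  left <- right * rep(c(-1, 1, 1), each = nrow(right))
  midline <- rbind(sph(45, 90),    # anterior midline
                   sph(45, -90))   # posterior midline
  ref <- c(0, 0, 1)                # vertex reference
  pos <- rbind(midline, left, right, ref)
  # assign labels so that the right central site is e12 (sensorimotor role)
  # and the right posterior-inferior site is e32 (deep posterior role)
  n <- nrow(pos)
  labels <- rep(NA_character_, n)
  labels[n] <- "ref"
  i_e12 <- 2 + nrow(left) + 3                 # right ring-1, phi = 20
  i_e32 <- 2 + nrow(left) + 9 + 1             # right ring-3, phi = -75 (occipito-inferior)
  labels[i_e12] <- "e12"
  labels[i_e32] <- "e32"
  free <- setdiff(seq_len(n - 1), c(i_e12, i_e32))
  labels[free] <- paste0("e", setdiff(1:32, c(12, 32)))
  ord <- c(match(paste0("e", 1:32), labels), n)
  m <- new_montage(labels[ord], pos[ord, , drop = FALSE], "ref",
                   roles = list(e12 = "e12", e32 = "e32"))
  stopifnot(sum(m$midline[m$labels != "ref"]) == 2L)
  m
}

#' @export
print.ssep_montage <- function(x, ...) {
  cat("<ssep_montage> ", length(x$labels), " electrodes (reference: ",
      x$reference, "), ", sum(x$midline), " on the midline\n", sep = "")
  invisible(x)
}

#' Recorded (non-reference) channel labels of a montage
#' @param montage an `ssep_montage`
#' @return character vector of recorded channel labels, in montage order
#' @export
recorded_channels <- function(montage) {
  montage$labels[montage$labels != montage$reference]
}

#' Write a montage to a 4-column delimited file
#' @param montage an `ssep_montage`
#' @param path output path
#' @export
write_montage <- function(montage, path) {
  tab <- data.frame(label = montage$labels, montage$pos)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Rotate montage positions by a small rigid rotation
#'
#' Used by the simulator to emulate session-to-session cap placement
#' variability.
#' @param montage an `ssep_montage`
#' @param axis 3-vector rotation axis (normalized internally)
#' @param angle_deg rotation angle in degrees
#' @return rotated `ssep_montage`
#' @export
rotate_montage <- function(montage, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  out <- montage
  out$pos <- montage$pos %*% t(R)
  rownames(out$pos) <- montage$labels
  out$midline <- montage$midline   # nominal flags kept: labels do not move
  out
}
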