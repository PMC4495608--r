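#' Global field power
#'
#' The GFP of a scalp map is the spatial standard deviation of the
#' average-referenced potentials across electrodes, using the population
#' (divide-by-n) convention: `sqrt(mean((v - mean(v))^2))`. It is a
#' reference-independent measure of map strength. For a channels x frames
#' matrix the GFP is returned per frame.
#'
#' @param x numeric vector (one map) or channels x frames matrix
#' @return GFP in microvolts, scalar or per-frame vector
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2) stop("GFP needs at least 2 channels")
    xc <- sweep(x, 2, colMeans(x))
    sqrt(colMeans(xc^2))
  } else {
    if (length(x) < 2) stop("GFP needs at least 2 channels")
    sqrt(mean((x - mean(x))^2))
  }
}

#' Spatial correlation between two scalp maps
#'
#' The strength-independent similarity of two average-referenced maps,
#' `SC = sum(u*v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))`. SC is signed and
#' polarity-sensitive throughout this package: a map and its voltage
#' inversion are treated as distinct topographies (SC = -1), because an
#' evoked-potential component sequence can contain genuine polarity
#' reversals.
#'
#' @param u,v numeric vectors (average-referenced scalp maps, same montage)
#' @return SC in `[-1, 1]`
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("maps must share a montage")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("SC undefined for a zero-norm map")
  sum(u * v) / (nu * nv)
}

# SC of every frame (columns of X, centered) against every template column;
# zero-norm frames get NA rows.
sc_frames_templates <- function(X, templates) {
  Xc <- sweep(X, 2, colMeans(X))
  Tc <- sweep(templates, 2, colMeans(templates))
  nx <- sqrt(colSums(Xc^2))
  nt <- sqrt(colSums(Tc^2))
  sc <- crossprod(Xc, Tc) / outer(nx, nt)
  sc[nx == 0, ] <- NA_real_
  sc
}

#' Global explained variance of a labeled template fit
#'
#' The GEV is the fraction of the GFP-weighted data variance explained by
#' the template assigned at each frame:
#' `GEV = sum_t (GFP_t * SC(v_t, T_L(t)))^2 / sum_t GFP_t^2`.
#' The per-map GEV restricts the numerator to the frames labeled with that
#' map; unlabeled frames contribute zero, and the per-map values sum to the
#' total.
#'
#' @param series channels x frames matrix of average-referenced data
#'   (an analysis window), or an `ssep_evoked` (then `window` selects frames)
#' @param templates channels x K matrix of template maps
#' @param labels integer vector of per-frame template indices
#'   (`NA` = unlabeled), length = number of frames
#' @param window optional `c(t0, t1)` ms when `series` is an evoked
#' @return list with `per_map` (length-K vector) and `total`
#' @export
gev <- function(series, templates, labels, window = NULL) {
  if (inherits(series, "ssep_evoked")) {
    sel <- if (is.null(window)) rep(TRUE, ncol(series$data))
           else in_window(series$times, window)
    series <- series$data[, sel, drop = FALSE]
  }
  stopifnot(ncol(series) == length(labels))
  K <- ncol(templates)
  g <- gfp(series)
  denom <- sum(g^2)
  if (denom == 0) stop("GEV undefined: all-zero GFP in window")
  sc <- sc_frames_templates(series, templates)
  per_map <- numeric(K)
  lab_ok <- !is.na(labels)
  for (k in seq_len(K)) {
    idx <- which(lab_ok & labels == k)
    if (length(idx))
      per_map[k] <- sum((g[idx] * sc[idx, k])^2, na.rm = TRUE) / denom
  }
  list(per_map = per_map, total = sum(per_map))
}
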