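#' Modified K-means segmentation of an evoked potential
#'
#' Clusters the average-referenced scalp maps of an analysis window into K
#' template topographies, maximizing the global explained variance with
#' polarity-sensitive (signed) spatial correlation: each frame is assigned
#' to the template with the highest signed SC, and each template is
#' recomputed as the GFP-weighted mean of its frames, renormalized to unit
#' GFP, until the labeling reaches a fixed point (at most 500 iterations).
#' Templates are initialized from K distinct random frames; the best of
#' `restarts` seeded restarts (highest total GEV, ties to the lower restart
#' index) is returned.
#'
#' @param evoked an average-referenced `ssep_evoked`
#' @param window analysis window `c(t0, t1)` ms (half-open)
#' @param K number of templates (>= 1, at most the number of frames)
#' @param restarts number of random restarts
#' @param seed RNG seed; the result is bit-reproducible given it
#' @return list with `templates` (an `ssep_templates`: `K`, `templates`
#'   channels x K, `window`, `seed`, `gev_total`, `best_restart`) and
#'   `labeling` (an `ssep_labeling`: per-frame template index, `NA` for
#'   zero-field frames)
#' @export
kmeans_segment <- function(evoked, window, K, restarts = 100, seed = 1) {
  sel <- in_window(evoked$times, window)
  X <- evoked$data[, sel, drop = FALSE]
  times <- evoked$times[sel]
  n_t <- ncol(X)
  if (K > n_t) stop("K exceeds the number of frames in the window")
  set.seed(seed)
  g <- gfp(X)
  norms <- sqrt(colSums(X^2))
  ok <- norms > 0
  Xn <- X
  Xn[, ok] <- sweep(X[, ok, drop = FALSE], 2, norms[ok], "/")
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- sample(which(ok), K)
    tmpl <- Xn[, init, drop = FALSE]
    lab <- rep(NA_integer_, n_t)
    for (it in 1:500) {
      sc <- crossprod(Xn[, ok, drop = FALSE], tmpl)   # frames x K, signed
      new_lab <- rep(NA_integer_, n_t)
      new_lab[ok] <- max.col(sc, ties.method = "first")
      for (k in seq_len(K)) {
        idx <- which(new_lab == k)
        if (!length(idx)) {             # empty cluster: re-seed from the
          worst <- which(ok)[which.min(apply(sc, 1, max))]
          new_lab[worst] <- k           # worst-explained frame
          idx <- worst
        }
        tk <- X[, idx, drop = FALSE] %*% g[idx]
        nk <- gfp(as.vector(tk))
        if (nk > 0) tmpl[, k] <- tk / nk
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
    tot <- gev(X, tmpl, lab)$total
    if (is.null(best) || tot > best$gev) {
      best <- list(tmpl = tmpl, lab = lab, gev = tot, restart = r)
    }
  }
  tmpl <- sweep(best$tmpl, 2, colMeans(best$tmpl))    # keep zero-mean exact
  tmpl <- sweep(tmpl, 2, apply(tmpl, 2, gfp), "/")
  rownames(tmpl) <- rownames(evoked$data)
  templates <- structure(list(K = K, templates = tmpl, window = window,
                              seed = seed, gev_total = best$gev,
                              best_restart = best$restart),
                         class = "ssep_templates")
  labeling <- structure(list(labels = best$lab, times = times,
                             window = window, K = K,
                             frame_ms = 1000 / evoked$rate),
                        class = "ssep_labeling")
  list(templates = templates, labeling = labeling)
}

#' @export
print.ssep_templates <- function(x, ...) {
  cat("<ssep_templates> K = ", x$K, ", window [", x$window[1], ", ",
      x$window[2], ") ms, total GEV ", round(x$gev_total, 4), "\n", sep = "")
  invisible(x)
}

# contiguous runs of identical labels; returns data.frame(start, end, label)
label_runs <- function(labels) {
  r <- rle(ifelse(is.na(labels), -1L, labels))
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, end = ends,
             label = ifelse(r$values == -1L, NA_integer_, r$values))
}

#' Post-process a segmentation: absorb short runs, merge similar templates
#'
#' Two rules applied in a fixed order: (1) any contiguous labeled run
#' shorter than `min_frames` frames (0.4 ms at 5 kHz) is reassigned
#' frame-by-frame to the preceding or following run's template, whichever
#' correlates better (signed SC) with that frame; (2) template pairs with
#' signed SC above `merge_sc` are merged (GFP-weighted mean over their
#' frames, renormalized) until no pair qualifies, after which the
#' absorption pass is repeated once. K and the label indices are updated.
#'
#' @param templates an `ssep_templates`
#' @param labeling the matching `ssep_labeling`
#' @param evoked the segmented evoked (for frame data)
#' @param min_frames minimum run length kept, in frames
#' @param merge_sc merge threshold on the signed SC
#' @return list with updated `templates` and `labeling`
#' @export
postprocess_clusters <- function(templates, labeling, evoked,
                                 min_frames = 2, merge_sc = 0.92) {
  sel <- in_window(evoked$times, labeling$window)
  X <- evoked$data[, sel, drop = FALSE]
  g <- gfp(X)
  lab <- labeling$labels
  tmpl <- templates$templates

  absorb <- function(lab, tmpl) {
    repeat {
      runs <- label_runs(lab)
      short <- which(!is.na(runs$label) &
                       (runs$end - runs$start + 1) < min_frames)
      if (!length(short)) return(lab)
      i <- short[1]
      prev_lab <- if (i > 1) runs$label[i - 1] else NA_integer_
      next_lab <- if (i < nrow(runs)) runs$label[i + 1] else NA_integer_
      for (t in runs$start[i]:runs$end[i]) {
        cand <- stats::na.omit(c(prev_lab, next_lab))
        if (!length(cand)) { lab[t] <- NA_integer_; next }
        scs <- vapply(cand, function(k)
          spatial_correlation(X[, t], tmpl[, k]), 0)
        lab[t] <- cand[which.max(scs)]
      }
    }
  }

  merge_pass <- function(lab, tmpl) {
    repeat {
      K <- ncol(tmpl)
      if (K < 2) return(list(lab = lab, tmpl = tmpl))
      scm <- crossprod(sweep(tmpl, 2, sqrt(colSums(tmpl^2)), "/"))
      diag(scm) <- -Inf
      mx <- which(scm == max(scm), arr.ind = TRUE)[1, ]
      if (scm[mx[1], mx[2]] <= merge_sc) return(list(lab = lab, tmpl = tmpl))
      i <- min(mx); j <- max(mx)
      wi <- sum(g[which(lab == i)]); wj <- sum(g[which(lab == j)])
      if (wi + wj == 0) { wi <- 1; wj <- 1 }
      tnew <- (wi * tmpl[, i] + wj * tmpl[, j])
      tnew <- tnew - mean(tnew)
      tnew <- tnew / gfp(tnew)
      tmpl[, i] <- tnew
      tmpl <- tmpl[, -j, drop = FALSE]
      lab[lab == j] <- i
      lab[!is.na(lab) & lab > j] <- lab[!is.na(lab) & lab > j] - 1L
    }
  }

  lab <- absorb(lab, tmpl)
  m <- merge_pass(lab, tmpl)
  lab <- absorb(m$lab, m$tmpl)
  tmpl <- m$tmpl
  # drop templates with no labeled frames and renumber
  used <- sort(unique(stats::na.omit(lab)))
  tmpl <- tmpl[, used, drop = FALSE]
  lab <- match(lab, used)
  K <- ncol(tmpl)
  templates$templates <- tmpl
  templates$K <- K
  templates$gev_total <- gev(X, tmpl, lab)$total
  labeling$labels <- as.integer(lab)
  labeling$K <- K
  list(templates = templates, labeling = labeling)
}

# within-cluster dispersion: residual sum of squares of each frame about its
# (unit-norm) template direction; unlabeled frames contribute their full power
dispersion_w <- function(X, tmpl, lab) {
  un <- sweep(tmpl, 2, sqrt(colSums(tmpl^2)), "/")
  tot <- colSums(X^2)
  expl <- numeric(ncol(X))
  ok <- !is.na(lab)
  if (any(ok))
    expl[ok] <- (colSums(X[, ok, drop = FALSE] * un[, lab[ok], drop = FALSE]))^2
  sum(tot - expl)
}

#' Choose the number of template maps
#'
#' Runs [kmeans_segment()] + [postprocess_clusters()] for each K in
#' `k_range` and evaluates two model-selection criteria on the
#' within-cluster dispersion W(K):
#' the Krzanowski-Lai criterion `KL(K) = |DIFF(K)| / |DIFF(K+1)|` with
#' `DIFF(K) = (K-1)^(2/p) W(K-1) - K^(2/p) W(K)` (p = electrode count),
#' maximized over interior K, and the cross-validation criterion
#' `CV(K) = sigma2_K * ((p-1)/(p-1-K))^2` with `sigma2_K` the mean residual
#' variance `W(K) / (T (p-1))`, minimized.
#'
#' @inheritParams kmeans_segment
#' @param k_range candidate K values (consecutive integers)
#' @return list with `best_k_kl`, `best_k_cv`, `curve` (data.frame K, W,
#'   KL, CV, K_eff after post-processing) and `segmentations` (per-K
#'   results of the clustering + post-processing)
#' @export
select_k <- function(evoked, window, k_range = 1:10, restarts = 100,
                     seed = 1, min_frames = 2, merge_sc = 0.92) {
  sel <- in_window(evoked$times, window)
  X <- evoked$data[, sel, drop = FALSE]
  if (max(k_range) > ncol(X)) stop("k_range exceeds the frame count")
  p <- nrow(X)
  segs <- vector("list", length(k_range))
  W <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    s <- kmeans_segment(evoked, window, k_range[i], restarts, seed)
    s <- postprocess_clusters(s$templates, s$labeling, evoked,
                              min_frames, merge_sc)
    segs[[i]] <- s
    W[i] <- dispersion_w(X, s$templates$templates, s$labeling$labels)
  }
  diff_k <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    if (i == 1) next
    diff_k[i] <- (k_range[i] - 1)^(2 / p) * W[i - 1] -
      k_range[i]^(2 / p) * W[i]
  }
  KL <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    if (i > 1 && i < length(k_range) && !is.na(diff_k[i + 1]) &&
        abs(diff_k[i + 1]) > 0)
      KL[i] <- abs(diff_k[i]) / abs(diff_k[i + 1])
  }
  n_t <- ncol(X)
  sigma2 <- W / (n_t * (p - 1))
  CV <- ifelse(k_range < p - 1,
               sigma2 * ((p - 1) / (p - 1 - k_range))^2, NA_real_)
  if (all(is.na(KL))) stop("k_range too small to evaluate the KL criterion")
  curve <- data.frame(K = k_range, W = W, KL = KL, CV = CV,
                      K_eff = vapply(segs, function(s) s$templates$K, 0L))
  list(best_k_kl = k_range[which.max(KL)],
       best_k_cv = k_range[which.min(CV)],
       curve = curve, segmentations = segs)
}
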