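#' Fit template maps back to an individual evoked response
#'
#' Assigns to each frame of the analysis window the template with the
#' highest signed spatial correlation, with no temporal smoothing, then
#' rejects (sets to unlabeled, without reassignment) every contiguous run
#' of `min_frames` frames or fewer — segments of 0.4 ms or less at 5 kHz.
#' Zero-field frames are unlabeled.
#'
#' @param evoked an average-referenced `ssep_evoked`
#' @param templates an `ssep_templates` (or channels x K matrix)
#' @param window analysis window `c(t0, t1)` ms
#' @param min_frames runs of this many frames or fewer are rejected
#' @return an `ssep_labeling`
#' @export
fit_templates <- function(evoked, templates, window, min_frames = 2) {
  tmpl <- if (inherits(templates, "ssep_templates")) templates$templates
          else templates
  sel <- in_window(evoked$times, window)
  X <- evoked$data[, sel, drop = FALSE]
  times <- evoked$times[sel]
  norms <- sqrt(colSums(X^2))
  ok <- norms > 0
  lab <- rep(NA_integer_, ncol(X))
  if (any(ok)) {
    Xn <- sweep(X[, ok, drop = FALSE], 2, norms[ok], "/")
    un <- sweep(tmpl, 2, sqrt(colSums(tmpl^2)), "/")
    sc <- crossprod(Xn, un)
    lab[ok] <- max.col(sc, ties.method = "first")
  }
  runs <- label_runs(lab)
  for (i in seq_len(nrow(runs))) {
    if (!is.na(runs$label[i]) &&
        (runs$end[i] - runs$start[i] + 1) <= min_frames)
      lab[runs$start[i]:runs$end[i]] <- NA_integer_
  }
  structure(list(labels = lab, times = times, window = window,
                 K = ncol(tmpl), frame_ms = 1000 / evoked$rate),
            class = "ssep_labeling")
}

#' Eight topographic parameters of each fitted component map
#'
#' For every template map of a back-fit labeling: latency at first onset
#' (time of the first labeled frame), duration (total labeled time; the
#' labeled frames need not be contiguous), global explained variance,
#' latency at best SC, mean SC, maximum GFP, latency at maximum GFP and
#' mean GFP, all over the frames labeled with that map. Maps with no
#' labeled frames produce a row of missing values with a warning.
#'
#' @inheritParams fit_templates
#' @param labeling an `ssep_labeling` from [fit_templates()]
#' @param session optional session identifier stored in the result
#' @return data.frame of class `ssep_fit`, one row per map with the eight
#'   parameters
#' @export
map_parameters <- function(evoked, templates, labeling, session = NA) {
  tmpl <- if (inherits(templates, "ssep_templates")) templates$templates
          else templates
  sel <- in_window(evoked$times, labeling$window)
  X <- evoked$data[, sel, drop = FALSE]
  times <- evoked$times[sel]
  lab <- labeling$labels
  stopifnot(length(lab) == ncol(X))
  g <- gfp(X)
  gv <- gev(X, tmpl, lab)
  K <- ncol(tmpl)
  out <- data.frame(session = session, map = seq_len(K),
                    latency_first_onset = NA_real_, duration = NA_real_,
                    gev = NA_real_, latency_best_sc = NA_real_,
                    mean_sc = NA_real_, max_gfp = NA_real_,
                    latency_max_gfp = NA_real_, mean_gfp = NA_real_)
  frame_ms <- labeling$frame_ms
  for (k in seq_len(K)) {
    idx <- which(!is.na(lab) & lab == k)
    if (!length(idx)) {
      warning("map ", k, " has no labeled frames; parameters set missing")
      next
    }
    scs <- vapply(idx, function(t) spatial_correlation(X[, t], tmpl[, k]), 0)
    out$latency_first_onset[k] <- times[idx[1]]
    out$duration[k] <- length(idx) * frame_ms
    out$gev[k] <- gv$per_map[k]
    out$latency_best_sc[k] <- times[idx[which.max(scs)]]
    out$mean_sc[k] <- mean(scs)
    out$max_gfp[k] <- max(g[idx])
    out$latency_max_gfp[k] <- times[idx[which.max(g[idx])]]
    out$mean_gfp[k] <- mean(g[idx])
  }
  class(out) <- c("ssep_fit", "data.frame")
  out
}

# Shapiro-Wilk normality gate; degenerate (constant or tiny) samples count
# as non-normal so the rank test path is taken
is_normal <- function(x, alpha = 0.05) {
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p >= alpha
}

# Mann-Whitney U rank-sum test. Latencies are quantized to the frame grid,
# so ties are the rule; the normal approximation's p-value then cannot get
# small even for perfectly separated small groups. For small samples the
# exact permutation distribution of the rank sum (which handles ties) is
# enumerated instead.
mann_whitney <- function(a, b, max_enum = 2e5) {
  nA <- length(a); nB <- length(b)
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  if (choose(nA + nB, nA) <= max_enum) {
    r <- rank(c(a, b))
    combos <- utils::combn(nA + nB, nA)
    sums <- colSums(matrix(r[combos], nrow = nA))
    obs <- sum(r[seq_len(nA)])
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  } else p <- w$p.value
  list(statistic = unname(w$statistic), p.value = p)
}

#' Compare latencies of successive component maps across sessions
#'
#' For each pair of successive maps and each of the two latency parameters
#' (first onset, best SC), tests whether the per-session latencies differ:
#' Shapiro-Wilk (alpha 0.05) on each group decides between an unpaired
#' two-tailed t-test (both normal) and a Mann-Whitney U rank-sum test.
#' Significance is declared at `alpha / n_electrodes` (the literal
#' Bonferroni-by-electrode-count correction of the source protocol; the
#' divisor is configurable). Pairs with fewer than 3 observations in either
#' group are skipped and flagged.
#'
#' @param fits an `ssep_fit` table covering several sessions
#' @param alpha base significance level
#' @param n_electrodes Bonferroni divisor
#' @return data.frame: map pair, parameter, test used, statistic, raw p,
#'   adjusted threshold, significance flag
#' @export
compare_successive_map_latencies <- function(fits, alpha = 0.01,
                                             n_electrodes = 33) {
  maps <- sort(unique(fits$map))
  params <- c("latency_first_onset", "latency_best_sc")
  rows <- list()
  thr <- alpha / n_electrodes
  for (m in maps[-length(maps)]) {
    for (p in params) {
      a <- fits[[p]][fits$map == m]
      b <- fits[[p]][fits$map == m + 1]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 3 || length(b) < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          map_pair = paste0(m, "-", m + 1), parameter = p, test = "skipped",
          statistic = NA_real_, p_value = NA_real_, threshold = thr,
          significant = NA)
        next
      }
      normal <- is_normal(a) && is_normal(b)
      if (normal) {
        tt <- stats::t.test(a, b, var.equal = TRUE)
        test <- "t"; stat <- unname(tt$statistic); pv <- tt$p.value
      } else {
        tt <- mann_whitney(a, b)
        test <- "mann-whitney"; stat <- tt$statistic; pv <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        map_pair = paste0(m, "-", m + 1), parameter = p, test = test,
        statistic = stat, p_value = pv, threshold = thr,
        significant = pv < thr)
    }
  }
  do.call(rbind, rows)
}

#' Compare the eight fitting parameters between two session groups
#'
#' Two-tailed unpaired t-tests per (map, parameter) cell between two groups
#' of back-fit results (e.g. pre- vs post-craniotomy sessions), with the
#' Bonferroni-by-electrode-count threshold `alpha / n_electrodes`.
#' Zero-variance cells are flagged and counted not significant.
#'
#' @param fitsA,fitsB `ssep_fit` tables (one row per session x map)
#' @param alpha base significance level
#' @param n_electrodes Bonferroni divisor
#' @return data.frame: map, parameter, group means and SEs, t, p,
#'   significance flag
#' @export
compare_groups <- function(fitsA, fitsB, alpha = 0.01, n_electrodes = 33) {
  params <- c("latency_first_onset", "duration", "gev", "latency_best_sc",
              "mean_sc", "max_gfp", "latency_max_gfp", "mean_gfp")
  maps <- sort(union(fitsA$map, fitsB$map))
  thr <- alpha / n_electrodes
  se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- list()
  for (m in maps) {
    for (p in params) {
      a <- fitsA[[p]][fitsA$map == m]; a <- a[!is.na(a)]
      b <- fitsB[[p]][fitsB$map == m]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          map = m, parameter = p, mean_A = mean(a), se_A = NA_real_,
          mean_B = mean(b), se_B = NA_real_, t = NA_real_,
          p_value = NA_real_, threshold = thr, significant = NA,
          note = "too few observations")
        next
      }
      res <- tryCatch({
        tt <- stats::t.test(a, b, var.equal = TRUE)
        list(t = unname(tt$statistic), p = tt$p.value, note = "")
      }, error = function(e) list(t = NA_real_, p = NA_real_,
                                  note = "zero variance"))
      rows[[length(rows) + 1]] <- data.frame(
        map = m, parameter = p, mean_A = mean(a), se_A = se(a),
        mean_B = mean(b), se_B = se(b), t = res$t, p_value = res$p,
        threshold = thr,
        significant = !is.na(res$p) && res$p < thr, note = res$note)
    }
  }
  do.call(rbind, rows)
}

#' Back-fit a template set to several sessions and collect parameters
#'
#' Convenience wrapper: [fit_templates()] + [map_parameters()] per session.
#' @param evokeds list of average-referenced `ssep_evoked`
#' @inheritParams fit_templates
#' @return combined `ssep_fit` table with a `session` column
#' @export
backfit_sessions <- function(evokeds, templates, window, min_frames = 2) {
  out <- lapply(seq_along(evokeds), function(s) {
    lab <- fit_templates(evokeds[[s]], templates, window, min_frames)
    map_parameters(evokeds[[s]], templates, lab, session = s)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ssep_fit", "data.frame")
  res
}
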