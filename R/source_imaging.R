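#' Build a regular source space inside the brain shell
#'
#' A cubic grid (with a node at the head center) intersected with the open
#' brain sphere; the grid spacing is searched so the point count comes as
#' close as possible to `n_target` (ties to the finer grid). Neighbors are
#' 6-connected grid adjacency. The construction is deterministic given the
#' head geometry.
#'
#' @param head an `ssep_head`
#' @param n_target desired number of solution points (default 3000)
#' @return an `ssep_sources`: `points` (n x 3, mm), `spacing` (mm),
#'   `neighbors` (adjacency index list), `head`
#' @export
build_source_space <- function(head, n_target = 3000) {
  if (n_target < 10) stop("n_target too small")
  rb <- brain_radius(head)
  h0 <- (4 / 3 * pi * rb^3 / n_target)^(1 / 3)
  count_for <- function(h) {
    m <- floor(rb / h)
    ax <- (-m:m) * h
    sum(outer(outer(ax^2, ax^2, "+"), ax^2, "+") < rb^2)
  }
  hs <- h0 * seq(0.8, 1.25, by = 0.005)
  counts <- vapply(hs, count_for, 0)
  h <- hs[which.min(abs(counts - n_target))]
  m <- floor(rb / h)
  ax <- (-m:m) * h
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside <- rowSums(grid^2) < rb^2
  pts <- grid[inside, , drop = FALSE]
  # integer grid coordinates for adjacency lookup
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- round(pts / h)
  idx <- stats::setNames(seq_len(nrow(pts)), key(ijk))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  neighbors <- lapply(seq_len(nrow(pts)), function(i) {
    nb <- idx[key(sweep(offs, 2, ijk[i, ], "+"))]
    unname(nb[!is.na(nb)])
  })
  structure(list(points = unname(pts), spacing = h, neighbors = neighbors,
                 head = head),
            class = "ssep_sources")
}

#' @export
print.ssep_sources <- function(x, ...) {
  cat("<ssep_sources> ", nrow(x$points), " points, spacing ",
      round(x$spacing, 2), " mm\n", sep = "")
  invisible(x)
}

#' Lead field of a source space
#'
#' The electrodes x (3 x sources) gain matrix of the 3-shell sphere model,
#' computed with the same analytic series as the simulator's forward
#' solution ([forward_gain()]) so forward and inverse share one code path.
#' Electrode positions are projected radially onto the scalp sphere (the
#' per-electrode radial scaling of the locally-adapted-sphere idea reduces
#' to this projection for a spherical cap). Rows are average-referenced:
#' every gain column sums to zero over electrodes.
#'
#' @param head an `ssep_head`
#' @param montage an `ssep_montage`
#' @param space an `ssep_sources`
#' @return an `ssep_leadfield`: `gain`, `head`, `montage`, `space`
#' @export
compute_leadfield <- function(head, montage, space) {
  gain <- forward_gain(head, montage, space$points, reference = "average")
  structure(list(gain = gain, head = head, montage = montage,
                 space = space),
            class = "ssep_leadfield")
}

# 6-neighbor discrete Laplacian-like operator B = 6 I - A; boundary points
# keep the full diagonal weight with fewer neighbors, which makes B strictly
# diagonally dominant there and hence invertible (no ghost points)
grid_laplacian <- function(space) {
  n <- nrow(space$points)
  ii <- rep(seq_len(n), lengths(space$neighbors))
  jj <- unlist(space$neighbors)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  Matrix::Diagonal(n, 6) - A
}

#' Precompute the LORETA inverse operator family
#'
#' The distributed linear inverse `T(alpha) = W^-1 K' (K W^-1 K' + alpha H)^+`
#' with `W = (B'B) (x) I3` (B the 6-neighbor discrete Laplacian with
#' reduced-neighbor boundary rows, penalizing spatially rough current
#' distributions), `H` the average-reference centering operator, and a grid
#' of `n_alphas` Tikhonov regularization levels log-spaced over
#' `[1e-4, 1e2]` times the mean eigenvalue of `K W^-1 K'`.
#'
#' @param leadfield an `ssep_leadfield`
#' @param n_alphas number of regularization levels (default 13)
#' @return an `ssep_inverse`: `T_list` (per-alpha (3 n_s) x n_e matrices),
#'   `alphas`, `gain`, `space`
#' @export
loreta_operator <- function(leadfield, n_alphas = 13) {
  K <- leadfield$gain
  space <- leadfield$space
  n_e <- nrow(K)
  n_s <- nrow(space$points)
  B <- grid_laplacian(space)
  BtB <- Matrix::crossprod(B)
  # W^-1 K' with W = BtB (x) I3: solve per orientation block
  Kt <- t(K)
  WiKt <- matrix(0, 3 * n_s, n_e)
  for (a in 1:3) {
    rows <- seq(a, 3 * n_s, by = 3)
    WiKt[rows, ] <- as.matrix(Matrix::solve(BtB, Kt[rows, , drop = FALSE]))
  }
  M <- K %*% WiKt
  H <- diag(n_e) - matrix(1 / n_e, n_e, n_e)
  mean_eig <- sum(diag(M)) / n_e
  alphas <- 10^seq(log10(1e-4), log10(1e2),
                   length.out = n_alphas) * mean_eig
  T_list <- lapply(alphas, function(al) WiKt %*% MASS::ginv(M + al * H))
  structure(list(T_list = T_list, alphas = alphas, gain = K,
                 M = M, H = H, space = space),
            class = "ssep_inverse")
}

#' @export
print.ssep_inverse <- function(x, ...) {
  cat("<ssep_inverse> ", nrow(x$space$points), " sources, ",
      length(x$alphas), " regularization levels\n", sep = "")
  invisible(x)
}

# generalized cross-validation score of one alpha on a data matrix
gcv_score <- function(op, i, V) {
  A <- op$gain %*% op$T_list[[i]]
  R <- V - A %*% V
  denom <- (nrow(op$gain) - sum(diag(A)))^2
  sum(R^2) / ncol(V) / denom
}

#' Estimate current densities
#'
#' Applies the inverse operator frame by frame: `J = T(alpha) V`, with the
#' CD magnitude at each source the Euclidean norm of its three orientation
#' components (nominal mA/mm^3). The regularization level is either a fixed
#' grid index or chosen by generalized cross-validation on the data, which
#' operationalizes picking "the right amount of regularization for the
#' noise level".
#'
#' @param op an `ssep_inverse`
#' @param x an average-referenced `ssep_evoked` or `ssep_epochs`
#' @param alpha_select `"gcv"` or `"fixed"`
#' @param alpha_index grid index used when `alpha_select = "fixed"`
#' @param keep_components also return the raw orientation components `J`
#'   (evoked input only); the inverse is linear in `J`, while the reported
#'   magnitude is its per-source Euclidean norm
#' @return an `ssep_cd`: `magnitude` (sources x frames matrix for an
#'   evoked; trials x sources x frames array for epochs), `alpha_index`,
#'   `alpha`, `times`, and optionally `components`
#' @export
estimate_cd <- function(op, x, alpha_select = c("gcv", "fixed"),
                        alpha_index = 1, keep_components = FALSE) {
  alpha_select <- match.arg(alpha_select)
  if (x$reference_mode != "average") stop("input must be average-referenced")
  n_e <- nrow(op$gain)
  if (inherits(x, "ssep_evoked")) {
    V <- x$data
    if (nrow(V) != n_e) stop("channel count mismatch with the lead field")
    if (alpha_select == "gcv")
      alpha_index <- which.min(vapply(seq_along(op$alphas),
                                      function(i) gcv_score(op, i, V), 0))
    J <- op$T_list[[alpha_index]] %*% V
    n_s <- nrow(op$space$points)
    mag <- sqrt(J[seq(1, 3 * n_s, 3), ]^2 + J[seq(2, 3 * n_s, 3), ]^2 +
                  J[seq(3, 3 * n_s, 3), ]^2)
    mag <- matrix(mag, n_s, ncol(V))
    if (keep_components) {
      out <- structure(list(magnitude = mag, components = J,
                            alpha_index = alpha_index,
                            alpha = op$alphas[alpha_index],
                            times = x$times, window = x$window),
                       class = "ssep_cd")
      return(out)
    }
  } else if (inherits(x, "ssep_epochs")) {
    d <- dim(x$data)
    if (d[2] != n_e) stop("channel count mismatch with the lead field")
    flat <- matrix(aperm(x$data, c(2, 1, 3)), n_e)   # ch x (trial*frame)
    if (alpha_select == "gcv")
      alpha_index <- which.min(vapply(seq_along(op$alphas),
                                      function(i) gcv_score(op, i, flat), 0))
    J <- op$T_list[[alpha_index]] %*% flat
    n_s <- nrow(op$space$points)
    mag <- sqrt(J[seq(1, 3 * n_s, 3), ]^2 + J[seq(2, 3 * n_s, 3), ]^2 +
                  J[seq(3, 3 * n_s, 3), ]^2)
    mag <- aperm(array(mag, dim = c(n_s, d[1], d[3])), c(2, 1, 3))
  } else stop("unsupported input")
  structure(list(magnitude = mag, alpha_index = alpha_index,
                 alpha = op$alphas[alpha_index], times = x$times,
                 window = x$window),
            class = "ssep_cd")
}

#' Baseline-vs-post paired-t statistics on current densities
#'
#' For every source and every post-stimulus frame, a paired t-test across
#' epochs between that frame's CD magnitude and the epoch's mean baseline
#' CD (the pre-stimulus period), two-tailed, significant at `alpha`
#' (uncorrected). Zero-variance cells are flagged and not significant.
#'
#' @param cd an `ssep_cd` computed on epochs
#' @param baseline baseline window `c(t0, t1)` ms
#' @param post post-stimulus window `c(t0, t1)` ms
#' @param alpha significance level
#' @return an `ssep_source_stats`: `t`, `p` (sources x post frames),
#'   `mask`, `times`, `alpha`
#' @export
cd_stats <- function(cd, baseline = c(-100, 0), post = c(0, 200),
                     alpha = 0.05) {
  if (length(dim(cd$magnitude)) != 3)
    stop("cd_stats needs epoch-level current densities")
  n_ep <- dim(cd$magnitude)[1]
  if (n_ep < 2) stop("need at least 2 epochs")
  bsel <- in_window(cd$times, baseline)
  psel <- in_window(cd$times, post)
  base <- apply(cd$magnitude[, , bsel, drop = FALSE], c(1, 2), mean)
  D <- cd$magnitude[, , psel, drop = FALSE] -
    array(base, dim = c(dim(base), sum(psel)))
  m <- apply(D, c(2, 3), mean)
  s <- apply(D, c(2, 3), stats::sd)
  zero <- s == 0
  t <- m / ifelse(zero, 1, s / sqrt(n_ep))
  t[zero] <- 0
  p <- 2 * stats::pt(abs(t), n_ep - 1, lower.tail = FALSE)
  p[zero] <- 1
  structure(list(t = t, p = p, mask = p < alpha & !zero,
                 zero_variance = zero, times = cd$times[psel],
                 alpha = alpha),
            class = "ssep_source_stats")
}

#' Average source t-values over component-map windows
#'
#' Averages the per-frame t-values over the frames labeled with each
#' component map, per source. The masked output averages only the
#' significant cells; a map whose frames contain no significant cell at a
#' source gets `NA` there (an all-`NA` map is the "ns" outcome).
#'
#' @param statmap an `ssep_source_stats`
#' @param labeling an `ssep_labeling` whose window lies inside the post
#'   interval of `statmap`
#' @return list: `mean_t` (sources x maps), `masked_t` (significant cells
#'   only), `n_frames` per map
#' @export
window_average_t <- function(statmap, labeling) {
  frame_of <- match(round(labeling$times, 6), round(statmap$times, 6))
  if (anyNA(frame_of[!is.na(labeling$labels)]))
    stop("labeling window extends outside the post-stimulus interval")
  K <- labeling$K
  n_s <- nrow(statmap$t)
  mean_t <- matrix(NA_real_, n_s, K)
  masked_t <- matrix(NA_real_, n_s, K)
  n_frames <- integer(K)
  for (k in seq_len(K)) {
    cols <- frame_of[!is.na(labeling$labels) & labeling$labels == k]
    n_frames[k] <- length(cols)
    if (!length(cols)) {
      warning("map ", k, " has no frames in the post interval")
      next
    }
    tk <- statmap$t[, cols, drop = FALSE]
    mk <- statmap$mask[, cols, drop = FALSE]
    mean_t[, k] <- rowMeans(tk)
    any_sig <- rowSums(mk) > 0
    masked_t[any_sig, k] <- rowSums(tk * mk)[any_sig] /
      rowSums(mk)[any_sig]
  }
  list(mean_t = mean_t, masked_t = masked_t, n_frames = n_frames)
}
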