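#' Three-shell spherical head model
#'
#' Concentric-sphere head geometry: scalp surface at 100 % of the scalp
#' radius, outer skull boundary at 78 % and brain/inner-skull boundary at
#' 68 %, with relative conductivities brain 1.0, skull 0.05, scalp 1.0.
#' The default scalp radius of 40 mm is a nominal adult macaque head size.
#'
#' @param scalp_radius scalp radius in mm
#' @param shell_fractions named fractions `c(scalp, skull, brain)` of the
#'   scalp radius
#' @param conductivities named relative conductivities
#'   `c(brain, skull, scalp)`
#' @return an `ssep_head`
#' @export
head_model <- function(scalp_radius = 40,
                       shell_fractions = c(scalp = 1.00, skull = 0.78,
                                           brain = 0.68),
                       conductivities = c(brain = 1.0, skull = 0.05,
                                          scalp = 1.0)) {
  stopifnot(scalp_radius > 0,
            shell_fractions[["brain"]] > 0,
            shell_fractions[["brain"]] < shell_fractions[["skull"]],
            shell_fractions[["skull"]] < shell_fractions[["scalp"]],
            all(conductivities > 0))
  structure(list(scalp_radius = scalp_radius,
                 shell_fractions = shell_fractions,
                 conductivities = conductivities),
            class = "ssep_head")
}

#' @export
print.ssep_head <- function(x, ...) {
  cat("<ssep_head> scalp ", x$scalp_radius, " mm; shells ",
      paste(x$shell_fractions, collapse = "/"), "; conductivities ",
      paste(x$conductivities, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Brain-shell radius of a head model (mm)
#' @param head an `ssep_head`
#' @export
brain_radius <- function(head)
  head$scalp_radius * head$shell_fractions[["brain"]]

# Per-harmonic transfer factor g_n = C_n / S_n for the 3-shell sphere:
# the scalp-surface potential coefficient per unit source coefficient.
# For each order n the radial solution in every layer is a*rho^n +
# b*rho^-(n+1); matching potential and radial current at both interfaces
# and zero current at the scalp gives a 5x5 linear system. Unknowns are
# rescaled by interface-radius powers so the system stays well-conditioned
# at high n. With equal conductivities g_n reduces to the homogeneous
# closed form (2n+1)/n (asserted in the tests).
shell_transfer <- function(head, n_terms) {
  rho1 <- head$shell_fractions[["brain"]]
  rho2 <- head$shell_fractions[["skull"]]
  s1 <- head$conductivities[["brain"]]
  s2 <- head$conductivities[["skull"]]
  s3 <- head$conductivities[["scalp"]]
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    q12 <- (rho1 / rho2)^n
    p12 <- (rho1 / rho2)^(n + 1)
    r2n <- rho2^n
    r2n1 <- rho2^(n + 1)
    # unknowns: A1*rho1^n, A2*rho2^n, B2*rho1^-(n+1), A3, B3*rho2^-(n+1)
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # potential continuity at rho1 (source term normalized to 1 there)
    M[1, ] <- c(1, -q12, -1, 0, 0);            rhs[1] <- -1
    # radial current continuity at rho1
    M[2, ] <- c(s1 * n, -s2 * n * q12, s2 * (n + 1), 0, 0)
    rhs[2] <- s1 * (n + 1)
    # potential continuity at rho2
    M[3, ] <- c(0, 1, p12, -r2n, -1)
    # radial current continuity at rho2
    M[4, ] <- c(0, s2 * n, -s2 * (n + 1) * p12, -s3 * n * r2n, s3 * (n + 1))
    # zero radial current at the scalp surface
    M[5, ] <- c(0, 0, 0, n, -(n + 1) * r2n1)
    sol <- solve(M, rhs)
    # scalp value (A3 + B3) per unit source coefficient S
    g[n] <- (sol[4] + sol[5] * r2n1) / rho1^(n + 1)
  }
  g
}

# Legendre P_n(x) and P_n'(x) recursions, vectorized over x (matrix ok).
# Iterator form: legendre_step advances (P_{n-1}, P_n, P'_{n-1}, P'_n).

#' Scalp potentials of dipole sources in the 3-shell sphere
#'
#' Computes the analytic series solution for the potential at each montage
#' electrode generated by point dipoles inside the brain shell. The same
#' routine backs both the simulator and the inverse module's lead field, so
#' forward and inverse stay algebraically consistent. Units are nominal:
#' microvolts per unit dipole moment with the model's relative
#' conductivities.
#'
#' @param head an `ssep_head`
#' @param montage an `ssep_montage` (positions are projected onto the scalp
#'   sphere)
#' @param positions n_s x 3 matrix of dipole positions in mm (strictly
#'   inside the brain shell)
#' @param moments optional n_s x 3 matrix of dipole moments; if `NULL` the
#'   full gain matrix for unit moments along x, y, z is returned
#' @param n_terms series truncation order (default 60)
#' @param reference `"average"` (rows centered per map) or `"raw"`
#' @return if `moments` is given, an electrodes x n_s matrix of potentials
#'   (summed over no one, one column per dipole); otherwise an electrodes x
#'   (3 n_s) gain matrix with columns ordered (x, y, z) per source
#' @export
forward_gain <- function(head, montage, positions, moments = NULL,
                         n_terms = 60, reference = c("average", "raw")) {
  reference <- match.arg(reference)
  positions <- matrix(positions, ncol = 3)
  R <- head$scalp_radius
  rb <- brain_radius(head)
  rad <- sqrt(rowSums(positions^2))
  if (any(rad >= rb)) stop("dipole on or outside the brain shell")
  E <- montage$pos / sqrt(rowSums(montage$pos^2))   # unit electrode dirs
  n_e <- nrow(E)
  n_s <- nrow(positions)
  g <- shell_transfer(head, n_terms)
  sigma1 <- head$conductivities[["brain"]]
  beta <- rad / R
  bhat <- positions / ifelse(rad > 0, rad, 1)
  X <- E %*% t(bhat)                      # cos(gamma), n_e x n_s
  unit_axes <- diag(3)
  out <- matrix(0, n_e, 3 * n_s)
  # Legendre recursions over the full electrode x source matrix
  Pm1 <- matrix(1, n_e, n_s)   # P_0
  P <- X                        # P_1
  Dm1 <- matrix(0, n_e, n_s)   # P_0'
  D <- matrix(1, n_e, n_s)     # P_1'
  scale0 <- 1 / (4 * pi * sigma1 * R^2)
  central <- rad < 1e-9 * R
  betapow <- rep(1, n_s)                  # beta^(n-1)
  for (n in seq_len(n_terms)) {
    kn <- g[n] * betapow * scale0         # per-source series weight
    for (a in 1:3) {
      u <- unit_axes[, a]
      mr <- as.vector(bhat %*% u)         # radial moment component
      Eu <- as.vector(E %*% u)
      # tangential factor (m - mr*bhat) . e_hat = Eu - mr * cos(gamma)
      contrib <- sweep(P, 2, n * mr * kn, "*") +
        (outer(Eu, rep(1, n_s)) - sweep(X, 2, mr, "*")) *
        sweep(D, 2, kn, "*")
      cols <- a + 3 * (seq_len(n_s) - 1)
      out[, cols] <- out[, cols] + contrib
    }
    # advance recursions to order n+1
    if (n < n_terms) {
      Pn1 <- ((2 * n + 1) * X * P - n * Pm1) / (n + 1)
      Dn1 <- Dm1 + (2 * n + 1) * P
      Pm1 <- P; P <- Pn1
      Dm1 <- D; D <- Dn1
      betapow <- betapow * beta
    }
  }
  # a dipole at the exact center: only the n = 1 term, axis = moment axis
  if (any(central)) {
    for (s in which(central)) {
      cols <- 3 * (s - 1) + (1:3)
      out[, cols] <- g[1] * scale0 * E
    }
  }
  if (reference == "average") out <- sweep(out, 2, colMeans(out))
  rownames(out) <- montage$labels
  if (!is.null(moments)) {
    moments <- matrix(moments, ncol = 3)
    v <- vapply(seq_len(n_s), function(s)
      out[, 3 * (s - 1) + (1:3), drop = FALSE] %*% moments[s, ],
      numeric(n_e))
    matrix(v, nrow = n_e, dimnames = list(montage$labels, NULL))
  } else out
}

#' Scalp topography of a single dipole
#'
#' Convenience wrapper around [forward_gain()] for one source; returns the
#' average-referenced scalp map (one value per montage electrode, including
#' the reference electrode).
#' @inheritParams forward_gain
#' @param position 3-vector, mm
#' @param moment 3-vector dipole moment
#' @return named numeric vector over montage electrodes
#' @export
forward_topography <- function(head, montage, position, moment,
                               n_terms = 60, reference = "average") {
  v <- forward_gain(head, montage, matrix(position, 1, 3),
                    moments = matrix(moment, 1, 3), n_terms = n_terms,
                    reference = reference)
  stats::setNames(as.vector(v), montage$labels)
}
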