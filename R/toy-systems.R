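## Analytic toy systems for the built-in Langevin backend.  These play the
## role of the solvated all-atom systems a production cascade run would
## use, at desk scale: every potential has an analytic gradient, and each
## system is shaped so that one cascade type has a measurable rare event.
##
## Systems (all fully 3-D so the geometry/selection machinery is exercised
## unchanged):
##   double_well_1d  one particle, double well along x, harmonic tether in
##                   y/z.  Barrier default 8 kBT at 300 K.
##   double_well_2d  as above with a soft harmonic y direction.
##   lj_dimer        two particles: Lennard-Jones pair (well depth 10 kBT)
##                   with a flat-bottom transverse tube and a flat-bottom
##                   outer wall, so dissociation is a rare event and the
##                   unbound state occupies a well-defined finite volume.
##   bead_chain      6 beads, harmonic bonds plus Go-like native contacts;
##                   the native helix ships as the folding reference.

#' Construct a toy dynamics system
#'
#' @param name One of `"double_well_1d"`, `"double_well_2d"`,
#'   `"lj_dimer"`, `"bead_chain"`.
#' @param ... Parameter overrides (see Details).
#' @details Common parameters: `mass` (g/mol).  Double wells: `barrier`
#'   (kJ/mol, default 8 kBT at 300 K), `separation` (half well distance
#'   `a`, nm; minima at x = -a and +a), `k_perp` (tether, kJ/mol/nm^2).
#'   lj_dimer: `epsilon` (kJ/mol, default 10 kBT), `sigma` (nm),
#'   `rho_c`/`k_rho` (flat-bottom transverse tube radius/stiffness),
#'   `r_c`/`k_wall` (outer wall), `k_tether` (tether of particle 1).
#'   bead_chain: `k_bond`, `bond_len`, `eps_contact`, `k_rep`.
#' @return Object of class `toy_system` with elements `name`, `params`,
#'   `masses`, `potential(X)`, `gradient(X)`, `x0` (initial
#'   [snapshot()]), `reference` (target snapshot or NULL).
#' @export
toy_system <- function(name = c("double_well_1d", "double_well_2d",
                                "lj_dimer", "bead_chain"), ...) {
  name <- match.arg(name)
  switch(name,
         double_well_1d = make_double_well(list(...), twod = FALSE),
         double_well_2d = make_double_well(list(...), twod = TRUE),
         lj_dimer       = make_lj_dimer(list(...)),
         bead_chain     = make_bead_chain(list(...)))
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy system \"%s\": %d particle(s)\n", x$name,
              length(x$masses)))
  invisible(x)
}

defaults <- function(user, def) {
  for (k in names(user)) def[[k]] <- user[[k]]
  def
}

make_double_well <- function(user, twod) {
  p <- defaults(user, list(barrier = 8 * kBT(300), separation = 1,
                           k_perp = 100, k_y = 10, mass = 1))
  ky <- if (twod) p$k_y else p$k_perp
  h <- p$barrier; a <- p$separation; kp <- p$k_perp
  pot <- function(X) {
    x <- X[1, 1]; y <- X[1, 2]; z <- X[1, 3]
    h * (x^2 / a^2 - 1)^2 + 0.5 * ky * y^2 + 0.5 * kp * z^2
  }
  grad <- function(X) {
    x <- X[1, 1]
    matrix(c(4 * h * x * (x^2 / a^2 - 1) / a^2,
             ky * X[1, 2], kp * X[1, 3]), 1, 3)
  }
  x0 <- snapshot(matrix(c(-a, 0, 0), 1, 3), names = "P1", masses = p$mass)
  ref <- snapshot(matrix(c(a, 0, 0), 1, 3), names = "P1", masses = p$mass)
  structure(list(name = if (twod) "double_well_2d" else "double_well_1d",
                 params = p, masses = p$mass, potential = pot,
                 gradient = grad, x0 = x0, reference = ref),
            class = "toy_system")
}

make_lj_dimer <- function(user) {
  ## The unbound region is a flat-bottom tube along +x (radius rho_c) with
  ## a one-sided wall at x = 0 and an outer wall at r_c, so the ligand
  ## dissociates in one direction and the volume it samples when unbound
  ## is well defined and finite.
  p <- defaults(user, list(epsilon = 10 * kBT(300), sigma = 0.34,
                           rho_c = 0.3, k_rho = 1000, r_c = 2.0,
                           k_wall = 1000, k_x = 2000, k_tether = 1000,
                           mass = c(40, 40)))
  eps <- p$epsilon; sig <- p$sigma
  flat <- function(v, c0, k) if (v > c0) 0.5 * k * (v - c0)^2 else 0
  dflat <- function(v, c0, k) if (v > c0) k * (v - c0) else 0
  pot <- function(X) {
    d <- X[2, ] - X[1, ]
    r <- sqrt(sum(d^2)); rho <- sqrt(d[[2]]^2 + d[[3]]^2)
    sr6 <- (sig / r)^6
    4 * eps * (sr6^2 - sr6) +
      flat(rho, p$rho_c, p$k_rho) + flat(r, p$r_c, p$k_wall) +
      (if (d[[1]] < 0) 0.5 * p$k_x * d[[1]]^2 else 0) +
      0.5 * p$k_tether * sum(X[1, ]^2)
  }
  grad <- function(X) {
    d <- X[2, ] - X[1, ]
    r <- sqrt(sum(d^2)); rho <- sqrt(d[[2]]^2 + d[[3]]^2)
    sr6 <- (sig / r)^6
    dVdr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r + dflat(r, p$r_c, p$k_wall)
    g2 <- dVdr * d / r
    if (rho > 1e-12) {
      drho <- dflat(rho, p$rho_c, p$k_rho) * c(0, d[[2]], d[[3]]) / rho
      g2 <- g2 + drho
    }
    if (d[[1]] < 0) g2 <- g2 + c(p$k_x * d[[1]], 0, 0)
    rbind(-g2 + p$k_tether * X[1, ], g2)
  }
  r0 <- sig * 2^(1 / 6)
  x0 <- snapshot(rbind(c(0, 0, 0), c(r0, 0, 0)), names = c("P1", "P2"),
                 resno = c(1L, 2L), masses = p$mass)
  ref <- snapshot(rbind(c(0, 0, 0), c(p$r_c, 0, 0)),
                  names = c("P1", "P2"), resno = c(1L, 2L),
                  masses = p$mass)
  structure(list(name = "lj_dimer", params = p, masses = p$mass,
                 potential = pot, gradient = grad, x0 = x0,
                 reference = ref), class = "toy_system")
}

## Native fold: a tight helix of 6 beads with bond length `bond_len`.
bead_chain_native <- function(bond_len = 0.38, n = 6L) {
  t <- seq(0, by = 1.6, length.out = n)
  raw <- cbind(cos(t), sin(t), 0.25 * t)
  d <- sqrt(sum((raw[2, ] - raw[1, ])^2))
  raw * bond_len / d
}

make_bead_chain <- function(user) {
  p <- defaults(user, list(n = 6L, k_bond = 2000, bond_len = 0.38,
                           eps_contact = 4 * kBT(300), k_rep = 0.2,
                           mass = 10))
  n <- p$n
  native <- bead_chain_native(p$bond_len, n)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 2L, , drop = FALSE]
  dnat <- sqrt(rowSums((native[pairs[, 1], ] - native[pairs[, 2], ])^2))
  contact <- dnat < 2.2 * p$bond_len
  pot <- function(X) {
    v <- 0
    for (i in seq_len(n - 1L)) {
      b <- sqrt(sum((X[i + 1L, ] - X[i, ])^2))
      v <- v + 0.5 * p$k_bond * (b - p$bond_len)^2
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      r <- sqrt(sum((X[j, ] - X[i, ])^2))
      if (contact[[k]]) {
        s <- dnat[[k]] / r
        v <- v + p$eps_contact * (5 * s^12 - 6 * s^10)
      } else v <- v + p$k_rep * (p$bond_len / r)^12
    }
    v
  }
  grad <- function(X) {
    G <- matrix(0, n, 3)
    for (i in seq_len(n - 1L)) {
      d <- X[i + 1L, ] - X[i, ]; b <- sqrt(sum(d^2))
      f <- p$k_bond * (b - p$bond_len) * d / b
      G[i, ] <- G[i, ] - f; G[i + 1L, ] <- G[i + 1L, ] + f
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      d <- X[j, ] - X[i, ]; r <- sqrt(sum(d^2))
      dVdr <- if (contact[[k]]) {
        s <- dnat[[k]] / r
        p$eps_contact * (-60 * s^12 + 60 * s^10) / r
      } else -12 * p$k_rep * (p$bond_len / r)^12 / r
      f <- dVdr * d / r
      G[i, ] <- G[i, ] - f; G[j, ] <- G[j, ] + f
    }
    G
  }
  ## extended chain as the unfolded initial state
  ext <- cbind(p$bond_len * (seq_len(n) - 1L), 0, 0)
  masses <- rep(p$mass, n)
  nm <- paste0("B", seq_len(n))
  x0 <- snapshot(ext, names = nm, resno = seq_len(n), masses = masses)
  ref <- snapshot(native, names = nm, resno = seq_len(n), masses = masses)
  structure(list(name = "bead_chain", params = p, masses = masses,
                 potential = pot, gradient = grad, x0 = x0,
                 reference = ref), class = "toy_system")
}

#' Finite-difference consistency check of a toy system's gradient
#'
#' @param system A [toy_system()].
#' @param X Coordinates to test at (defaults to a perturbed initial
#'   state).
#' @param h Finite-difference step.
#' @return Maximum relative deviation between the analytic and central
#'   finite-difference gradient.
#' @export
check_gradient <- function(system, X = NULL, h = 1e-6) {
  if (is.null(X)) X <- system$x0$coords + 0.05
  g <- system$gradient(X)
  fd <- g * 0
  for (i in seq_len(nrow(X))) for (j in 1:3) {
    Xp <- X; Xm <- X
    Xp[i, j] <- Xp[i, j] + h; Xm[i, j] <- Xm[i, j] - h
    fd[i, j] <- (system$potential(Xp) - system$potential(Xm)) / (2 * h)
  }
  max(abs(g - fd)) / max(abs(g), 1)
}
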