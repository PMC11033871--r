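## Coordinate algebra shared by the selection features and post tools.

#' Atom group
#'
#' @param indices Atom indices (1-based, unique, within bounds).
#' @param masses Per-atom masses in g/mol (recycled from the structure
#'   when resolved through [resolve_selection()]).
#' @return Object of class `atom_group`.
#' @export
atom_group <- function(indices, masses = rep(1, length(indices))) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("empty atom group")
  if (anyDuplicated(indices)) stop("atom group indices must be unique")
  if (any(masses <= 0)) stop("atom masses must be > 0")
  structure(list(indices = indices, masses = as.numeric(masses)),
            class = "atom_group")
}

#' Resolve a selection string against a snapshot
#'
#' One internal selection dialect is used regardless of the `analyzer`
#' keyword: clauses joined by `and`, each of which is `all`,
#' `resid A-B,C,...` (residue numbers), `name N1 N2 ...` (atom names), or
#' `index A-B,C,...` (1-based atom indices).  Example:
#' `"resid 1-68 and name CA"`.
#'
#' @param sel Selection string.
#' @param snap A [snapshot()] providing atom names, residue numbers and
#'   masses.
#' @return An [atom_group()].
#' @export
resolve_selection <- function(sel, snap) {
  n <- n_atoms(snap)
  keep <- rep(TRUE, n)
  for (clause in strsplit(trimws(sel), "\\s+and\\s+")[[1]]) {
    tok <- strsplit(trimws(clause), "\\s+")[[1]]
    kind <- tolower(tok[[1]])
    if (kind == "all") next
    if (length(tok) < 2L) stop("malformed selection clause: ", clause)
    args <- paste(tok[-1], collapse = " ")
    if (kind == "resid") {
      keep <- keep & snap$resno %in% expand_ranges(args)
    } else if (kind == "index") {
      keep <- keep & seq_len(n) %in% expand_ranges(args)
    } else if (kind == "name") {
      keep <- keep & snap$names %in% strsplit(args, "[ ,]+")[[1]]
    } else stop("unknown selection keyword: ", kind)
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection matches no atoms: ", sel)
  atom_group(idx, snap$masses[idx])
}

expand_ranges <- function(txt) {
  out <- integer()
  for (piece in strsplit(txt, "[ ,]+")[[1]]) {
    if (grepl("^[0-9]+-[0-9]+$", piece)) {
      ab <- as.integer(strsplit(piece, "-")[[1]])
      out <- c(out, ab[[1]]:ab[[2]])
    } else out <- c(out, as.integer(piece))
  }
  out
}

#' Center of mass of an atom group
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param group An [atom_group()].
#' @return Length-3 vector (nm).
#' @export
center_of_mass <- function(coords, group) {
  m <- group$masses
  colSums(coords[group$indices, , drop = FALSE] * m) / sum(m)
}

#' Distance between the centers of mass of two groups
#'
#' The inter-center-of-mass distance d_com is the selection feature of
#' the dissociation and association cascade types.
#'
#' @param coords N x 3 coordinate matrix (nm).
#' @param group1,group2 [atom_group()]s.
#' @return Distance in nm.
#' @export
com_distance <- function(coords, group1, group2) {
  sqrt(sum((center_of_mass(coords, group1) -
              center_of_mass(coords, group2))^2))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the
#' mass-weighted squared deviation of `mobile` from `reference` over
#' `fit_group`.  Reflections are corrected by flipping the sign of the
#' smallest singular vector when the determinant is negative.
#'
#' @param mobile,reference N x 3 coordinate matrices (nm).
#' @param fit_group [atom_group()] with at least 3 non-collinear atoms.
#' @param mass_weighted Weight atoms by mass (default FALSE: plain RMSD
#'   over selected atoms).
#' @return List with `rotation` (3 x 3, det = +1) and `translation`
#'   (length 3); the fitted mobile is `mobile %*% t(rotation) +
#'   translation` applied row-wise.
#' @export
superpose <- function(mobile, reference, fit_group = NULL,
                      mass_weighted = FALSE) {
  if (is.null(fit_group))
    fit_group <- atom_group(seq_len(nrow(mobile)))
  idx <- fit_group$indices
  if (length(idx) < 3L) stop("degenerate fit: need >= 3 atoms")
  w <- if (mass_weighted) fit_group$masses else rep(1, length(idx))
  w <- w / sum(w)
  X <- mobile[idx, , drop = FALSE]
  Y <- reference[idx, , drop = FALSE]
  xc <- colSums(X * w); yc <- colSums(Y * w)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  s <- svd(crossprod(Xc * w, Yc))            # 3x3 covariance
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2L)
    stop("degenerate fit: collinear atoms")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)                  # proper rotation
  list(rotation = R, translation = as.numeric(yc - R %*% xc))
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix.
#' @param transform List with `rotation` and `translation` as returned
#'   by [superpose()].
#' @export
apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

#' RMSD after best-fit superposition
#'
#' Fits `mobile` on `reference` using `fit_group`, then measures the
#' RMSD over `rmsd_group` (which may differ — e.g. best-fit on one
#' domain, measure displacement of another).
#'
#' @inheritParams superpose
#' @param rmsd_group [atom_group()] over which the RMSD is computed;
#'   defaults to `fit_group`.
#' @return RMSD in nm.
#' @export
rmsd_after_fit <- function(mobile, reference, fit_group = NULL,
                           rmsd_group = NULL, mass_weighted = FALSE) {
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference atom counts differ")
  if (is.null(fit_group)) fit_group <- atom_group(seq_len(nrow(mobile)))
  if (is.null(rmsd_group)) rmsd_group <- fit_group
  tr <- superpose(mobile, reference, fit_group, mass_weighted)
  fitted <- apply_transform(mobile, tr)
  idx <- rmsd_group$indices
  w <- if (mass_weighted) rmsd_group$masses else rep(1, length(idx))
  w <- w / sum(w)
  d2 <- rowSums((fitted[idx, , drop = FALSE] -
                   reference[idx, , drop = FALSE])^2)
  sqrt(sum(w * d2))
}

#' Principal component projection
#'
#' Mean-centers `points`, diagonalizes the unbiased covariance and
#' returns the scores on the leading components together with the axes.
#'
#' @param points M x D matrix.
#' @param n_components Number of components (>= 1, < M).
#' @return List with `scores` (M x d), `axes` (d x D orthonormal rows)
#'   and `variances` (length d eigenvalues).
#' @export
pca_project <- function(points, n_components = 2L) {
  points <- as.matrix(points)
  if (nrow(points) <= n_components)
    stop("need more points than components")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  if (n_components > sum(eg$values > 1e-12 * max(eg$values, 1e-300)))
    stop("n_components exceeds the rank of the point cloud")
  axes <- t(eg$vectors[, seq_len(n_components), drop = FALSE])
  list(scores = X %*% t(axes), axes = axes,
       variances = eg$values[seq_len(n_components)])
}
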