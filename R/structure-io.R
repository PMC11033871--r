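## Snapshot: one frame of a system.  Coordinates are always N x 3 in nm;
## atom names / residue labels are kept so group-selection strings work on
## structures read from PDB as well as on toy systems.

#' Construct a snapshot
#'
#' @param coords N x 3 numeric matrix of coordinates in nm.
#' @param names Atom names (length N); default `"CA"`.
#' @param resid Residue names (length N); default `"GLY"`.
#' @param resno Residue numbers (length N); default `seq_len(N)`.
#' @param masses Atom masses in g/mol (length N); default 1.
#' @param velocities Optional N x 3 matrix, nm/ps.
#' @param provenance Optional named list (`trial`, `cycle`, `replica`,
#'   `frame`).
#' @return Object of class `snapshot`.
#' @export
snapshot <- function(coords, names = NULL, resid = NULL, resno = NULL,
                     masses = NULL, velocities = NULL, provenance = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n < 1L) stop("snapshot needs at least one atom")
  structure(list(
    coords     = coords,
    names      = if (is.null(names)) rep("CA", n) else as.character(names),
    resid      = if (is.null(resid)) rep("GLY", n) else as.character(resid),
    resno      = if (is.null(resno)) seq_len(n) else as.integer(resno),
    masses     = if (is.null(masses)) rep(1, n) else as.numeric(masses),
    velocities = velocities,
    provenance = provenance
  ), class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("snapshot: %d atoms", nrow(x$coords)))
  if (!is.null(x$provenance))
    cat(sprintf("  [trial %s cycle %s replica %s frame %s]",
                x$provenance$trial %||% "?", x$provenance$cycle %||% "?",
                x$provenance$replica %||% "?", x$provenance$frame %||% "?"))
  cat("\n")
  invisible(x)
}

n_atoms <- function(snap) nrow(snap$coords)

#' Read a structure file into a snapshot
#'
#' Supports PDB (`.pdb`, coordinates in Angstrom on disk, converted to
#' nm) via bio3d, and the package's internal coordinate table (`.csv`
#' with columns `name,resid,resno,mass,x,y,z`, coordinates already in
#' nm).
#'
#' @param path Path to a `.pdb` or `.csv` structure file.
#' @return A [snapshot()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "resid", "resno", "mass", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("coordinate table ", path, " must have columns: ",
           paste(need, collapse = ","))
    if (nrow(tab) == 0L) stop("structure file has zero atoms: ", path)
    return(snapshot(cbind(tab$x, tab$y, tab$z), names = tab$name,
                    resid = tab$resid, resno = tab$resno,
                    masses = tab$mass))
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("unparseable PDB file ", path, ": ",
                         conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("structure file has zero atoms: ", path)
  a <- pdb$atom
  snapshot(cbind(a$x, a$y, a$z) / 10,  # Angstrom -> nm
           names = a$elety, resid = a$resid, resno = a$resno,
           masses = guess_masses(a$elety))
}

#' Write a snapshot to disk
#'
#' PDB output is in Angstrom; coordinate-table CSV output stays in nm.
#'
#' @param snap A [snapshot()].
#' @param path Output path; `.pdb` or `.csv` decides the format.
#' @export
write_structure <- function(snap, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(data.frame(
      name = snap$names, resid = snap$resid, resno = snap$resno,
      mass = snap$masses, x = snap$coords[, 1], y = snap$coords[, 2],
      z = snap$coords[, 3]), path, row.names = FALSE)
  } else {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(snap$coords)) * 10,
                     elety = snap$names, resid = snap$resid,
                     resno = snap$resno, chain = "A")
  }
  invisible(path)
}

## Rough per-element masses for PDB input; toy systems carry exact masses.
guess_masses <- function(elety) {
  el <- toupper(substr(trimws(elety), 1L, 1L))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}
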