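## Trajectory container and file formats.
##
## In memory a trajectory is a `pacs_traj`: frames x atoms x 3 array (nm)
## plus the atom metadata of its first snapshot and a provenance record.
## On disk three formats are supported: "xyz" (plain text, nm), "pdb"
## (multi-model PDB, Angstrom) and "bintab" (binary table: a small header
## plus little-endian doubles, lossless).

#' Construct a trajectory from snapshots or a coordinate array
#'
#' @param frames List of [snapshot()]s with identical atom counts, or a
#'   frames x atoms x 3 array.
#' @param template Snapshot providing atom metadata when `frames` is an
#'   array.
#' @param provenance Optional named list (`trial`, `cycle`, `replica`).
#' @return Object of class `pacs_traj`.
#' @export
pacs_traj <- function(frames, template = NULL, provenance = NULL) {
  if (is.list(frames)) {
    if (!length(frames)) stop("empty frame sequence")
    template <- frames[[1]]
    arr <- array(0, dim = c(length(frames), n_atoms(template), 3))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]$coords
  } else {
    arr <- frames
    if (length(dim(arr)) != 3L) stop("coordinate array must be frames x atoms x 3")
    if (is.null(template))
      template <- snapshot(matrix(arr[1, , ], ncol = 3))
  }
  structure(list(coords = arr, names = template$names,
                 resid = template$resid, resno = template$resno,
                 masses = template$masses, provenance = provenance),
            class = "pacs_traj")
}

#' @export
print.pacs_traj <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n",
              dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pacs_traj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a snapshot
#'
#' @param traj A `pacs_traj`.
#' @param i Frame index (1-based).
#' @param frame0 Frame number of the trajectory's first frame in its
#'   provenance record (0-based frames on disk).
#' @export
get_frame <- function(traj, i, frame0 = 0L) {
  prov <- traj$provenance
  if (!is.null(prov)) prov$frame <- frame0 + i - 1L
  snapshot(matrix(traj$coords[i, , ], ncol = 3), names = traj$names,
           resid = traj$resid, resno = traj$resno, masses = traj$masses,
           provenance = prov)
}

#' Write a trajectory to disk
#'
#' @param traj A `pacs_traj` (or list of snapshots).
#' @param path Output path.
#' @param format One of `"xyz"`, `"pdb"`, `"bintab"`.
#' @export
write_trajectory <- function(traj, path, format = c("bintab", "xyz", "pdb")) {
  format <- match.arg(format)
  if (is.list(traj) && !inherits(traj, "pacs_traj")) traj <- pacs_traj(traj)
  nf <- n_frames(traj); na <- dim(traj$coords)[2]
  if (nf < 1L) stop("empty frame sequence")
  if (format == "bintab") {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar("PACSBT1", con, nchars = 7, eos = NULL)
    writeBin(as.numeric(c(nf, na)), con, size = 8L, endian = "little")
    writeBin(as.numeric(aperm(traj$coords, c(3, 2, 1))), con,
             size = 8L, endian = "little")
  } else if (format == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nf)) {
      writeLines(c(as.character(na), sprintf("frame %d", i - 1L)), con)
      writeLines(sprintf("%s %.9f %.9f %.9f", traj$names,
                         traj$coords[i, , 1], traj$coords[i, , 2],
                         traj$coords[i, , 3]), con)
    }
  } else {
    xyz <- matrix(0, nf, 3L * na)
    for (i in seq_len(nf))
      xyz[i, ] <- as.numeric(t(traj$coords[i, , ])) * 10
    bio3d::write.pdb(file = path, xyz = xyz, elety = traj$names,
                     resid = traj$resid, resno = traj$resno, chain = "A")
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' The format is inferred from the file content (`bintab` magic, XYZ
#' header, otherwise PDB).
#'
#' @param path Input path.
#' @param template Optional snapshot supplying atom metadata (bintab and
#'   xyz store coordinates only).
#' @return A `pacs_traj`.
#' @export
read_trajectory <- function(path, template = NULL) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  con <- file(path, "rb")
  magic <- suppressWarnings(readChar(con, 7, useBytes = TRUE))
  if (identical(magic, "PACSBT1")) {
    dims <- readBin(con, "numeric", 2L, size = 8L, endian = "little")
    nf <- as.integer(dims[[1]]); na <- as.integer(dims[[2]])
    flat <- readBin(con, "numeric", nf * na * 3L, size = 8L,
                    endian = "little")
    close(con)
    arr <- aperm(array(flat, dim = c(3, na, nf)), c(3, 2, 1))
    return(pacs_traj(arr, template = template))
  }
  close(con)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*[0-9]+\\s*$", first)) {            # xyz
    lines <- readLines(path, warn = FALSE)
    na <- as.integer(first)
    block <- na + 2L
    nf <- length(lines) %/% block
    arr <- array(0, dim = c(nf, na, 3))
    nm <- character(na)
    for (i in seq_len(nf)) {
      body <- lines[((i - 1L) * block + 3L):((i - 1L) * block + 2L + na)]
      tok <- do.call(rbind, strsplit(trimws(body), "\\s+"))
      if (i == 1L) nm <- tok[, 1]
      arr[i, , ] <- matrix(as.numeric(tok[, 2:4]), ncol = 3)
    }
    tmpl <- template %||% snapshot(matrix(arr[1, , ], ncol = 3), names = nm)
    return(pacs_traj(arr, template = tmpl))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) %/% 3L
  arr <- array(0, dim = c(nf, na, 3))
  for (i in seq_len(nf))
    arr[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
  tmpl <- template %||% snapshot(matrix(arr[1, , ], ncol = 3),
                                 names = pdb$atom$elety,
                                 resid = pdb$atom$resid,
                                 resno = pdb$atom$resno,
                                 masses = guess_masses(pdb$atom$elety))
  pacs_traj(arr, template = tmpl)
}
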