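## Post-cascade utilities: representative pathway extraction along the
## lineage, trajectory refitting, COM pseudo-trajectories, atom-subset
## reduction, cleanup, and MSM feature extraction.

read_trial_meta <- function(trial_dir) {
  path <- file.path(trial_dir, "trial_meta.csv")
  if (!file.exists(path)) stop("not a finished trial (no trial_meta.csv): ",
                               trial_dir)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.list(tab$value), tab$key)
}

#' Extract the representative pathway of a finished trial
#'
#' Picks the terminal snapshot optimizing the selection feature in the
#' final cycle (ties broken by lower replica then frame), walks the
#' lineage back to cycle 0, and concatenates each ancestor replica's
#' frames up to and including its selected frame — the part of every
#' branch that actually lies on the path.
#'
#' @param trial_dir Trial directory (`.../trialTTT`).
#' @param criterion `"final"` (default) optimizes the feature over the
#'   final cycle only; `"global"` over all cycles.
#' @param template Optional [snapshot()] supplying atom metadata.
#' @return Object of class `representative_path`: a [pacs_traj()] plus a
#'   per-frame provenance data frame (`cycle`, `replica`, `frame`,
#'   `value`).
#' @export
genrepresent <- function(trial_dir, criterion = c("final", "global"),
                         template = NULL) {
  criterion <- match.arg(criterion)
  meta <- read_trial_meta(trial_dir)
  ids <- parse_run_path(trial_dir)
  root <- dirname(trial_dir)
  n_cyc <- as.integer(meta$n_cycles)
  minimize <- identical(meta$direction, "minimize")
  lineage <- if (file.exists(file.path(trial_dir, "lineage.csv")))
    utils::read.csv(file.path(trial_dir, "lineage.csv")) else data.frame()

  summaries <- lapply(0:n_cyc, function(cc)
    utils::read.csv(file.path(run_path(root, ids$trial, cc),
                              "summary.csv")))
  pool <- if (criterion == "final") summaries[[n_cyc + 1L]]
  else do.call(rbind, summaries)
  key <- if (minimize) pool$value else -pool$value
  term <- pool[order(key, pool$replica, pool$frame)[1L], ]

  ## walk parents from the terminal snapshot back to cycle 0
  segs <- list(term)
  cur <- term
  while (cur$cycle > 0L) {
    hit <- lineage[lineage$child_cycle == cur$cycle &
                     lineage$child_replica == cur$replica, ]
    if (nrow(hit) != 1L)
      stop("broken lineage: no parent record for cycle ", cur$cycle,
           " replica ", cur$replica)
    cur <- data.frame(cycle = hit$parent_cycle,
                      replica = hit$parent_replica,
                      frame = hit$parent_frame,
                      value = hit$feature_at_selection)
    segs <- c(list(cur), segs)
  }

  frames <- list(); prov <- data.frame()
  for (seg in segs) {
    tr <- load_replica_traj(root, ids$trial, seg$cycle, seg$replica,
                            template)
    take <- seq_len(seg$frame + 1L)
    for (i in take) frames <- c(frames, list(get_frame(tr, i)))
    vals <- summaries[[seg$cycle + 1L]]
    vals <- vals[vals$replica == seg$replica, ]
    vals <- vals[order(vals$frame), ]
    prov <- rbind(prov, data.frame(cycle = seg$cycle,
                                   replica = seg$replica,
                                   frame = take - 1L,
                                   value = vals$value[take]))
  }
  structure(list(traj = pacs_traj(frames), provenance = prov,
                 terminal = term), class = "representative_path")
}

#' @export
print.representative_path <- function(x, ...) {
  cat(sprintf(
    "representative path: %d frames over cycles %d..%d (terminal value %.4f)\n",
    n_frames(x$traj), min(x$provenance$cycle), max(x$provenance$cycle),
    x$terminal$value))
  invisible(x)
}

#' Best-fit every frame of a trajectory onto a reference
#'
#' @param traj A [pacs_traj()].
#' @param reference Reference [snapshot()].
#' @param fit_group [atom_group()] used for the superposition (default:
#'   all atoms).
#' @return The refitted trajectory.
#' @export
fit_trajectory <- function(traj, reference, fit_group = NULL) {
  nf <- n_frames(traj)
  out <- traj
  for (i in seq_len(nf)) {
    X <- matrix(traj$coords[i, , ], ncol = 3)
    tr <- superpose(X, reference$coords, fit_group)
    out$coords[i, , ] <- apply_transform(X, tr)
  }
  out
}

#' Center-of-mass pseudo-trajectory
#'
#' Reduces each frame to the center of mass of `group`, optionally
#' written as a multi-model PDB with one pseudo-atom per model.
#'
#' @param traj A [pacs_traj()].
#' @param group An [atom_group()].
#' @param path Optional output PDB path.
#' @return Invisibly, the frames x 3 matrix of COM positions (nm).
#' @export
gencom <- function(traj, group, path = NULL) {
  nf <- n_frames(traj)
  coms <- t(vapply(seq_len(nf), function(i)
    center_of_mass(matrix(traj$coords[i, , ], ncol = 3), group),
    numeric(3)))
  if (!is.null(path)) {
    pseudo <- pacs_traj(array(coms, dim = c(nf, 1L, 3)),
                        template = snapshot(matrix(coms[1, ], 1, 3),
                                            names = "COM", resid = "COM"))
    write_trajectory(pseudo, path, "pdb")
  }
  invisible(coms)
}

#' Reduce a trajectory to a subset of atoms
#'
#' @param traj A [pacs_traj()].
#' @param keep_group [atom_group()] of atoms to keep.
#' @return Trajectory containing exactly the kept atoms, coordinates
#'   unchanged.
#' @export
rmmol <- function(traj, keep_group) {
  idx <- keep_group$indices
  out <- traj
  out$coords <- traj$coords[, idx, , drop = FALSE]
  out$names <- traj$names[idx]; out$resid <- traj$resid[idx]
  out$resno <- traj$resno[idx]; out$masses <- traj$masses[idx]
  out
}

#' Remove files unnecessary after analysis
#'
#' Deletes (or, with `policy = "dry-run"`, merely lists) the raw
#' per-replica trajectory files of a finished trial.  Ranking CSVs,
#' lineage records, seed files, metadata and any reduced trajectories
#' are never touched; an unfinished trial is refused.
#'
#' @param trial_dir Trial directory.
#' @param policy `"dry-run"` (default) or `"execute"`.
#' @return Data frame listing the targeted files and whether each was
#'   removed.
#' @export
rmfile <- function(trial_dir, policy = c("dry-run", "execute")) {
  policy <- match.arg(policy)
  read_trial_meta(trial_dir)   # refuses unfinished trials
  targets <- list.files(trial_dir, pattern = "^traj\\.dat$",
                        recursive = TRUE, full.names = TRUE)
  removed <- rep(FALSE, length(targets))
  if (policy == "execute" && length(targets))
    removed <- file.remove(targets)
  data.frame(path = targets, removed = removed,
             stringsAsFactors = FALSE)
}

#' Extract MSM features from a finished trial
#'
#' Writes one array per (cycle, replica) with one value per frame —
#' the MSM feature may differ from the run's selection feature — in
#' NumPy `.npy` format with a CSV mirror, plus an index CSV.
#'
#' @param trial_dir Trial directory.
#' @param feature Either the string `"com_distance"` or `"rmsd"`, or a
#'   function `(pacs_traj) -> numeric` (one value per frame).
#' @param output Output directory (default `file.path(trial_dir,
#'   "features")`).
#' @param group1,group2 [atom_group()]s for `"com_distance"`.
#' @param reference Reference [snapshot()] and @param fit_group /
#'   `rmsd_group` groups for `"rmsd"`.
#' @param fit_group,rmsd_group See [rmsd_after_fit()].
#' @param template Optional snapshot with atom metadata.
#' @return Invisibly, the index data frame (`cycle`, `replica`, `file`,
#'   `n_frames`).
#' @export
genfeature <- function(trial_dir, feature = "com_distance",
                       output = file.path(trial_dir, "features"),
                       group1 = NULL, group2 = NULL, reference = NULL,
                       fit_group = NULL, rmsd_group = NULL,
                       template = NULL) {
  meta <- read_trial_meta(trial_dir)
  ids <- parse_run_path(trial_dir)
  root <- dirname(trial_dir)
  n_cyc <- as.integer(meta$n_cycles)
  dir.create(output, recursive = TRUE, showWarnings = FALSE)

  fn <- if (is.function(feature)) feature
  else if (identical(feature, "com_distance")) {
    if (is.null(group1) || is.null(group2))
      stop("com_distance feature needs group1 and group2")
    function(tr) vapply(seq_len(n_frames(tr)), function(i)
      com_distance(matrix(tr$coords[i, , ], ncol = 3), group1, group2), 0)
  } else if (identical(feature, "rmsd")) {
    if (is.null(reference)) stop("rmsd feature needs a reference")
    function(tr) vapply(seq_len(n_frames(tr)), function(i)
      rmsd_after_fit(matrix(tr$coords[i, , ], ncol = 3),
                     reference$coords, fit_group, rmsd_group), 0)
  } else stop("unresolvable feature spec")

  index <- data.frame()
  for (cc in 0:n_cyc) {
    cdir <- run_path(root, ids$trial, cc)
    reps <- sort(list.files(cdir, pattern = "^replica[0-9]{3}$"))
    if (!length(reps)) stop("missing cycle directory content: cycle ", cc)
    for (rd in reps) {
      r <- as.integer(sub("replica", "", rd))
      tpath <- file.path(cdir, rd, "traj.dat")
      if (!file.exists(tpath))
        stop("missing trajectory for (cycle ", cc, ", replica ", r, ")")
      tr <- read_trajectory(tpath, template = template)
      vals <- as.numeric(fn(tr))
      if (length(vals) != n_frames(tr))
        stop("feature function returned wrong length")
      base <- sprintf("feature_c%03d_r%03d", cc, r)
      write_npy(vals, file.path(output, paste0(base, ".npy")))
      utils::write.csv(data.frame(frame = seq_along(vals) - 1L,
                                  value = vals),
                       file.path(output, paste0(base, ".csv")),
                       row.names = FALSE)
      index <- rbind(index, data.frame(cycle = cc, replica = r,
                                       file = paste0(base, ".npy"),
                                       n_frames = length(vals)))
    }
  }
  utils::write.csv(index, file.path(output, "index.csv"),
                   row.names = FALSE)
  invisible(index)
}

#' Load genfeature output as a list of per-replica numeric vectors
#' @param feature_dir Directory written by [genfeature()].
#' @return Named list of numeric vectors, ordered by (cycle, replica).
#' @export
read_features <- function(feature_dir) {
  idx <- utils::read.csv(file.path(feature_dir, "index.csv"))
  idx <- idx[order(idx$cycle, idx$replica), ]
  out <- lapply(seq_len(nrow(idx)), function(i)
    read_npy(file.path(feature_dir, idx$file[[i]])))
  names(out) <- sprintf("c%03d_r%03d", idx$cycle, idx$replica)
  out
}

## ---- minimal NumPy .npy (v1.0) serialization for 1-D float64 arrays ------

#' Write a numeric vector as a NumPy .npy file
#' @param x Numeric vector.
#' @param path Output path.
#' @export
write_npy <- function(x, path) {
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d,), }",
                  length(x))
  ## total header (magic 6 + version 2 + len 2 + dict + newline) % 64 == 0
  pad <- (64L - (10L + nchar(dict) + 1L) %% 64L) %% 64L
  dict <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(0x93L, 0x4eL, 0x55L, 0x4dL, 0x50L, 0x59L, 0x01L, 0x00L),
           con, size = 1L)
  writeBin(nchar(dict), con, size = 2L, endian = "little")
  writeChar(dict, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a 1-D float64 NumPy .npy file
#' @param path Input path.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(as.integer(magic[1:6]),
                 c(0x93L, 0x4eL, 0x55L, 0x4dL, 0x50L, 0x59L)))
    stop("not an npy file: ", path)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  m <- regmatches(header, regexec("'shape':\\s*\\((\\d+),?\\)", header))[[1]]
  n <- as.integer(m[[2]])
  if (!grepl("'<f8'", header)) stop("unsupported npy dtype in ", path)
  readBin(con, "numeric", n, size = 8L, endian = "little")
}
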