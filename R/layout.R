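## On-disk layout: trial{T:03d}/cycle{C:03d}/replica{R:03d}.
## Trials are numbered from 1; cycles and replicas from 0 (cycle 0 is the
## initialization cycle run from the input structure).

#' Directory path for a (trial, cycle, replica) triple
#'
#' @param root Run root directory.
#' @param trial Trial number (1-based).
#' @param cycle Cycle number (0-based); omit for the trial directory.
#' @param replica Replica number (0-based); omit for the cycle directory.
#' @return Path string.
#' @export
run_path <- function(root, trial, cycle = NULL, replica = NULL) {
  stopifnot(trial >= 1)
  p <- file.path(root, sprintf("trial%03d", trial))
  if (!is.null(cycle)) {
    stopifnot(cycle >= 0)
    p <- file.path(p, sprintf("cycle%03d", cycle))
    if (!is.null(replica)) {
      stopifnot(replica >= 0)
      p <- file.path(p, sprintf("replica%03d", replica))
    }
  }
  p
}

#' Parse a run-layout path back into its indices
#'
#' Inverse of [run_path()]: extracts `(trial, cycle, replica)` from a
#' path containing `trialTTT/cycleCCC/replicaRRR` components.
#'
#' @param path Path string.
#' @return Named list with `trial`, and `cycle` / `replica` when present
#'   (otherwise `NA`).
#' @export
parse_run_path <- function(path) {
  parts <- strsplit(path, "[/\\\\]")[[1]]
  pick <- function(prefix) {
    hit <- grep(paste0("^", prefix, "[0-9]{3}$"), parts, value = TRUE)
    if (length(hit)) as.integer(sub(prefix, "", hit[[length(hit)]])) else NA_integer_
  }
  out <- list(trial = pick("trial"), cycle = pick("cycle"),
              replica = pick("replica"))
  if (is.na(out$trial)) stop("not a run-layout path: ", path)
  out
}
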