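## The mdrun loop: initialize a trial, iterate cycles (run replicas ->
## analyze -> rank -> export seeds), record lineage, stop on threshold or
## max_cycle.
##
## Cycle 0 is a single replica propagated from the input structure (or
## `cycle0_replicas` independent ones); every later cycle runs n_replica
## replicas from the exported seeds, each with freshly drawn
## Maxwell-Boltzmann velocities.  Everything is reproducible from the
## trial's root seed: per-(cycle, replica) child seeds come from
## [child_seed()].

#' Run one cascade-selection trial
#'
#' @param cfg A `pacs_config` (see [load_config()]); programmatic
#'   construction via a list with the same fields also works.
#' @param root Run root directory (created if needed).
#' @param system A [toy_system()] for the toy backend; when NULL it is
#'   built from the `mdconf` file.
#' @param params An [md_params()]; when NULL taken from `mdconf`.
#' @param initial Initial [snapshot()]; defaults to the `initial`
#'   config keyword (a structure file) or the toy system's own initial
#'   state.
#' @param reference Reference [snapshot()] for RMSD types; defaults to
#'   the `reference` config keyword or the toy system's reference.
#' @param context Extra backend context (e.g. `frames` for the mock
#'   backend).
#' @param cycle0_replicas Number of independent replicas in the
#'   initialization cycle (default 1).
#' @param quiet Suppress the per-cycle progress line.
#' @return Object of class `pacs_trial`: stop reason, per-cycle best
#'   feature values, the lineage table, and the on-disk location.
#' @export
run_trial <- function(cfg, root = tempfile("pacsrun"), system = NULL,
                      params = NULL, initial = NULL, reference = NULL,
                      context = list(), cycle0_replicas = 1L,
                      quiet = TRUE) {
  if (identical(cfg$simulator, "toy") &&
      (is.null(system) || is.null(params))) {
    if (is.null(cfg$mdconf))
      stop("toy backend needs either `system`+`params` or an mdconf file")
    mc <- read_mdconf(cfg$mdconf)
    system <- system %||% mc$system
    params <- params %||% mc$params
  }
  params <- params %||% md_params()
  if (is.null(initial)) {
    initial <- if (!is.null(cfg$initial)) read_structure(cfg$initial)
    else if (!is.null(system)) system$x0
    else stop("no initial structure")
  }
  if (is.null(reference) && cfg$type %in% c("target", "rmsd")) {
    reference <- if (!is.null(cfg$reference) && file.exists(cfg$reference))
      read_structure(cfg$reference)
    else if (identical(cfg$type, "rmsd")) initial   # RMSD from the start
    else if (!is.null(system)) system$reference
    else stop("type \"", cfg$type, "\" requires a reference structure")
  }
  evaluator <- if (identical(cfg$type, "template")) {
    if (is.null(cfg$template)) stop("template type needs the template keyword")
    template_hook(cfg$template, cfg)
  }
  spec <- selection_spec(cfg, initial, reference, evaluator)
  if (identical(cfg$simulator, "toy")) context$system <- system

  trial_dir <- run_path(root, cfg$trial)
  dir.create(trial_dir, recursive = TRUE, showWarnings = FALSE)
  root_seed <- child_seed(cfg$seed, cfg$trial, 0L, 2L)

  seeds <- list(list(snap = initial, parent = NULL))    # cycle-0 seeds
  if (cycle0_replicas > 1L)
    seeds <- rep(seeds, cycle0_replicas)
  lineage <- data.frame()
  all_values <- list()
  best <- numeric()
  adst <- if (identical(cfg$type, "a_d")) ad_state()
  ad_phases <- character()
  ee_feat <- NULL; ee_prov <- NULL
  stop_reason <- "max_cycle"
  cyc <- 0L

  repeat {
    cdir <- run_path(root, cfg$trial, cyc)
    trajs <- vector("list", length(seeds))
    values <- vector("list", length(seeds))
    for (r in seq_along(seeds)) {
      rdir <- run_path(root, cfg$trial, cyc, r - 1L)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      sd_vel <- child_seed(root_seed, cyc, r - 1L, 0L)
      sd_dyn <- child_seed(root_seed, cyc, r - 1L, 1L)
      vel <- mb_velocities(initial$masses, params$temperature, sd_vel)
      p <- params; p$seed <- sd_dyn
      write_structure(seeds[[r]]$snap, file.path(rdir, "seed.csv"))
      backend_run(cfg$simulator, seeds[[r]]$snap, vel, p, rdir, context)
      trajs[[r]] <- read_trajectory(file.path(rdir, "traj.dat"),
                                    template = initial)
      trajs[[r]]$provenance <- list(trial = cfg$trial, cycle = cyc,
                                    replica = r - 1L)
      if (!identical(cfg$type, "ee"))
        values[[r]] <- evaluate_feature(
          trajs[[r]], spec, list(cycle = cyc, replica = r - 1L))
      else {
        nf <- n_frames(trajs[[r]])
        flat <- t(vapply(seq_len(nf), function(i)
          as.numeric(trajs[[r]]$coords[i, spec$group1$indices, ]),
          numeric(3 * length(spec$group1$indices))))
        ee_feat <- rbind(ee_feat, flat)
        ee_prov <- rbind(ee_prov, data.frame(cycle = cyc,
                                             replica = r - 1L,
                                             frame = seq_len(nf) - 1L))
        values[[r]] <- data.frame(cycle = cyc, replica = r - 1L,
                                  frame = seq_len(nf) - 1L,
                                  value = NA_real_)
      }
    }
    cvals <- do.call(rbind, values)
    all_values[[cyc + 1L]] <- cvals

    if (identical(cfg$type, "ee")) {
      sel <- ee_select(ee_feat, ee_prov, cfg$n_replica)
      cbest <- NA_real_
      direction <- "maximize"
    } else {
      direction <- if (identical(cfg$type, "template"))
        evaluator$direction
      else feature_direction(cfg$type,
                             if (!is.null(adst)) adst$phase else "dissociation")
      sel <- rank_and_select(cvals, cfg$n_replica, direction)
      cbest <- if (direction == "minimize") min(cvals$value)
      else max(cvals$value)
    }
    best <- c(best, cbest)

    ranking <- if (identical(cfg$type, "ee")) sel else {
      rk <- cvals
      key <- if (direction == "minimize") rk$value else -rk$value
      rk$rank <- rank(key, ties.method = "first")
      rk
    }
    utils::write.csv(ranking, file.path(cdir, "summary.csv"),
                     row.names = FALSE)
    if (!quiet)
      message(sprintf("cycle %3d  best %s = %.4f", cyc, cfg$type, cbest))

    if (!is.null(adst)) {
      ad_phases <- c(ad_phases, adst$phase)
      adst <- ad_update(adst, cvals, cfg)
    }

    dec <- check_stop(cbest, cfg, cyc)
    if (dec != "continue") { stop_reason <- dec; break }

    ## export seeds for cycle cyc+1
    seeds <- vector("list", cfg$n_replica)
    for (r in seq_len(cfg$n_replica)) {
      pr <- sel[r, ]
      src <- if (pr$cycle == cyc) trajs[[pr$replica + 1L]]
      else load_replica_traj(root, cfg$trial, pr$cycle, pr$replica,
                             initial)
      seeds[[r]] <- list(snap = get_frame(src, pr$frame + 1L),
                         parent = pr)
      lineage <- rbind(lineage, data.frame(
        child_cycle = cyc + 1L, child_replica = r - 1L,
        parent_cycle = pr$cycle, parent_replica = pr$replica,
        parent_frame = pr$frame, feature_at_selection = pr$value))
    }
    cyc <- cyc + 1L
  }

  if (nrow(lineage))
    utils::write.csv(lineage, file.path(trial_dir, "lineage.csv"),
                     row.names = FALSE)
  meta <- data.frame(
    key = c("type", "direction", "n_replica", "max_cycle", "n_cycles",
            "stop_reason", "seed", "simulator"),
    value = c(cfg$type,
              if (identical(cfg$type, "ee")) "maximize" else direction,
              cfg$n_replica, cfg$max_cycle, cyc, stop_reason, cfg$seed,
              cfg$simulator))
  utils::write.csv(meta, file.path(trial_dir, "trial_meta.csv"),
                   row.names = FALSE)

  structure(list(config = cfg, root = root, trial = cfg$trial,
                 n_cycles = cyc, stop_reason = stop_reason, best = best,
                 lineage = lineage, values = all_values,
                 ad_phases = ad_phases, params = params),
            class = "pacs_trial")
}

#' @export
print.pacs_trial <- function(x, ...) {
  cat(sprintf("cascade trial %d (%s): %d cycle(s), stopped on %s\n",
              x$trial, x$config$type, x$n_cycles + 1L, x$stop_reason))
  if (length(x$best) && !all(is.na(x$best)))
    cat(sprintf("  best feature: first %.4f, last %.4f\n",
                x$best[[1]], x$best[[length(x$best)]]))
  invisible(x)
}

#' @export
summary.pacs_trial <- function(object, ...) {
  cat(sprintf("cascade trial %d, type %s, %d replicas/cycle\n",
              object$trial, object$config$type, object$config$n_replica))
  cat(sprintf("  cycles run: %d (stop: %s)\n", object$n_cycles + 1L,
              object$stop_reason))
  if (length(object$best) && !all(is.na(object$best))) {
    cat("  per-cycle best feature values:\n")
    print(round(object$best, 4))
  }
  invisible(object)
}

#' @export
plot.pacs_trial <- function(x, ...) {
  graphics::plot(seq_along(x$best) - 1L, x$best, type = "b",
                 xlab = "cycle", ylab = "best selection feature", ...)
  invisible(x)
}

#' Stop decision after a cycle
#'
#' The run stops when the cycle counter reaches `max_cycle`, or when the
#' `threshold` keyword is satisfied: best feature <= threshold for
#' minimizing types, >= threshold for maximizing types.  The `ee` and
#' `a_d` types ignore `threshold` and stop only at `max_cycle`; the
#' comparison is inclusive.
#'
#' @param best_value Best feature value of the finished cycle.
#' @param cfg The run configuration.
#' @param cycle 0-based cycle index just finished.
#' @return `"continue"`, `"threshold"` or `"max_cycle"`.
#' @export
check_stop <- function(best_value, cfg, cycle) {
  if (!cfg$type %in% c("ee", "a_d") && !is.null(cfg$threshold) &&
      is.finite(best_value)) {
    dir <- feature_direction(cfg$type)
    hit <- if (dir == "minimize") best_value <= cfg$threshold
    else best_value >= cfg$threshold
    if (hit) return("threshold")
  }
  if (cycle >= cfg$max_cycle) return("max_cycle")
  "continue"
}

load_replica_traj <- function(root, trial, cycle, replica, template) {
  path <- file.path(run_path(root, trial, cycle, replica), "traj.dat")
  if (!file.exists(path))
    stop("missing trajectory for cycle ", cycle, " replica ", replica)
  tr <- read_trajectory(path, template = template)
  tr$provenance <- list(trial = trial, cycle = cycle, replica = replica)
  tr
}

#' Verify the seed-optimality invariant of a finished trial
#'
#' For every cycle c >= 1, the rank-1 seed's recorded feature must equal
#' the extremum of the full candidate pool of cycle c-1 (selection never
#' discards the best candidate).
#'
#' @param trial A `pacs_trial`.
#' @return Maximum absolute deviation over cycles (0 when the invariant
#'   holds exactly).
#' @export
seed_optimality_gap <- function(trial) {
  if (identical(trial$config$type, "ee"))
    stop("seed optimality is defined for scalar-feature types only")
  if (!nrow(trial$lineage)) return(0)
  dirs <- trial$lineage
  gap <- 0
  for (cc in unique(dirs$child_cycle)) {
    rec <- dirs[dirs$child_cycle == cc & dirs$child_replica == 0L, ]
    pool <- trial$values[[cc]]
    dirn <- feature_direction(trial$config$type,
                              if (length(trial$ad_phases) >= cc)
                                trial$ad_phases[[cc]] else "dissociation")
    ext <- if (dirn == "minimize") min(pool$value) else max(pool$value)
    gap <- max(gap, abs(rec$feature_at_selection - ext))
  }
  gap
}
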