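# Fixtures are built in code: a TOML config writer (so tests exercise the
# real input path) and small deterministic structures.

write_toy_config <- function(dir = tempfile("cfg"), type = "target",
                             n_replica = 5L, max_cycle = 10L,
                             threshold = NULL, seed = 1L,
                             system = "double_well_1d",
                             dt = 0.01, n_steps = 200L,
                             save_interval = 5L, friction = 50,
                             temperature = 300, extra = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mdconf <- file.path(dir, "md.toml")
  writeLines(c("[params]",
               sprintf("dt = %g", dt),
               sprintf("n_steps = %d", n_steps),
               sprintf("save_interval = %d", save_interval),
               sprintf("temperature = %g", temperature),
               sprintf("friction = %g", friction),
               "[system]",
               sprintf('name = "%s"', system)), mdconf)
  cfg <- file.path(dir, "input.toml")
  lines <- c('simulator = "toy"',
             sprintf('type = "%s"', type),
             sprintf("n_replica = %d", n_replica),
             sprintf("max_cycle = %d", max_cycle),
             if (!is.null(threshold)) sprintf("threshold = %g", threshold),
             sprintf("seed = %d", seed),
             sprintf('mdconf = "%s"', mdconf),
             extra)
  writeLines(lines, cfg)
  cfg
}

# random rigid transform helpers
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_structure <- function(n, scale = 1) {
  matrix(stats::rnorm(3 * n, sd = scale), n, 3)
}

# hand-rolled 3-atom PDB text (coordinates in Angstrom)
tiny_pdb <- function(path, coords_ang) {
  lines <- vapply(seq_len(nrow(coords_ang)), function(i)
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, coords_ang[i, 1], coords_ang[i, 2], coords_ang[i, 3]),
    "")
  writeLines(c(lines, "END"), path)
  path
}

# Builds a synthetic finished trial on disk with fully known contents so
# the representative-path extraction can be checked against a
# hand-assembled oracle.
build_synthetic_trial <- function(root) {
  # 3 cycles: cycle 0 one replica, cycles 1-2 two replicas each.
  # Feature = x coordinate of the single atom, maximized.
  mkframes <- function(xs) {
    arr <- array(0, dim = c(length(xs), 1, 3))
    arr[, 1, 1] <- xs
    pacs_traj(arr, template = snapshot(matrix(0, 1, 3)))
  }
  layout <- list(
    `0` = list(`0` = c(0.0, 0.3, 0.1)),
    `1` = list(`0` = c(0.3, 0.5, 0.2), `1` = c(0.3, 0.1, 0.4)),
    `2` = list(`0` = c(0.5, 0.7, 0.6), `1` = c(0.4, 0.2, 0.9)))
  for (cc in names(layout)) for (rr in names(layout[[cc]])) {
    d <- run_path(root, 1, as.integer(cc), as.integer(rr))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(mkframes(layout[[cc]][[rr]]),
                     file.path(d, "traj.dat"), "bintab")
  }
  for (cc in names(layout)) {
    rows <- do.call(rbind, lapply(names(layout[[cc]]), function(rr)
      data.frame(cycle = as.integer(cc), replica = as.integer(rr),
                 frame = seq_along(layout[[cc]][[rr]]) - 1L,
                 value = layout[[cc]][[rr]])))
    rows$rank <- rank(-rows$value, ties.method = "first")
    utils::write.csv(rows, file.path(run_path(root, 1, as.integer(cc)),
                                     "summary.csv"), row.names = FALSE)
  }
  # lineage: cycle1 seeds from cycle0 frame 1 (x=0.3) for both replicas;
  # cycle2 replica0 from (c1, r0, f1, 0.5); replica1 from (c1, r1, f2, 0.4)
  lineage <- data.frame(
    child_cycle = c(1L, 1L, 2L, 2L), child_replica = c(0L, 1L, 0L, 1L),
    parent_cycle = c(0L, 0L, 1L, 1L), parent_replica = c(0L, 0L, 0L, 1L),
    parent_frame = c(1L, 1L, 1L, 2L),
    feature_at_selection = c(0.3, 0.3, 0.5, 0.4))
  utils::write.csv(lineage, file.path(run_path(root, 1), "lineage.csv"),
                   row.names = FALSE)
  meta <- data.frame(key = c("type", "direction", "n_replica",
                             "max_cycle", "n_cycles", "stop_reason",
                             "seed", "simulator"),
                     value = c("dissociation", "maximize", "2", "2", "2",
                               "max_cycle", "1", "toy"))
  utils::write.csv(meta, file.path(run_path(root, 1), "trial_meta.csv"),
                   row.names = FALSE)
  run_path(root, 1)
}
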