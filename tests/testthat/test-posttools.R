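
test_that("genrepresent matches the hand-assembled pathway oracle", {
  root <- tempfile()
  td <- build_synthetic_trial(root)
  rp <- genrepresent(td)
  # terminal = best of final cycle: (c2, r1, f2, x = 0.9);
  # its parent chain: (c1, r1, frames 0..2) from (c0, r0, frame 1);
  # oracle concatenation of x coordinates:
  oracle_x <- c(0.0, 0.3,            # cycle 0 frames 0..1
                0.3, 0.1, 0.4,       # cycle 1 replica 1 frames 0..2
                0.4, 0.2, 0.9)       # cycle 2 replica 1 frames 0..2
  expect_equal(rp$traj$coords[, 1, 1], oracle_x, tolerance = 1e-12)
  expect_identical(rp$provenance$cycle, c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(rp$provenance$replica,
                   c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L))
  # segments join exactly at parent frames and the joint feature equals
  # the recorded feature_at_selection
  expect_equal(rp$provenance$value[2], 0.3)   # joint into cycle 1
  expect_equal(rp$provenance$value[5], 0.4)   # joint into cycle 2
  # provenance cycles never decrease
  expect_true(all(diff(rp$provenance$cycle) >= 0))

  # broken lineage is reported with the gap
  lg <- utils::read.csv(file.path(td, "lineage.csv"))
  utils::write.csv(lg[-4, ], file.path(td, "lineage.csv"),
                   row.names = FALSE)
  expect_error(genrepresent(td), "lineage")
})

test_that("genrepresent on a single-cycle trial returns the best replica", {
  root <- tempfile()
  td <- build_synthetic_trial(root)
  meta <- utils::read.csv(file.path(td, "trial_meta.csv"))
  meta$value[meta$key == "n_cycles"] <- "0"
  utils::write.csv(meta, file.path(td, "trial_meta.csv"),
                   row.names = FALSE)
  rp <- genrepresent(td)
  expect_equal(rp$traj$coords[, 1, 1], c(0.0, 0.3), tolerance = 1e-12)
})

test_that("trajectory refitting is optimal, idempotent and exact on rigid copies", {
  set.seed(40)
  base <- random_structure(8)
  ref <- snapshot(base)
  rigid <- lapply(1:4, function(i)
    snapshot(base %*% t(random_rotation()) +
               matrix(stats::rnorm(3), 8, 3, byrow = TRUE)))
  fitted <- fit_trajectory(pacs_traj(rigid), ref)
  for (i in 1:4)
    expect_equal(matrix(fitted$coords[i, , ], ncol = 3), base,
                 tolerance = 1e-10)
  # idempotence
  again <- fit_trajectory(fitted, ref)
  expect_equal(again$coords, fitted$coords, tolerance = 1e-10)
  # optimality: fitted RMSD never exceeds unfitted RMSD
  noisy <- pacs_traj(lapply(1:5, function(i)
    snapshot(base + matrix(stats::rnorm(24, sd = 0.3), 8, 3))))
  fn <- fit_trajectory(noisy, ref)
  for (i in 1:5) {
    unf <- sqrt(mean(rowSums((matrix(noisy$coords[i, , ], ncol = 3) -
                                base)^2)))
    fit <- sqrt(mean(rowSums((matrix(fn$coords[i, , ], ncol = 3) -
                                base)^2)))
    expect_lte(fit, unf + 1e-12)
  }
})

test_that("COM pseudo-trajectories hit the per-frame centers of mass", {
  arr <- array(0, dim = c(3, 2, 3))
  arr[, 2, 1] <- c(2, 4, 6)             # second atom moves along x
  traj <- pacs_traj(arr, template = snapshot(matrix(0, 2, 3)))
  g <- atom_group(1:2)
  coms <- gencom(traj, g)
  expect_equal(coms[, 1], c(1, 2, 3))   # midpoints

  f <- tempfile(fileext = ".pdb")
  gencom(traj, g, path = f)
  back <- read_trajectory(f)
  expect_identical(n_frames(back), 3L)
  expect_equal(back$coords[, 1, ], coms, tolerance = 1e-3) # PDB precision

  static <- pacs_traj(array(1, dim = c(4, 2, 3)))
  cs <- gencom(static, g)
  expect_true(all(cs == 1))
})

test_that("rmmol keeps exactly the requested atoms with values intact", {
  set.seed(41)
  arr <- array(stats::rnorm(5 * 5 * 3), dim = c(5, 5, 3))
  traj <- pacs_traj(arr, template = snapshot(matrix(0, 5, 3),
                                             masses = c(1, 2, 3, 4, 5)))
  keep <- atom_group(c(2L, 4L), masses = c(2, 4))
  red <- rmmol(traj, keep)
  expect_identical(dim(red$coords), c(5L, 2L, 3L))
  expect_identical(red$coords[, 1, ], arr[, 2, ])
  expect_identical(red$coords[, 2, ], arr[, 4, ])
  # COM of the kept group preserved exactly
  for (i in 1:5)
    expect_identical(center_of_mass(matrix(arr[i, , ], ncol = 3), keep),
                     center_of_mass(matrix(red$coords[i, , ], ncol = 3),
                                    atom_group(1:2, masses = c(2, 4))))
  # idempotent with the same (renumbered) group
  red2 <- rmmol(red, atom_group(1:2, masses = c(2, 4)))
  expect_identical(red2$coords, red$coords)
})

test_that("rmfile lists raw trajectories, spares records, refuses active trials", {
  root <- tempfile()
  td <- build_synthetic_trial(root)
  rep1 <- rmfile(td, "dry-run")
  expect_identical(nrow(rep1), 5L)                # 1 + 2 + 2 trajectories
  expect_true(all(grepl("traj\\.dat$", rep1$path)))
  expect_false(any(rep1$removed))
  expect_true(all(file.exists(rep1$path)))        # dry-run deletes nothing
  # dry-run is a pure function of the tree
  expect_identical(rmfile(td, "dry-run"), rep1)

  rep2 <- rmfile(td, "execute")
  expect_true(all(rep2$removed))
  expect_false(any(file.exists(rep2$path)))
  # records survive
  expect_true(file.exists(file.path(td, "lineage.csv")))
  expect_true(all(file.exists(file.path(run_path(root, 1, 0:2),
                                        "summary.csv"))))

  active <- run_path(tempfile(), 2)
  dir.create(active, recursive = TRUE)
  expect_error(rmfile(active, "dry-run"), "finished")
})

test_that("genfeature reproduces the run's own selection feature", {
  cfg <- load_config(write_toy_config(type = "dissociation",
                                      n_replica = 3L, max_cycle = 2L,
                                      threshold = 50, system = "lj_dimer",
                                      n_steps = 60L, friction = 5,
                                      extra = c('selection1 = "resid 1"',
                                                'selection2 = "resid 2"')))
  root <- tempfile()
  tr <- run_trial(cfg, root = root)
  td <- run_path(root, 1)
  s <- toy_system("lj_dimer")
  idx <- genfeature(td, "com_distance", group1 = atom_group(1),
                    group2 = atom_group(2), template = s$x0)
  expect_identical(nrow(idx), 7L)   # 1 + 3 + 3 replicas
  feats <- read_features(file.path(td, "features"))
  # arrays equal the ranking CSV values
  for (cc in 0:2) {
    summ <- utils::read.csv(file.path(run_path(root, 1, cc),
                                      "summary.csv"))
    for (r in unique(summ$replica)) {
      v <- summ$value[summ$replica == r][order(summ$frame[summ$replica == r])]
      got <- feats[[sprintf("c%03d_r%03d", cc, r)]]
      expect_equal(got, v, tolerance = 1e-10)
    }
  }
  # an rmsd feature against the trial's own initial frame starts at 0
  tr0 <- read_trajectory(file.path(run_path(root, 1, 0, 0), "traj.dat"),
                         template = s$x0)
  ref0 <- get_frame(tr0, 1)
  # (single-bead fit groups fall back to unfitted RMSD, exercised here
  # with the dimer's two atoms as measurement group)
  fdir <- tempfile()
  genfeature(td, function(tr) vapply(seq_len(n_frames(tr)), function(i)
    sqrt(mean(rowSums((matrix(tr$coords[i, , ], ncol = 3) -
                         ref0$coords)^2))), 0),
    output = fdir, template = s$x0)
  v00 <- read_npy(file.path(fdir, "feature_c000_r000.npy"))
  expect_equal(v00[[1]], 0, tolerance = 1e-12)

  # missing replica directory is reported by (cycle, replica)
  unlink(file.path(run_path(root, 1, 1, 2), "traj.dat"))
  expect_error(genfeature(td, "com_distance", group1 = atom_group(1),
                          group2 = atom_group(2), template = s$x0),
               "cycle 1, replica 2")
})
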