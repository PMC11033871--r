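make_values <- function(v, cycle = 0L) {
  data.frame(cycle = rep(cycle, length(v)),
             replica = seq_along(v) - 1L,
             frame = rep(0L, length(v)), value = v)
}

test_that("ranking picks the extremes with deterministic tie-breaks", {
  v <- make_values(c(0.5, 0.2, 0.9))
  sel <- rank_and_select(v, 2, "minimize")
  expect_equal(sel$value, c(0.2, 0.5))
  expect_identical(sel$rank, 1:2)

  # all equal: first three by provenance order
  v2 <- make_values(rep(1, 5))
  sel2 <- rank_and_select(v2, 3, "minimize")
  expect_identical(sel2$replica, 0:2)

  # full-sort oracle on 500 random values
  set.seed(30)
  v3 <- data.frame(cycle = 0L, replica = sample(0:9, 500, TRUE),
                   frame = sample(0:49, 500, TRUE),
                   value = stats::runif(500))
  v3 <- v3[!duplicated(v3[c("replica", "frame")]), ]
  sel3 <- rank_and_select(v3, 50, "maximize")
  oracle <- utils::head(v3[order(-v3$value, v3$replica, v3$frame), ], 50)
  expect_equal(sel3$value, oracle$value)
  expect_identical(sel3$replica, oracle$replica)

  # fewer candidates than seeds: cyclic reuse to exactly n_rep
  sel4 <- rank_and_select(make_values(c(3, 1)), 5, "minimize")
  expect_identical(nrow(sel4), 5L)
  expect_equal(sel4$value, c(1, 3, 1, 3, 1))
  expect_identical(sel4$rank, 1:5)

  expect_error(rank_and_select(make_values(numeric()), 3, "minimize"),
               "empty")

  # determinism
  expect_identical(rank_and_select(v3, 50, "maximize"), sel3)
})

test_that("selection features follow the cascade type", {
  # dissociation: feature equals the inter-COM distance, frame by frame
  nf <- 5
  arr <- array(0, dim = c(nf, 2, 3))
  for (i in seq_len(nf)) arr[i, 2, 1] <- 1 + 0.5 * (i - 1)  # 1 .. 3 nm
  traj <- pacs_traj(arr, template = snapshot(matrix(0, 2, 3),
                                             resno = c(1L, 2L)))
  spec <- structure(list(type = "dissociation",
                         group1 = atom_group(1), group2 = atom_group(2)),
                    class = "selection_spec")
  vals <- evaluate_feature(traj, spec, list(cycle = 0, replica = 0))
  expect_equal(vals$value, seq(1, 3, by = 0.5))
  expect_identical(vals$frame, 0:4)

  # target: frame identical to the reference scores 0
  set.seed(31)
  ref <- snapshot(random_structure(5))
  g <- atom_group(1:5)
  spec2 <- structure(list(type = "target", group1 = g, group2 = g,
                          group3 = g, group4 = g, reference = ref),
                     class = "selection_spec")
  t2 <- pacs_traj(list(ref, ref))
  expect_equal(evaluate_feature(t2, spec2)$value, c(0, 0),
               tolerance = 1e-12)

  # rmsd type on a rigidly rotating trajectory: superposition removes
  # the rotation, all values 0
  frames <- lapply(1:4, function(i) {
    R <- random_rotation()
    snapshot(ref$coords %*% t(R) + i)
  })
  spec3 <- spec2; spec3$type <- "rmsd"
  expect_lt(max(evaluate_feature(pacs_traj(frames), spec3)$value), 1e-10)
})

test_that("the a/d phase machine switches as its thresholds dictate", {
  cfg <- list(type = "a_d", d_threshold = 5.0, bound_threshold = 3L,
              frame_sel = 2L)
  st <- ad_state()
  expect_identical(st$phase, "dissociation")

  # reaching d_threshold switches to association
  st2 <- ad_update(st, make_values(c(4.0, 5.2)), cfg)
  expect_identical(st2$phase, "association")

  # three consecutive non-improving association cycles switch back
  st3 <- ad_update(st2, make_values(c(3.0, 3.5)), cfg)   # sets baseline
  st3 <- ad_update(st3, make_values(c(3.2, 3.4)), cfg)   # stack 1
  expect_identical(st3$stack_counter, 1L)
  st3 <- ad_update(st3, make_values(c(3.3, 3.6)), cfg)   # stack 2
  # an improving cycle resets the counter
  st4 <- ad_update(st3, make_values(c(2.5, 3.0)), cfg)
  expect_identical(st4$stack_counter, 0L)
  expect_identical(st4$phase, "association")
  # without improvement the counter runs to bound_threshold
  st5 <- st3
  st5 <- ad_update(st5, make_values(c(3.4, 3.9)), cfg)   # stack 3
  expect_identical(st5$phase, "dissociation")
  expect_identical(st5$stack_counter, 0L)

  # only the first frame_sel frames count in the association metric
  stA <- st2
  v <- data.frame(cycle = 1L, replica = 0L, frame = 0:3,
                  value = c(4, 4, 0.1, 0.1))
  stA <- ad_update(stA, v, cfg)
  expect_equal(stA$prev_metric, 4)   # frames 2,3 ignored (frame_sel = 2)

  expect_error(ad_update(st, make_values(1), list(type = "target")),
               "a_d")
})

test_that("hull-edge selection finds the extreme corners and fills up", {
  set.seed(32)
  inner <- matrix(stats::runif(200, -0.5, 0.5), 100, 2)
  corners <- rbind(c(-2, -2), c(2, -2), c(2, 2), c(-2, 2))
  feats <- rbind(inner, corners)
  prov <- data.frame(cycle = 0L, replica = 0L,
                     frame = seq_len(nrow(feats)) - 1L)
  sel <- ee_select(feats, prov, n_rep = 4, dims = 2)
  expect_setequal(sel$frame, 100:103)        # exactly the corners

  # n_rep beyond the vertex count: filled, no duplicates until exhausted
  tri <- rbind(c(0, 0), c(4, 0), c(0, 4),
               matrix(stats::runif(30, 0.5, 1.2), 15, 2))
  prov2 <- data.frame(cycle = 0L, replica = 0L,
                      frame = seq_len(nrow(tri)) - 1L)
  nv <- length(convex_hull(tri)$vertex_indices)
  sel2 <- ee_select(tri, prov2, n_rep = nv + 3, dims = 2)
  expect_identical(nrow(sel2), nv + 3L)
  expect_identical(anyDuplicated(sel2$frame), 0L)

  # the selected vertex set equals the reference hull's vertex set
  set.seed(33)
  cloud <- matrix(stats::rnorm(120), 60, 2)
  prov3 <- data.frame(cycle = 0L, replica = 0L, frame = 0:59)
  hv <- convex_hull(cloud)$vertex_indices
  sel3 <- ee_select(cloud, prov3, n_rep = length(hv), dims = 2)
  expect_setequal(sel3$frame + 1L, hv)
  # ranked by descending distance from the projected centroid
  expect_true(all(diff(sel3$value) <= 1e-12))

  expect_error(ee_select(cloud[1:2, ], prov3[1:2, ], 2), "at least")
})

test_that("user template hooks plug in as selection features", {
  hook <- tempfile(fileext = ".R")
  writeLines(c("prepare <- function(config) list()",
               "evaluate <- function(traj, context) seq_len(dim(traj$coords)[1]) - 1",
               'direction <- function() "maximize"'), hook)
  h <- template_hook(hook)
  expect_identical(h$direction, "maximize")

  s <- toy_system("double_well_1d")
  tr <- propagate(s, params = md_params(n_steps = 40, save_interval = 10,
                                        seed = 1))
  spec <- structure(list(type = "template", evaluator = h),
                    class = "selection_spec")
  vals <- evaluate_feature(tr, spec)
  expect_equal(vals$value, 0:4)   # frame index: last frame always seeds

  bad <- tempfile(fileext = ".R")
  writeLines(c("prepare <- function(config) NULL",
               'direction <- function() "minimize"'), bad)
  expect_error(template_hook(bad), "evaluate")
})

test_that("a d_com template reproduces the built-in dissociation feature", {
  hook <- tempfile(fileext = ".R")
  writeLines(c(
    "prepare <- function(config) list()",
    "evaluate <- function(traj, context) {",
    "  vapply(seq_len(dim(traj$coords)[1]), function(i)",
    "    pacsmd::com_distance(matrix(traj$coords[i, , ], ncol = 3),",
    "      pacsmd::atom_group(1), pacsmd::atom_group(2)), 0)",
    "}",
    'direction <- function() "maximize"'), hook)

  s <- toy_system("lj_dimer")
  base <- write_toy_config(type = "dissociation", n_replica = 3L,
                           max_cycle = 3L, threshold = 50,
                           system = "lj_dimer", n_steps = 100L,
                           friction = 5,
                           extra = c('selection1 = "resid 1"',
                                     'selection2 = "resid 2"'))
  cfg_d <- load_config(base)
  tmpl <- write_toy_config(type = "template", n_replica = 3L,
                           max_cycle = 3L, system = "lj_dimer",
                           n_steps = 100L, friction = 5,
                           extra = sprintf('template = "%s"', hook))
  cfg_t <- load_config(tmpl)

  t_d <- run_trial(cfg_d, root = tempfile(), system = s)
  t_t <- run_trial(cfg_t, root = tempfile(), system = s)
  expect_equal(t_t$lineage[c("parent_replica", "parent_frame")],
               t_d$lineage[c("parent_replica", "parent_frame")])
  expect_equal(t_t$lineage$feature_at_selection,
               t_d$lineage$feature_at_selection, tolerance = 1e-12)
})
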