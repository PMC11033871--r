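## Selection: the per-cycle feature evaluation, ranking, and reseeding
## decisions.  The selection feature depends on the cascade type:
##   target        RMSD to a reference, minimized (t-PaCS)
##   rmsd          RMSD from the initial structure, maximized (rmsdPaCS)
##   dissociation  inter-COM distance, maximized (dPaCS)
##   association   inter-COM distance, minimized (aPaCS)
##   a_d           alternating dissociation/association phases
##   ee            convex-hull edge expansion in PCA space
##   template      user-supplied evaluator

#' Direction in which a selection feature is optimized
#' @param type Cascade type tag.
#' @param phase For `a_d`: current phase (`"dissociation"` or
#'   `"association"`).
#' @return `"minimize"` or `"maximize"`.
#' @export
feature_direction <- function(type, phase = "dissociation") {
  switch(type,
         target = "minimize", association = "minimize",
         rmsd = "maximize", dissociation = "maximize",
         a_d = if (phase == "dissociation") "maximize" else "minimize",
         stop("no fixed direction for type ", type))
}

#' Build a selection specification from a configuration
#'
#' Resolves the selection strings against the run's structure (and the
#' reference structure, which may be indexed differently — that is what
#' `selection3`/`selection4` are for) into a reusable spec.
#'
#' @param cfg A `pacs_config`.
#' @param snap Snapshot of the simulated system (group resolution
#'   target).
#' @param reference Reference [snapshot()] for RMSD-based types.
#' @param evaluator Optional template evaluator from [template_hook()].
#' @return Object of class `selection_spec`.
#' @export
selection_spec <- function(cfg, snap, reference = NULL, evaluator = NULL) {
  type <- cfg$type
  if (type %in% c("target", "rmsd") && is.null(reference))
    stop("type \"", type, "\" requires a reference structure")
  g <- function(sel, s) if (is.null(sel)) atom_group(seq_len(n_atoms(s)),
                                                     s$masses)
  else resolve_selection(sel, s)
  spec <- list(
    type = type,
    group1 = g(cfg$selection1, snap),
    group2 = g(cfg$selection2, snap),
    reference = reference,
    evaluator = evaluator)
  if (!is.null(reference)) {
    spec$group3 <- g(cfg$selection3, reference)
    spec$group4 <- g(cfg$selection4, reference)
    if (length(spec$group3$indices) != length(spec$group1$indices) ||
        length(spec$group4$indices) != length(spec$group2$indices))
      stop("selection3/selection4 must match selection1/selection2 sizes")
  }
  structure(spec, class = "selection_spec")
}

#' Evaluate the selection feature on every frame of a trajectory
#'
#' RMSD types best-fit `selection1` onto the reference's `selection3`
#' and measure the RMSD of `selection2` against `selection4`; distance
#' types measure the distance between the centers of mass of
#' `selection1` and `selection2`.
#'
#' @param traj A [pacs_traj()].
#' @param spec A [selection_spec()].
#' @param provenance Named list (`trial`, `cycle`, `replica`) attached
#'   to each value.
#' @return Data frame with columns `cycle`, `replica`, `frame` (0-based)
#'   and `value`.
#' @export
evaluate_feature <- function(traj, spec, provenance = list()) {
  nf <- n_frames(traj)
  vals <- numeric(nf)
  if (spec$type %in% c("target", "rmsd")) {
    refc <- spec$reference$coords
    g1 <- spec$group1; g2 <- spec$group2
    g3 <- spec$group3; g4 <- spec$group4
    for (i in seq_len(nf)) {
      X <- matrix(traj$coords[i, , ], ncol = 3)
      vals[[i]] <- rmsd_mapped(X, refc, g1, g3, g2, g4)
    }
  } else if (spec$type %in% c("dissociation", "association", "a_d")) {
    for (i in seq_len(nf)) {
      X <- matrix(traj$coords[i, , ], ncol = 3)
      vals[[i]] <- com_distance(X, spec$group1, spec$group2)
    }
  } else if (spec$type == "template") {
    if (is.null(spec$evaluator))
      stop("template type requires an evaluator (see template_hook)")
    vals <- as.numeric(spec$evaluator$evaluate(traj, spec$evaluator$context))
    if (length(vals) != nf)
      stop("template evaluator returned ", length(vals),
           " values for ", nf, " frames")
  } else stop("evaluate_feature does not handle type ", spec$type)
  if (any(!is.finite(vals))) stop("non-finite feature value")
  data.frame(cycle   = provenance$cycle %||% NA_integer_,
             replica = provenance$replica %||% NA_integer_,
             frame   = seq_len(nf) - 1L,
             value   = vals)
}

## RMSD with possibly different index maps in mobile and reference:
## fit pairs (group1 -> group3), measure pairs (group2 -> group4).
## A fit group of fewer than 3 atoms cannot define a superposition; such
## systems (single particles in an external potential) are not
## translation/rotation invariant, so the RMSD is then taken unfitted.
rmsd_mapped <- function(X, refc, g1, g3, g2, g4) {
  nfit <- length(g1$indices)
  M <- rbind(X[g1$indices, , drop = FALSE], X[g2$indices, , drop = FALSE])
  R <- rbind(refc[g3$indices, , drop = FALSE],
             refc[g4$indices, , drop = FALSE])
  msr <- nfit + seq_along(g2$indices)
  if (nfit < 3L)
    return(sqrt(mean(rowSums((M[msr, , drop = FALSE] -
                                R[msr, , drop = FALSE])^2))))
  fitg <- atom_group(seq_len(nfit), g1$masses)
  msrg <- atom_group(msr, g2$masses)
  rmsd_after_fit(M, R, fit_group = fitg, rmsd_group = msrg)
}

#' Rank candidate snapshots and pick the next cycle's seeds
#'
#' Sorts by feature value (ascending when minimizing, descending when
#' maximizing), breaking ties by (cycle, replica, frame) ascending, and
#' keeps the top `n_rep`.  When fewer candidates than `n_rep` exist,
#' seeds are reused cyclically so exactly `n_rep` seeds always emerge
#' (duplicates later receive distinct velocity seeds, so their replicas
#' still diverge).
#'
#' @param values Data frame as produced by [evaluate_feature()].
#' @param n_rep Number of seeds required.
#' @param direction `"minimize"` or `"maximize"`.
#' @return Data frame of `n_rep` rows with a `rank` column (1 = best).
#' @export
rank_and_select <- function(values, n_rep,
                            direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  if (!nrow(values)) stop("empty candidate list")
  key <- if (direction == "minimize") values$value else -values$value
  ord <- order(key, values$cycle, values$replica, values$frame)
  sel <- values[ord, , drop = FALSE][seq_len(min(n_rep, nrow(values))), ,
                                     drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  if (nrow(sel) < n_rep) {
    idx <- rep(seq_len(nrow(sel)), length.out = n_rep)
    sel <- sel[idx, , drop = FALSE]
    sel$rank <- seq_len(n_rep)
  }
  rownames(sel) <- NULL
  sel
}

#' Initial state of the a/d phase machine
#' @return Object of class `ad_state`.
#' @export
ad_state <- function() {
  structure(list(phase = "dissociation", stack_counter = 0L,
                 prev_metric = NULL, best_history = numeric()),
            class = "ad_state")
}

#' Update the a/d phase machine after one cycle
#'
#' In the dissociation phase, once the cycle-best inter-COM distance
#' reaches `d_threshold` the run switches to association.  In the
#' association phase, the cycle metric is the minimum distance over the
#' first `frame_sel` frames of every replica; a cycle that does not
#' decrease it relative to the previous cycle counts as "stacked", and
#' `bound_threshold` consecutive stacked cycles switch back to
#' dissociation.
#'
#' @param state An [ad_state()].
#' @param cycle_values Feature data frame of the finished cycle.
#' @param cfg A `pacs_config` with type `a_d`.
#' @return Updated `ad_state`.
#' @export
ad_update <- function(state, cycle_values, cfg) {
  if (!identical(cfg$type, "a_d")) stop("ad_update requires type a_d")
  for (kw in c("d_threshold", "bound_threshold", "frame_sel"))
    if (is.null(cfg[[kw]])) stop("missing a_d keyword: ", kw)
  if (state$phase == "dissociation") {
    best <- max(cycle_values$value)
    state$best_history <- c(state$best_history, best)
    if (best >= cfg$d_threshold) {
      state$phase <- "association"
      state$stack_counter <- 0L
      state$prev_metric <- NULL
    }
  } else {
    early <- cycle_values[cycle_values$frame < cfg$frame_sel, , drop = FALSE]
    metric <- min(early$value)
    state$best_history <- c(state$best_history, metric)
    if (!is.null(state$prev_metric) && metric >= state$prev_metric) {
      state$stack_counter <- state$stack_counter + 1L
    } else state$stack_counter <- 0L
    state$prev_metric <- metric
    if (state$stack_counter >= cfg$bound_threshold) {
      state$phase <- "dissociation"
      state$stack_counter <- 0L
      state$prev_metric <- NULL
    }
  }
  state
}

#' Hull-edge selection for the expansion-ensemble cascade type
#'
#' Projects all accumulated snapshots onto the leading principal
#' components, takes the convex-hull vertices of the projection ranked
#' by distance from the projected centroid (farthest first), and — when
#' the hull has fewer vertices than `n_rep` — fills with the non-vertex
#' points closest to the hull boundary.
#'
#' @param features M x d matrix of accumulated snapshot features
#'   (rows align with `provenance`).
#' @param provenance Data frame with columns `cycle`, `replica`,
#'   `frame`.
#' @param n_rep Number of seeds.
#' @param dims Number of principal components (default 2).
#' @return Data frame of selected rows with a `rank` column.
#' @export
ee_select <- function(features, provenance, n_rep, dims = 2L) {
  features <- as.matrix(features)
  if (nrow(features) < dims + 1L)
    stop("need at least dims+1 accumulated snapshots")
  proj <- if (ncol(features) > dims)
    pca_project(features, dims)$scores
  else {
    sweep(features, 2, colMeans(features))
  }
  if (ncol(proj) < 2L) proj <- cbind(proj, 0)  # degenerate 1-D cloud
  hull <- tryCatch(convex_hull(proj[, 1:2, drop = FALSE]),
                   error = function(e)
                     stop("degenerate snapshot cloud: ",
                          conditionMessage(e)))
  ctr <- colMeans(proj[, 1:2, drop = FALSE])
  verts <- hull$vertex_indices
  vd <- sqrt(rowSums(sweep(proj[verts, 1:2, drop = FALSE], 2, ctr)^2))
  ord <- verts[order(-vd, provenance$cycle[verts], provenance$replica[verts],
                     provenance$frame[verts])]
  picked <- utils::head(ord, n_rep)
  if (length(picked) < n_rep) {
    rest <- setdiff(seq_len(nrow(proj)), verts)
    if (length(rest)) {
      bdist <- vapply(rest, function(i)
        dist_to_hull_boundary(proj[i, 1:2], proj[hull$facets, 1:2,
                                                 drop = FALSE]), 0)
      rest <- rest[order(bdist, provenance$cycle[rest],
                         provenance$replica[rest], provenance$frame[rest])]
      picked <- c(picked, utils::head(rest, n_rep - length(picked)))
    }
    if (length(picked) < n_rep)
      picked <- rep(picked, length.out = n_rep)
  }
  out <- provenance[picked, , drop = FALSE]
  out$value <- vapply(picked, function(i)
    sqrt(sum((proj[i, 1:2] - ctr)^2)), 0)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## minimum distance from a 2-D point to the closed polygon through `poly`
## (rows in hull vertex order)
dist_to_hull_boundary <- function(p, poly) {
  k <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(k)) {
    a <- poly[i, ]; b <- poly[if (i == k) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    dmin <- min(dmin, sqrt(sum((p - (a + t * ab))^2)))
  }
  dmin
}

#' Load a user-defined selection feature
#'
#' The hook file is an R script defining three callables: `prepare(config)
#' -> context`, `evaluate(trajectory, context) -> per-frame scalars`, and
#' `direction() -> "minimize"|"maximize"`.
#'
#' @param path Path to the R script.
#' @param cfg Optional `pacs_config` passed to `prepare`.
#' @return List with `evaluate`, `direction`, `context`.
#' @export
template_hook <- function(path, cfg = NULL) {
  if (!file.exists(path)) stop("template file not found: ", path)
  env <- new.env(parent = globalenv())
  sys.source(path, envir = env)
  for (fn in c("prepare", "evaluate", "direction"))
    if (!exists(fn, envir = env, inherits = FALSE) ||
        !is.function(get(fn, envir = env)))
      stop("template file must define function: ", fn)
  list(evaluate = get("evaluate", envir = env),
       direction = get("direction", envir = env)(),
       context = get("prepare", envir = env)(cfg))
}
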