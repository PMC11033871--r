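## Markov state model estimation from cascade-generated features:
## k-means++ discretization, sliding-window count matrices at a lag time,
## maximum-likelihood (or symmetrized, detailed-balance) transition
## matrices on the largest strongly connected state set, stationary
## distributions and implied timescales.
##
## Counting never crosses replica boundaries: cascade reseeding makes the
## set of segments disconnected in phase space, so each segment
## contributes its own (t, t+lag) pairs only.

#' k-means clustering with k-means++ initialization
#'
#' k++ seeding (first center uniform, subsequent centers with
#' probability proportional to the squared distance to the nearest
#' chosen center) followed by Lloyd iterations until the maximum center
#' shift drops below `tol` or `max_iter` is reached.  A center left
#' empty during Lloyd is reseeded on the point farthest from its
#' assigned center, so every returned center is non-empty.
#'
#' @param data M x d matrix (a vector is treated as M x 1).
#' @param k Number of clusters (1 <= k <= M).
#' @param seed RNG seed (deterministic output for a given seed).
#' @param max_iter,tol Lloyd convergence controls.
#' @return List with `centers` (k x d), `assignments` (length M,
#'   1-based) and `iterations`.
#' @export
kmeans_pp <- function(data, k, seed = 1L, max_iter = 500L, tol = 1e-8) {
  data <- as.matrix(data)
  M <- nrow(data)
  if (k > M) stop("k exceeds the number of points")
  set.seed(seed)
  ## k++ seeding
  centers <- data[sample.int(M, 1L), , drop = FALSE]
  if (k > 1L) {
    d2 <- rowSums(sweep(data, 2, centers[1L, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / M, M)
      nxt <- sample.int(M, 1L, prob = p)
      centers <- rbind(centers, data[nxt, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(data, 2, centers[j, ])^2))
    }
  }
  assign_to <- function(ctr) {
    cross <- data %*% t(ctr)
    d <- outer(rowSums(data^2), rowSums(ctr^2), "+") - 2 * cross
    max.col(-d, ties.method = "first")
  }
  it <- 0L
  repeat {
    it <- it + 1L
    lab <- assign_to(centers)
    newc <- centers
    for (j in seq_len(k)) {
      idx <- which(lab == j)
      if (!length(idx)) {          # reseed empty cluster
        far <- which.max(rowSums((data - centers[lab, , drop = FALSE])^2))
        newc[j, ] <- data[far, ]
      } else newc[j, ] <- colMeans(data[idx, , drop = FALSE])
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol || it >= max_iter) break
  }
  list(centers = centers, assignments = assign_to(centers),
       iterations = it)
}

#' Sliding-window transition count matrix
#'
#' `C[i, j]` counts the (t, t + lag) state pairs within each discrete
#' trajectory; pairs are never formed across trajectory boundaries.
#'
#' @param dtrajs List of integer state sequences (1-based states), or a
#'   single vector.
#' @param lag Lag time in frames (>= 1).
#' @param n_states Number of states (default: maximum observed).
#' @return k x k count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  n_states <- n_states %||% max(unlist(dtrajs))
  C <- matrix(0, n_states, n_states)
  any_pairs <- FALSE
  for (dt in dtrajs) {
    Tn <- length(dt)
    if (Tn <= lag) next
    any_pairs <- TRUE
    from <- dt[seq_len(Tn - lag)]
    to <- dt[seq_len(Tn - lag) + lag]
    for (i in seq_along(from))
      C[from[[i]], to[[i]]] <- C[from[[i]], to[[i]]] + 1
  }
  if (!any_pairs) stop("all trajectories are shorter than the lag")
  C
}

#' Transition matrix on the largest strongly connected state set
#'
#' `mle` row-normalizes the raw counts; `symmetrized` row-normalizes
#' `(C + t(C)) / 2`, which satisfies detailed balance with its own
#' stationary distribution.  States outside the largest strongly
#' connected component of the count graph are dropped; the returned
#' `states` maps rows of `T` back to the original state indices.
#'
#' @param C Count matrix.
#' @param estimator `"mle"` or `"symmetrized"`.
#' @return List with `T` (row-stochastic) and `states` (original
#'   indices of the retained states).
#' @export
transition_matrix <- function(C, estimator = c("mle", "symmetrized")) {
  estimator <- match.arg(estimator)
  if (any(C < 0)) stop("negative counts")
  if (estimator == "symmetrized") C <- (C + t(C)) / 2
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  keep <- which(comp$membership == which.max(sizes))
  if (!length(keep)) stop("empty connected set")
  Cs <- C[keep, keep, drop = FALSE]
  rs <- rowSums(Cs)
  if (any(rs == 0)) stop("zero-row state inside the connected set")
  list(T = Cs / rs, states = keep)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum 1.
#'
#' @param T Irreducible row-stochastic matrix.
#' @return Probability vector.
#' @export
stationary_distribution <- function(T) {
  if (any(abs(rowSums(T) - 1) > 1e-8)) stop("rows of T must sum to 1")
  eg <- eigen(t(T))
  i1 <- which.min(abs(eg$values - 1))
  if (sum(abs(eg$values - 1) < 1e-10) > 1L)
    stop("transition matrix appears reducible")
  pi <- Re(eg$vectors[, i1])
  pi <- pi / sum(pi)
  if (any(pi < -1e-12)) stop("negative stationary probability")
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Implied relaxation timescales
#'
#' t_i = -lag / ln |lambda_(i+1)| for the eigenvalue spectrum sorted by
#' modulus (the stationary eigenvalue is excluded).  Complex eigenvalues
#' are reported by modulus with a warning; eigenvalues at or above 1
#' give +Inf.
#'
#' @param T Row-stochastic matrix.
#' @param lag Lag time (frames, or any time unit — the timescales come
#'   back in the same unit).
#' @param n Number of timescales.
#' @return Numeric vector of length `n`.
#' @export
implied_timescales <- function(T, lag, n = 1L) {
  ev <- eigen(T, only.values = TRUE)$values
  ev <- ev[order(-abs(ev))][-1L]      # drop the stationary eigenvalue
  if (n > length(ev)) stop("n exceeds the available eigenvalues")
  ev <- ev[seq_len(n)]
  if (any(abs(Im(ev)) > 1e-12))
    warning("complex eigenvalues: timescales reported by modulus")
  lam <- abs(ev)
  ifelse(lam >= 1, Inf, -lag / log(lam))
}

#' Restrict feature segments to a value range for model building
#'
#' Frames outside `[min_value, max_value]` are removed and each segment
#' is split at the removals, so lagged transition pairs are never formed
#' across an excluded frame.  This mirrors the common practice of
#' clustering only snapshots below a distance cutoff (e.g. excluding the
#' region where a restraining wall, not the molecular interaction,
#' shapes the distribution).
#'
#' @param features List of numeric vectors.
#' @param max_value,min_value Inclusive bounds.
#' @return List of numeric vectors (possibly more, shorter segments).
#' @export
clip_features <- function(features, max_value = Inf, min_value = -Inf) {
  out <- list()
  for (f in features) {
    ok <- f >= min_value & f <= max_value
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values))
      out <- c(out, list(f[starts[[i]]:ends[[i]]]))
  }
  out
}

#' Build a Markov state model from feature trajectories
#'
#' Pools the feature segments, discretizes them with [kmeans_pp()],
#' counts transitions at the given lag within segments only, estimates
#' the transition matrix on the largest connected set and derives the
#' stationary distribution and implied timescales.
#'
#' @param features List of per-replica numeric vectors (1-D features) or
#'   matrices (rows = frames), e.g. from [read_features()].
#' @param k Number of microstates.
#' @param lag Lag time in frames.
#' @param seed Clustering seed.
#' @param temperature Temperature (K), carried for free-energy
#'   conversion.
#' @param estimator Passed to [transition_matrix()].
#' @param n_timescales Number of implied timescales to report.
#' @return Object of class `markov_model` with fields `centers`,
#'   `dtrajs`, `lag`, `C`, `T`, `pi`, `states`, `timescales`,
#'   `temperature`.
#' @export
markov_model <- function(features, k, lag, seed = 1L, temperature = 300,
                         estimator = "mle", n_timescales = 2L) {
  if (!is.list(features)) features <- list(features)
  mats <- lapply(features, function(f) if (is.matrix(f)) f
                 else matrix(f, ncol = 1))
  pooled <- do.call(rbind, mats)
  km <- kmeans_pp(pooled, k, seed = seed)
  ## relabel so 1-D centers are in ascending order
  ord <- if (ncol(pooled) == 1L) order(km$centers[, 1]) else seq_len(k)
  relab <- match(seq_len(k), ord)
  centers <- km$centers[ord, , drop = FALSE]
  lab <- relab[km$assignments]
  lens <- vapply(mats, nrow, 0L)
  ends <- cumsum(lens)
  dtrajs <- lapply(seq_along(mats), function(i)
    lab[(ends[[i]] - lens[[i]] + 1L):ends[[i]]])
  C <- count_matrix(dtrajs, lag, n_states = k)
  tm <- transition_matrix(C, estimator)
  pi <- stationary_distribution(tm$T)
  its <- implied_timescales(tm$T, lag,
                            min(n_timescales, nrow(tm$T) - 1L))
  structure(list(centers = centers, dtrajs = dtrajs, lag = lag, C = C,
                 T = tm$T, states = tm$states, pi = pi,
                 timescales = its, temperature = temperature,
                 estimator = estimator), class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf(
    "Markov state model: %d/%d connected states, lag %g frame(s), %s estimator\n",
    length(x$states), nrow(x$centers), x$lag, x$estimator))
  cat(sprintf("  slowest implied timescale: %.3g frames\n",
              x$timescales[[1]]))
  invisible(x)
}

#' @export
summary.markov_model <- function(object, ...) {
  print(object)
  cat(sprintf("  %d segments, %d frames total\n", length(object$dtrajs),
              sum(lengths(object$dtrajs))))
  cat("  stationary distribution range: ",
      sprintf("%.3g .. %.3g\n", min(object$pi), max(object$pi)))
  invisible(object)
}
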