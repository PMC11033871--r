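## Convex hulls in 2 and 3 dimensions.  The 3-D hull is an incremental
## construction (quickhull family): seed tetrahedron, then insert each
## remaining point by deleting its visible facets and re-triangulating the
## horizon.  Hull volume of the sampled unbound region is what converts a
## PMF depth into a standard binding free energy.

#' Convex hull of a 2-D or 3-D point cloud
#'
#' @param points M x d matrix, d in {2, 3}, with at least d+1 affinely
#'   independent rows.
#' @return Object of class `pacs_hull` with `vertex_indices` (row indices
#'   of hull vertices), `volume` (area for d = 2, volume for d = 3),
#'   `facets` (matrix of vertex index triples for d = 3, ordered vertex
#'   cycle for d = 2) and `dim`.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (!d %in% c(2L, 3L)) stop("convex_hull supports d = 2 or 3")
  if (nrow(points) < d + 1L) stop("need at least d+1 points")
  if (d == 2L) hull2d(points) else hull3d(points)
}

#' @export
print.pacs_hull <- function(x, ...) {
  cat(sprintf("convex hull (%dD): %d vertices, %s = %g\n", x$dim,
              length(x$vertex_indices),
              if (x$dim == 2L) "area" else "volume", x$volume))
  invisible(x)
}

hull2d <- function(points) {
  idx <- grDevices::chull(points[, 1], points[, 2])  # counter-clockwise
  if (length(idx) < 3L) stop("degenerate input: points are collinear")
  x <- points[idx, 1]; y <- points[idx, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= 0) stop("degenerate input: zero-area hull")
  structure(list(vertex_indices = idx, volume = area, facets = idx,
                 dim = 2L), class = "pacs_hull")
}

hull3d <- function(points) {
  n <- nrow(points)
  scale <- max(apply(points, 2, function(v) diff(range(v))), 1e-12)
  eps <- 1e-10 * scale

  ## seed tetrahedron: extreme pair, then max-area, then max-volume point
  i1 <- which.max(points[, 1]); i2 <- which.min(points[, 1])
  if (i1 == i2) i2 <- if (i1 == 1L) 2L else 1L
  e <- points[i2, ] - points[i1, ]
  areas <- apply(points, 1, function(p) sum(cross3(e, p - points[i1, ])^2))
  i3 <- which.max(areas)
  if (sqrt(areas[[i3]]) < eps * scale)
    stop("degenerate input: points are collinear")
  nrm <- cross3(e, points[i3, ] - points[i1, ])
  vols <- abs(as.vector((points - matrix(points[i1, ], n, 3, byrow = TRUE))
                        %*% nrm))
  i4 <- which.max(vols)
  if (vols[[i4]] < eps * scale^2)
    stop("degenerate input: points are coplanar")

  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(points[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, points = points,
                   inside = centroid))

  for (p in setdiff(seq_len(n), verts)) {
    vis <- apply(faces, 1, function(f) {
      nrm <- face_normal(points, f)
      sum(nrm * (points[p, ] - points[f[[1]], ])) > eps
    })
    if (!any(vis)) next                       # interior or on hull
    ## horizon = edges shared by exactly one visible facet
    edges <- do.call(rbind, lapply(which(vis), function(i) {
      f <- faces[i, ]
      rbind(sort(f[c(1, 2)]), sort(f[c(2, 3)]), sort(f[c(1, 3)]))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    inside <- colMeans(points[unique(as.integer(faces)), , drop = FALSE])
    newf <- t(apply(horizon, 1, function(ed)
      orient_face(c(ed[[1]], ed[[2]], p), points, inside)))
    faces <- rbind(faces, newf)
  }

  vi <- sort(unique(as.integer(faces)))
  o <- colMeans(points[vi, , drop = FALSE])
  vol <- sum(apply(faces, 1, function(f) {
    a <- points[f[[1]], ] - o; b <- points[f[[2]], ] - o
    cc <- points[f[[3]], ] - o
    sum(a * cross3(b, cc)) / 6
  }))
  structure(list(vertex_indices = vi, volume = abs(vol), facets = faces,
                 dim = 3L), class = "pacs_hull")
}

cross3 <- function(a, b) {
  c(a[[2]] * b[[3]] - a[[3]] * b[[2]],
    a[[3]] * b[[1]] - a[[1]] * b[[3]],
    a[[1]] * b[[2]] - a[[2]] * b[[1]])
}

face_normal <- function(points, f) {
  cross3(points[f[[2]], ] - points[f[[1]], ],
         points[f[[3]], ] - points[f[[1]], ])
}

## flip vertex order so the normal points away from an interior point
orient_face <- function(f, points, inside) {
  nrm <- face_normal(points, f)
  if (sum(nrm * (inside - points[f[[1]], ])) > 0) f[c(1, 3, 2)] else f
}

#' Test whether points lie inside or on a 3-D hull
#'
#' @param hull A `pacs_hull` with `dim == 3`.
#' @param hull_points The point matrix the hull was built from.
#' @param query M x 3 matrix of query points.
#' @param tol Slack on the facet half-space test.
#' @return Logical vector.
#' @export
hull_contains <- function(hull, hull_points, query, tol = 1e-9) {
  query <- matrix(query, ncol = 3)
  apply(query, 1, function(q) {
    all(apply(hull$facets, 1, function(f) {
      nrm <- face_normal(hull_points, f)
      sum(nrm * (q - hull_points[f[[1]], ])) <=
        tol * sqrt(sum(nrm^2)) + 1e-300
    }))
  })
}
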