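test_that("centers of mass and inter-COM distances match direct sums", {
  co <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(co, atom_group(1:2)), c(1, 0, 0))
  co2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(center_of_mass(co2, atom_group(1:2, masses = c(1, 3))),
               c(3, 0, 0))

  # 3-4-5 triangle
  co3 <- rbind(c(1, 0, 0), c(4, 4, 0))
  expect_equal(com_distance(co3, atom_group(1), atom_group(2)), 5)
  expect_equal(com_distance(co3, atom_group(1), atom_group(1)), 0)

  # brute-force oracle on random weighted groups
  set.seed(10)
  for (i in 1:10) {
    co <- random_structure(20)
    m <- stats::runif(20, 0.5, 40)
    g <- atom_group(sample(20, 8), masses = m[1:8])
    oracle <- colSums(co[g$indices, ] * g$masses) / sum(g$masses)
    expect_equal(center_of_mass(co, g), oracle, tolerance = 1e-12)
    g2 <- atom_group(sample(20, 5))
    oracle_d <- sqrt(sum((center_of_mass(co, g) -
                            center_of_mass(co, g2))^2))
    expect_equal(com_distance(co, g, g2), oracle_d, tolerance = 1e-12)
    expect_equal(com_distance(co, g2, g), com_distance(co, g, g2))
  }
  expect_error(atom_group(integer()), "empty")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(11)
  X <- random_structure(12)
  idt <- superpose(X, X)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-10)
  expect_equal(idt$translation, c(0, 0, 0), tolerance = 1e-10)

  # 90-degree rotation about z plus a shift is recovered exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- X %*% t(Rz) + matrix(c(1, 2, 3), 12, 3, byrow = TRUE)
  expect_equal(rmsd_after_fit(Y, X), 0, tolerance = 1e-10)
  tr <- superpose(Y, X)
  expect_equal(tr$rotation %*% Rz, diag(3), tolerance = 1e-10)

  expect_error(superpose(X, X, atom_group(1:2)), "degenerate")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(coll, coll + 1), "collinear|degenerate")
})

test_that("fitted RMSD of noisy rotated copies beats an optimizer oracle", {
  # independent oracle: direct minimization of the residual over Euler
  # angles + translation, multi-start
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
             sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
             -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
  }
  set.seed(12)
  for (rep in 1:3) {
    X <- random_structure(10)
    Y <- (X + matrix(stats::rnorm(30, sd = 0.01), 10, 3)) %*%
      t(random_rotation()) + matrix(stats::rnorm(3), 10, 3, byrow = TRUE)
    got <- rmsd_after_fit(Y, X)
    obj <- function(p) {
      fit <- Y %*% t(euler(p[1:3])) +
        matrix(p[4:6], 10, 3, byrow = TRUE)
      sqrt(mean(rowSums((fit - X)^2)))
    }
    oracle <- min(vapply(1:8, function(s) {
      set.seed(100 + s)
      stats::optim(c(stats::runif(3, -pi, pi), stats::rnorm(3)), obj,
                   method = "BFGS",
                   control = list(maxit = 500))$value
    }, 0))
    expect_lte(got, oracle + 1e-6)   # Kabsch is the global optimum
    expect_gte(got, oracle - 1e-6)
  }
})

test_that("fitted RMSD is symmetric and rigid-transform invariant", {
  set.seed(13)
  for (i in 1:5) {
    X <- random_structure(8)
    Y <- random_structure(8)
    expect_equal(rmsd_after_fit(X, Y), rmsd_after_fit(Y, X),
                 tolerance = 1e-10)
    R <- random_rotation(); tr <- stats::rnorm(3)
    Xr <- X %*% t(R) + matrix(tr, 8, 3, byrow = TRUE)
    expect_equal(rmsd_after_fit(Xr, Y), rmsd_after_fit(X, Y),
                 tolerance = 1e-10)
  }
})

test_that("superposition never returns an improper rotation", {
  set.seed(14)
  for (i in 1:10) {
    X <- random_structure(6)
    Y <- X; Y[, 1] <- -Y[, 1]           # mirror image
    tr <- superpose(Y, X)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
    tr2 <- superpose(random_structure(6), random_structure(6))
    expect_equal(det(tr2$rotation), 1, tolerance = 1e-10)
  }
})

test_that("fit and measurement groups can differ", {
  set.seed(15)
  X <- random_structure(10)
  Y <- X
  Y[9:10, ] <- Y[9:10, ] + matrix(c(0.5, 0, 0), 2, 3, byrow = TRUE)
  gA <- atom_group(1:8); gB <- atom_group(9:10)
  # fit on A is exact there, so the B residual is the hand-computed shift
  expect_equal(rmsd_after_fit(Y, X, gA, gB), 0.5, tolerance = 1e-10)
  expect_equal(rmsd_after_fit(Y, X, gA, gA), 0, tolerance = 1e-10)
})

test_that("PCA projection recovers axes, variances and reconstruction", {
  # points on a line: first axis parallel, residual variance 0
  t <- seq(-1, 1, length.out = 30)
  dirv <- c(2, 1, 2) / 3
  line <- outer(t, dirv)
  p <- pca_project(line + 1, n_components = 1)
  expect_equal(abs(sum(p$axes[1, ] * dirv)), 1, tolerance = 1e-10)

  set.seed(16)
  cloud <- matrix(stats::rnorm(3000), 1000, 3)
  p3 <- pca_project(cloud, 3)
  expect_lt(max(p3$variances) / min(p3$variances), 1.3) # isotropic
  # completeness: full reconstruction
  rec <- p3$scores %*% p3$axes
  rec <- sweep(rec, 2, -colMeans(cloud))
  expect_equal(rec, cloud, tolerance = 1e-10)
  # eigen-oracle: variances are the covariance eigenvalues
  expect_equal(sort(p3$variances), sort(eigen(stats::cov(cloud))$values),
               tolerance = 1e-10)

  expect_error(pca_project(line, 2), "rank")
})

test_that("selection strings resolve residues, names and indices", {
  snap <- snapshot(random_structure(6),
                   names = c("CA", "CB", "CA", "CB", "CA", "CB"),
                   resno = c(1, 1, 2, 2, 3, 3))
  expect_identical(resolve_selection("resid 1-2 and name CA", snap)$indices,
                   c(1L, 3L))
  expect_identical(resolve_selection("all", snap)$indices, 1:6)
  expect_identical(resolve_selection("index 2,5-6", snap)$indices,
                   c(2L, 5L, 6L))
  expect_error(resolve_selection("resid 99", snap), "no atoms")
  expect_error(resolve_selection("chain A", snap), "unknown")
})
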