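## Langevin dynamics (BAOAB splitting), Maxwell-Boltzmann velocity
## reinitialization, and the dynamics-backend contract.

#' Integration parameters for the toy backend
#'
#' @param dt Time step (ps).
#' @param n_steps Number of integration steps.
#' @param save_interval Save every this many steps (frame 0 is the
#'   initial state, so a run yields `n_steps / save_interval + 1`
#'   frames).
#' @param temperature Thermostat temperature (K).
#' @param friction Langevin friction (1/ps); 0 gives microcanonical
#'   velocity-Verlet dynamics.
#' @param seed RNG seed for the thermostat noise.
#' @return Object of class `md_params`.
#' @export
md_params <- function(dt = 0.01, n_steps = 200L, save_interval = 5L,
                      temperature = 300, friction = 1.0, seed = 1L) {
  stopifnot(dt > 0, n_steps >= 0, save_interval >= 1,
            n_steps %% save_interval == 0 || n_steps == 0,
            temperature >= 0, friction >= 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed)), class = "md_params")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws each velocity component independently from
#' Normal(0, sqrt(kB T / m_i)); this is the velocity reinitialization
#' applied to every replica at the start of each cascade cycle, which
#' decorrelates branches grown from the same parent snapshot.
#'
#' @param masses Per-atom masses (g/mol).
#' @param temperature Temperature (K).
#' @param seed RNG seed (deterministic output for a given seed).
#' @return N x 3 matrix of velocities (nm/ps).
#' @export
mb_velocities <- function(masses, temperature, seed) {
  if (any(masses <= 0)) stop("masses must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  set.seed(seed)
  n <- length(masses)
  sd <- sqrt(kBT(temperature) / masses)
  matrix(stats::rnorm(3L * n), n, 3) * sd
}

#' Propagate a toy system with underdamped Langevin dynamics
#'
#' BAOAB splitting: half kick, half drift, exact Ornstein-Uhlenbeck
#' velocity update, half drift, half kick.  With `friction = 0` the
#' scheme reduces to velocity Verlet and conserves energy.
#'
#' @param system A [toy_system()].
#' @param x0 N x 3 initial coordinates (nm); defaults to the system's
#'   initial snapshot.
#' @param v0 N x 3 initial velocities (nm/ps); defaults to zero.
#' @param params An [md_params()].
#' @return A [pacs_traj()] with `params$n_steps / params$save_interval +
#'   1` frames, frame 1 being the initial state.
#' @export
propagate <- function(system, x0 = NULL, v0 = NULL, params = md_params()) {
  if (is.null(x0)) x0 <- system$x0$coords
  x <- matrix(as.numeric(x0), ncol = 3)
  n <- nrow(x)
  if (n != length(system$masses))
    stop("x0 shape does not match the system")
  v <- if (is.null(v0)) matrix(0, n, 3) else matrix(as.numeric(v0), ncol = 3)
  m <- system$masses
  dt <- params$dt
  nf <- params$n_steps %/% params$save_interval
  frames <- array(0, dim = c(nf + 1L, n, 3))
  frames[1, , ] <- x
  if (params$n_steps == 0L)
    return(pacs_traj(frames, template = system$x0))

  c1 <- exp(-params$friction * dt)
  c2 <- sqrt((1 - c1^2) * kBT(params$temperature) / m)   # per-atom sd
  set.seed(params$seed)
  noise <- if (params$friction > 0 && params$temperature > 0)
    array(stats::rnorm(params$n_steps * n * 3L),
          dim = c(params$n_steps, n, 3))
  else NULL

  f <- -system$gradient(x)
  for (s in seq_len(params$n_steps)) {
    v <- v + (0.5 * dt) * f / m
    x <- x + (0.5 * dt) * v
    if (!is.null(noise))
      v <- c1 * v + c2 * matrix(noise[s, , ], n, 3)
    else v <- c1 * v
    x <- x + (0.5 * dt) * v
    f <- -system$gradient(x)
    if (!all(is.finite(f)))
      stop("integration failure (non-finite force) at step ", s)
    v <- v + (0.5 * dt) * f / m
    if (s %% params$save_interval == 0L)
      frames[s %/% params$save_interval + 1L, , ] <- x
  }
  pacs_traj(frames, template = system$x0)
}

## ---- backend contract -----------------------------------------------------
## A backend is a function (seed_snapshot, velocities, params, workdir,
## context) -> pacs_traj.  The engine writes the returned trajectory to
## disk under the run layout.  The toy backend fulfils the contract
## natively; `mock` replays canned frames (stands in for an external MD
## engine in tests); external engines would be registered the same way.

backend_registry <- new.env(parent = emptyenv())

#' Register a dynamics backend
#' @param name Backend tag (matched against the `simulator` keyword).
#' @param fn Function `(seed_snapshot, velocities, params, workdir,
#'   context) -> pacs_traj`.
#' @export
register_backend <- function(name, fn) {
  assign(name, fn, envir = backend_registry)
  invisible(name)
}

#' Run one replica through a registered backend
#'
#' @param backend Backend tag.
#' @param seed_structure A [snapshot()] providing the initial
#'   coordinates.
#' @param velocities N x 3 initial velocities.
#' @param params An [md_params()].
#' @param workdir Replica directory; the trajectory is written there as
#'   `traj.dat` (binary table).
#' @param context Backend-specific context (for `"toy"`: list with
#'   element `system`; for `"mock"`: list with element `frames`, a
#'   `pacs_traj`).
#' @return Path of the written trajectory file.
#' @export
backend_run <- function(backend, seed_structure, velocities, params,
                        workdir, context = list()) {
  if (!exists(backend, envir = backend_registry))
    stop("unknown backend \"", backend, "\"; registered: ",
         paste(ls(backend_registry), collapse = ", "))
  fn <- get(backend, envir = backend_registry)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  traj <- fn(seed_structure, velocities, params, workdir, context)
  path <- file.path(workdir, "traj.dat")
  write_trajectory(traj, path, "bintab")
  path
}

toy_backend <- function(seed_structure, velocities, params, workdir,
                        context) {
  if (is.null(context$system)) stop("toy backend needs context$system")
  propagate(context$system, x0 = seed_structure$coords, v0 = velocities,
            params = params)
}

mock_backend <- function(seed_structure, velocities, params, workdir,
                         context) {
  if (is.null(context$frames)) stop("mock backend needs context$frames")
  context$frames
}

#' Derive a child RNG seed for a (cycle, replica) pair
#'
#' Documented splitting function: repeated multiply-and-add modulo a
#' Mersenne prime, so every (root, cycle, replica, stream) combination
#' maps to a distinct, reproducible seed below 2^31.
#'
#' @param root Root seed of the trial.
#' @param cycle,replica 0-based indices.
#' @param stream Sub-stream tag (0 = velocity draw, 1 = thermostat
#'   noise).
#' @return Integer seed in `[1, 2147483628]`.
#' @export
child_seed <- function(root, cycle, replica, stream = 0L) {
  h <- 17
  for (v in c(root, cycle, replica, stream))
    h <- (h * 1000003 + (v + 40503)) %% 2147483629
  as.integer(h + 1)
}

#' Read toy-backend run parameters from an mdconf TOML file
#'
#' The `mdconf` keyword of the configuration names a TOML file with a
#' `[params]` table ([md_params()] fields) and, for the toy backend, a
#' `[system]` table (`name` plus parameter overrides).
#'
#' @param path Path to the mdconf file.
#' @return List with `params` (an [md_params()]) and `system` (a
#'   [toy_system()] or NULL).
#' @export
read_mdconf <- function(path) {
  raw <- parse_toml(path)
  take <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(raw), value = TRUE)
    stats::setNames(raw[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  p <- take("params")
  params <- do.call(md_params, p[names(p) %in% names(formals(md_params))])
  sysspec <- take("system")
  system <- NULL
  if (!is.null(sysspec$name)) {
    nm <- sysspec$name
    sysspec$name <- NULL
    system <- do.call(toy_system, c(list(name = nm), sysspec))
  }
  list(params = params, system = system)
}
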