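## Run configuration: a flat TOML file using the canonical PaCS-MD keyword
## set (simulator, type, n_replica, max_cycle, threshold, d_threshold,
## bound_threshold, frame_sel, selection1..4, reference, analyzer, mdconf).

PACS_TYPES <- c("target", "rmsd", "dissociation", "association",
                "a_d", "ee", "template")

## Keywords consumed by the toolkit itself.  Anything else in the file is
## reported with a warning (backend-specific keys are tolerated, never
## silently dropped).
PACS_KEYWORDS <- c("simulator", "type", "n_replica", "max_cycle",
                   "threshold", "d_threshold", "bound_threshold",
                   "frame_sel", "selection1", "selection2", "selection3",
                   "selection4", "reference", "analyzer", "mdconf",
                   "trial", "seed", "initial", "template")

#' Parse a flat TOML document
#'
#' Minimal TOML-dialect reader covering what a run configuration needs:
#' `key = value` pairs with string, integer, float and boolean scalars,
#' `#` comments, and `[table]` headers (keys inside a table are returned
#' as `table.key`).  Arrays and multi-line strings are not supported.
#'
#' @param path Path to the file.
#' @return Named list of scalar values.
#' @export
parse_toml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  prefix <- ""
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    ## strip comments outside quoted strings
    ln <- sub('^([^"#]*("[^"]*"[^"#]*)*)#.*$', "\\1", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      prefix <- paste0(gsub("^\\[|\\]$", "", ln), ".")
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed line ", i, " in ", path, ": ", ln)
    key <- paste0(prefix, m[[2]])
    raw <- trimws(m[[3]])
    out[[key]] <-
      if (grepl('^".*"$', raw) || grepl("^'.*'$", raw)) {
        substr(raw, 2L, nchar(raw) - 1L)
      } else if (raw %in% c("true", "false")) {
        raw == "true"
      } else if (grepl("^[+-]?[0-9]+$", raw)) {
        as.integer(raw)
      } else {
        val <- suppressWarnings(as.numeric(raw))
        if (is.na(val)) stop("unparseable value on line ", i, " of ",
                             path, ": ", raw)
        val
      }
  }
  out
}

#' Load and validate a PaCS-MD run configuration
#'
#' Reads a TOML configuration file, validates the keyword set, applies the
#' documented defaults (`selection3 <- selection1`, `selection4 <-
#' selection2` when absent) and returns an immutable `pacs_config`.
#'
#' Mandatory keywords are `type`, `n_replica` and `simulator`.  `type`
#' must be one of `r paste(PACS_TYPES, collapse = ", ")`.  `threshold`
#' (nm) stops the run when the selection feature crosses it; the `ee`
#' and `a_d` types ignore it and stop only at `max_cycle`.  The `a_d`
#' type additionally requires `d_threshold` (nm, dissociation-phase
#' target), `bound_threshold` (cycles of stacked association movements
#' before switching back) and `frame_sel` (number of first frames judged
#' for stacking).
#'
#' @param path Path to the TOML configuration file.
#' @return Object of class `pacs_config`: a named list of validated
#'   settings.
#' @examples
#' cfg_file <- tempfile(fileext = ".toml")
#' writeLines(c('simulator = "toy"', 'type = "dissociation"',
#'              "n_replica = 5", "max_cycle = 10", "threshold = 3.0",
#'              'selection1 = "resid 1"', 'selection2 = "resid 2"'),
#'            cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$n_replica
#' @export
load_config <- function(path) {
  raw <- parse_toml(path)
  unknown <- setdiff(names(raw), PACS_KEYWORDS)
  ## tolerate table-qualified backend keys quietly, warn on bare unknowns
  unknown <- unknown[!grepl("\\.", unknown)]
  if (length(unknown))
    warning("unknown configuration keyword(s) ignored: ",
            paste(unknown, collapse = ", "))

  for (kw in c("type", "n_replica", "simulator"))
    if (is.null(raw[[kw]]))
      stop("missing mandatory keyword: ", kw)
  if (!raw$type %in% PACS_TYPES)
    stop("unknown type \"", raw$type, "\"; must be one of: ",
         paste(PACS_TYPES, collapse = ", "))

  cfg <- list(
    simulator  = raw$simulator,
    type       = raw$type,
    n_replica  = as.integer(raw$n_replica),
    max_cycle  = as.integer(raw$max_cycle %||% 1L),
    threshold  = raw$threshold,
    d_threshold     = raw$d_threshold,
    bound_threshold = if (!is.null(raw$bound_threshold))
      as.integer(raw$bound_threshold),
    frame_sel  = if (!is.null(raw$frame_sel)) as.integer(raw$frame_sel),
    selection1 = raw$selection1,
    selection2 = raw$selection2,
    selection3 = raw$selection3 %||% raw$selection1,
    selection4 = raw$selection4 %||% raw$selection2,
    reference  = raw$reference,
    analyzer   = raw$analyzer %||% "internal",
    mdconf     = raw$mdconf,
    trial      = as.integer(raw$trial %||% 1L),
    seed       = as.integer(raw$seed %||% 1L),
    initial    = raw$initial,
    template   = raw$template,
    extra      = raw[grepl("\\.", names(raw))]
  )

  if (cfg$n_replica < 1L) stop("n_replica must be >= 1")
  if (cfg$max_cycle < 1L) stop("max_cycle must be >= 1")
  if (!is.null(cfg$threshold) && cfg$threshold <= 0)
    stop("threshold must be > 0 when present")
  if (cfg$trial < 1L) stop("trial must be >= 1")
  if (cfg$type == "a_d")
    for (kw in c("d_threshold", "bound_threshold", "frame_sel"))
      if (is.null(cfg[[kw]]))
        stop("type \"a_d\" requires keyword: ", kw)

  structure(cfg, class = "pacs_config")
}

#' @export
print.pacs_config <- function(x, ...) {
  cat("PaCS-MD configuration\n")
  cat(sprintf("  simulator: %s   type: %s   analyzer: %s\n",
              x$simulator, x$type, x$analyzer))
  cat(sprintf("  n_replica: %d   max_cycle: %d   trial: %d   seed: %d\n",
              x$n_replica, x$max_cycle, x$trial, x$seed))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold: %g nm\n", x$threshold))
  if (identical(x$type, "a_d"))
    cat(sprintf("  d_threshold: %g nm  bound_threshold: %d  frame_sel: %d\n",
                x$d_threshold, x$bound_threshold, x$frame_sel))
  for (s in paste0("selection", 1:4))
    if (!is.null(x[[s]])) cat(sprintf("  %s: %s\n", s, x[[s]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
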