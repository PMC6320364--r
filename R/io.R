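#' Read and write trajectory tables
#'
#' Trajectories are exchanged as tab-separated tables with columns `t_s`,
#' `x_um` and optionally `fext_fN`; `#`-prefixed header lines carry a JSON
#' metadata object (time step, seed). The round trip is lossless at full
#' double precision.
#'
#' @param traj a trajectory data frame (columns `t`, `x`, optional `fext`).
#' @param path file path.
#' @return `read_trajectory()` returns a `pt_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @name trajectory_io
NULL

#' @rdname trajectory_io
#' @export
write_trajectory <- function(traj, path) {
  meta <- list(dt = attr(traj, "dt"), seed = attr(traj, "seed"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  df <- data.frame(t_s = sprintf("%.17g", traj$t), x_um = sprintf("%.17g", traj$x))
  if ("fext" %in% names(traj)) df$fext_fN <- sprintf("%.17g", traj$fext)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  if (length(meta_lines)) {
    meta <- tryCatch(
      jsonlite::fromJSON(sub("^#\\s*", "", lines[meta_lines[1]])),
      error = function(e) list())
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  if (!length(body)) abort("empty trajectory file.")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("t_s", "x_um"))) {
    abort(sprintf("malformed trajectory header at line %d: expected 't_s\\tx_um'.",
                  if (length(meta_lines)) meta_lines[1] + 1 else 1))
  }
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (any(diff(df$t_s) <= 0)) {
    bad <- which(diff(df$t_s) <= 0)[1] + 1
    abort(sprintf("non-monotone time at data row %d.", bad))
  }
  new_trajectory(df$t_s, df$x_um,
                 fext = if ("fext_fN" %in% names(df)) df$fext_fN else NULL,
                 dt = meta$dt %||% mean(diff(df$t_s)), seed = meta$seed)
}

#' Write path-time events as a tab-separated table
#'
#' @param events event tibble (as from [detect_transition_paths()]).
#' @param path file path.
#' @param traj_id identifier recorded with every event.
#' @export
write_events <- function(events, path, traj_id = 1L) {
  df <- data.frame(traj_id = traj_id,
                   direction = as.character(events$direction),
                   t_start_s = events$t_start, tau_s = events$tau)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- JSON run configuration ------------------------------------------------

parse_potential_config <- function(cfg) {
  v <- cfg$variant %||% abort("potential config needs a `variant` field.")
  switch(v,
    flat = potential_flat(),
    quartic = potential_quartic(cfg$a, cfg$b, cfg$c),
    from_barrier = quartic_from_barrier(cfg$dU1, cfg$dU2, cfg$L),
    linear = potential_linear(cfg$f),
    traps = potential_traps(cfg$centers, cfg$depths, cfg$widths),
    tabulated = potential_tabulated(cfg$x, cfg$U),
    abort(sprintf("unknown potential variant '%s'.", v))
  )
}

parse_diffusion_config <- function(cfg) {
  if (is.numeric(cfg)) return(diffusion_constant(cfg))
  if (!is.null(cfg$x)) diffusion_tabulated(cfg$x, cfg$D) else diffusion_constant(cfg$D)
}

#' Read a JSON run configuration
#'
#' Parses and validates the package's JSON configuration schema: objects
#' `units` (kBT), `potential` (variant plus parameters), `diffusion`,
#' optional `telegraph`, `sim` (dt, t_max, x0, record_stride, bounds, seed),
#' optional `interval`, and protocol-specific fields.
#'
#' @param path path to a JSON file.
#' @return a list with parsed component objects.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  units <- units(kBT = cfg$units$kBT %||% 4.11)
  pot <- parse_potential_config(cfg$potential %||% list(variant = "flat"))
  dif <- parse_diffusion_config(cfg$diffusion %||% 0.15)
  tel <- if (!is.null(cfg$telegraph)) {
    telegraph_spec(cfg$telegraph$f0, cfg$telegraph$alpha,
                   initial_level = cfg$telegraph$initial_level %||% "random",
                   offset = cfg$telegraph$offset %||% 0)
  }
  sim <- cfg$sim %||% list()
  config <- sim_config(
    t_max = sim$t_max %||% 100, dt = sim$dt %||% 1e-3, x0 = sim$x0 %||% 0,
    record_stride = sim$record_stride %||% 1L,
    bounds = sim$bounds, seed = sim$seed
  )
  interval <- if (!is.null(cfg$interval)) as_interval(cfg$interval)
  list(units = units, potential = pot, diffusion = dif, telegraph = tel,
       config = config, interval = interval, raw = cfg)
}
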