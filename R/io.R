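# Experiment and sweep drivers that persist their artifacts to disk. Every
# CSV carries the resolved configuration hash as a leading comment line so
# outputs are traceable to the exact configuration that produced them.

write_stamped_csv <- function(df, path, hash) {
  writeLines(sprintf("# config_hash: %s", hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run an experiment and write its artifacts
#'
#' Runs one swelling experiment and writes the resolved configuration
#' (YAML), the metric time series, per-snapshot field profiles, and a fit of
#' the front-decay rate to an output directory.
#'
#' @param config A [gel_config()], or a path to a YAML config file.
#' @param dir Output directory (created if needed).
#' @param overrides Named list of [gel_config()] arguments overriding the
#'   loaded configuration (used by the command-line driver).
#' @param quiet Passed to [run_gel()].
#' @return The `gel_run`, invisibly; artifacts land in `dir`.
#' @export
run_experiment <- function(config, dir, overrides = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_gel_config(config)
  if (!is.null(overrides) && length(overrides)) {
    lst <- modifyList(config_to_list(config), overrides)
    en <- do.call(interaction_energies, lst$energies)
    me <- do.call(mechanical_params, lst$mech)
    config <- do.call(gel_config,
                      c(lst[setdiff(names(lst), c("energies", "mech"))],
                        list(energies = en, mech = me)))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  write_gel_config(config, file.path(dir, "config.yaml"))
  run <- run_gel(config, quiet = quiet)
  write_stamped_csv(run$metrics, file.path(dir, "metrics.csv"), hash)
  snap_dir <- file.path(dir, "snapshots")
  dir.create(snap_dir, showWarnings = FALSE)
  for (tm in unique(run$snapshots$time)) {
    snap <- dplyr::filter(run$snapshots, .data$time == tm)
    write_stamped_csv(snap,
                      file.path(snap_dir, sprintf("snapshot_%07.3fs.csv", tm)),
                      hash)
  }
  fit <- tryCatch(fit_decay_rate(run), error = function(e) NULL)
  summary <- glance(run)
  summary$gamma <- if (is.null(fit)) NA_real_ else fit$gamma
  summary$config_hash <- hash
  write_stamped_csv(summary, file.path(dir, "summary.csv"), hash)
  invisible(run)
}

#' Run a bath-molarity sweep with per-point caching
#'
#' Drives [gamma_sweep()] one molarity at a time, caching each point in its
#' own CSV so an interrupted sweep resumes without recomputation.
#'
#' @param case Case preset name.
#' @param bath_Na Vector of bath sodium molarities (M).
#' @param dir Output directory.
#' @param window Fit window passed to [fit_decay_rate()].
#' @param ... Further [gel_config()] arguments (shared across points).
#' @return The sweep tibble (class `gel_sweep`).
#' @export
run_sweep <- function(case, bath_Na, dir, window = c(0.2, 0.8), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(bath_Na, function(m) {
    cache <- file.path(dir, sprintf("%s_%0.6gM.csv", case, m))
    if (file.exists(cache)) return(read_stamped_csv(cache))
    cfg <- gel_config(case = case, bath_Na = m, ...)
    row <- gamma_sweep(m, case = case, window = window, ...)
    write_stamped_csv(row, cache, config_hash(cfg))
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gel_sweep", class(out))
  write_stamped_csv(out, file.path(dir, sprintf("sweep_%s.csv", case)),
                    rlang::hash(list(case = case, bath_Na = bath_Na)))
  out
}
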