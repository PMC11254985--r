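# Study-level reporting: config-driven runs, CSV export, figures. The thin
# command-line wrapper in inst/cli/apopkpd.R calls simulate_study() and
# profile_table().

#' Read a scenario configuration file
#'
#' Parses a YAML (or JSON, which YAML subsumes) scenario configuration into a
#' [scenario_grid()] plus optional typical-parameter overrides. Recognized
#' top-level keys: `formulations`, `doses_mg`, `cv_levels`, `n_subjects`,
#' `seed`, `t_end_min`, `dt_min`, `mcic`, `varied`, and `parameters` (a block
#' of per-formulation `pk`/`pd` overrides, merged over the shipped values).
#' Unknown keys are an error, so typos never pass silently.
#'
#' @param path Path to the configuration file. The default configuration
#'   shipped with the package is at
#'   `system.file("extdata", "default_scenario.yaml", package = "apopkpd")`.
#' @return List with elements `grid` (a `scenario_grid`), `params`
#'   (per-formulation parameter lists) and `overrides` (names of every
#'   overridden parameter, for provenance logging).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("formulations", "doses_mg", "cv_levels", "n_subjects", "seed",
             "t_end_min", "dt_min", "mcic", "varied", "parameters")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (k in c("formulations", "cv_levels", "n_subjects", "seed", "mcic",
              "varied"))
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  if (!is.null(cfg$doses_mg)) args$doses_mg <- lapply(cfg$doses_mg, unlist)
  if (!is.null(cfg$t_end_min)) args$t_end <- cfg$t_end_min
  if (!is.null(cfg$dt_min)) args$dt <- cfg$dt_min
  grid <- do.call(scenario_grid, args)

  params <- list()
  overrides <- character()
  for (f in grid$formulations) {
    pset <- default_params(f)
    ov <- cfg$parameters[[f]]
    for (block in intersect(names(ov), c("pk", "pd"))) {
      for (p in names(ov[[block]])) {
        if (!p %in% names(pset[[block]]))
          stop("unknown ", block, " parameter override `", p, "` for ", f,
               call. = FALSE)
        pset[[block]][[p]] <- ov[[block]][[p]]
        overrides <- c(overrides, paste(f, block, p, sep = "."))
      }
    }
    # re-validate through the constructors
    pset$pk <- do.call(if (f == "sc") sc_pk_params else sl_pk_params,
                       unclass(pset$pk))
    pset$pd <- do.call(pd_params, unclass(pset$pd))
    params[[f]] <- pset
  }
  if (!is.null(cfg$mcic)) for (f in names(params))
    params[[f]]$pd$mcic <- cfg$mcic
  list(grid = grid, params = params, overrides = overrides)
}

#' Run the full study from a configuration file and write all artifacts
#'
#' Convenience driver: reads the configuration, runs [run_grid()], and writes
#' to `out_dir`:
#' \itemize{
#'   \item `summary_cv<level>.csv` - one long summary table per CV level
#'     (columns formulation, dose_mg, cv, endpoint, mean, sd, median, n_used,
#'     responder_fraction);
#'   \item `subjects_<cell>.csv` - per-subject endpoint table per cell
#'     (missing `time_to_response` written as an empty field);
#'   \item `population_<cell>.csv` - the sampled parameters per cell, so any
#'     endpoint computation can be replayed;
#'   \item `profiles_<cell>.csv` - pointwise mean and typical-subject
#'     profiles;
#'   \item `run_metadata.yaml` - seed, parameter provenance and package
#'     version;
#'   \item optional `fig_concentration.pdf` / `fig_updrs.pdf` panels.
#' }
#'
#' @param config Path to a scenario configuration (default: the shipped one).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional master-seed override.
#' @param plots Write the two figure files (default `TRUE`).
#' @param quiet Suppress per-cell progress messages.
#' @return The `apo_study` object, invisibly.
#' @export
simulate_study <- function(config = system.file("extdata",
                                                "default_scenario.yaml",
                                                package = "apopkpd"),
                           out_dir, seed = NULL, plots = TRUE,
                           quiet = FALSE) {
  sc_cfg <- read_scenario_config(config)
  if (!is.null(seed)) sc_cfg$grid$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!quiet)
    message("running ", length(sc_cfg$grid$formulations), " formulation(s) x ",
            length(sc_cfg$grid$cv_levels), " CV level(s), n = ",
            sc_cfg$grid$n_subjects)
  study <- run_grid(sc_cfg$grid, params = sc_cfg$params)

  for (cv in sc_cfg$grid$cv_levels) {
    slice <- study$summary[study$summary$cv == cv, ]
    utils::write.csv(slice,
                     file.path(out_dir, sprintf("summary_cv%g.csv", cv)),
                     row.names = FALSE, na = "")
  }
  for (label in names(study$cells)) {
    cell <- study$cells[[label]]
    utils::write.csv(cell$subjects,
                     file.path(out_dir, paste0("subjects_", label, ".csv")),
                     row.names = FALSE, na = "")
    utils::write.csv(cell$population,
                     file.path(out_dir, paste0("population_", label, ".csv")),
                     row.names = FALSE, na = "")
    utils::write.csv(cell$mean_profiles,
                     file.path(out_dir, paste0("profiles_", label, ".csv")),
                     row.names = FALSE, na = "")
  }
  meta <- list(package_version = as.character(utils::packageVersion("apopkpd")),
               config = normalizePath(config),
               master_seed = sc_cfg$grid$seed,
               cell_seeds = lapply(study$cells, function(c_) c_$cell$seed),
               parameter_overrides = as.list(sc_cfg$overrides),
               mcic = sc_cfg$grid$mcic,
               n_subjects = sc_cfg$grid$n_subjects,
               failed_cells = as.list(study$failed))
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
  if (plots) {
    save_quietly(plot_mean_profiles(study, "cp"),
                 file.path(out_dir, "fig_concentration.pdf"))
    save_quietly(plot_mean_profiles(study, "d_updrs"),
                 file.path(out_dir, "fig_updrs.pdf"))
  }
  if (!quiet) message("wrote ", length(study$cells), " cells to ", out_dir)
  invisible(study)
}

save_quietly <- function(plot, path) {
  grDevices::pdf(path, width = 8, height = 4.5)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Mean profile panels across the study grid
#'
#' One panel per formulation showing the pointwise Monte-Carlo mean profile
#' for every dose (plasma concentration, or UPDRS change from baseline with a
#' dashed line at the response threshold), at one CV level.
#'
#' @param study An `apo_study` from [run_grid()].
#' @param what `"cp"` (plasma concentration) or `"d_updrs"` (UPDRS change).
#' @param cv CV level to plot (default: the first in the grid).
#' @return A ggplot object.
#' @export
plot_mean_profiles <- function(study, what = c("cp", "d_updrs"), cv = NULL) {
  what <- match.arg(what)
  if (is.null(cv)) cv <- study$grid$cv_levels[1]
  keep <- vapply(study$cells, function(c_) c_$cell$cv == cv, logical(1))
  dat <- do.call(rbind, lapply(study$cells[keep], function(c_) {
    data.frame(formulation = toupper(c_$cell$formulation),
               dose = factor(c_$cell$dose_mg),
               time_min = c_$mean_profiles$time_min,
               value = if (what == "cp") c_$mean_profiles$mean_cp
                       else c_$mean_profiles$mean_d_updrs)
  }))
  ylab <- if (what == "cp") "Mean plasma concentration (ng/mL)"
          else "Mean UPDRS III change from baseline (points)"
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = time_min, y = value,
                                         colour = dose)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~formulation, scales = "free_y") +
    ggplot2::labs(x = "Time after dose (min)", y = ylab, colour = "Dose (mg)",
                  title = sprintf("IIV %g%% CV", 100 * cv)) +
    ggplot2::theme_bw()
  if (what == "d_updrs")
    p <- p + ggplot2::geom_hline(yintercept = -study$grid$mcic,
                                 linetype = "dashed")
  p
}

#' Typical-subject profile table
#'
#' Plasma, effect-site and UPDRS-change profiles for the typical (no
#' variability) subject of one formulation and dose, suitable for CSV export.
#'
#' @param formulation `"sc"` or `"sl"`.
#' @param dose_mg Dose (mg).
#' @param grid Time grid (min).
#' @param path Optional file path; if given, the table is also written as CSV.
#' @return The profile `data.frame` (columns `time_min`, `cp`, `ce`,
#'   `d_updrs`), invisibly if `path` is given.
#' @export
profile_table <- function(formulation = c("sc", "sl"), dose_mg,
                          grid = time_grid(), path = NULL) {
  prof <- subject_profiles(match.arg(formulation), dose_mg, grid = grid)
  if (!is.null(path)) {
    utils::write.csv(prof, path, row.names = FALSE)
    return(invisible(prof))
  }
  prof
}
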