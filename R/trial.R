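# Monte-Carlo trial orchestration over the dose x formulation x variability
# grid: sample a virtual population per cell, simulate every subject, extract
# endpoints, and summarize.

#' Scenario grid for the full study
#'
#' Declares the simulated study design. The defaults are the study
#' conditions: doses 1-4 mg subcutaneous and 20-50 mg sublingual, three
#' inter-individual variability levels (15/30/45% CV), 500 subjects per cell,
#' a 0-90 min window sampled every 0.25 min.
#'
#' @param formulations Subset of `c("sc", "sl")`.
#' @param doses_mg Named list of dose vectors (mg) per formulation.
#' @param cv_levels Coefficients of variation (fractions, >= 0).
#' @param n_subjects Subjects per cell, >= 1.
#' @param seed Master seed; each cell derives its own sub-seed from it, so
#'   adding cells never perturbs existing ones.
#' @param t_end,dt Evaluation window end and sampling step (min).
#' @param mcic Response threshold magnitude (UPDRS points).
#' @param varied Varied-parameter set, or `NULL` for the per-formulation
#'   default ([default_varied()]).
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(formulations = c("sc", "sl"),
                          doses_mg = list(sc = c(1, 2, 3, 4),
                                          sl = c(20, 30, 40, 50)),
                          cv_levels = c(0.15, 0.30, 0.45),
                          n_subjects = 500,
                          seed = 1L,
                          t_end = 90, dt = 0.25,
                          mcic = 3.25,
                          varied = NULL) {
  formulations <- match.arg(formulations, several.ok = TRUE)
  stopifnot(all(unlist(doses_mg) > 0), all(cv_levels >= 0), n_subjects >= 1,
            t_end > 0, dt > 0, mcic > 0)
  if (!all(formulations %in% names(doses_mg)))
    stop("`doses_mg` must have an entry for every formulation", call. = FALSE)
  structure(list(formulations = formulations, doses_mg = doses_mg,
                 cv_levels = cv_levels, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), t_end = t_end, dt = dt, mcic = mcic,
                 varied = varied),
            class = "scenario_grid")
}

#' Deterministic per-cell seed
#'
#' Expands a master seed into one sub-seed per (formulation, dose, cv) cell by
#' hashing the cell label, so every cell's population is independent of which
#' other cells are run. Kept below 2^31 - 1.
#'
#' @param master Master seed (integer).
#' @param formulation,dose_mg,cv Cell identifiers.
#' @return A single integer seed.
#' @export
cell_seed <- function(master, formulation, dose_mg, cv) {
  key <- sprintf("%s|%.6g|%.6g", formulation, dose_mg, cv)
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer(h + 1)
}

#' Simulate one scenario cell
#'
#' Samples `n` subjects for one (formulation, dose, cv) cell, simulates each
#' subject's plasma, effect-site and UPDRS-change profiles, extracts all
#' per-subject endpoints, and computes summary statistics and pointwise mean
#' profiles. Deterministic given the seed.
#'
#' @param formulation `"sc"` or `"sl"`.
#' @param dose_mg Dose (mg).
#' @param cv Inter-individual variability (fraction, >= 0).
#' @param n Number of subjects.
#' @param seed Seed for this cell's population.
#' @param params Typical parameters (list with `pk`, `pd`), default the
#'   shipped set for the formulation.
#' @param t_end,dt Evaluation window end and sampling step (min).
#' @param mcic Response threshold magnitude (UPDRS points); defaults to the
#'   value in `params$pd`.
#' @param varied Varied-parameter set, or `NULL` for [default_varied()].
#' @return A list of class `cell_result` with elements
#'   \describe{
#'     \item{subjects}{per-subject endpoint table (one row per subject).}
#'     \item{population}{the sampled parameter table
#'       ([sample_population()]).}
#'     \item{summary}{long summary table from [summarize_endpoints()].}
#'     \item{mean_profiles}{pointwise mean `cp` and `d_updrs` across
#'       subjects, plus the typical subject's profiles.}
#'     \item{cell}{identifiers (formulation, dose, cv, n, seed, mcic).}
#'   }
#' @examples
#' \donttest{
#' res <- run_cell("sc", 2, cv = 0.3, n = 100, seed = 7)
#' subset(res$summary, endpoint == "cmax")
#' }
#' @export
run_cell <- function(formulation = c("sc", "sl"), dose_mg, cv, n = 500,
                     seed = 1L, params = NULL, t_end = 90, dt = 0.25,
                     mcic = NULL, varied = NULL) {
  formulation <- match.arg(formulation)
  if (is.null(params)) params <- default_params(formulation)
  if (is.null(mcic)) mcic <- params$pd$mcic
  grid <- time_grid(t_end, dt)
  pop <- sample_population(params$pk, params$pd,
                           iiv_spec(cv, varied = varied, seed = seed), n)
  sim <- simulate_cohort(formulation, dose_mg, pop, params$pd, grid)
  records <- extract_endpoints(grid, sim$cp, sim$d_updrs, mcic, t_end)
  typ <- subject_profiles(formulation, dose_mg, pk = params$pk,
                          pd = params$pd, grid = grid)
  mean_prof <- data.frame(time_min = grid,
                          mean_cp = rowMeans(sim$cp),
                          mean_d_updrs = rowMeans(sim$d_updrs),
                          typical_cp = typ$cp,
                          typical_d_updrs = typ$d_updrs)
  cell <- list(formulation = formulation, dose_mg = dose_mg, cv = cv, n = n,
               seed = seed, mcic = mcic)
  summary <- cbind(as.data.frame(cell[c("formulation", "dose_mg", "cv")]),
                   summarize_endpoints(records))
  structure(list(subjects = records, population = pop, summary = summary,
                 mean_profiles = mean_prof, cell = cell),
            class = "cell_result")
}

# Simulate plasma and UPDRS-change matrices (time x subject) for a sampled
# population. The subcutaneous closed form is evaluated for all subjects at
# once; the sublingual model steps one matrix exponential per subject.
simulate_cohort <- function(formulation, dose_mg, pop, pd_typ, grid) {
  n <- nrow(pop)
  t_h <- grid / 60
  if (formulation == "sc") {
    kel <- pop$cl / pop$v
    degen <- pairwise_collision(kel, pop$ka, pop$ke0)
    scale <- dose_mg * MG_TO_NG * pop$f / (pop$v * 1000)
    E_kel <- exp(-outer(t_h, kel))       # time x subject
    E_ka <- exp(-outer(t_h, pop$ka))
    E_ke0 <- exp(-outer(t_h, pop$ke0))
    cp <- sweep(E_kel - E_ka, 2, scale * pop$ka / (pop$ka - kel), `*`)
    amp <- scale * pop$ka * pop$ke0
    ce <- sweep(E_kel, 2, amp / ((pop$ka - kel) * (pop$ke0 - kel)), `*`) +
          sweep(E_ka, 2, amp / ((kel - pop$ka) * (pop$ke0 - pop$ka)), `*`) +
          sweep(E_ke0, 2, amp / ((kel - pop$ke0) * (pop$ka - pop$ke0)), `*`)
    for (i in which(degen)) {   # rare rate collisions: exact matrix route
      prm <- subject_params(pop, i)
      prof <- subject_profiles("sc", dose_mg, pk = prm$pk, pd = prm$pd,
                               grid = grid)
      cp[, i] <- prof$cp
      ce[, i] <- prof$ce
    }
  } else {
    cp <- ce <- matrix(0, length(grid), n)
    for (i in seq_len(n)) {
      pk <- sl_pk_params(cl = pop$cl[i], v = pop$v[i], ka = pop$ka[i],
                         k12 = pop$k12[i], k21 = pop$k21[i], f = pop$f[i])
      A <- sl_rate_matrix(pk, ke0 = pop$ke0[i])
      X <- lin_ode_states(A, c(dose_mg * MG_TO_NG * pk$f, rep(0, 5)), grid)
      cp[, i] <- X["central", ] / (pk$v * 1000)
      ce[, i] <- X["ce", ] / (pk$v * 1000)
    }
  }
  cp <- pmax(cp, 0)
  ce <- pmax(ce, 0)
  d_updrs <- matrix(0, length(grid), n)
  for (i in seq_len(n)) {
    ceg_i <- ce[, i]^pop$g[i]
    d_updrs[, i] <- -pop$b0[i] * pop$emax[i] * ceg_i /
      (ceg_i + pop$ec50[i]^pop$g[i])
  }
  list(cp = cp, ce = ce, d_updrs = d_updrs)
}

pairwise_collision <- function(a, b, c) {
  tol <- 1e-6 * pmax(a, b, c)
  (abs(a - b) < tol) | (abs(a - c) < tol) | (abs(b - c) < tol)
}

# endpoint records for every column of the profile matrices
extract_endpoints <- function(grid, cp, d_updrs, mcic, t_end) {
  n <- ncol(cp)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ew <- clip_window(grid, cp[, i], t_end)
    dw <- clip_window(grid, d_updrs[, i], t_end)
    out[[i]] <- cbind(subject_id = i,
                      data.frame(auc_0_90 = trapz(ew$t, ew$v),
                                 cmax = max(ew$v),
                                 tmax = refined_argmax(ew$t, ew$v)),
                      response_metrics_vec(dw$t, dw$v, mcic))
  }
  do.call(rbind, out)
}

#' Summarize per-subject endpoints for one cell
#'
#' Mean, SD, median and n for every endpoint, plus the responder fraction.
#' Crossing-defined endpoints are summarized over responders only
#' (`time_to_response`, which is undefined for non-responders, and
#' `response_duration`, reported as `response_duration` with `n_used` equal to
#' the responder count); `response_duration_all` additionally reports the
#' all-subject mean with non-responders contributing 0. All other endpoints
#' are summarized over all subjects.
#'
#' @param records Per-subject endpoint table (from [run_cell()]'s `subjects`).
#' @return A long `data.frame` with columns `endpoint`, `mean`, `sd`,
#'   `median`, `n_used`, `responder_fraction`.
#' @export
summarize_endpoints <- function(records) {
  resp <- records$responder_flag
  one <- function(name, x) {
    x <- x[!is.na(x)]
    data.frame(endpoint = name,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else
                 if (length(x)) 0 else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               n_used = length(x))
  }
  rows <- rbind(
    one("auc_0_90", records$auc_0_90),
    one("cmax", records$cmax),
    one("tmax", records$tmax),
    one("time_to_response", records$time_to_response),
    one("response_duration", records$response_duration[resp]),
    one("response_duration_all", records$response_duration),
    one("auec_0_90", records$auec_0_90),
    one("max_change", records$max_change),
    one("time_to_max_change", records$time_to_max_change))
  rows$responder_fraction <- mean(resp)
  rows
}

#' Run the full simulated study
#'
#' Executes [run_cell()] for every (formulation, dose, cv) cell of a
#' [scenario_grid()], with per-cell seeds derived from the master seed via
#' [cell_seed()]. Cells that error are reported and skipped; completed cells
#' are still returned.
#'
#' @param grid A [scenario_grid()].
#' @param params Optional list of typical parameter overrides per formulation
#'   (e.g. `list(sc = list(pk = ..., pd = ...))`); defaults to the shipped
#'   sets.
#' @param keep_subjects Keep the per-subject tables in each cell (default
#'   `TRUE`; set `FALSE` to reduce memory for large grids).
#' @return An object of class `apo_study`: list with `summary` (all cells,
#'   long format), `cells` (named list of `cell_result`s), `grid`, and
#'   `failed` (character vector of failed cell labels, normally empty).
#' @examples
#' \donttest{
#' study <- run_grid(scenario_grid(cv_levels = 0.3, n_subjects = 50, seed = 1))
#' head(study$summary)
#' }
#' @export
run_grid <- function(grid, params = NULL, keep_subjects = TRUE) {
  stopifnot(inherits(grid, "scenario_grid"))
  cells <- list()
  failed <- character()
  for (f in grid$formulations) {
    pset <- if (!is.null(params[[f]])) params[[f]] else default_params(f)
    for (dose in grid$doses_mg[[f]]) {
      for (cv in grid$cv_levels) {
        label <- sprintf("%s_%g_mg_cv%g", f, dose, cv)
        res <- tryCatch(
          run_cell(f, dose, cv, n = grid$n_subjects,
                   seed = cell_seed(grid$seed, f, dose, cv),
                   params = pset, t_end = grid$t_end, dt = grid$dt,
                   mcic = grid$mcic, varied = grid$varied),
          error = function(e) {
            warning("cell ", label, " failed: ", conditionMessage(e),
                    call. = FALSE)
            NULL
          })
        if (is.null(res)) {
          failed <- c(failed, label)
        } else {
          if (!keep_subjects) res$subjects <- NULL
          cells[[label]] <- res
        }
      }
    }
  }
  summary <- do.call(rbind, c(lapply(cells, `[[`, "summary"),
                              make.row.names = FALSE))
  structure(list(summary = summary, cells = cells, grid = grid,
                 failed = failed),
            class = "apo_study")
}

#' @export
print.apo_study <- function(x, ...) {
  g <- x$grid
  cat("Simulated apomorphine study:", length(x$cells), "cells",
      sprintf("(%d subjects each, master seed %d)\n", g$n_subjects, g$seed))
  cm <- subset(x$summary, x$summary$endpoint == "cmax")
  print(cm[, c("formulation", "dose_mg", "cv", "mean", "sd")],
        row.names = FALSE, digits = 4)
  if (length(x$failed)) cat("FAILED cells:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cell_result <- function(x, ...) {
  c_ <- x$cell
  cat(sprintf("Scenario cell: %s %g mg, CV %g, n = %d (seed %d)\n",
              toupper(c_$formulation), c_$dose_mg, c_$cv, c_$n, c_$seed))
  print(x$summary[, c("endpoint", "mean", "sd", "n_used",
                      "responder_fraction")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
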