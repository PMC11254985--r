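#' Inter-individual variability specification
#'
#' Describes how a virtual population is sampled around the typical parameter
#' values: each varied parameter is multiplied by an independent lognormal
#' deviate `exp(eta)`, `eta ~ N(0, log(1 + cv^2))`. This parameterization is
#' median-preserving (the median subject is the typical subject) and gives the
#' sampled parameter a coefficient of variation of exactly `cv` in
#' distribution. `cv = 0` collapses every subject onto the typical vector.
#'
#' @param cv Coefficient of variation (fraction, >= 0). The study design uses
#'   0.15, 0.30 and 0.45.
#' @param varied Character vector of parameter names receiving variability.
#'   `NULL` means the default set for the formulation at sampling time: all PK
#'   rate/volume parameters (`cl`, `v`, `ka`, and `k12`/`k21` for sublingual)
#'   plus `ke0`, `ec50` and `b0`; bioavailability, `emax`, `g` and `mcic` stay
#'   fixed.
#' @param seed Integer seed making the population reproducible.
#' @return An object of class `iiv_spec`.
#' @export
iiv_spec <- function(cv, varied = NULL, seed = 1L) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("`cv` must be a single nonnegative number", call. = FALSE)
  if (!is.null(varied) && !is.character(varied))
    stop("`varied` must be NULL or a character vector of parameter names",
         call. = FALSE)
  structure(list(cv = cv, varied = varied, seed = as.integer(seed)),
            class = "iiv_spec")
}

#' Default set of parameters receiving inter-individual variability
#'
#' @param formulation `"sc"` or `"sl"`.
#' @return Character vector of parameter names.
#' @export
default_varied <- function(formulation = c("sc", "sl")) {
  formulation <- match.arg(formulation)
  pk <- if (formulation == "sc") c("cl", "v", "ka")
        else c("cl", "v", "ka", "k12", "k21")
  c(pk, "ke0", "ec50", "b0")
}

#' Sample a virtual population
#'
#' Draws `n` subjects around the typical PK and PD parameter vectors under the
#' lognormal inter-individual variability model of [iiv_spec()]. Draws are
#' laid out one subject at a time, so subject `i`'s parameters do not depend
#' on `n`; the same seed always reproduces the identical table.
#'
#' @param pk Typical PK parameters ([sc_pk_params()] or [sl_pk_params()]).
#' @param pd Typical PD parameters ([pd_params()]).
#' @param iiv An [iiv_spec()].
#' @param n Number of subjects, >= 1.
#' @return A `data.frame` of class `virtual_population`: one row per subject,
#'   columns `subject_id` plus every PK and PD parameter. Attributes record
#'   the formulation, `cv`, `seed` and varied set.
#' @examples
#' pop <- sample_population(sc_pk_params(), pd_params(),
#'                          iiv_spec(cv = 0.3, seed = 42), n = 5)
#' pop$cl
#' @export
sample_population <- function(pk, pd, iiv, n) {
  stopifnot(inherits(pk, "pk_params"), inherits(pd, "pd_params"),
            inherits(iiv, "iiv_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  formulation <- if (inherits(pk, "sc_pk_params")) "sc" else "sl"
  typ <- c(unclass(pk), unclass(pd))
  varied <- if (is.null(iiv$varied)) default_varied(formulation) else iiv$varied
  unknown <- setdiff(varied, names(typ))
  if (length(unknown))
    stop("unknown varied parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tab <- as.data.frame(lapply(typ, rep, times = n))
  if (iiv$cv > 0 && length(varied)) {
    sdlog <- sqrt(log(1 + iiv$cv^2))
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old), add = TRUE)
    set.seed(iiv$seed)
    eta <- matrix(stats::rnorm(n * length(varied), 0, sdlog),
                  nrow = n, byrow = TRUE, dimnames = list(NULL, varied))
    for (p in varied) tab[[p]] <- tab[[p]] * exp(eta[, p])
  }
  structure(cbind(subject_id = seq_len(n), tab),
            formulation = formulation, cv = iiv$cv, seed = iiv$seed,
            varied = varied,
            class = c("virtual_population", "data.frame"))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Rebuild the classed parameter objects for one row of a population table.
subject_params <- function(pop, i) {
  formulation <- attr(pop, "formulation")
  row <- pop[i, , drop = FALSE]
  pk <- if (formulation == "sc") {
    sc_pk_params(cl = row$cl, v = row$v, ka = row$ka, f = row$f)
  } else {
    sl_pk_params(cl = row$cl, v = row$v, ka = row$ka, k12 = row$k12,
                 k21 = row$k21, f = row$f)
  }
  pd <- pd_params(ke0 = row$ke0, ec50 = row$ec50, b0 = row$b0,
                  emax = row$emax, g = row$g, mcic = row$mcic)
  list(pk = pk, pd = pd)
}
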