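#' Subcutaneous apomorphine PK parameters
#'
#' One-compartment disposition with first-order absorption from a subcutaneous
#' depot. Parameters are apparent (F-scaled) population values as estimated
#' from extravascular dosing; the elimination rate constant is always derived
#' as `kel = cl / v` and never stored separately.
#'
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent central volume V/F (L).
#' @param ka First-order absorption rate constant (1/h).
#' @param f Absolute bioavailability, in (0, 1]. Subcutaneous apomorphine is
#'   completely bioavailable, so the default is 1.
#'
#' @return An object of class `sc_pk_params` (named list).
#' @seealso [sl_pk_params()], [pd_params()], [default_params()]
#' @examples
#' p <- sc_pk_params()
#' p$cl / p$v  # elimination rate constant (1/h)
#' @export
sc_pk_params <- function(cl = 191, v = 153, ka = 14.9, f = 1) {
  check_positive(c(cl = cl, v = v, ka = ka))
  check_fraction(f, "f")
  structure(list(cl = cl, v = v, ka = ka, f = f),
            class = c("sc_pk_params", "pk_params"))
}

#' Sublingual apomorphine PK parameters
#'
#' Two-compartment disposition with a delayed absorption described by a chain
#' of three transit compartments. All rate constants are first order; `k12`
#' and `k21` are the central/peripheral transfer constants. As for the
#' subcutaneous model, clearance and volume are apparent and `kel = cl / v`.
#'
#' @param cl Apparent clearance CL/F (L/h).
#' @param v Apparent central volume V/F (L).
#' @param ka First-order transit/absorption rate constant (1/h), shared by the
#'   three transit compartments.
#' @param k12,k21 Central-to-peripheral and peripheral-to-central first-order
#'   transfer rate constants (1/h).
#' @param f Absolute bioavailability, in (0, 1]. The sublingual film is only
#'   partially absorbed (part of the dose is swallowed); default 0.206.
#'
#' @return An object of class `sl_pk_params` (named list).
#' @seealso [sc_pk_params()], [sl_rate_matrix()]
#' @export
sl_pk_params <- function(cl = 80.7, v = 438, ka = 6.58, k12 = 0.613,
                         k21 = 0.0048, f = 0.206) {
  check_positive(c(cl = cl, v = v, ka = ka, k12 = k12, k21 = k21))
  check_fraction(f, "f")
  structure(list(cl = cl, v = v, ka = ka, k12 = k12, k21 = k21, f = f),
            class = c("sl_pk_params", "pk_params"))
}

#' Effect-compartment / sigmoid-Emax PD parameters
#'
#' The plasma-effect-site link `dCe/dt = ke0 (Cp - Ce)` delays the effect
#' relative to plasma, and the UPDRS Part III motor score responds to the
#' effect-site concentration through an inhibitory sigmoid-Emax (Hill) model
#' with baseline `b0`: the modelled score is
#' `b0 * (1 - emax * Ce^g / (Ce^g + ec50^g))`.
#'
#' @param ke0 First-order plasma-effect-site equilibration rate constant (1/h).
#' @param ec50 Effect-site concentration producing half the maximal effect
#'   (ng/mL).
#' @param b0 Baseline UPDRS Part III motor score (points).
#' @param emax Maximal fractional inhibition of the baseline score, in (0, 1].
#' @param g Hill (sigmoidicity) coefficient, dimensionless.
#' @param mcic Minimum clinically important change (positive magnitude, UPDRS
#'   points). A subject "responds" when the change from baseline reaches
#'   `-mcic`. Must satisfy `mcic < b0 * emax`, otherwise no subject can ever
#'   respond.
#'
#' @return An object of class `pd_params` (named list).
#' @seealso [updrs_change_profile()], [ce_threshold()]
#' @export
pd_params <- function(ke0 = 5.36, ec50 = 10.7, b0 = 24.3, emax = 1, g = 3,
                      mcic = 3.25) {
  check_positive(c(ke0 = ke0, ec50 = ec50, b0 = b0, g = g, mcic = mcic))
  check_fraction(emax, "emax")
  if (mcic >= b0 * emax)
    stop("`mcic` must be smaller than b0 * emax (the largest achievable change)",
         call. = FALSE)
  structure(list(ke0 = ke0, ec50 = ec50, b0 = b0, emax = emax, g = g,
                 mcic = mcic),
            class = "pd_params")
}

#' Shipped population parameter sets
#'
#' Reads the plain-text parameter configuration shipped with the package
#' (`extdata/apomorphine_parameters.yaml`), holding the published population
#' PK typical values for each formulation and the shared PK/PD (effect-site +
#' sigmoid-Emax) typical values.
#'
#' @param formulation `"sc"` (subcutaneous) or `"sl"` (sublingual).
#' @return A list with elements `pk` (an `sc_pk_params` or `sl_pk_params`) and
#'   `pd` (a `pd_params`).
#' @examples
#' default_params("sc")$pk$cl
#' @export
default_params <- function(formulation = c("sc", "sl")) {
  formulation <- match.arg(formulation)
  cfg <- yaml::read_yaml(system.file("extdata", "apomorphine_parameters.yaml",
                                     package = "apopkpd", mustWork = TRUE))
  pk_fields <- cfg[[formulation]]$pk
  pk <- if (formulation == "sc") do.call(sc_pk_params, pk_fields)
        else do.call(sl_pk_params, pk_fields)
  list(pk = pk, pd = do.call(pd_params, cfg$pd))
}

#' Effect-site concentration equivalent to the response threshold
#'
#' Inverts the Hill equation: the change from baseline reaches `-mcic` exactly
#' when the effect-site concentration reaches
#' `ec50 * (mcic / (b0 * emax - mcic))^(1/g)`. With the shipped typical values
#' and `mcic = 3.25` this is about 5.74 ng/mL.
#'
#' @param pd A [pd_params()] object.
#' @param mcic Optional threshold override (UPDRS points); defaults to
#'   `pd$mcic`.
#' @return Effect-site concentration (ng/mL).
#' @export
ce_threshold <- function(pd, mcic = pd$mcic) {
  stopifnot(inherits(pd, "pd_params"))
  if (mcic <= 0 || mcic >= pd$b0 * pd$emax)
    stop("`mcic` must lie in (0, b0 * emax)", call. = FALSE)
  pd$ec50 * (mcic / (pd$b0 * pd$emax - mcic))^(1 / pd$g)
}

#' @export
print.pk_params <- function(x, ...) {
  kind <- if (inherits(x, "sc_pk_params")) "subcutaneous (1-cmt, first-order absorption)"
          else "sublingual (2-cmt, 3 transit compartments)"
  cat("Apomorphine PK parameters:", kind, "\n")
  print(unlist(x))
  cat("derived kel (1/h):", x$cl / x$v, "\n")
  invisible(x)
}

#' @export
print.pd_params <- function(x, ...) {
  cat("Effect-compartment / sigmoid-Emax PD parameters\n")
  print(unlist(x))
  cat("Ce threshold for a -", x$mcic, "point response (ng/mL): ",
      format(ce_threshold(x)), "\n", sep = "")
  invisible(x)
}

# -- internal validation helpers ---------------------------------------------

check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("parameter(s) must be finite and strictly positive: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.finite(x) || x <= 0 || x > 1)
    stop("`", name, "` must lie in (0, 1]", call. = FALSE)
  invisible(x)
}
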