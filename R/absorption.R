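# Oral absorption: Weibull tablet dissolution coupled to first-order
# luminal absorption with a solubility cap.
#
# The dissolution profile is parameterised by the 50%-dissolution time t50
# and the shape factor b: F(t) = 1 - exp(-ln(2) (t/t50)^b), so F(t50) = 1/2
# exactly (the textbook Weibull scale is lambda = t50 / ln(2)^(1/b), i.e.
# the 63.2% time). Inside the ODE system dissolution is expressed through
# its hazard h(t) = ln(2) b / t50 (t/t50)^(b-1), which reproduces F exactly
# and lets the luminal solubility cap scale the instantaneous rate.
# Dissolved drug transfers to the liver (portal uptake) with first-order
# rate ka = 2 P_int A_mult / r for a cylindrical small intestine of radius
# r = 1.25 cm and mucosal surface amplification A_mult (default 30).

LUMEN_VOLUME_L <- 0.25
INTESTINE_RADIUS_CM <- 1.25
SURFACE_AMPLIFICATION <- 30

#' Construct a dose regimen
#'
#' @param dose_mg oral dose in mg, single administration.
#' @param formulation `"tablet_weibull"` (film-coated tablet) or
#'   `"capsule_immediate"` (immediate-release capsule, modelled as the
#'   same Weibull with t50 halved).
#' @param t50_min time to 50% dissolved, minutes.
#' @param shape_b Weibull shape factor.
#' @param schedule dosing times in hours; only single-dose schedules are
#'   supported.
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_mg,
                         formulation = c("tablet_weibull",
                                         "capsule_immediate"),
                         t50_min = 12.0, shape_b = 0.80,
                         schedule = 0) {
  formulation <- match.arg(formulation)
  if (!is.numeric(dose_mg) || dose_mg <= 0) {
    stop("dose_mg must be > 0", call. = FALSE)
  }
  if (t50_min <= 0) stop("t50_min must be > 0", call. = FALSE)
  if (shape_b <= 0) stop("shape_b must be > 0", call. = FALSE)
  if (length(schedule) != 1L) {
    stop("only single-dose schedules are supported", call. = FALSE)
  }
  if (formulation == "capsule_immediate") t50_min <- t50_min / 2
  structure(list(dose_mg = dose_mg, formulation = formulation,
                 t50_min = t50_min, shape_b = shape_b,
                 schedule = schedule),
            class = "dose_regimen")
}

#' Weibull dissolved fraction
#'
#' `F(t) = 1 - exp(-ln(2) (t/t50)^b)`; `F(t50) = 0.5` exactly, `F(0) = 0`,
#' monotone non-decreasing with limit 1.
#'
#' @param t time since dosing, minutes (`t >= 0`).
#' @param t50 50%-dissolution time, minutes.
#' @param b shape factor.
#' @return dissolved fraction of dose in \[0, 1\].
#' @examples
#' weibull_dissolved_fraction(12, t50 = 12, b = 0.80)
#' @export
weibull_dissolved_fraction <- function(t, t50, b) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  stopifnot(t50 > 0, b > 0)
  1 - exp(-log(2) * (t / t50)^b)
}

# Instantaneous dissolution hazard h(t) (1/min); floored near t = 0 where
# shapes b < 1 are integrably singular.
dissolution_hazard <- function(t, t50, b) {
  t <- pmax(t, 1e-8)
  log(2) * b / t50 * (t / t50)^(b - 1)
}

# First-order luminal absorption rate constant (1/min).
absorption_rate_constant <- function(compound,
                                     radius_cm = INTESTINE_RADIUS_CM,
                                     amplification = SURFACE_AMPLIFICATION) {
  2 * compound$intestinal_permeability_cm_min * amplification / radius_cm
}

# Luminal saturation concentration in nmol/L.
lumen_saturation_nmol_L <- function(compound) {
  mg_per_L_to_nmol_per_L(compound$solubility_mg_L,
                         compound$molecular_weight)
}

#' Oral absorption input kinetics
#'
#' Integrates the dissolution/lumen subsystem alone (undissolved dose,
#' dissolved amount in a fixed luminal volume with a solubility cap,
#' first-order transfer to the absorption target) and returns the state
#' over time. Used to inspect the oral input function outside the
#' whole-body model; the PBPK engine integrates the identical equations
#' jointly with disposition.
#'
#' @param regimen a [dose_regimen()].
#' @param compound a `compound_parameters` object.
#' @param times_min output times, minutes.
#' @param lumen_volume_L luminal fluid volume (default 0.25 L).
#' @return data.frame with columns `time_min`, `undissolved_nmol`,
#'   `lumen_nmol`, `absorbed_nmol`, `input_rate_nmol_min`.
#' @export
absorption_profile <- function(regimen, compound, times_min,
                               lumen_volume_L = LUMEN_VOLUME_L) {
  stopifnot(inherits(regimen, "dose_regimen"),
            inherits(compound, "compound_parameters"))
  dose_nmol <- mg_to_nmol(regimen$dose_mg, compound$molecular_weight)
  ka <- absorption_rate_constant(compound)
  csat <- lumen_saturation_nmol_L(compound)
  rhs <- function(t, y, p) {
    cap <- clamp(1 - y[2] / lumen_volume_L / csat, 0, 1)
    diss <- dissolution_hazard(t, regimen$t50_min, regimen$shape_b) *
      y[1] * cap
    abs_rate <- ka * y[2]
    list(c(-diss, diss - abs_rate, abs_rate))
  }
  y0 <- c(undissolved = dose_nmol, lumen = 0, absorbed = 0)
  times <- sort(unique(c(0, times_min)))
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-8)
  out <- as.data.frame(out)[match(times_min, times), ]
  data.frame(time_min = times_min,
             undissolved_nmol = out$undissolved,
             lumen_nmol = out$lumen,
             absorbed_nmol = out$absorbed,
             input_rate_nmol_min = ka * out$lumen)
}

#' Instantaneous oral input rate
#'
#' Rate (nmol/min) at which drug enters the absorption target at time
#' `t_min`; the time-integral over \[0, Inf) is bounded by the dose in
#' nmol (`dose_mg * 1e6 / MW`).
#'
#' @inheritParams absorption_profile
#' @param t_min time since dosing, minutes (vector allowed).
#' @return input rate(s), nmol/min.
#' @export
oral_input_rate <- function(regimen, compound, t_min) {
  if (compound$intestinal_permeability_cm_min <= 0) {
    return(rep(0, length(t_min)))
  }
  absorption_profile(regimen, compound, t_min)$input_rate_nmol_min
}
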