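# Local sensitivity analysis over model input parameters.
#
# S = (dPK/PK) / (dp/p) with a forward finite difference at a relative
# perturbation of +10% by default: simulate at p and p*(1 + dp/p),
# recompute the PK metric by NCA, and form the normalised ratio. A
# sensitivity of +1.0 means a +10% input change moves the metric +10%.

#' Construct a simulation scenario
#'
#' Bundles compounds, individual, genotype, regimen and solver settings
#' into one addressable object for sensitivity analysis and fitting.
#' Genotype kcat overrides are applied to the compound pathways at
#' construction so every model input is directly perturbable afterwards.
#'
#' @param parent,metabolite `compound_parameters`.
#' @param individual a `virtual_individual`; defaults to the reference
#'   individual.
#' @param genotype optional [genotype_profile()].
#' @param regimen a [dose_regimen()].
#' @param settings solver settings.
#' @return object of class `pbpk_scenario`.
#' @export
scenario <- function(parent = load_compound("doxepin"),
                     metabolite = load_compound("nordoxepin"),
                     individual = reference_individual(),
                     genotype = NULL,
                     regimen = dose_regimen(75),
                     settings = default_sim_settings()) {
  if (!is.null(genotype)) {
    stopifnot(inherits(genotype, "genotype_profile"))
    parent$pathways$CYP2D6$kcat_per_min <-
      genotype$kcat_overrides[["doxepin"]]
    metabolite$pathways$CYP2D6$kcat_per_min <-
      genotype$kcat_overrides[["nordoxepin"]]
  }
  structure(list(parent = parent, metabolite = metabolite,
                 individual = individual, genotype = genotype,
                 regimen = regimen, settings = settings),
            class = "pbpk_scenario")
}

#' Simulate a scenario
#'
#' @param sc a [scenario()].
#' @param duration_h,output_grid_h passed to [simulate_model()].
#' @return a `pbpk_sim`.
#' @export
simulate_scenario <- function(sc, duration_h = 96, output_grid_h = NULL) {
  stopifnot(inherits(sc, "pbpk_scenario"))
  m <- build_model(sc$parent, sc$metabolite, sc$individual,
                   genotype = NULL, regimen = sc$regimen,
                   settings = sc$settings)
  simulate_model(m, duration_h, output_grid_h)
}

# Addressable scenario parameters: accessor/mutator pairs keyed by name.
scenario_parameter_registry <- function() {
  path_param <- function(get, set) list(get = get, set = set)
  reg <- list(
    dose_mg = path_param(
      function(sc) sc$regimen$dose_mg,
      function(sc, v) { sc$regimen$dose_mg <- v; sc }),
    t50_min = path_param(
      function(sc) sc$regimen$t50_min,
      function(sc, v) { sc$regimen$t50_min <- v; sc }),
    shape_b = path_param(
      function(sc) sc$regimen$shape_b,
      function(sc, v) { sc$regimen$shape_b <- v; sc }),
    ref_conc.CYP2D6 = path_param(
      function(sc) sc$parent$pathways$CYP2D6$reference_concentration_uM,
      function(sc, v) {
        sc$parent$pathways$CYP2D6$reference_concentration_uM <- v
        sc$metabolite$pathways$CYP2D6$reference_concentration_uM <- v
        sc
      }),
    ref_conc.CYP2C19 = path_param(
      function(sc) sc$parent$pathways$CYP2C19$reference_concentration_uM,
      function(sc, v) {
        sc$parent$pathways$CYP2C19$reference_concentration_uM <- v
        sc
      })
  )
  cpd_params <- function(role) {
    out <- list()
    out[[paste0(role, ".fraction_unbound")]] <- path_param(
      function(sc) sc[[role]]$fraction_unbound,
      function(sc, v) { sc[[role]]$fraction_unbound <- v; sc })
    out[[paste0(role, ".log_p")]] <- path_param(
      function(sc) sc[[role]]$log_p,
      function(sc, v) { sc[[role]]$log_p <- v; sc })
    out[[paste0(role, ".solubility")]] <- path_param(
      function(sc) sc[[role]]$solubility_mg_L,
      function(sc, v) { sc[[role]]$solubility_mg_L <- v; sc })
    for (enz in c("CYP2D6", "CYP2C19")) {
      local({
        e <- enz; r <- role
        out[[paste0(r, ".km.", e)]] <<- path_param(
          function(sc) sc[[r]]$pathways[[e]]$km_uM,
          function(sc, v) { sc[[r]]$pathways[[e]]$km_uM <- v; sc })
        out[[paste0(r, ".kcat.", e)]] <<- path_param(
          function(sc) sc[[r]]$pathways[[e]]$kcat_per_min,
          function(sc, v) { sc[[r]]$pathways[[e]]$kcat_per_min <- v; sc })
      })
    }
    out
  }
  reg <- c(reg, cpd_params("parent"), cpd_params("metabolite"))
  reg$metabolite.total_hepatic_clearance <- path_param(
    function(sc) sc$metabolite$total_hepatic_clearance_L_min,
    function(sc, v) { sc$metabolite$total_hepatic_clearance_L_min <- v; sc })
  reg
}

lookup_parameter <- function(name) {
  reg <- scenario_parameter_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario parameter: ", name, "; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Get or set an addressable scenario parameter
#'
#' @param sc a [scenario()].
#' @param name parameter name, e.g. `"dose_mg"`,
#'   `"parent.kcat.CYP2D6"`, `"ref_conc.CYP2D6"`,
#'   `"metabolite.total_hepatic_clearance"`.
#' @param value new value (for the setter).
#' @return current value, or the modified scenario.
#' @export
scenario_parameter <- function(sc, name) {
  p <- lookup_parameter(name)
  v <- p$get(sc)
  if (is.null(v) || !is.finite(v)) {
    stop("parameter ", name, " is not set in this scenario",
         call. = FALSE)
  }
  v
}

#' @rdname scenario_parameter
#' @export
set_scenario_parameter <- function(sc, name, value) {
  p <- lookup_parameter(name)
  if (is.null(p$get(sc))) {
    stop("parameter ", name, " is not set in this scenario",
         call. = FALSE)
  }
  p$set(sc, value)
}

extract_metric <- function(sim, compound, metric) {
  prof <- sim$profiles[[compound]]
  if (is.null(prof)) {
    prof <- sim$profiles[[match(compound, c("parent", "metabolite"))]]
  }
  m <- suppressWarnings(nca(prof))
  switch(metric, AUC_inf = m$auc_inf, Cmax = m$cmax,
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Local sensitivity of a PK metric to one input parameter
#'
#' @param sc a [scenario()].
#' @param parameter addressable parameter name (see
#'   [scenario_parameter()]).
#' @param metric `"AUC_inf"` or `"Cmax"`.
#' @param compound compound name in the simulation output (or
#'   `"parent"` / `"metabolite"`).
#' @param rel_perturbation relative perturbation dp/p, > 0
#'   (default 0.10); a forward difference is used.
#' @param duration_h simulated duration.
#' @return one-row data.frame of class `sensitivity_result` with columns
#'   `parameter`, `compound`, `metric`, `sensitivity`, `perturbation`,
#'   `base_value`.
#' @export
local_sensitivity <- function(sc, parameter,
                              metric = c("AUC_inf", "Cmax"),
                              compound = "parent",
                              rel_perturbation = 0.10,
                              duration_h = 96) {
  metric <- match.arg(metric)
  stopifnot(rel_perturbation > 0)
  base_value <- scenario_parameter(sc, parameter)
  pk0 <- extract_metric(simulate_scenario(sc, duration_h), compound,
                        metric)
  sc1 <- set_scenario_parameter(sc, parameter,
                                base_value * (1 + rel_perturbation))
  pk1 <- extract_metric(simulate_scenario(sc1, duration_h), compound,
                        metric)
  s <- ((pk1 - pk0) / pk0) / rel_perturbation
  out <- data.frame(parameter = parameter, compound = compound,
                    metric = metric, sensitivity = s,
                    perturbation = rel_perturbation,
                    base_value = base_value)
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Ranked sensitivity panel
#'
#' Computes [local_sensitivity()] for each parameter and returns the
#' results sorted by decreasing |S|, flagging |S| > 0.5 as influential.
#'
#' @inheritParams local_sensitivity
#' @param parameters non-empty character vector of parameter names.
#' @return data.frame sorted by `abs(sensitivity)` descending with an
#'   `influential` logical column.
#' @export
rank_sensitivities <- function(sc, parameters,
                               metric = c("AUC_inf", "Cmax"),
                               compound = "parent",
                               rel_perturbation = 0.10,
                               duration_h = 96) {
  if (length(parameters) == 0) {
    stop("parameters must be non-empty", call. = FALSE)
  }
  metric <- match.arg(metric)
  rows <- do.call(rbind, lapply(parameters, function(p) {
    local_sensitivity(sc, p, metric, compound, rel_perturbation,
                      duration_h)
  }))
  rows <- rows[order(-abs(rows$sensitivity)), ]
  rows$influential <- abs(rows$sensitivity) > 0.5
  rownames(rows) <- NULL
  rows
}
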