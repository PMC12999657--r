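# Whole-body PBPK engine.
#
# Perfusion-limited organ compartments plus arterial and venous blood;
# venous blood feeds the lung, the lung feeds arterial blood, and gut,
# spleen and stomach drain through the liver (portal inflow). Both
# compounds share the topology; all metabolism is hepatic and acts on the
# unbound liver water concentration C_liver * fu / Kp_liver (well-stirred
# convention). CYP2C19 flux on the parent appears mole-for-mole as
# metabolite in the liver compartment. Amounts are carried in nmol,
# concentrations in nmol/L, time in minutes internally (hours at the
# interfaces). Renal clearance is absent for both compounds.

BLOOD_COMPARTMENTS <- c("arterial", "venous")

default_sim_settings <- function() {
  list(rtol = 1e-8, atol = 1e-10, output_step_h = 0.25)
}

#' Michaelis-Menten metabolic rate
#'
#' `v = kcat * E * Cu / (Km + Cu) * V_liver * 1e3` in nmol/min, for
#' kcat in 1/min, enzyme and substrate concentrations in umol/L and liver
#' volume in L. Zero when `Cu = 0` or `kcat = 0`; saturates at
#' `kcat * E * V * 1e3` for `Cu >> Km`.
#'
#' @param kcat turnover number, 1/min.
#' @param enzyme_conc enzyme concentration, umol/L.
#' @param km Michaelis constant, umol/L.
#' @param c_unbound unbound substrate concentration, umol/L.
#' @param liver_volume liver volume, L.
#' @return rate in nmol/min.
#' @examples
#' michaelis_menten_rate(260, 0.40, 88, 1, 1)
#' @export
michaelis_menten_rate <- function(kcat, enzyme_conc, km, c_unbound,
                                  liver_volume) {
  stopifnot(kcat >= 0, enzyme_conc >= 0, km > 0, c_unbound >= 0,
            liver_volume >= 0)
  kcat * enzyme_conc * c_unbound / (km + c_unbound) * liver_volume * 1e3
}

#' Build the whole-body parent-metabolite model
#'
#' Applies the genotype's CYP2D6 kcat overrides to both compounds,
#' computes partition coefficients with each compound's configured method,
#' scales enzyme reference concentrations by the individual's abundance
#' multipliers, and assembles the flow topology from the individual's
#' physiology.
#'
#' @param parent parent `compound_parameters` (must carry a CYP2C19
#'   pathway producing the metabolite and a CYP2D6 pathway producing
#'   inactive products).
#' @param metabolite metabolite `compound_parameters` (CYP2D6 pathway
#'   producing inactive products plus a total hepatic clearance; must not
#'   carry a metabolite-forming pathway).
#' @param individual a `virtual_individual`.
#' @param genotype optional [genotype_profile()]; omitted means the base
#'   (non-genotyped) turnover numbers are used as configured.
#' @param regimen a [dose_regimen()] for the parent, or `NULL` for no
#'   dosing.
#' @param settings solver settings list (`rtol`, `atol`,
#'   `output_step_h`).
#' @return object of class `pbpk_model`.
#' @export
build_model <- function(parent, metabolite, individual,
                        genotype = NULL, regimen = NULL,
                        settings = default_sim_settings()) {
  stopifnot(inherits(parent, "compound_parameters"),
            inherits(metabolite, "compound_parameters"),
            inherits(individual, "virtual_individual"))
  check_pathway <- function(cpd, enzyme, product, role) {
    p <- cpd$pathways[[enzyme]]
    if (is.null(p) || p$product != product) {
      stop("model build error: ", role, " must carry a ", enzyme,
           " pathway with product '", product, "'", call. = FALSE)
    }
    p
  }
  check_pathway(parent, "CYP2C19", "metabolite", "parent")
  check_pathway(parent, "CYP2D6", "inactive", "parent")
  check_pathway(metabolite, "CYP2D6", "inactive", "metabolite")
  if (any(vapply(metabolite$pathways, function(p) p$product == "metabolite",
                 logical(1)))) {
    stop("model build error: metabolite-forming pathway configured on ",
         "the metabolite", call. = FALSE)
  }
  if (is.null(metabolite$total_hepatic_clearance_L_min)) {
    stop("model build error: metabolite requires a total hepatic ",
         "clearance", call. = FALSE)
  }
  if (!is.null(genotype)) {
    stopifnot(inherits(genotype, "genotype_profile"))
    parent$pathways$CYP2D6$kcat_per_min <-
      genotype$kcat_overrides[["doxepin"]]
    metabolite$pathways$CYP2D6$kcat_per_min <-
      genotype$kcat_overrides[["nordoxepin"]]
  }

  comps <- c(BLOOD_COMPARTMENTS, model_organs())
  nc <- length(comps)
  V <- individual$organ_volumes[comps]
  Qf <- individual$blood_flows
  portal_organs <- c("gut", "spleen", "stomach")
  co <- sum(Qf)
  Q <- matrix(0, nc, nc, dimnames = list(comps, comps))
  for (org in names(Qf)) Q["arterial", org] <- Qf[[org]]
  for (org in portal_organs) {
    Q[org, "liver"] <- Qf[[org]]
  }
  Q["liver", "venous"] <- Qf[["liver"]] + sum(Qf[portal_organs])
  direct <- setdiff(names(Qf), c(portal_organs, "liver"))
  for (org in direct) Q[org, "venous"] <- Qf[[org]]
  Q["venous", "lung"] <- co
  Q["lung", "arterial"] <- co

  kp_parent <- c(arterial = 1, venous = 1,
                 calc_partition_coefficients(parent))
  kp_met <- c(arterial = 1, venous = 1,
              calc_partition_coefficients(metabolite))
  liver <- match("liver", comps)

  mult <- individual$enzyme_multipliers
  elim <- list()
  add_mm <- function(elim, cpd_idx, cpd, enzyme, product_idx) {
    p <- cpd$pathways[[enzyme]]
    c(elim, list(list(type = "mm", compound = cpd_idx, comp = liver,
                      kcat = p$kcat_per_min,
                      enzyme_uM = p$reference_concentration_uM *
                        mult[[enzyme]],
                      km_uM = p$km_uM, product = product_idx,
                      label = paste0(cpd$name, "_", enzyme))))
  }
  elim <- add_mm(elim, 1L, parent, "CYP2C19", 2L)
  elim <- add_mm(elim, 1L, parent, "CYP2D6", NA_integer_)
  elim <- add_mm(elim, 2L, metabolite, "CYP2D6", NA_integer_)
  elim <- c(elim, list(list(
    type = "linear", compound = 2L, comp = liver,
    clint = metabolite$total_hepatic_clearance_L_min,
    product = NA_integer_,
    label = paste0(metabolite$name, "_hepatic_clearance"))))

  absorption <- if (is.null(regimen)) {
    list(type = "none")
  } else {
    list(type = "weibull_oral", compound = 1L, target = liver,
         dose_nmol = mg_to_nmol(regimen$dose_mg, parent$molecular_weight),
         t50 = regimen$t50_min, b = regimen$shape_b,
         ka = absorption_rate_constant(parent),
         lumen_V = LUMEN_VOLUME_L,
         csat = lumen_saturation_nmol_L(parent))
  }

  structure(list(
    compartments = comps, V = V, Q = Q,
    sample_comp = match("venous", comps),
    compounds = list(
      list(name = parent$name, fu = parent$fraction_unbound,
           kp = kp_parent, mw = parent$molecular_weight),
      list(name = metabolite$name, fu = metabolite$fraction_unbound,
           kp = kp_met, mw = metabolite$molecular_weight)
    ),
    elim = elim, absorption = absorption,
    individual = individual, genotype = genotype, regimen = regimen,
    parent = parent, metabolite = metabolite,
    settings = settings
  ), class = "pbpk_model")
}

#' One-compartment model with first-order absorption
#'
#' Degenerate topology (single compartment, no flows, linear clearance,
#' first-order depot absorption) built as a `pbpk_model` and integrated by
#' the same solver path as the whole-body model. Its closed-form solution
#' is the Bateman equation, used as the analytic oracle for the engine.
#'
#' @param volume_L compartment volume.
#' @param clearance_L_min linear clearance.
#' @param ka_per_min first-order absorption rate constant.
#' @param dose_nmol dose placed in the depot at time zero.
#' @return a `pbpk_model`.
#' @export
one_compartment_model <- function(volume_L, clearance_L_min, ka_per_min,
                                  dose_nmol) {
  structure(list(
    compartments = "central",
    V = c(central = volume_L),
    Q = matrix(0, 1, 1, dimnames = list("central", "central")),
    sample_comp = 1L,
    compounds = list(list(name = "drug", fu = 1,
                          kp = c(central = 1), mw = 300)),
    elim = list(list(type = "linear", compound = 1L, comp = 1L,
                     clint = clearance_L_min, product = NA_integer_,
                     label = "drug_clearance")),
    absorption = list(type = "depot", compound = 1L, target = 1L,
                      dose_nmol = dose_nmol, ka = ka_per_min),
    settings = default_sim_settings()
  ), class = "pbpk_model")
}

# Assemble the RHS closure and initial state for a model.
model_system <- function(model) {
  nc <- length(model$compartments)
  npd <- length(model$compounds)
  V <- unname(model$V)
  Qt <- t(model$Q)
  qout <- rowSums(model$Q)
  vkp <- vapply(model$compounds, function(cp) V * unname(cp$kp),
                numeric(nc))                     # nc x npd
  fu <- vapply(model$compounds, `[[`, numeric(1), "fu")
  elim <- model$elim
  nelim <- length(elim)
  abs_type <- model$absorption$type
  a <- model$absorption
  n_amount <- nc * npd
  # state: amounts | undissolved, lumen (oral) or depot | cum_absorbed,
  # cumulative eliminated per process
  n_abs_states <- switch(abs_type, weibull_oral = 2L, depot = 1L, none = 0L)
  i_abs <- if (n_abs_states) n_amount + seq_len(n_abs_states) else integer(0)
  i_cumabs <- n_amount + n_abs_states + 1L
  i_cume <- i_cumabs + seq_len(nelim)

  y0 <- numeric(i_cumabs + nelim)
  if (abs_type == "weibull_oral") {
    y0[i_abs[1]] <- a$dose_nmol
  } else if (abs_type == "depot") {
    y0[i_abs[1]] <- a$dose_nmol
  }

  rhs <- function(t, y, p) {
    A <- matrix(y[seq_len(n_amount)], nc, npd)
    Cout <- A / vkp
    dA <- Qt %*% Cout - qout * Cout
    dy <- numeric(length(y))
    for (k in seq_len(nelim)) {
      e <- elim[[k]]
      c_unb <- Cout[e$comp, e$compound] * fu[e$compound]   # nmol/L unbound
      v <- if (e$type == "mm") {
        cu_uM <- c_unb / 1e3
        e$kcat * e$enzyme_uM * cu_uM / (e$km_uM + cu_uM) * V[e$comp] * 1e3
      } else {
        e$clint * c_unb
      }
      dA[e$comp, e$compound] <- dA[e$comp, e$compound] - v
      if (!is.na(e$product)) {
        dA[e$comp, e$product] <- dA[e$comp, e$product] + v
      }
      dy[i_cume[k]] <- v
    }
    if (abs_type == "weibull_oral") {
      undiss <- y[i_abs[1]]
      lumen <- y[i_abs[2]]
      cap <- clamp(1 - lumen / a$lumen_V / a$csat, 0, 1)
      diss <- dissolution_hazard(t, a$t50, a$b) * undiss * cap
      inp <- a$ka * lumen
      dA[a$target, a$compound] <- dA[a$target, a$compound] + inp
      dy[i_abs[1]] <- -diss
      dy[i_abs[2]] <- diss - inp
      dy[i_cumabs] <- inp
    } else if (abs_type == "depot") {
      inp <- a$ka * y[i_abs[1]]
      dA[a$target, a$compound] <- dA[a$target, a$compound] + inp
      dy[i_abs[1]] <- -inp
      dy[i_cumabs] <- inp
    }
    dy[seq_len(n_amount)] <- dA
    list(dy)
  }
  list(rhs = rhs, y0 = y0, nc = nc, npd = npd,
       i_abs = i_abs, i_cumabs = i_cumabs, i_cume = i_cume,
       elim_labels = vapply(elim, `[[`, character(1), "label"))
}

#' Simulate a PBPK model
#'
#' Integrates the mass-balance system with a stiff-capable solver
#' (`deSolve::lsoda`) and returns venous plasma concentration-time
#' profiles plus mass-balance diagnostics.
#'
#' @param model a `pbpk_model`.
#' @param duration_h simulated duration in hours (default 96, covering
#'   more than five terminal half-lives of both compounds).
#' @param output_grid_h output times in hours; defaults to a regular grid
#'   at the settings' `output_step_h`.
#' @return object of class `pbpk_sim`: a list with `time_h`, one
#'   concentration profile data.frame (`time_h`, `conc_nmol_L`) per
#'   compound under `profiles`, cumulative absorbed/eliminated amounts
#'   under `cumulative`, and a `balance` data.frame with relative
#'   mass-balance errors per output time.
#' @export
simulate_model <- function(model, duration_h = 96, output_grid_h = NULL) {
  stopifnot(inherits(model, "pbpk_model"))
  st <- model$settings
  grid_h <- output_grid_h %||% seq(0, duration_h, by = st$output_step_h)
  stopifnot(all(diff(grid_h) > 0), all(grid_h >= 0))
  times_min <- c(0, grid_h[grid_h > 0] * 60)
  sys <- model_system(model)
  sol <- deSolve::lsoda(sys$y0, times_min, sys$rhs, parms = NULL,
                        rtol = st$rtol, atol = st$atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failure at t = ", max(sol[, 1]) / 60,
         " h; last good state returned in condition", call. = FALSE)
  }
  sol <- unclass(sol)
  keep <- match(round(grid_h * 60, 9), round(sol[, 1], 9))
  sol <- sol[keep, , drop = FALSE]
  y <- sol[, -1, drop = FALSE]
  if (min(y) < -1e-6 * max(abs(y), 1)) {
    stop("negative state beyond tolerance in simulation", call. = FALSE)
  }
  y[y < 0] <- 0

  nc <- sys$nc; npd <- sys$npd
  sample_i <- model$sample_comp
  profiles <- lapply(seq_len(npd), function(pd) {
    amt <- y[, (pd - 1) * nc + sample_i]
    data.frame(time_h = grid_h,
               conc_nmol_L = amt / unname(model$V[sample_i]))
  })
  names(profiles) <- vapply(model$compounds, `[[`, character(1), "name")

  cum <- data.frame(time_h = grid_h,
                    absorbed = y[, sys$i_cumabs])
  for (k in seq_along(sys$i_cume)) {
    cum[[sys$elim_labels[k]]] <- y[, sys$i_cume[k]]
  }

  balance <- mass_balance(model, sys, y, grid_h)
  structure(list(time_h = grid_h, profiles = profiles,
                 cumulative = cum, balance = balance, model = model),
            class = "pbpk_sim")
}

# Mass-balance diagnostics: input into each compound's disposition system
# must equal circulating amounts plus everything eliminated onward.
mass_balance <- function(model, sys, y, grid_h) {
  nc <- sys$nc; npd <- sys$npd
  elim <- model$elim
  out <- data.frame(time_h = grid_h)
  for (pd in seq_len(npd)) {
    in_body <- rowSums(y[, (pd - 1) * nc + seq_len(nc), drop = FALSE])
    eliminated <- 0
    for (k in seq_along(elim)) {
      if (elim[[k]]$compound == pd) {
        eliminated <- eliminated + y[, sys$i_cume[k]]
      }
    }
    formed <- 0
    for (k in seq_along(elim)) {
      prod <- elim[[k]]$product
      if (!is.na(prod) && prod == pd) formed <- formed + y[, sys$i_cume[k]]
    }
    input <- if (!is.null(model$absorption$compound) &&
                 model$absorption$type != "none" &&
                 model$absorption$compound == pd) {
      y[, sys$i_cumabs] + formed
    } else {
      formed
    }
    nm <- model$compounds[[pd]]$name
    out[[paste0("input_", nm)]] <- input
    out[[paste0("accounted_", nm)]] <- in_body + eliminated
    denom <- pmax(input, max(input) * 1e-12, .Machine$double.eps)
    out[[paste0("rel_err_", nm)]] <-
      abs(input - (in_body + eliminated)) / denom
  }
  out
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim>", length(x$time_h), "output times over",
      max(x$time_h), "h\n")
  for (nm in names(x$profiles)) {
    p <- x$profiles[[nm]]
    cat(sprintf("  %s: Cmax %.3g nmol/L at %.2f h\n", nm,
                max(p$conc_nmol_L), p$time_h[which.max(p$conc_nmol_L)]))
  }
  invisible(x)
}

#' Simulate a virtual population
#'
#' Simulates every individual under the same genotype and regimen and
#' summarises per-compound concentration profiles by arithmetic mean and
#' empirical 5th/95th percentiles (order statistics with linear
#' interpolation, `stats::quantile` type 7) at each output time.
#'
#' @inheritParams build_model
#' @param population non-empty list of `virtual_individual`s.
#' @param duration_h simulated duration in hours.
#' @param output_grid_h output grid in hours.
#' @return object of class `pbpk_population_sim`: list with `time_h`,
#'   per-compound concentration matrices (individual x time) under
#'   `individual_conc`, and per-compound summary data.frames (`time_h`,
#'   `mean`, `p5`, `p95`) under `summary`.
#' @export
simulate_population <- function(parent, metabolite, population,
                                genotype = NULL, regimen = NULL,
                                duration_h = 96, output_grid_h = NULL,
                                settings = default_sim_settings()) {
  if (length(population) == 0) {
    stop("population must be non-empty", call. = FALSE)
  }
  if (length(population) < 20) {
    warning("population of size ", length(population),
            " < 20: empirical 5th/95th percentiles are unstable",
            call. = FALSE)
  }
  sims <- lapply(population, function(ind) {
    m <- build_model(parent, metabolite, ind, genotype, regimen, settings)
    simulate_model(m, duration_h, output_grid_h)
  })
  time_h <- sims[[1]]$time_h
  cpd_names <- names(sims[[1]]$profiles)
  conc <- lapply(cpd_names, function(nm) {
    do.call(rbind, lapply(sims, function(s) s$profiles[[nm]]$conc_nmol_L))
  })
  names(conc) <- cpd_names
  summ <- lapply(conc, function(m) {
    data.frame(time_h = time_h,
               mean = colMeans(m),
               p5 = apply(m, 2, stats::quantile, probs = 0.05,
                          names = FALSE),
               p95 = apply(m, 2, stats::quantile, probs = 0.95,
                           names = FALSE))
  })
  structure(list(time_h = time_h, individual_conc = conc,
                 summary = summ, n = length(population)),
            class = "pbpk_population_sim")
}

#' Write concentration-time profiles as delimited text
#'
#' Long-format TSV with columns `time_h`, `compound`,
#' `concentration_nmol_per_L`, `statistic`; header comment lines record
#' seed, genotype, dose and the configuration hash when given.
#'
#' @param x a `pbpk_sim` or `pbpk_population_sim`.
#' @param path output file.
#' @param meta optional named list written into the header
#'   (seed, genotype, dose_mg, config_hash, ...).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, meta = list()) {
  rows <- if (inherits(x, "pbpk_sim")) {
    do.call(rbind, lapply(names(x$profiles), function(nm) {
      data.frame(time_h = x$time_h, compound = nm,
                 concentration_nmol_per_L = x$profiles[[nm]]$conc_nmol_L,
                 statistic = "individual")
    }))
  } else if (inherits(x, "pbpk_population_sim")) {
    do.call(rbind, lapply(names(x$summary), function(nm) {
      s <- x$summary[[nm]]
      do.call(rbind, lapply(c("mean", "p5", "p95"), function(st) {
        data.frame(time_h = x$time_h, compound = nm,
                   concentration_nmol_per_L = s[[st]], statistic = st)
      }))
    }))
  } else {
    stop("x must be a pbpk_sim or pbpk_population_sim", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, as.character(meta[[k]]))
  }, character(1))
  writeLines(c("# doxpbpk concentration-time profiles", hdr), con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
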