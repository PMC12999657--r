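# Virtual-individual and population synthesis.
#
# Demographics are sampled uniformly within the printed study ranges (age,
# weight) and sex by the female fraction. Organ volumes scale from the
# bundled 73 kg reference physiology as (W/Wref)^1 and regional blood flows
# as (W/Wref)^0.75 (standard allometry). Enzyme abundance multipliers are
# lognormal with median 1 and geometric SD 1.4 per enzyme, independent
# across individuals and enzymes.

REFERENCE_WEIGHT_KG <- 73
ENZYME_GSD_DEFAULT <- 1.4

#' Reference adult physiology table
#'
#' @return data.frame with columns `organ`, `volume_L`, `flow_L_min`
#'   (flow is `NA` for the arterial/venous pools and lung, which carries
#'   the whole cardiac output).
#' @export
reference_physiology <- function() {
  if (is.null(.doxpbpk_env$reference_physiology)) {
    phys <- read_bundled_csv("reference_physiology.csv")
    phys$flow_L_min <- suppressWarnings(as.numeric(phys$flow_L_min))
    .doxpbpk_env$reference_physiology <- phys
  }
  .doxpbpk_env$reference_physiology
}

#' Construct a demographic specification
#'
#' @param n number of individuals, `>= 1`.
#' @param female_fraction fraction of females in \[0, 1\].
#' @param age_range numeric length-2, years (min, max).
#' @param weight_range numeric length-2, kg (min, max).
#' @param genotype optional [genotype_profile()].
#' @param enzyme_gsd geometric SD of the lognormal enzyme-abundance
#'   multipliers (median 1); default 1.4.
#' @return object of class `demographic_spec`.
#' @export
demographic_spec <- function(n, female_fraction = 0,
                             age_range, weight_range,
                             genotype = NULL,
                             enzyme_gsd = ENZYME_GSD_DEFAULT) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must be in [0, 1]", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    stop("age_range must be (min, max) with min <= max", call. = FALSE)
  }
  if (length(weight_range) != 2L || weight_range[1] > weight_range[2]) {
    stop("weight_range must be (min, max) with min <= max", call. = FALSE)
  }
  if (enzyme_gsd < 1) stop("enzyme_gsd must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 age_range = as.numeric(age_range),
                 weight_range = as.numeric(weight_range),
                 genotype = genotype, enzyme_gsd = enzyme_gsd),
            class = "demographic_spec")
}

#' Demographic specification for a bundled study group
#'
#' Builds the [demographic_spec()] matching one row of the bundled study
#' demographics table.
#'
#' @param cyp2d6 `"none"` (non-genotyped development group), `"UM"`,
#'   `"NM"`, `"IM"` or `"PM"`.
#' @param compound `"doxepin"` or `"nordoxepin"` (the PM metabolite row
#'   has a slightly different age range).
#' @param n optional override of the group size (e.g. 100 for the
#'   virtual-population evaluation).
#' @return a `demographic_spec`.
#' @export
study_demographic_spec <- function(cyp2d6 = "none", compound = "doxepin",
                                   n = NULL) {
  demo <- read_bundled_csv("study_demographics.csv")
  row <- demo[demo$cyp2d6 == cyp2d6 & demo$compound == compound, ]
  if (nrow(row) != 1L) {
    stop("no demographics on record for cyp2d6=", cyp2d6,
         ", compound=", compound, call. = FALSE)
  }
  genotype <- if (cyp2d6 == "none") {
    genotype_profile(phenotype = "non_genotyped")
  } else {
    genotype_profile(phenotype = cyp2d6)
  }
  demographic_spec(n = n %||% row$n,
                   female_fraction = row$female_pct / 100,
                   age_range = c(row$age_min, row$age_max),
                   weight_range = c(row$weight_min, row$weight_max),
                   genotype = genotype)
}

#' Sample one virtual individual
#'
#' @param spec a [demographic_spec()].
#' @param seed integer seed; the same spec and seed always give the same
#'   individual.
#' @return object of class `virtual_individual` with demographics, organ
#'   volumes (L), regional blood flows (L/min) and enzyme abundance
#'   multipliers.
#' @export
sample_individual <- function(spec, seed) {
  stopifnot(inherits(spec, "demographic_spec"))
  with_seed(seed, {
    sex <- if (stats::runif(1) < spec$female_fraction) "F" else "M"
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    weight <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
    sdlog <- log(spec$enzyme_gsd)
    mult <- stats::rlnorm(2, meanlog = 0, sdlog = sdlog)
    names(mult) <- c("CYP2D6", "CYP2C19")
    phys <- reference_physiology()
    vol_scale <- weight / REFERENCE_WEIGHT_KG
    flow_scale <- (weight / REFERENCE_WEIGHT_KG)^0.75
    volumes <- stats::setNames(phys$volume_L * vol_scale, phys$organ)
    perfused <- !is.na(phys$flow_L_min)
    flows <- stats::setNames(phys$flow_L_min[perfused] * flow_scale,
                             phys$organ[perfused])
    structure(list(sex = sex, age = age, weight = weight,
                   organ_volumes = volumes, blood_flows = flows,
                   enzyme_multipliers = mult, seed = as.integer(seed)),
              class = "virtual_individual")
  })
}

#' Reference individual with deterministic physiology
#'
#' The 73 kg reference physiology with all enzyme multipliers fixed at 1;
#' used for representative-individual simulations (genotype comparisons,
#' sensitivity analysis, fitting).
#'
#' @param weight body weight in kg (physiology is rescaled
#'   allometrically).
#' @return a `virtual_individual`.
#' @export
reference_individual <- function(weight = REFERENCE_WEIGHT_KG) {
  phys <- reference_physiology()
  vol_scale <- weight / REFERENCE_WEIGHT_KG
  flow_scale <- (weight / REFERENCE_WEIGHT_KG)^0.75
  volumes <- stats::setNames(phys$volume_L * vol_scale, phys$organ)
  perfused <- !is.na(phys$flow_L_min)
  flows <- stats::setNames(phys$flow_L_min[perfused] * flow_scale,
                           phys$organ[perfused])
  structure(list(sex = "M", age = 30, weight = weight,
                 organ_volumes = volumes, blood_flows = flows,
                 enzyme_multipliers = c(CYP2D6 = 1, CYP2C19 = 1),
                 seed = NA_integer_),
            class = "virtual_individual")
}

#' Build a virtual population
#'
#' @param spec a [demographic_spec()]; `spec$n` individuals are drawn.
#' @param seed integer seed; individual i is drawn with derived seed
#'   `seed + i - 1`.
#' @return list of `virtual_individual` objects.
#' @export
build_population <- function(spec, seed) {
  stopifnot(inherits(spec, "demographic_spec"))
  lapply(seq_len(spec$n), function(i) sample_individual(spec, seed + i - 1))
}

#' Superimpose proportional lognormal residual error on a profile
#'
#' Multiplies each model concentration by an independent lognormal factor
#' with median 1 and coefficient of variation `cv`; `cv = 0` returns the
#' input unchanged. Used to create synthetic "observed" datasets for
#' parameter-recovery studies.
#'
#' @param profile data.frame with columns `time_h`, `conc_nmol_L`.
#' @param cv proportional residual coefficient of variation, `>= 0`.
#' @param seed integer seed.
#' @return data.frame like `profile` with noisy `conc_nmol_L`, plus
#'   attributes `cv` and `seed`.
#' @export
generate_observed_profile <- function(profile, cv, seed) {
  stopifnot(is.data.frame(profile),
            all(c("time_h", "conc_nmol_L") %in% names(profile)))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  out <- profile
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    out$conc_nmol_L <- with_seed(seed, {
      profile$conc_nmol_L *
        stats::rlnorm(nrow(profile), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  attr(out, "cv") <- cv
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write / read a population as delimited text
#'
#' One row per individual; header comments record the seed and spec.
#'
#' @param population list of `virtual_individual`.
#' @param path output file.
#' @param seed seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path, seed = NA) {
  rows <- do.call(rbind, lapply(seq_along(population), function(i) {
    ind <- population[[i]]
    data.frame(id = i, sex = ind$sex, age_yr = ind$age,
               weight_kg = ind$weight,
               cyp2d6_mult = ind$enzyme_multipliers[["CYP2D6"]],
               cyp2c19_mult = ind$enzyme_multipliers[["CYP2C19"]],
               seed = ind$seed)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# doxpbpk virtual population; n=%d; seed=%s",
                       length(population), as.character(seed)),
               "# columns: id sex age_yr weight_kg cyp2d6_mult cyp2c19_mult seed"),
             con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
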