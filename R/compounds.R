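# Compound parameterisation and tissue-to-plasma partitioning.
#
# Two partition methods are implemented behind a single dispatch:
#  * rodgers_rowland — the mechanistic equations for moderate-to-strong
#    bases (intracellular ionisation + acidic-phospholipid association,
#    with the association constant back-calculated from blood-cell
#    partitioning), falling back to the neutral-compound form with a
#    residual protein-association term otherwise;
#  * schmitt — a membrane-composition method where neutral and ionised
#    species carry different affinities for neutral lipid, neutral
#    phospholipid and acidic phospholipid, plus a protein term.
# Both read the same bundled tissue composition table.

PH_PLASMA <- 7.4
PH_INTRACELL <- 7.0
PH_BLOOD_CELL <- 7.22
HEMATOCRIT <- 0.45

#' Construct a compound parameter set
#'
#' @param name compound name.
#' @param molecular_weight g/mol.
#' @param log_p octanol/water log partition coefficient.
#' @param pka acid dissociation constant (negative log).
#' @param is_base `TRUE` for a basic centre, `FALSE` for acidic.
#' @param fraction_unbound unbound fraction in plasma (0, 1].
#' @param solubility_mg_L aqueous solubility, mg/L at `solubility_ph`.
#' @param solubility_ph pH at which solubility is stated.
#' @param intestinal_permeability_cm_min specific intestinal permeability,
#'   cm/min.
#' @param organ_permeability_cm_min specific organ permeability, cm/min.
#' @param partition_method `"rodgers_rowland"` or `"schmitt"`.
#' @param pathways named list of enzyme pathways built with
#'   [enzyme_pathway()]; names are enzyme identifiers.
#' @param total_hepatic_clearance_L_min optional intrinsic hepatic
#'   clearance (L/min, referenced to unbound liver water concentration)
#'   lumping elimination routes not modelled as explicit pathways.
#' @param blood_plasma_ratio blood:plasma concentration ratio (default 1).
#' @param cyp2d6_kcat_by_phenotype optional named numeric vector/list of
#'   CYP2D6 turnover numbers (1/min) by phenotype.
#' @return object of class `compound_parameters`.
#' @export
compound_parameters <- function(name,
                                molecular_weight,
                                log_p,
                                pka,
                                is_base = TRUE,
                                fraction_unbound,
                                solubility_mg_L,
                                solubility_ph = 7.0,
                                intestinal_permeability_cm_min,
                                organ_permeability_cm_min,
                                partition_method = c("rodgers_rowland",
                                                     "schmitt"),
                                pathways = list(),
                                total_hepatic_clearance_L_min = NULL,
                                blood_plasma_ratio = 1.0,
                                cyp2d6_kcat_by_phenotype = NULL) {
  partition_method <- match.arg(partition_method)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molecular_weight) || molecular_weight <= 0) {
    stop("molecular_weight must be > 0", call. = FALSE)
  }
  if (!is.numeric(fraction_unbound) ||
      fraction_unbound <= 0 || fraction_unbound > 1) {
    stop("fraction_unbound must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(solubility_mg_L) || solubility_mg_L <= 0) {
    stop("solubility_mg_L must be > 0", call. = FALSE)
  }
  if (intestinal_permeability_cm_min <= 0 ||
      organ_permeability_cm_min <= 0) {
    stop("permeabilities must be > 0", call. = FALSE)
  }
  if (!is.null(total_hepatic_clearance_L_min) &&
      total_hepatic_clearance_L_min < 0) {
    stop("total_hepatic_clearance_L_min must be >= 0", call. = FALSE)
  }
  for (p in pathways) {
    if (!inherits(p, "enzyme_pathway")) {
      stop("pathways must be built with enzyme_pathway()", call. = FALSE)
    }
  }
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    log_p = log_p,
    pka = pka,
    is_base = isTRUE(is_base),
    fraction_unbound = fraction_unbound,
    solubility_mg_L = solubility_mg_L,
    solubility_ph = solubility_ph,
    intestinal_permeability_cm_min = intestinal_permeability_cm_min,
    organ_permeability_cm_min = organ_permeability_cm_min,
    partition_method = partition_method,
    pathways = pathways,
    total_hepatic_clearance_L_min = total_hepatic_clearance_L_min,
    blood_plasma_ratio = blood_plasma_ratio,
    cyp2d6_kcat_by_phenotype = cyp2d6_kcat_by_phenotype
  ), class = "compound_parameters")
}

#' Construct a Michaelis-Menten enzyme pathway
#'
#' @param enzyme `"CYP2D6"` or `"CYP2C19"`.
#' @param km_uM Michaelis constant, umol/L.
#' @param kcat_per_min turnover number, 1/min; 0 encodes an absent (poor
#'   metaboliser) pathway.
#' @param reference_concentration_uM hepatic reference enzyme
#'   concentration, umol/L.
#' @param product `"metabolite"` if the pathway forms the tracked
#'   metabolite mole-for-mole, `"inactive"` otherwise.
#' @return object of class `enzyme_pathway`.
#' @export
enzyme_pathway <- function(enzyme = c("CYP2D6", "CYP2C19"),
                           km_uM, kcat_per_min,
                           reference_concentration_uM,
                           product = c("inactive", "metabolite")) {
  enzyme <- match.arg(enzyme)
  product <- match.arg(product)
  if (km_uM <= 0) stop("km_uM must be > 0", call. = FALSE)
  if (kcat_per_min < 0) stop("kcat_per_min must be >= 0", call. = FALSE)
  if (reference_concentration_uM <= 0) {
    stop("reference_concentration_uM must be > 0", call. = FALSE)
  }
  structure(list(enzyme = enzyme, km_uM = km_uM,
                 kcat_per_min = kcat_per_min,
                 reference_concentration_uM = reference_concentration_uM,
                 product = product),
            class = "enzyme_pathway")
}

#' Load a compound parameter file
#'
#' Reads a flat key-value YAML compound file (the bundled `doxepin.yaml`
#' and `nordoxepin.yaml` carry the model input values).
#'
#' @param name_or_path `"doxepin"`, `"nordoxepin"`, or a path to a
#'   compound YAML file.
#' @return a `compound_parameters` object.
#' @export
load_compound <- function(name_or_path) {
  path <- if (name_or_path %in% c("doxepin", "nordoxepin")) {
    extdata_path(paste0(name_or_path, ".yaml"))
  } else name_or_path
  if (!file.exists(path)) {
    stop("compound file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  pathways <- lapply(names(y$pathways %||% list()), function(enz) {
    p <- y$pathways[[enz]]
    enzyme_pathway(enzyme = enz, km_uM = p$km_uM,
                   kcat_per_min = p$kcat_per_min,
                   reference_concentration_uM = p$reference_concentration_uM,
                   product = p$product)
  })
  names(pathways) <- names(y$pathways %||% list())
  compound_parameters(
    name = y$name,
    molecular_weight = y$molecular_weight,
    log_p = y$log_p,
    pka = y$pka,
    is_base = y$is_base %||% TRUE,
    fraction_unbound = y$fraction_unbound,
    solubility_mg_L = y$solubility_mg_L,
    solubility_ph = y$solubility_ph %||% 7.0,
    intestinal_permeability_cm_min = y$intestinal_permeability_cm_min,
    organ_permeability_cm_min = y$organ_permeability_cm_min,
    partition_method = y$partition_method,
    pathways = pathways,
    total_hepatic_clearance_L_min = y$total_hepatic_clearance_L_min,
    blood_plasma_ratio = y$blood_plasma_ratio %||% 1.0,
    cyp2d6_kcat_by_phenotype = y$cyp2d6_kcat_by_phenotype
  )
}

#' @export
print.compound_parameters <- function(x, ...) {
  cat("<compound_parameters>", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol, logP %.2f, pKa %.2f (%s), fu %.2f\n",
              x$molecular_weight, x$log_p, x$pka,
              if (x$is_base) "base" else "acid", x$fraction_unbound))
  cat(sprintf("  partition method: %s; pathways: %s\n",
              x$partition_method,
              paste(names(x$pathways), collapse = ", ")))
  invisible(x)
}

#' Fraction of a compound ionised at a given pH
#'
#' Henderson-Hasselbalch ionisation. For a monoprotic base the ionised
#' fraction is 1 / (1 + 10^(pH - pKa)); for an acid, 1 / (1 + 10^(pKa - pH)).
#'
#' @param pka acid dissociation constant.
#' @param ph pH of the medium.
#' @param is_base `TRUE` for a base.
#' @return ionised fraction in \[0, 1\].
#' @examples
#' ionized_fraction(9.76, 7.4, is_base = TRUE)
#' @export
ionized_fraction <- function(pka, ph, is_base = TRUE) {
  stopifnot(is.finite(pka), is.finite(ph))
  if (is_base) 1 / (1 + 10^(ph - pka)) else 1 / (1 + 10^(pka - ph))
}

#' Bundled tissue composition table
#'
#' @return data.frame of per-tissue composition fractions (see the header
#'   of `inst/extdata/tissue_composition.csv` for provenance and units).
#' @export
tissue_composition <- function() {
  if (is.null(.doxpbpk_env$tissue_composition)) {
    .doxpbpk_env$tissue_composition <-
      read_bundled_csv("tissue_composition.csv")
  }
  .doxpbpk_env$tissue_composition
}

tissue_row <- function(tissues, name) {
  i <- match(name, tissues$tissue)
  if (is.na(i)) {
    stop("tissue composition table has no entry for tissue: ", name,
         call. = FALSE)
  }
  tissues[i, ]
}

# Rodgers-Rowland moderate-to-strong base equation for one tissue.
# X terms are the intracellular-to-plasma ratios of (neutral + ionised)
# species implied by the pH gradient.
rr_base_kpu <- function(row, P, pka, fu, bp_ratio, tissues) {
  den <- 1 + 10^(pka - PH_PLASMA)
  x_iw <- (1 + 10^(pka - PH_INTRACELL)) / den
  lipid <- (P * row$f_nl + (0.3 * P + 0.7) * row$f_np) / den
  ka_ap <- rr_kaap(P, pka, fu, bp_ratio, tissues)
  ap <- ka_ap * row$ap_mg_per_g * 10^(pka - PH_INTRACELL) / den
  row$f_ew + x_iw * row$f_iw + lipid + ap
}

# Acidic-phospholipid association constant back-calculated from blood-cell
# partitioning (Kpu_BC from the blood:plasma ratio and haematocrit).
rr_kaap <- function(P, pka, fu, bp_ratio, tissues) {
  bc <- tissue_row(tissues, "blood_cells")
  den <- 1 + 10^(pka - PH_PLASMA)
  kpu_bc <- (bp_ratio - (1 - HEMATOCRIT)) / (HEMATOCRIT * fu)
  x_bc <- (1 + 10^(pka - PH_BLOOD_CELL)) / den
  lipid_bc <- (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np) / den
  resid <- kpu_bc - x_bc * bc$f_iw - lipid_bc
  ka <- resid * den / (bc$ap_mg_per_g * 10^(pka - PH_BLOOD_CELL))
  max(ka, 0)
}

# Rodgers-Rowland neutral / weak-base form with a residual protein
# association term scaled by the tissue:plasma protein ratio.
rr_neutral_kpu <- function(row, P, fu, tissues) {
  pl <- tissue_row(tissues, "plasma")
  lipid_pl <- P * pl$f_nl + (0.3 * P + 0.7) * pl$f_np
  ka_pr <- max(1 / fu - 1 - lipid_pl, 0)
  ra <- row$f_protein / pl$f_protein
  row$f_ew + row$f_iw + P * row$f_nl + (0.3 * P + 0.7) * row$f_np +
    ka_pr * ra
}

# Membrane-composition (Schmitt-type) method. Species-specific affinities:
# the ionised species partitions 1000x less into neutral (storage) lipid and
# 10x less into phospholipid membrane than the neutral species; cations gain
# a 20-fold electrostatic enhancement at acidic phospholipids. Protein
# affinity follows the published linear regression on the neutral-species
# lipid affinity. Constants are documented in the methods vignette.
schmitt_kpu <- function(row, P, pka, is_base, fu, tissues) {
  has_ion <- is.finite(pka)
  fi <- if (has_ion) ionized_fraction(pka, PH_INTRACELL, is_base) else 0
  fn <- 1 - fi
  m_np <- 0.3 * P + 0.7           # neutral-species phospholipid affinity
  k_nl <- P * (fn + 1e-3 * fi)
  k_np <- m_np * (fn + 0.1 * fi)
  k_ap <- if (is_base) m_np * (fn + 20 * 0.1 * fi) else k_np
  k_prot <- 0.163 + 0.0221 * P * fn
  # cell-water accumulation from the pH gradient (ion trapping for bases)
  w_iw <- if (has_ion && is_base) {
    (1 + 10^(pka - PH_INTRACELL)) / (1 + 10^(pka - PH_PLASMA))
  } else if (has_ion) {
    (1 + 10^(PH_INTRACELL - pka)) / (1 + 10^(PH_PLASMA - pka))
  } else 1
  f_ap <- row$ap_mg_per_g / 1000  # mg/g ~ fraction
  row$f_ew + w_iw * row$f_iw + k_nl * row$f_nl + k_np * row$f_np +
    k_ap * f_ap + k_prot * row$f_protein
}

#' Tissue-to-plasma partition coefficients
#'
#' Computes the Kp map for every organ in the model topology with the
#' method named in `compound$partition_method`.
#'
#' @param compound a `compound_parameters` object.
#' @param tissues tissue composition table; defaults to the bundled table.
#' @param organs character vector of organs to compute; defaults to the
#'   standard model topology.
#' @return named numeric vector of Kp values (plasma-referenced), all > 0.
#' @export
calc_partition_coefficients <- function(compound,
                                        tissues = tissue_composition(),
                                        organs = model_organs()) {
  stopifnot(inherits(compound, "compound_parameters"))
  P <- 10^compound$log_p
  fu <- compound$fraction_unbound
  strong_base <- compound$is_base && is.finite(compound$pka) &&
    compound$pka >= 7
  kp <- vapply(organs, function(org) {
    row <- tissue_row(tissues, org)
    kpu <- if (compound$partition_method == "rodgers_rowland") {
      if (strong_base) {
        rr_base_kpu(row, P, compound$pka, fu,
                    compound$blood_plasma_ratio, tissues)
      } else {
        rr_neutral_kpu(row, P, fu, tissues)
      }
    } else {
      schmitt_kpu(row, P, compound$pka, compound$is_base, fu, tissues)
    }
    kpu * fu
  }, numeric(1))
  if (any(!is.finite(kp)) || any(kp <= 0)) {
    stop("partition coefficient calculation produced non-positive Kp",
         call. = FALSE)
  }
  kp
}

#' Organs of the standard whole-body topology
#'
#' Thirteen perfusion-limited organs; arterial/venous blood and lung are
#' handled separately by the engine (lung uses its own Kp).
#' @return character vector of organ names.
#' @export
model_organs <- function() {
  c("lung", "brain", "heart", "kidney", "liver", "gut", "spleen",
    "stomach", "muscle", "adipose", "skin", "bone", "rest")
}
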