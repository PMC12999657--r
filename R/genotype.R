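# CYP2D6 activity-score / phenotype handling.
#
# Phenotype classification follows the 2019 CPIC/DPWG consensus on the sum
# of the two allele activity scores x: PM at x = 0, IM for 0 < x < 1.25,
# NM for 1.25 <= x <= 2.25, UM for x > 2.5. Scores in the unassigned gap
# (2.25, 2.5] are classified NM with a warning rather than inventing a
# fifth category.

CYP2D6_PHENOTYPES <- c("UM", "NM", "IM", "PM")

# Activity scores of representative alleles.
CYP2D6_ALLELE_SCORES <- c(
  "*1" = 1.0, "*2" = 1.0, "*27" = 1.0, "*33" = 1.0,
  "*17" = 0.5, "*31" = 0.5, "*49" = 0.5,
  "*10" = 0.25,
  "*3" = 0, "*4" = 0, "*5" = 0, "*6" = 0, "*36" = 0
)

#' CYP2D6 phenotype from an activity score
#'
#' @param x activity score (sum of the two allele scores), `x >= 0`.
#' @return one of `"UM"`, `"NM"`, `"IM"`, `"PM"` per element of `x`.
#'   Scores in the consensus gap (2.25, 2.5\] return `"NM"` with a warning.
#' @examples
#' phenotype_from_activity_score(c(3, 2, 1, 0))
#' @export
phenotype_from_activity_score <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("activity score must be finite numeric", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("activity score must be >= 0", call. = FALSE)
  }
  out <- character(length(x))
  out[x == 0] <- "PM"
  out[x > 0 & x < 1.25] <- "IM"
  out[x >= 1.25 & x <= 2.25] <- "NM"
  out[x > 2.5] <- "UM"
  gap <- x > 2.25 & x <= 2.5
  if (any(gap)) {
    out[gap] <- "NM"
    warning("activity score(s) ", paste(x[gap], collapse = ", "),
            " fall in the unassigned consensus gap (2.25, 2.5]; ",
            "classified as NM", call. = FALSE)
  }
  out
}

#' CYP2D6 activity score from an allele pair
#'
#' Convenience summation over the bundled representative allele scores.
#'
#' @param alleles character vector of two star alleles, e.g.
#'   `c("*1", "*4")`.
#' @return numeric activity score.
#' @export
activity_score_from_alleles <- function(alleles) {
  stopifnot(is.character(alleles))
  unknown <- setdiff(alleles, names(CYP2D6_ALLELE_SCORES))
  if (length(unknown)) {
    stop("no activity score on record for allele(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(CYP2D6_ALLELE_SCORES[alleles])
}

#' Genotype-specific CYP2D6 turnover number
#'
#' Exact lookup of the phenotype-specific kcat (1/min) for a compound;
#' `"non_genotyped"` returns the base (development-population) value.
#'
#' @param compound `"doxepin"`, `"nordoxepin"`, or a
#'   `compound_parameters` object carrying a phenotype kcat table.
#' @param phenotype `"UM"`, `"NM"`, `"IM"`, `"PM"` or `"non_genotyped"`.
#' @return kcat in 1/min.
#' @examples
#' kcat_for("doxepin", "PM")
#' kcat_for("nordoxepin", "NM")
#' @export
kcat_for <- function(compound, phenotype) {
  tab <- if (inherits(compound, "compound_parameters")) {
    compound$cyp2d6_kcat_by_phenotype
  } else if (is.character(compound) &&
             compound %in% c("doxepin", "nordoxepin")) {
    load_compound(compound)$cyp2d6_kcat_by_phenotype
  } else {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  if (is.null(tab)) {
    stop("compound carries no CYP2D6 phenotype kcat table", call. = FALSE)
  }
  if (!phenotype %in% names(tab)) {
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  }
  as.numeric(tab[[phenotype]])
}

#' Construct a CYP2D6 genotype profile
#'
#' Either an activity score or an explicit phenotype may be given; the
#' kcat overrides for both compounds are resolved from the bundled
#' phenotype tables. A PM profile carries kcat 0 for both compounds.
#'
#' @param activity_score optional activity score (classified via
#'   [phenotype_from_activity_score()]).
#' @param phenotype optional explicit phenotype; `"non_genotyped"` selects
#'   the base (development) turnover numbers.
#' @param alleles optional character pair of star alleles, summed via
#'   [activity_score_from_alleles()].
#' @return object of class `genotype_profile` with fields
#'   `activity_score`, `phenotype`, `kcat_overrides`.
#' @export
genotype_profile <- function(activity_score = NULL, phenotype = NULL,
                             alleles = NULL) {
  if (!is.null(alleles)) {
    activity_score <- activity_score_from_alleles(alleles)
  }
  if (is.null(phenotype)) {
    if (is.null(activity_score)) {
      stop("give an activity score, alleles, or a phenotype",
           call. = FALSE)
    }
    phenotype <- phenotype_from_activity_score(activity_score)
  } else {
    if (!phenotype %in% c(CYP2D6_PHENOTYPES, "non_genotyped")) {
      stop("unknown phenotype: ", phenotype, call. = FALSE)
    }
  }
  overrides <- c(doxepin = kcat_for("doxepin", phenotype),
                 nordoxepin = kcat_for("nordoxepin", phenotype))
  structure(list(activity_score = activity_score,
                 phenotype = phenotype,
                 kcat_overrides = overrides),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("<genotype_profile> CYP2D6", x$phenotype)
  if (!is.null(x$activity_score)) {
    cat(sprintf(" (activity score %.2f)", x$activity_score))
  }
  cat("\n  kcat overrides (1/min):",
      paste(names(x$kcat_overrides), x$kcat_overrides,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
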