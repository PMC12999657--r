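# Model-qualification arithmetic: fold error, geometric mean fold error,
# fold-range coverage, and the tabulated goodness-of-fit report.

#' Fold error of a prediction
#'
#' `predicted / observed`, the standard PBPK qualification ratio; a value
#' inside \[0.5, 2\] satisfies the twofold criterion.
#'
#' @param predicted predicted PK value(s), > 0.
#' @param observed observed PK value(s), > 0.
#' @return fold error(s).
#' @examples
#' fold_error(709.02, 692.47)
#' @export
fold_error <- function(predicted, observed) {
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0)) {
    stop("fold_error requires positive finite inputs", call. = FALSE)
  }
  predicted / observed
}

#' Geometric mean fold error
#'
#' `GMFE = 10^(mean(|log10(pred_i / obs_i)|))`; 1.0 is perfect and the
#' statistic is invariant under swapping predicted and observed.
#'
#' @param predicted predicted values, or a data.frame with columns
#'   `predicted` and `observed`.
#' @param observed observed values (ignored when `predicted` is a
#'   data.frame).
#' @return GMFE, a scalar `>= 1`.
#' @examples
#' gmfe(c(2, 1), c(1, 2))
#' @export
gmfe <- function(predicted, observed = NULL) {
  if (is.data.frame(predicted)) {
    observed <- predicted$observed
    predicted <- predicted$predicted
  }
  if (length(predicted) == 0) {
    stop("gmfe requires at least one pair", call. = FALSE)
  }
  fe <- fold_error(predicted, observed)
  10^mean(abs(log10(fe)))
}

#' Fraction of fold errors within a symmetric fold range
#'
#' @param fold_errors numeric vector of fold errors (> 0).
#' @param bound fold bound > 1 (e.g. 2 for the twofold criterion,
#'   1.25 for the 1.25-fold range).
#' @return fraction of entries f with `1/bound <= f <= bound`.
#' @examples
#' coverage_fraction(c(1.0, 1.2, 3.0), 2)
#' @export
coverage_fraction <- function(fold_errors, bound) {
  if (length(fold_errors) == 0) {
    stop("coverage_fraction requires a non-empty list", call. = FALSE)
  }
  if (bound <= 1) stop("bound must be > 1", call. = FALSE)
  if (any(fold_errors <= 0)) {
    stop("fold errors must be positive", call. = FALSE)
  }
  mean(fold_errors >= 1 / bound & fold_errors <= bound)
}

#' Bundled observed/predicted PK reference table
#'
#' The published observed and model-predicted AUC (0-inf), Cmax and Tmax
#' values for doxepin and nordoxepin after a single 75 mg oral doxepin
#' dose, across the non-genotyped development group and the four CYP2D6
#' phenotype groups, with the printed 2 d.p. fold errors.
#'
#' @return data.frame with columns `study`, `compound`, `cyp2d6`,
#'   `metric`, `observed`, `predicted`, `unit`, `fold_error_printed`.
#' @export
reference_pk_values <- function() {
  read_bundled_csv("reference_pk_values.csv")
}

#' Goodness-of-fit evaluation table
#'
#' Computes the fold error for every predicted/observed pair and the GMFE
#' per compound and metric. Displayed fold errors are rounded half-up to
#' 2 d.p., matching the conventional presentation.
#'
#' @param pairs data.frame with columns `compound`, `metric`, `observed`,
#'   `predicted` (extra columns are carried through).
#' @return data.frame of `pairs` plus `fold_error` and rounded
#'   `fold_error_2dp`, with a `gmfe` attribute: data.frame of GMFE per
#'   (compound, metric).
#' @export
evaluation_table <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  required <- c("compound", "metric", "observed", "predicted")
  missing <- setdiff(required, names(pairs))
  if (length(missing)) {
    stop("pairs is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- pairs
  if (nrow(pairs) == 0) {
    out$fold_error <- numeric(0)
    out$fold_error_2dp <- numeric(0)
    attr(out, "gmfe") <- data.frame(compound = character(0),
                                    metric = character(0),
                                    gmfe = numeric(0))
    return(out)
  }
  out$fold_error <- fold_error(pairs$predicted, pairs$observed)
  out$fold_error_2dp <- round_half_up(out$fold_error, 2)
  groups <- unique(out[, c("compound", "metric")])
  groups$gmfe <- vapply(seq_len(nrow(groups)), function(i) {
    sel <- out$compound == groups$compound[i] &
      out$metric == groups$metric[i]
    gmfe(out$predicted[sel], out$observed[sel])
  }, numeric(1))
  attr(out, "gmfe") <- groups
  out
}

#' Format an evaluation table as aligned plain text
#'
#' @param tab output of [evaluation_table()].
#' @return character vector of report lines.
#' @export
format_evaluation_table <- function(tab) {
  header <- sprintf("%-12s %-10s %-6s %12s %12s %10s",
                    "compound", "group", "metric", "observed",
                    "predicted", "fold error")
  if (nrow(tab) == 0) return(header)
  group <- if ("cyp2d6" %in% names(tab)) tab$cyp2d6 else ""
  lines <- sprintf("%-12s %-10s %-6s %12.2f %12.2f %10.2f",
                   tab$compound, group, tab$metric, tab$observed,
                   tab$predicted, tab$fold_error_2dp)
  g <- attr(tab, "gmfe")
  glines <- sprintf("GMFE %-12s %-6s %.2f", g$compound, g$metric,
                    round_half_up(g$gmfe, 2))
  c(header, lines, "", glines)
}

#' Evaluate predictions against observations
#'
#' Joins a predictions table to an observations table on the identifying
#' columns and returns the [evaluation_table()]. Rows present in only one
#' of the inputs raise an error listing the unmatched labels.
#'
#' @param predictions data.frame with columns `compound`, `cyp2d6`,
#'   `metric`, `predicted`.
#' @param observations data.frame with columns `compound`, `cyp2d6`,
#'   `metric`, `observed`.
#' @return evaluation table (see [evaluation_table()]).
#' @export
evaluate_predictions <- function(predictions, observations) {
  keys <- c("compound", "cyp2d6", "metric")
  stopifnot(all(keys %in% names(predictions)),
            all(keys %in% names(observations)))
  label <- function(d) do.call(paste, c(d[keys], sep = "/"))
  lp <- label(predictions); lo <- label(observations)
  unmatched <- c(setdiff(lp, lo), setdiff(lo, lp))
  if (length(unmatched)) {
    stop("unmatched evaluation rows: ",
         paste(unmatched, collapse = "; "), call. = FALSE)
  }
  merged <- merge(predictions, observations, by = keys, sort = FALSE)
  evaluation_table(merged)
}
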