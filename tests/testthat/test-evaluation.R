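# Fold error, GMFE, coverage and the goodness-of-fit report.

ref_tab <- reference_pk_values()

test_that("fold error is the predicted/observed ratio", {
  expect_equal(round_half_up(fold_error(709.02, 692.47), 2), 1.02)
  expect_equal(round_half_up(fold_error(4640.32, 1820.00), 2), 2.55)
  expect_equal(fold_error(3.7, 3.7), 1.0)
  # multiplicative: fold_error(a x, x) = a
  expect_equal(fold_error(2.5 * 7, 7), 2.5)
  expect_error(fold_error(-1, 2), "positive")
  expect_error(fold_error(1, 0), "positive")
})

test_that("every printed fold error in the reference table is reproduced at 2 d.p.", {
  recomputed <- round_half_up(
    fold_error(ref_tab$predicted, ref_tab$observed), 2)
  expect_equal(recomputed, ref_tab$fold_error_printed)
  # table structure sanity: 10 AUC + 10 Cmax + 2 Tmax rows
  expect_equal(sum(ref_tab$metric == "AUC"), 10)
  expect_equal(sum(ref_tab$metric == "Cmax"), 10)
  expect_equal(sum(ref_tab$metric == "Tmax"), 2)
})

test_that("GMFE matches its anchors and invariances", {
  geno <- ref_tab[ref_tab$compound == "doxepin" &
                    ref_tab$metric == "AUC" &
                    ref_tab$cyp2d6 != "none", ]
  expect_equal(round_half_up(gmfe(geno$predicted, geno$observed), 2),
               1.13)
  expect_equal(gmfe(c(5, 9), c(5, 9)), 1.0)
  expect_equal(gmfe(c(2, 1), c(1, 2)), 2.0)
  # invariant under swapping predicted and observed
  expect_equal(gmfe(geno$predicted, geno$observed),
               gmfe(geno$observed, geno$predicted))
  expect_gte(gmfe(runif(5, 0.5, 2), runif(5, 0.5, 2)), 1)
  expect_error(gmfe(numeric(0), numeric(0)), "at least one")
})

test_that("coverage fraction counts entries inside the fold range", {
  expect_equal(coverage_fraction(c(1.0, 1.2, 3.0), 2), 2 / 3)
  expect_equal(coverage_fraction(c(1.0, 1.2, 3.0), 1e9), 1.0)
  geno_fe <- c(1.27, 1.11, 1.01, 1.15)
  expect_equal(coverage_fraction(geno_fe, 2), 1.0)
  # the reciprocal side counts too
  expect_equal(coverage_fraction(c(0.4, 0.6, 1.5), 2), 2 / 3)
  expect_error(coverage_fraction(numeric(0), 2), "non-empty")
  expect_error(coverage_fraction(c(1, 2), 0.9), "bound")
})

test_that("evaluation tables reproduce printed cells and group GMFEs", {
  tab <- evaluation_table(ref_tab)
  expect_equal(tab$fold_error_2dp, ref_tab$fold_error_printed)
  g <- attr(tab, "gmfe")
  dox_auc <- g$gmfe[g$compound == "doxepin" & g$metric == "AUC"]
  expect_gt(dox_auc, 1)
  # empty input: header-only table
  empty <- evaluation_table(ref_tab[0, ])
  expect_equal(nrow(empty), 0)
  expect_length(format_evaluation_table(empty), 1)
  # single-metric input: single-section table
  one <- evaluation_table(ref_tab[ref_tab$metric == "Tmax", ])
  expect_equal(nrow(attr(one, "gmfe")), 2)
})

test_that("prediction/observation joins reject unmatched labels", {
  preds <- data.frame(compound = "doxepin", cyp2d6 = c("NM", "IM"),
                      metric = "AUC", predicted = c(500, 1000))
  obs <- data.frame(compound = "doxepin", cyp2d6 = c("NM", "PM"),
                    metric = "AUC", observed = c(398, 2291))
  expect_error(evaluate_predictions(preds, obs), "IM")
  obs2 <- data.frame(compound = "doxepin", cyp2d6 = c("NM", "IM"),
                     metric = "AUC", observed = c(398, 933))
  tab <- evaluate_predictions(preds, obs2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$fold_error, tab$predicted / tab$observed)
  single <- evaluate_predictions(preds[1, ], obs2[1, ])
  expect_equal(nrow(single), 1)
})
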