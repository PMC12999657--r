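# CYP2D6 activity-score classification and phenotype kcat lookups.

test_that("consensus activity-score classification reproduces the study scores", {
  expect_identical(phenotype_from_activity_score(0), "PM")
  expect_identical(phenotype_from_activity_score(1.0), "IM")
  expect_identical(phenotype_from_activity_score(2.0), "NM")
  expect_identical(phenotype_from_activity_score(3.0), "UM")
  expect_identical(phenotype_from_activity_score(c(3, 2, 1, 0)),
                   c("UM", "NM", "IM", "PM"))
})

test_that("classification boundaries follow the consensus rule", {
  expect_identical(phenotype_from_activity_score(1.25), "NM")
  expect_identical(phenotype_from_activity_score(2.25), "NM")
  expect_identical(phenotype_from_activity_score(1.24), "IM")
  expect_identical(phenotype_from_activity_score(2.51), "UM")
  expect_identical(phenotype_from_activity_score(0.25), "IM")
})

test_that("the unassigned gap (2.25, 2.5] classifies NM with a warning", {
  expect_warning(ph <- phenotype_from_activity_score(2.4), "gap")
  expect_identical(ph, "NM")
  expect_warning(phenotype_from_activity_score(2.5), "gap")
})

test_that("negative or non-finite activity scores are rejected", {
  expect_error(phenotype_from_activity_score(-0.5), ">= 0")
  expect_error(phenotype_from_activity_score(NA_real_), "finite")
})

test_that("phenotype kcat lookups match the model input tables", {
  expect_equal(kcat_for("doxepin", "PM"), 0)
  expect_equal(kcat_for("doxepin", "UM"), 505)
  expect_equal(kcat_for("doxepin", "NM"), 299)
  expect_equal(kcat_for("doxepin", "IM"), 85)
  expect_equal(kcat_for("doxepin", "non_genotyped"), 260)
  expect_equal(kcat_for("nordoxepin", "NM"), 165)
  expect_equal(kcat_for("nordoxepin", "UM"), 505)
  expect_equal(kcat_for("nordoxepin", "IM"), 30)
  expect_equal(kcat_for("nordoxepin", "PM"), 0)
  expect_equal(kcat_for("nordoxepin", "non_genotyped"), 160)
  expect_error(kcat_for("aspirin", "NM"), "unknown compound")
  expect_error(kcat_for("doxepin", "XX"), "unknown phenotype")
})

test_that("kcat is non-decreasing along PM -> IM -> NM -> UM", {
  for (cpd in c("doxepin", "nordoxepin")) {
    kc <- vapply(c("PM", "IM", "NM", "UM"), kcat_for, numeric(1),
                 compound = cpd)
    expect_true(all(diff(kc) >= 0), info = cpd)
  }
})

test_that("allele scores sum to the activity score", {
  expect_equal(activity_score_from_alleles(c("*1", "*1")), 2.0)
  expect_equal(activity_score_from_alleles(c("*1", "*4")), 1.0)
  expect_equal(activity_score_from_alleles(c("*4", "*4")), 0)
  expect_equal(activity_score_from_alleles(c("*10", "*17")), 0.75)
  expect_error(activity_score_from_alleles(c("*1", "*999")), "\\*999")
})

test_that("genotype profiles resolve consistent kcat overrides", {
  pm <- genotype_profile(activity_score = 0)
  expect_identical(pm$phenotype, "PM")
  expect_equal(unname(pm$kcat_overrides), c(0, 0))
  um <- genotype_profile(alleles = c("*1", "*1"), phenotype = NULL)
  expect_identical(um$phenotype, "NM")
  expect_equal(um$kcat_overrides[["doxepin"]], 299)
  base <- genotype_profile(phenotype = "non_genotyped")
  expect_equal(unname(base$kcat_overrides), c(260, 160))
})
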