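# PBPK engine: rate law, model building, mass balance, oracles.

test_that("Michaelis-Menten rate law hits its anchors", {
  expect_equal(michaelis_menten_rate(260, 0.40, 88, 0, 1), 0)
  expect_equal(michaelis_menten_rate(0, 0.40, 88, 1, 1), 0)
  # hand arithmetic: 260 * 0.40 * 1 / (88 + 1) * 1e3
  expect_equal(michaelis_menten_rate(260, 0.40, 88, 1, 1), 1168.5,
               tolerance = 1e-4)
  # half the saturated rate at c = Km
  vmax <- 260 * 0.40 * 1 * 1e3
  expect_equal(michaelis_menten_rate(260, 0.40, 88, 88, 1), vmax / 2)
  # saturation limit
  expect_equal(michaelis_menten_rate(260, 0.40, 88, 1e9, 1), vmax,
               tolerance = 1e-6)
})

test_that("build_model applies genotype overrides and validates structure", {
  pm <- build_model(dox_fix, nor_fix, ref_ind,
                    genotype_profile(phenotype = "PM"), dose_regimen(75))
  kcats <- vapply(pm$elim, function(e) e$kcat %||% NA_real_, numeric(1))
  labels <- vapply(pm$elim, `[[`, character(1), "label")
  expect_equal(kcats[labels == "doxepin_CYP2D6"], 0, ignore_attr = TRUE)
  expect_equal(kcats[labels == "nordoxepin_CYP2D6"], 0,
               ignore_attr = TRUE)
  base <- build_model(dox_fix, nor_fix, ref_ind, NULL, dose_regimen(75))
  kb <- vapply(base$elim, function(e) e$kcat %||% NA_real_, numeric(1))
  lb <- vapply(base$elim, `[[`, character(1), "label")
  expect_equal(kb[lb == "doxepin_CYP2D6"], 260, ignore_attr = TRUE)
  expect_equal(kb[lb == "nordoxepin_CYP2D6"], 160, ignore_attr = TRUE)
  # exactly one metabolite-forming pathway
  products <- vapply(base$elim, function(e) !is.na(e$product), logical(1))
  expect_equal(sum(products), 1L)
  # misconfiguration: metabolite-forming pathway on the metabolite
  bad_met <- nor_fix
  bad_met$pathways$CYP2D6$product <- "metabolite"
  expect_error(build_model(dox_fix, bad_met, ref_ind, NULL,
                           dose_regimen(75)), "metabolite")
  # parent missing the demethylation pathway
  bad_par <- dox_fix
  bad_par$pathways$CYP2C19 <- NULL
  expect_error(build_model(bad_par, nor_fix, ref_ind, NULL,
                           dose_regimen(75)), "CYP2C19")
})

test_that("flows balance at the venous and arterial nodes", {
  m <- build_model(dox_fix, nor_fix, ref_ind, NULL, dose_regimen(75))
  Q <- m$Q
  inflow <- colSums(Q)
  outflow <- rowSums(Q)
  perfused <- m$compartments
  expect_equal(inflow[perfused], outflow[perfused], tolerance = 1e-12)
})

test_that("zero dose gives identically zero profiles", {
  m <- build_model(dox_fix, nor_fix, ref_ind, NULL, NULL)
  s <- simulate_model(m, duration_h = 24)
  expect_true(all(s$profiles$doxepin$conc_nmol_L == 0))
  expect_true(all(s$profiles$nordoxepin$conc_nmol_L == 0))
})

test_that("PM genotype eliminates nothing through CYP2D6", {
  s <- sim_genotype("PM", duration_h = 48)
  expect_true(all(s$cumulative$doxepin_CYP2D6 == 0))
  expect_true(all(s$cumulative$nordoxepin_CYP2D6 == 0))
  # demethylation still runs and feeds the metabolite mole-for-mole
  expect_gt(max(s$cumulative$doxepin_CYP2C19), 0)
})

test_that("mass balance closes to < 1e-6 relative at every output time", {
  s <- sim_genotype("NM", duration_h = 96)
  expect_lt(max(s$balance$rel_err_doxepin), 1e-6)
  expect_lt(max(s$balance$rel_err_nordoxepin), 1e-6)
})

test_that("the engine reproduces the Bateman closed form within 0.1%", {
  case <- bateman_case()
  m <- one_compartment_model(case$V, case$CL, case$ka, case$D)
  s <- simulate_model(m, duration_h = 24, output_grid_h = case$grid_h)
  expected <- bateman_closed_form(case)
  rel <- abs(s$profiles$drug$conc_nmol_L - expected) / expected
  expect_lt(max(rel), 1e-3)
})

test_that("genotype ordering of exposures mirrors metabolic capacity", {
  sims <- lapply(c(PM = "PM", IM = "IM", NM = "NM", UM = "UM"),
                 sim_genotype)
  auc_parent <- vapply(sims, function(s) {
    suppressWarnings(nca(s$profiles$doxepin)$auc_inf)
  }, numeric(1))
  auc_met <- vapply(sims, function(s) {
    suppressWarnings(nca(s$profiles$nordoxepin)$auc_inf)
  }, numeric(1))
  expect_true(auc_parent[["PM"]] > auc_parent[["IM"]])
  expect_true(auc_parent[["IM"]] > auc_parent[["NM"]])
  expect_true(auc_parent[["NM"]] > auc_parent[["UM"]])
  expect_true(auc_met[["PM"]] > auc_met[["UM"]])
})

test_that("population summaries are order statistics over individuals", {
  spec <- study_demographic_spec("NM", n = 24)
  pop <- build_population(spec, 3)
  psim <- simulate_population(dox_fix, nor_fix, pop,
                              genotype_profile(phenotype = "NM"),
                              dose_regimen(75), duration_h = 48)
  for (nm in names(psim$summary)) {
    s <- psim$summary[[nm]]
    expect_true(all(s$p5 <= s$p95 + 1e-12))
    expect_true(all(s$p5 <= s$mean + 1e-9 * max(s$mean)))
  }
  # degenerate population: identical individuals collapse the spread
  pop1 <- rep(list(reference_individual()), 20)
  d <- simulate_population(dox_fix, nor_fix, pop1,
                           genotype_profile(phenotype = "NM"),
                           dose_regimen(75), duration_h = 24)
  expect_equal(d$summary$doxepin$p5, d$summary$doxepin$mean,
               tolerance = 1e-10)
  expect_equal(d$summary$doxepin$p95, d$summary$doxepin$mean,
               tolerance = 1e-10)
  expect_warning(
    simulate_population(dox_fix, nor_fix, pop1[1:3],
                        genotype_profile(phenotype = "NM"),
                        dose_regimen(75), duration_h = 12),
    "unstable")
  expect_error(simulate_population(dox_fix, nor_fix, list(), NULL,
                                   dose_regimen(75)), "non-empty")
})
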