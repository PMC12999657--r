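# Virtual-individual sampling and synthetic observation noise.

test_that("sampled demographics stay inside the specification ranges", {
  spec <- study_demographic_spec("none")
  for (seed in c(1, 7, 123)) {
    ind <- sample_individual(spec, seed)
    expect_gte(ind$weight, 55); expect_lte(ind$weight, 90)
    expect_gte(ind$age, 22); expect_lte(ind$age, 50)
  }
  # property over random specs
  set.seed(99)
  for (i in 1:10) {
    lo_a <- runif(1, 18, 40); hi_a <- lo_a + runif(1, 1, 30)
    lo_w <- runif(1, 45, 70); hi_w <- lo_w + runif(1, 1, 40)
    spec_i <- demographic_spec(1, 0.5, c(lo_a, hi_a), c(lo_w, hi_w))
    ind <- sample_individual(spec_i, i)
    expect_true(ind$age >= lo_a && ind$age <= hi_a)
    expect_true(ind$weight >= lo_w && ind$weight <= hi_w)
    expect_true(all(ind$organ_volumes > 0))
    expect_true(all(ind$blood_flows > 0))
    expect_true(all(ind$enzyme_multipliers > 0))
    expect_lt(sum(ind$organ_volumes), ind$weight)
  }
})

test_that("sampling is deterministic for a fixed seed and spec", {
  spec <- study_demographic_spec("NM")
  expect_identical(sample_individual(spec, 42), sample_individual(spec, 42))
  p1 <- build_population(spec, 5)
  p2 <- build_population(spec, 5)
  expect_identical(p1, p2)
})

test_that("populations have the requested size and differ across seeds", {
  spec <- study_demographic_spec("none", n = 100)
  pop <- build_population(spec, 1)
  expect_length(pop, 100)
  expect_length(build_population(demographic_spec(1, 0, c(20, 30),
                                                  c(60, 80)), 1), 1)
  w1 <- vapply(build_population(spec, 1), `[[`, numeric(1), "weight")
  w2 <- vapply(build_population(spec, 1000), `[[`, numeric(1), "weight")
  expect_true(any(w1 != w2))
})

test_that("impossible demographic ranges are a configuration error", {
  expect_error(demographic_spec(5, 0, c(40, 20), c(60, 80)), "age_range")
  expect_error(demographic_spec(0, 0, c(20, 40), c(60, 80)), "n")
})

test_that("enzyme abundance multipliers are lognormal with median ~1", {
  spec <- demographic_spec(400, 0, c(20, 40), c(60, 80))
  pop <- build_population(spec, 11)
  m2d6 <- vapply(pop, function(i) i$enzyme_multipliers[["CYP2D6"]],
                 numeric(1))
  expect_equal(median(m2d6), 1, tolerance = 0.1)
  expect_equal(sd(log(m2d6)), log(1.4), tolerance = 0.15)
})

test_that("allometric scaling preserves physiology ratios", {
  heavy <- sample_individual(demographic_spec(1, 0, c(30, 30),
                                              c(90, 90)), 1)
  light <- sample_individual(demographic_spec(1, 0, c(30, 30),
                                              c(60, 60)), 1)
  expect_equal(unname(heavy$organ_volumes / light$organ_volumes),
               rep(90 / 60, length(heavy$organ_volumes)))
  expect_equal(unname(heavy$blood_flows / light$blood_flows),
               rep((90 / 60)^0.75, length(heavy$blood_flows)),
               tolerance = 1e-12)
})

test_that("proportional residual noise has the stated CV and is reproducible", {
  prof <- data.frame(time_h = 1, conc_nmol_L = 100)
  # cv = 0 is the identity
  expect_identical(generate_observed_profile(prof, 0, 1)$conc_nmol_L,
                   prof$conc_nmol_L)
  # Monte-Carlo check of the noise model at one time point
  reps <- vapply(seq_len(10000), function(s) {
    generate_observed_profile(prof, 0.10, s)$conc_nmol_L
  }, numeric(1))
  expect_equal(sd(reps) / mean(reps), 0.10, tolerance = 0.005)
  expect_true(all(reps >= 0))
  # fixed seed reproduces the noise
  expect_identical(generate_observed_profile(prof, 0.1, 7),
                   generate_observed_profile(prof, 0.1, 7))
  expect_error(generate_observed_profile(prof, -0.1, 1), "cv")
})
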