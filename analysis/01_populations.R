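#!/usr/bin/env Rscript
# Stage 1: build the virtual populations.
#
# One population per clinical study group (non-genotyped development group
# plus the four CYP2D6 phenotype groups) at the published group sizes, and
# an n = 100 evaluation population per group for the prediction-interval
# summaries. Writes one delimited file per population under results/.

suppressPackageStartupMessages(library(doxpbpk))

seed <- 20260924
dir.create("results/populations", recursive = TRUE, showWarnings = FALSE)

groups <- c("none", "NM", "IM", "PM", "UM")
for (g in groups) {
  spec <- study_demographic_spec(g)
  pop <- build_population(spec, seed)
  f <- sprintf("results/populations/population_%s_n%d.tsv", g, spec$n)
  write_population(pop, f, seed = seed)
  w <- vapply(pop, `[[`, numeric(1), "weight")
  message(sprintf(
    "group %-4s n=%2d  weight %5.1f-%5.1f kg (spec %.1f-%.1f)  -> %s",
    g, spec$n, min(w), max(w), spec$weight_range[1], spec$weight_range[2],
    f))
  # evaluation population, n = 100, seed offset to keep draws disjoint
  spec100 <- study_demographic_spec(g, n = 100)
  pop100 <- build_population(spec100, seed + 1000)
  write_population(pop100,
                   sprintf("results/populations/population_%s_n100.tsv", g),
                   seed = seed + 1000)
}
message("populations written under results/populations/")
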