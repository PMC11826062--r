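# Speciation: ionic strength, Davies coefficients, pool partitions.

# analytic ionization fractions at unit activity coefficients - the
# independent oracle for the carbonate partition
alpha_dic <- function(ph, ka1, ka2) {
  h <- 10^(-ph)
  denom <- 1 + ka1 / h + ka1 * ka2 / h^2
  c(co2 = 1, hco3 = ka1 / h, co3 = ka1 * ka2 / h^2) / denom
}

test_that("ionic strength sums m z^2 / 2 over major ions, with a configured fallback", {
  expect_equal(ionic_strength(list(major_ions = c("Na+" = 0.01, "Cl-" = 0.01))),
               0.01)
  expect_equal(ionic_strength(list(major_ions = c("Ca+2" = 0.001, "Cl-" = 0.002))),
               0.003)
  expect_equal(ionic_strength(list()), 0.01)
  expect_equal(ionic_strength(list(), run_config(default_ionic_strength = 0.002)),
               0.002)
  # measured organic-acid/DIC analytes ride along when major ions are present
  expect_equal(ionic_strength(list(major_ions = c("Na+" = 0.01, "Cl-" = 0.01),
                                   formate_molal = 2e-3)),
               0.011)
  expect_error(ionic_strength(list(major_ions = c("Na+" = -0.01))), "negative")
})

test_that("Davies coefficients honor limits and the hand-computed value", {
  expect_equal(activity_coefficient(1, 0, 25, DB), 1)
  expect_equal(activity_coefficient(-2, 0, 25, DB), 1)
  expect_equal(activity_coefficient(0, 0.3, 25, DB), 1)  # neutral species
  expect_equal(activity_coefficient(1, 0.01, 25, DB), 0.902, tolerance = 1e-3)
  # charge enters squared: z = +/-2 at the same I
  expect_equal(activity_coefficient(2, 0.05, 25, DB),
               activity_coefficient(-2, 0.05, 25, DB))
  expect_error(activity_coefficient(1, 0.6, 25, DB), "Davies")
  expect_error(activity_coefficient(3, 0.01, 25, DB), "charge")
})

test_that("carbonate partition matches the analytic fractions across pH 2-13", {
  ka1 <- exp(acid_ln_k("carbonic1", 25, DB))
  ka2 <- exp(acid_ln_k("carbonic2", 25, DB))
  g1 <- c("0" = 1, "1" = 1, "2" = 1)
  for (ph in seq(2, 13, by = 0.5)) {
    sp <- speciate_dic(1e-4, ph, 25, g1, DB)
    a <- alpha_dic(ph, ka1, ka2)
    expect_equal(sp$molality, unname(1e-4 * a), tolerance = 1e-12)
  }
  # worked value: DIC 3.4e-5 at pH 11.33 leaves ~3.09e-6 molal bicarbonate
  sp <- speciate_dic(3.4e-5, 11.33, 25, g1, DB)
  expect_equal(sp$molality[sp$species == "HCO3-"], 3.09e-6, tolerance = 0.02)
  # boundary cases
  expect_true(all(speciate_dic(0, 8, 25, g1, DB)$molality == 0))
  expect_true(all(is.na(speciate_dic(NA_real_, 8, 25, g1, DB)$molality)))
  # at pH = pKa2 with gamma = 1 the bicarbonate and carbonate activities match
  pka2 <- acid_pk("carbonic2", 25, DB)
  sp <- speciate_dic(1e-4, pka2, 25, g1, DB)
  expect_equal(sp$activity[sp$species == "HCO3-"],
               sp$activity[sp$species == "CO3-2"], tolerance = 1e-12)
})

test_that("pool mass balance holds to 1e-10 relative with activity corrections", {
  for (seed in 1:25) {
    set.seed(seed)
    total <- 10^runif(1, -6, -2)
    ph <- runif(1, 2, 13)
    t_c <- runif(1, 0, 50)
    i <- runif(1, 0, 0.3)
    g <- c("0" = 1, "1" = activity_coefficient(1, i, t_c, DB),
           "2" = activity_coefficient(2, i, t_c, DB))
    expect_equal(sum(speciate_dic(total, ph, t_c, g, DB)$molality), total,
                 tolerance = 1e-10)
    expect_equal(sum(speciate_monoprotic(total, "formic", ph, t_c,
                                         g[c("0", "1")], DB)$molality),
                 total, tolerance = 1e-10)
    expect_equal(sum(speciate_monoprotic(total, "acetic", ph, t_c,
                                         g[c("0", "1")], DB)$molality),
                 total, tolerance = 1e-10)
  }
})

test_that("monoprotic partition honors mass action", {
  g1 <- c("0" = 1, "1" = 1)
  # pH = pKa: equal acid and anion activities
  pka <- acid_pk("acetic", 25, DB)
  sp <- speciate_monoprotic(1e-5, "acetic", pka, 25, g1, DB)
  expect_equal(sp$activity[1], sp$activity[2], tolerance = 1e-12)
  # hyperalkaline formate pool is almost entirely anion
  sp <- speciate_monoprotic(3e-6, 3.75, 11.33, 25, g1, DB)
  expect_equal(sp$molality[sp$species == "HA"], 7.9e-14, tolerance = 0.02)
  expect_true(all(speciate_monoprotic(0, "formic", 8, 25, g1, DB)$molality == 0))
})

test_that("raising pH never raises neutral-acid activities at fixed totals", {
  phs <- seq(3, 13, by = 0.5)
  fluids <- lapply(phs, function(p) speciate(demo_sample(ph = p), DB))
  for (sp in c("CO2", "HCOOH", "CH3COOH")) {
    a <- vapply(fluids, activity_of, numeric(1), species = sp)
    expect_true(all(diff(a) <= 0), label = sp)
  }
})

test_that("speciate orchestrates pools, carries gases, and propagates nulls", {
  fl <- speciate(demo_sample(ph = 11.5), DB)
  # carbonate dominates bicarbonate above pKa2
  expect_gt(fl$species["CO3-2", "molality"], fl$species["HCO3-", "molality"])
  # neutral dissolved gases carried at measured molality with gamma = 1
  expect_equal(unname(activity_of(fl, "H2")), 2.3e-4)
  expect_equal(fl$species["CH4", "gamma"], 1)
  expect_equal(unname(activity_of(fl, "H2O")), 1)
  expect_equal(unname(activity_of(fl, "H+")), 10^-11.5)
  # a(H+) a(OH-) = Kw at the fluid temperature
  expect_equal(log(activity_of(fl, "H+") * activity_of(fl, "OH-")),
               acid_ln_k("water", 32, DB), tolerance = 1e-10,
               ignore_attr = TRUE)
  # null formate leaves formate species NA but DIC intact
  s <- demo_sample(); s$formate_molal <- NA
  fl2 <- speciate(s, DB)
  expect_true(is.na(activity_of(fl2, "HCOO-")))
  expect_false(is.na(activity_of(fl2, "HCO3-")))
  # neutral-pH fluid: CO2/HCO3- activity ratio is 10^(pKa1 - pH)
  fl7 <- speciate(demo_sample(ph = 7, t_c = 25), DB)
  expect_equal(log10(activity_of(fl7, "CO2") / activity_of(fl7, "HCO3-")),
               acid_pk("carbonic1", 25, DB) - 7, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(activity_of(fl, "Xe"), "unknown species")
})
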