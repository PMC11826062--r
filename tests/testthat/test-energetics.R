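# Affinity, limiting-reactant selection and energy supply.

test_that("reaction quotient is the signed log-linear activity product", {
  h <- RXN$hydrogenotrophic
  ones <- fluid_from_activities(
    stats::setNames(rep(1, length(h$stoich)), names(h$stoich)))
  expect_equal(reaction_quotient(h, ones), 0)
  # hand sum of exponents: a(H2)=1e-4, a(HCO3-)=1e-6, a(H+)=1e-11.5,
  # a(CH4)=1e-5, a(H2O)=1 -> ln Q = ln(10^28.5)
  fl <- fluid_from_activities(c("H2" = 1e-4, "HCO3-" = 1e-6,
                                "H+" = 10^-11.5, "CH4" = 1e-5, "H2O" = 1))
  expect_equal(reaction_quotient(h, fl), 28.5 * log(10), tolerance = 1e-12)
  # log-linearity: doubling a product activity with v = +3 adds 3 ln 2
  fl2 <- fluid_from_activities(c("H2" = 1e-4, "HCO3-" = 1e-6,
                                 "H+" = 10^-11.5, "CH4" = 1e-5, "H2O" = 2))
  expect_equal(reaction_quotient(h, fl2) - reaction_quotient(h, fl),
               3 * log(2), tolerance = 1e-12)
  # unevaluable quotients propagate as NA
  expect_true(is.na(reaction_quotient(h, fluid_from_activities(
    c("H2" = 1e-4, "HCO3-" = NA, "H+" = 1e-11, "CH4" = 1e-5, "H2O" = 1)))))
  expect_true(is.na(reaction_quotient(h, fluid_from_activities(
    c("H2" = 0, "HCO3-" = 1e-6, "H+" = 1e-11, "CH4" = 1e-5, "H2O" = 1)))))
})

test_that("affinity is RT(lnK - lnQ) per mole CH4, zero at equilibrium, antisymmetric", {
  h <- RXN$hydrogenotrophic
  # ln K - ln Q = 10 at 25 degC -> 24.79 kJ/mol
  ln_k <- log_k(h, 25, DB)
  a_target <- exp((ln_k - 10 -
                     sum(h$stoich[c("HCO3-", "H+", "CH4", "H2O")] *
                           log(c(1e-6, 10^-11.5, 1e-5, 1)))) /
                    h$stoich[["H2"]])
  fl <- fluid_from_activities(c("H2" = a_target, "HCO3-" = 1e-6,
                                "H+" = 10^-11.5, "CH4" = 1e-5, "H2O" = 1))
  out <- affinity(h, fl, t_c = 25, db = DB)
  expect_equal(out$ln_k - out$ln_q, 10, tolerance = 1e-9)
  expect_equal(out$affinity_kj_mol_ch4, 8.314 * 298.15 * 10 / 1000,
               tolerance = 1e-9)
  expect_equal(out$delta_g_j_mol, -out$affinity_kj_mol_ch4 * 1000)

  # equilibrium: Q = K -> A = 0
  a_eq <- exp((ln_k - sum(h$stoich[c("HCO3-", "H+", "CH4", "H2O")] *
                            log(c(1e-6, 10^-11.5, 1e-5, 1)))) /
                h$stoich[["H2"]])
  fl_eq <- fluid_from_activities(c("H2" = a_eq, "HCO3-" = 1e-6,
                                   "H+" = 10^-11.5, "CH4" = 1e-5, "H2O" = 1))
  expect_equal(affinity(h, fl_eq, 25, DB)$affinity_kj_mol_ch4, 0,
               tolerance = 1e-9)

  # reversing the reaction flips the sign of A
  rev <- reaction("reverse", -h$stoich)
  fl3 <- speciate(demo_sample(), DB)
  expect_equal(affinity(rev, fl3, 25, DB)$affinity_kj_mol_ch4,
               -affinity(h, fl3, 25, DB)$affinity_kj_mol_ch4,
               tolerance = 1e-9)
})

test_that("affinity strictly falls with product activity and rises with reactant activity", {
  h <- RXN$hydrogenotrophic
  base <- c("H2" = 1e-4, "HCO3-" = 1e-5, "H+" = 1e-11, "CH4" = 1e-5,
            "H2O" = 1)
  a0 <- affinity(h, fluid_from_activities(base), 25, DB)$affinity_kj_mol_ch4
  up_prod <- base; up_prod["CH4"] <- 2e-5
  expect_lt(affinity(h, fluid_from_activities(up_prod), 25,
                     DB)$affinity_kj_mol_ch4, a0)
  up_reac <- base; up_reac["H2"] <- 2e-4
  expect_gt(affinity(h, fluid_from_activities(up_reac), 25,
                     DB)$affinity_kj_mol_ch4, a0)
})

test_that("Hess path: A_formatotrophic = A_hydrogenotrophic + 4 A_formate-hydrolysis", {
  for (seed in 1:20) {
    fl <- speciate(random_sample(seed), DB)
    a_h <- affinity(RXN$hydrogenotrophic, fl, db = DB)$affinity_kj_mol_ch4
    a_f <- affinity(RXN$formatotrophic, fl, db = DB)$affinity_kj_mol_ch4
    a_hyd <- affinity(RXN$formate_hydrolysis, fl, db = DB)$affinity_kj_mol_ch4
    expect_equal(a_f, a_h + 4 * a_hyd, tolerance = 1e-6)
  }
})

test_that("affinity is invariant under rescaling of the reaction formula unit", {
  h <- RXN$hydrogenotrophic
  doubled <- reaction("2x", 2 * h$stoich, ch4_per_unit = 2)
  fl <- speciate(demo_sample(), DB)
  expect_equal(affinity(doubled, fl, db = DB)$affinity_kj_mol_ch4,
               affinity(h, fl, db = DB)$affinity_kj_mol_ch4,
               tolerance = 1e-9)
})

test_that("limiting reactant selection matches worked cases and brute force", {
  h <- RXN$hydrogenotrophic
  # DIC-limited site: 3.4e-5/1 < 2.3e-4/4
  lim <- limiting_reactant(h, list(dic_molal = 3.4e-5, h2_molal = 2.3e-4))
  expect_equal(lim$pool, "dic")
  expect_equal(lim$m_lim, 3.4e-5)
  expect_equal(lim$v_lim, 1)
  # H2-limited site: 2.1e-5/4 < 1.1e-4/1
  lim <- limiting_reactant(h, list(dic_molal = 1.1e-4, h2_molal = 2.1e-5))
  expect_equal(lim$pool, "h2")
  expect_equal(lim$v_lim, 4)
  # single-candidate reactions
  expect_equal(limiting_reactant(RXN$acetoclastic,
                                 list(acetate_molal = 1e-6))$pool, "acetate")
  # ties go to the carbon substrate
  lim <- limiting_reactant(h, list(dic_molal = 1e-5, h2_molal = 4e-5))
  expect_equal(lim$pool, "dic")
  # null pool -> null result
  expect_true(is.na(limiting_reactant(h, list(dic_molal = NA,
                                              h2_molal = 1e-4))$m_lim))

  # brute-force oracle: exhaustive min of m/|v| over candidates
  set.seed(42)
  for (k in 1:1000) {
    m <- stats::setNames(10^runif(2, -8, -2), c("dic", "h2"))
    lim <- limiting_reactant(h, list(dic_molal = m[["dic"]],
                                     h2_molal = m[["h2"]]))
    v <- c(dic = 1, h2 = 4)
    expect_equal(lim$m_lim / lim$v_lim, min(m / v))
  }
})

test_that("energy supply multiplies affinity by the limiting pool, clamping negatives", {
  expect_equal(energy_supply(65.2, 3.4e-5, 1), 2.2168)
  expect_equal(signif(energy_supply(100.4, 4.8e-6, 4), 2), 0.12)
  expect_equal(energy_supply(-4.2, 1.8e-4, 1), 0)
  expect_equal(energy_supply(0, 1e-4, 1), 0)
  expect_true(is.na(energy_supply(NA, 1e-4, 1)))
  expect_true(is.na(energy_supply(50, NA, 1)))
  expect_error(energy_supply(50, -1e-5, 1), "m_lim")
  # prescribed-scenario recovery: E = A m / v exactly
  for (a in c(12.5, 65.2, 97.2)) {
    for (m in c(1e-6, 3.4e-5)) {
      expect_equal(energy_supply(a, m, 4), a * 1000 * m / 4)
    }
  }
})

test_that("energetics_table computes three reactions per site and blanks missing inputs", {
  samples <- rbind(
    as.data.frame(demo_sample(), stringsAsFactors = FALSE),
    as.data.frame(demo_sample(), stringsAsFactors = FALSE))
  samples$site_id <- c("s1", "s2")
  samples$acetate_molal[2] <- NA
  samples <- validate_samples(samples)
  tab <- energetics_table(samples, DB)
  expect_s3_class(tab, "energy_results")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("site_id", "ph", "si_molal",
                      "affinity_hydrogenotrophic", "supply_hydrogenotrophic",
                      "affinity_formatotrophic", "supply_formatotrophic",
                      "affinity_acetoclastic", "supply_acetoclastic"))
  # null acetate blanks the acetoclastic cells only
  expect_true(is.na(tab$affinity_acetoclastic[2]))
  expect_true(is.na(tab$supply_acetoclastic[2]))
  expect_false(any(is.na(tab[1, -(1:3)])))
  # internal consistency: supply recomputed cell-wise from its own affinity
  lim <- limiting_reactant(RXN$hydrogenotrophic, samples[1, ])
  expect_equal(tab$supply_hydrogenotrophic[1],
               energy_supply(tab$affinity_hydrogenotrophic[1],
                             lim$m_lim, lim$v_lim))
})
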