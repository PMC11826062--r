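# Chemical affinity per mole CH4 and limiting-reactant energy supply per kg
# fluid for the three methanogenic catabolisms.

#' Reaction quotient of a speciated fluid
#'
#' `ln Q = sum(v_i ln a_i)` over the species of the reaction, activities from
#' the speciated fluid. Any required activity that is `NA` (unmeasured input)
#' or exactly 0 makes the quotient unevaluable and returns `NA`, which
#' propagates to a blank output cell.
#'
#' @param reaction A [reaction()].
#' @param fluid A [speciate()]d fluid.
#' @return ln Q (natural log), or `NA`.
#' @export
reaction_quotient <- function(reaction, fluid) {
  a <- activity_of(fluid, names(reaction$stoich))
  if (any(is.na(a)) || any(a == 0)) return(NA_real_)
  sum(reaction$stoich * log(a))
}

#' Chemical affinity of a methanogenic reaction
#'
#' `A = R T (ln K - ln Q)`, normalized to kJ per mole CH4 produced. Positive
#' affinity means the forward reaction releases energy. The Gibbs energy of
#' reaction per formula unit is `-A * ch4_per_unit` (in kJ).
#'
#' @param reaction A [reaction()].
#' @param fluid A [speciate()]d fluid.
#' @param t_c Temperature, degC; defaults to the fluid temperature.
#' @param db A [thermo_db()].
#' @return List with `site_id`, `reaction_id`, `ln_k`, `ln_q`,
#'   `delta_g_j_mol` (J per mole of reaction) and `affinity_kj_mol_ch4`.
#'   `NA` quotients propagate.
#' @examples
#' s <- list(site_id = "demo", ph = 11.3, temperature_c = 32,
#'           dic_molal = 3.4e-5, h2_molal = 2.3e-4, ch4_molal = 1e-5,
#'           formate_molal = 3e-6, acetate_molal = 3.2e-6)
#' affinity(methanogenesis_reactions()$hydrogenotrophic, speciate(s))
#' @export
affinity <- function(reaction, fluid, t_c = fluid$temperature_c,
                     db = thermo_db()) {
  ln_k <- log_k(reaction, t_c, db)
  ln_q <- reaction_quotient(reaction, fluid)
  t_k <- t_c + 273.15
  a_rxn_j <- db$gas_constant * t_k * (ln_k - ln_q)  # J per formula unit
  list(site_id = fluid$site_id,
       reaction_id = reaction$id,
       ln_k = ln_k,
       ln_q = ln_q,
       delta_g_j_mol = -a_rxn_j,
       affinity_kj_mol_ch4 = a_rxn_j / 1000 / reaction$ch4_per_unit)
}

#' Limiting reactant of a reaction in a sample
#'
#' Each candidate reactant pool is the *measured total* of that pool (the DIC
#' total, the formate total, the acetate total, dissolved H2) - the substrate
#' and everything in equilibrium with it, which re-supplies the substrate as
#' it is consumed. H+ and H2O are never candidates (solvent and pH are
#' buffered at the kg-fluid scale). The limiting pool minimizes
#' `m_pool / |v|`; ties are broken in favor of the carbon substrate.
#'
#' @param reaction A [reaction()].
#' @param sample One fluid sample (row or named list) with `*_molal` columns.
#' @return List with `pool` ("dic", "h2", "formate" or "acetate"), `species`
#'   (the reactant species drawing on it), `m_lim` (pool molality) and
#'   `v_lim` (positive stoichiometric coefficient). All-`NA` if any candidate
#'   pool is unmeasured.
#' @examples
#' limiting_reactant(methanogenesis_reactions()$hydrogenotrophic,
#'                   list(dic_molal = 3.4e-5, h2_molal = 2.3e-4))
#' @export
limiting_reactant <- function(reaction, sample) {
  pools <- reaction$pools
  .check(length(pools) > 0, "reaction has no limiting-reactant candidates")
  m <- vapply(names(pools), function(p) .field(sample, paste0(p, "_molal")),
              numeric(1))
  v <- abs(reaction$stoich[pools])
  if (any(is.na(m))) {
    return(list(pool = NA_character_, species = NA_character_,
                m_lim = NA_real_, v_lim = NA_real_))
  }
  ratio <- m / v
  best <- which(ratio == min(ratio))
  if (length(best) > 1) {
    carbon <- best[names(pools)[best] != "h2"]
    best <- if (length(carbon) > 0) carbon[1] else best[1]
  }
  list(pool = names(pools)[best],
       species = unname(pools[best]),
       m_lim = unname(m[best]),
       v_lim = unname(v[best]))
}

#' Energy supply per kg fluid
#'
#' `E = max(A, 0) * 1000 * m_lim / v_lim` - the joules obtainable from one kg
#' of fluid if the reaction runs until its limiting pool is exhausted.
#' Negative affinities clamp the supply to exactly 0 (the reaction cannot run
#' forward); the affinity itself stays signed. `NA` inputs propagate.
#'
#' @param affinity_kj_mol Affinity in kJ per mole CH4 (per formula unit for
#'   the unit-CH4 reactions used here).
#' @param m_lim Limiting pool molality (mol/kg), `>= 0`.
#' @param v_lim Positive stoichiometric coefficient of the limiting reactant.
#' @return Energy supply in J per kg fluid.
#' @examples
#' energy_supply(65.2, 3.4e-5, 1)   # 2.2168
#' energy_supply(-4.2, 1.8e-4, 1)   # 0
#' @export
energy_supply <- function(affinity_kj_mol, m_lim, v_lim) {
  .check(all(is.na(m_lim) | m_lim >= 0), "m_lim must be >= 0")
  .check(all(is.na(v_lim) | v_lim >= 1), "v_lim must be >= 1")
  ifelse(is.na(affinity_kj_mol) | is.na(m_lim) | is.na(v_lim),
         NA_real_,
         pmax(affinity_kj_mol, 0) * 1000 * m_lim / v_lim)
}

#' Per-site energetics table
#'
#' Runs speciation, affinity, limiting-reactant selection and energy supply
#' for the three methanogenic reactions over a table of samples. Sites whose
#' inputs are missing get blank (`NA`) cells: affinity needs every activity in
#' the reaction (including CH4), supply needs the affinity and every candidate
#' pool.
#'
#' @param samples A `fluid_samples` data frame.
#' @param db A [thermo_db()].
#' @param config A [run_config()].
#' @return A data frame of class `energy_results` with columns `site_id`,
#'   `ph`, `si_molal`, then `affinity_<reaction>` (kJ per mole CH4) and
#'   `supply_<reaction>` (J per kg fluid) for hydrogenotrophic,
#'   formatotrophic and acetoclastic methanogenesis.
#' @export
energetics_table <- function(samples, db = thermo_db(), config = run_config()) {
  validate_samples(samples)
  rxns <- methanogenesis_reactions()[c("hydrogenotrophic", "formatotrophic",
                                       "acetoclastic")]
  rows <- lapply(seq_len(nrow(samples)), function(k) {
    sm <- samples[k, ]
    fl <- speciate(sm, db, config)
    out <- list(site_id = sm$site_id, ph = sm$ph, si_molal = sm$si_molal)
    for (r in rxns) {
      af <- affinity(r, fl, db = db)$affinity_kj_mol_ch4
      lim <- limiting_reactant(r, sm)
      out[[paste0("affinity_", r$id)]] <- af
      out[[paste0("supply_", r$id)]] <-
        energy_supply(af, lim$m_lim, lim$v_lim)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("energy_results", class(res))
  res
}
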