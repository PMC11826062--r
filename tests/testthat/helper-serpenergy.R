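# Shared fixtures: thermodynamic db, reactions, and sample builders.

DB <- thermo_db()
RXN <- methanogenesis_reactions()

# a complete hyperalkaline sample (all pools measured, CH4 included)
demo_sample <- function(ph = 11.3, t_c = 32, dic = 3.4e-5, h2 = 2.3e-4,
                        ch4 = 1e-5, formate = 3e-6, acetate = 3.2e-6) {
  list(site_id = "demo", ph = ph, temperature_c = t_c,
       si_molal = 2e-6, dic_molal = dic, h2_molal = h2, ch4_molal = ch4,
       formate_molal = formate, acetate_molal = acetate)
}

# random valid sample spanning the field ranges; deterministic in `seed`
random_sample <- function(seed) {
  set.seed(seed)
  demo_sample(ph = runif(1, 7, 12), t_c = runif(1, 19, 36),
              dic = 10^runif(1, -5.5, -2.5), h2 = 10^runif(1, -8, -3),
              ch4 = 10^runif(1, -8, -4), formate = 10^runif(1, -7, -5),
              acetate = 10^runif(1, -7, -5))
}

# build a speciated_fluid directly from a named activity vector (gamma = 1),
# for reaction-quotient arithmetic tests
fluid_from_activities <- function(a, ph = 11.5, t_c = 25) {
  sp <- data.frame(species = names(a), charge = 0L,
                   molality = unname(a), gamma = 1, activity = unname(a),
                   stringsAsFactors = FALSE)
  rownames(sp) <- sp$species
  structure(list(site_id = "manual", ph = ph, temperature_c = t_c,
                 ionic_strength = 0, species = sp),
            class = "speciated_fluid")
}

# a minimal two-species thermo db for van't Hoff arithmetic: reaction A -> B
# has dG0 = 0 (ln K25 = 0) and a configurable reaction enthalpy
toy_db <- function(enthalpy_kj = 50) {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gas_constant: 8.314",
    "reference_temperature_c: 25.0",
    "davies_a:",
    "  temperature_c: [0.0, 25.0, 50.0, 75.0, 100.0]",
    "  value: [0.4918, 0.5092, 0.5336, 0.5639, 0.5998]",
    "  source: test",
    "species:",
    "  \"A\": {charge: 0, gibbs_kj: 0.0, enthalpy_kj: 0.0, source: test}",
    sprintf("  \"B\": {charge: 0, gibbs_kj: 0.0, enthalpy_kj: %s, source: test}",
            format(enthalpy_kj))), path)
  thermo_db(path)
}
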