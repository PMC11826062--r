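#' Load the thermodynamic constants database
#'
#' Reads standard-state formation properties (apparent standard molal Gibbs
#' energy and enthalpy of formation at 25 degC, 1 bar) for the aqueous species
#' involved in methanogenic catabolism, together with the universal gas
#' constant and the temperature-dependent Debye-Huckel A parameter used by the
#' Davies activity model. Every constant carries a source citation string.
#'
#' Equilibrium constants for reactions and acid dissociations are *derived*
#' from these formation properties (Hess's law), so thermodynamic cycles close
#' exactly by construction. Temperature extrapolation away from the 25 degC
#' anchors uses the van't Hoff relation, adequate for the 0-50 degC range of
#' near-surface fluids.
#'
#' @param path Path to a YAML constants file. Defaults to the compilation
#'   shipped with the package (SUPCRT-lineage values).
#' @return An object of class `thermo_db`: a list with elements
#'   `gas_constant` (J/(mol K)), `reference_temperature_c`, `formation`
#'   (data frame: species, charge, gibbs_kj, enthalpy_kj, source) and
#'   `davies_a` (data frame: temperature_c, value).
#' @examples
#' db <- thermo_db()
#' db$formation
#' @export
thermo_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thermo_constants.yaml",
                        package = "serpenergy", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("thermodynamic constants file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  form <- do.call(rbind, lapply(names(raw$species), function(sp) {
    e <- raw$species[[sp]]
    data.frame(species = sp, charge = as.integer(e$charge),
               gibbs_kj = as.numeric(e$gibbs_kj),
               enthalpy_kj = as.numeric(e$enthalpy_kj),
               source = as.character(e$source),
               stringsAsFactors = FALSE)
  }))
  rownames(form) <- form$species
  db <- list(
    gas_constant = as.numeric(raw$gas_constant),
    reference_temperature_c = as.numeric(raw$reference_temperature_c),
    formation = form,
    davies_a = data.frame(temperature_c = as.numeric(raw$davies_a$temperature_c),
                          value = as.numeric(raw$davies_a$value)),
    davies_a_source = raw$davies_a$source,
    source = path
  )
  class(db) <- "thermo_db"
  db
}

#' @export
print.thermo_db <- function(x, ...) {
  cat("<thermo_db> ", nrow(x$formation), " aqueous species, R = ",
      x$gas_constant, " J/(mol K)\n", sep = "")
  cat("  anchored at ", x$reference_temperature_c, " degC; source file: ",
      x$source, "\n", sep = "")
  invisible(x)
}

#' Debye-Huckel A parameter at a given temperature
#'
#' Linear interpolation of the tabulated limiting-law A parameter (log10
#' basis) against temperature.
#'
#' @param t_c Temperature in degC.
#' @param db A [thermo_db()] object.
#' @return A (dimensionless, log10 basis), e.g. 0.509 at 25 degC.
#' @export
davies_a_parameter <- function(t_c, db = thermo_db()) {
  rng <- range(db$davies_a$temperature_c)
  if (any(t_c < rng[1] | t_c > rng[2])) {
    stop("temperature outside tabulated Debye-Huckel range [",
         rng[1], ", ", rng[2], "] degC", call. = FALSE)
  }
  stats::approx(db$davies_a$temperature_c, db$davies_a$value, xout = t_c)$y
}

.require_species <- function(species, db, context = "reaction") {
  missing <- setdiff(species, db$formation$species)
  if (length(missing) > 0) {
    stop("species missing from thermodynamic database (", context, "): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Standard-state reaction properties from formation properties
#'
#' Assembles the standard Gibbs energy and enthalpy of a reaction at 25 degC
#' by Hess's law from the per-species formation properties.
#'
#' @param stoich Named numeric vector of signed stoichiometric coefficients
#'   (products positive, reactants negative), names are species ids.
#' @param db A [thermo_db()] object.
#' @return List with `gibbs_kj` and `enthalpy_kj` (kJ per mole of reaction).
#' @export
reaction_properties <- function(stoich, db = thermo_db()) {
  .require_species(names(stoich), db)
  g <- db$formation[names(stoich), "gibbs_kj"]
  h <- db$formation[names(stoich), "enthalpy_kj"]
  list(gibbs_kj = sum(stoich * g), enthalpy_kj = sum(stoich * h))
}

#' Equilibrium constant of a reaction at temperature
#'
#' ln K at 25 degC is `-dG0/(R T)` from the assembled standard Gibbs energy;
#' the van't Hoff relation with the assembled standard enthalpy extrapolates
#' to the fluid temperature.
#'
#' @param reaction A [reaction()] object or a named stoichiometry vector.
#' @param t_c Temperature in degC (0-100).
#' @param db A [thermo_db()] object.
#' @return ln K (natural log) at `t_c`.
#' @examples
#' rxns <- methanogenesis_reactions()
#' log_k(rxns$hydrogenotrophic, 25) / log(10)  # log10 K
#' @export
log_k <- function(reaction, t_c, db = thermo_db()) {
  stoich <- if (inherits(reaction, "reaction")) reaction$stoich else reaction
  if (any(t_c < 0 | t_c > 100)) {
    stop("temperature out of supported range [0, 100] degC", call. = FALSE)
  }
  props <- reaction_properties(stoich, db)
  t_ref <- db$reference_temperature_c + 273.15
  t_k <- t_c + 273.15
  ln_k_ref <- -props$gibbs_kj * 1000 / (db$gas_constant * t_ref)
  ln_k_ref - props$enthalpy_kj * 1000 / db$gas_constant * (1 / t_k - 1 / t_ref)
}

#' Construct a reaction object
#'
#' @param id Reaction identifier.
#' @param stoich Named numeric vector of signed coefficients (reactants
#'   negative, products positive).
#' @param ch4_per_unit Moles of CH4 produced per formula unit of reaction
#'   (used to normalize affinities to kJ per mole CH4).
#' @param pools Named character vector mapping limiting-reactant candidate
#'   pools (names: "dic", "h2", "formate", "acetate") to the reactant species
#'   that draws on each pool. H+ and H2O are never candidates.
#' @return An object of class `reaction`.
#' @export
reaction <- function(id, stoich, ch4_per_unit = 1, pools = character()) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), ch4_per_unit > 0)
  structure(list(id = id, stoich = stoich, ch4_per_unit = ch4_per_unit,
                 pools = pools),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste0(abs(v), " ", names(v))),
                           collapse = " + ")
  cat("<reaction> ", x$id, ": ", fmt(lhs), " -> ", fmt(rhs), "\n", sep = "")
  invisible(x)
}

#' The three methanogenic catabolic reactions
#'
#' Stoichiometries written with bicarbonate as the inorganic-carbon species,
#' appropriate for hyperalkaline fluids:
#' * hydrogenotrophic: `4 H2 + HCO3- + H+ -> CH4 + 3 H2O`
#' * formatotrophic: `4 HCOO- + H+ + H2O -> CH4 + 3 HCO3-`
#' * acetoclastic: `CH3COO- + H2O -> CH4 + HCO3-`
#'
#' Each produces one mole of CH4 per formula unit. The auxiliary formate
#' hydrolysis reaction `HCOO- + H2O -> HCO3- + H2` closes the thermodynamic
#' cycle between the hydrogenotrophic and formatotrophic pathways
#' (formatotrophic = hydrogenotrophic + 4 x hydrolysis) and is returned under
#' `formate_hydrolysis` for consistency checks.
#'
#' @return Named list of [reaction()] objects.
#' @export
methanogenesis_reactions <- function() {
  list(
    hydrogenotrophic = reaction(
      "hydrogenotrophic",
      c("H2" = -4, "HCO3-" = -1, "H+" = -1, "CH4" = 1, "H2O" = 3),
      pools = c(h2 = "H2", dic = "HCO3-")),
    formatotrophic = reaction(
      "formatotrophic",
      c("HCOO-" = -4, "H+" = -1, "H2O" = -1, "CH4" = 1, "HCO3-" = 3),
      pools = c(formate = "HCOO-")),
    acetoclastic = reaction(
      "acetoclastic",
      c("CH3COO-" = -1, "H2O" = -1, "CH4" = 1, "HCO3-" = 1),
      pools = c(acetate = "CH3COO-")),
    formate_hydrolysis = reaction(
      "formate_hydrolysis",
      c("HCOO-" = -1, "H2O" = -1, "HCO3-" = 1, "H2" = 1),
      pools = c(formate = "HCOO-"))
  )
}

# Dissociation stoichiometries used to derive acid constants from formation
# properties; keys are the names accepted by acid_ln_k().
.acid_reactions <- list(
  carbonic1 = c("CO2" = -1, "H2O" = -1, "HCO3-" = 1, "H+" = 1),
  carbonic2 = c("HCO3-" = -1, "CO3-2" = 1, "H+" = 1),
  formic    = c("HCOOH" = -1, "HCOO-" = 1, "H+" = 1),
  acetic    = c("CH3COOH" = -1, "CH3COO-" = 1, "H+" = 1),
  water     = c("H2O" = -1, "OH-" = 1, "H+" = 1)
)

#' Acid dissociation constants derived from formation properties
#'
#' @param name One of "carbonic1", "carbonic2", "formic", "acetic", "water".
#' @param t_c Temperature in degC.
#' @param db A [thermo_db()] object.
#' @return ln Ka (natural log) at `t_c`.
#' @examples
#' -acid_ln_k("carbonic1", 25) / log(10)  # pKa1 ~ 6.34
#' @export
acid_ln_k <- function(name, t_c, db = thermo_db()) {
  name <- match.arg(name, names(.acid_reactions))
  log_k(.acid_reactions[[name]], t_c, db)
}

#' @rdname acid_ln_k
#' @export
acid_pk <- function(name, t_c, db = thermo_db()) {
  -acid_ln_k(name, t_c, db) / log(10)
}
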