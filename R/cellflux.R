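# Diffusion-limited substrate delivery to a cell-sized sphere, with the
# metabolic-equilibrium lower bound on the boundary concentration.

#' Diffusion coefficients of the methanogenic substrates
#'
#' Tracer diffusion coefficients in water at 25 degC, 1 bar for the neutral
#' and anionic forms of the three carbon substrates. Used as-is across the
#' 19-36 degC range of the fluids (no temperature correction), matching the
#' convention of the flux tabulation they support.
#'
#' @return Data frame with columns `species`, `d_m2_s`, `source`.
#' @export
diffusion_coefficients <- function() {
  data.frame(
    species = c("CO2", "HCOOH", "CH3COOH", "HCO3-", "HCOO-", "CH3COO-"),
    d_m2_s = c(1.92e-9, 1.52e-9, 1.19e-9, 1.18e-9, 1.45e-9, 1.09e-9),
    source = c("Zeebe & Wolf-Gladrow compilation",
               "organic acid tracer data", "organic acid tracer data",
               "PhreeqC database", "limiting ionic conductance",
               "limiting ionic conductance"),
    stringsAsFactors = FALSE)
}

#' Equilibrium activity of a substrate
#'
#' Solves for the activity a substrate would have if the fluid were at
#' equilibrium with respect to the given reaction, all other activities held
#' fixed: with `v_s` the substrate's (negative) coefficient and `Q_rest` the
#' activity product over the remaining species, `a_eq = (K / Q_rest)^(1/v_s)`.
#' This is the lower bound on the substrate concentration at the surface of a
#' cell consuming it (metabolism can draw the substrate down no further than
#' equilibrium).
#'
#' @param reaction A [reaction()].
#' @param fluid A [speciate()]d fluid.
#' @param substrate Species id; must be a reactant of `reaction`.
#' @param t_c Temperature, degC.
#' @param db A [thermo_db()].
#' @return Equilibrium activity `a_eq`, or `NA` if any other required
#'   activity is missing or zero.
#' @export
equilibrium_substrate_activity <- function(reaction, fluid, substrate,
                                           t_c = fluid$temperature_c,
                                           db = thermo_db()) {
  v_s <- reaction$stoich[substrate]
  if (is.na(v_s) || length(v_s) == 0 || v_s >= 0) {
    stop("'", substrate, "' is not a reactant of reaction ", reaction$id,
         call. = FALSE)
  }
  others <- setdiff(names(reaction$stoich), substrate)
  a <- activity_of(fluid, others)
  if (any(is.na(a)) || any(a == 0)) return(NA_real_)
  ln_q_rest <- sum(reaction$stoich[others] * log(a))
  ln_k <- log_k(reaction, t_c, db)
  unname(exp((ln_k - ln_q_rest) / v_s))
}

#' Potential diffusive flux to a spherical cell
#'
#' `J = 4 pi D R (C_inf - C_R)` - the steady-state diffusion-limited rate of
#' substrate delivery to a sphere of radius R, an upper bound on microbial
#' uptake. Concentrations are mol/L (converted internally to mol/m^3) and the
#' result is reported in attomoles per day. A negative concentration
#' difference (bulk below the boundary value) clamps to zero flux with a
#' warning; efflux is out of scope.
#'
#' @param d Diffusion coefficient, m^2/s.
#' @param radius Sphere radius, m.
#' @param c_inf Bulk substrate concentration, mol/L.
#' @param c_r Substrate concentration at the sphere surface, mol/L.
#' @return Flux in attomol/day (amol = 1e-18 mol).
#' @examples
#' potential_flux(1.18e-9, 5e-7, 1e-6, 0)  # ~6.4e5 amol/day
#' @export
potential_flux <- function(d, radius, c_inf, c_r = 0) {
  .check(all(d > 0, na.rm = TRUE), "diffusion coefficient must be positive")
  .check(all(radius > 0, na.rm = TRUE), "radius must be positive")
  .check(all(c_inf >= 0, na.rm = TRUE) && all(c_r >= 0, na.rm = TRUE),
         "concentrations must be non-negative")
  dc <- c_inf - c_r
  clamped <- !is.na(dc) & dc < 0
  if (any(clamped)) {
    warning("bulk concentration below boundary concentration; ",
            "flux clamped to 0 for ", sum(clamped), " value(s)")
    dc[clamped] <- 0
  }
  # mol/L -> mol/m^3 (1e3), s -> day (86400), mol -> amol (1e18)
  4 * pi * d * radius * (dc * 1e3) * 86400 * 1e18
}

# metabolism whose equilibrium bounds each substrate's boundary concentration
.flux_metabolism <- c("CO2" = "hydrogenotrophic",
                      "HCO3-" = "hydrogenotrophic",
                      "HCOOH" = "formatotrophic",
                      "HCOO-" = "formatotrophic",
                      "CH3COOH" = "acetoclastic",
                      "CH3COO-" = "acetoclastic")

# native reactant of each metabolism, and the acid constant linking the
# neutral conjugate to it
.flux_native <- c(hydrogenotrophic = "HCO3-", formatotrophic = "HCOO-",
                  acetoclastic = "CH3COO-")
.flux_acid_k <- c(hydrogenotrophic = "carbonic1", formatotrophic = "formic",
                  acetoclastic = "acetic")

# equilibrium activity of any of the six flux species for one fluid:
# the anion comes straight from the metabolism's equilibrium; the neutral
# conjugate follows through the acid-dissociation equilibrium at fluid pH.
.equilibrium_flux_activity <- function(species, fluid, db) {
  met <- .flux_metabolism[[species]]
  rxn <- methanogenesis_reactions()[[met]]
  anion <- .flux_native[[met]]
  a_eq <- equilibrium_substrate_activity(rxn, fluid, anion, db = db)
  if (species == anion || is.na(a_eq)) return(a_eq)
  # neutral acid: a(HA) = a(A-) a(H+) / Ka
  a_h <- activity_of(fluid, "H+")
  ka <- exp(acid_ln_k(.flux_acid_k[[met]], fluid$temperature_c, db))
  a_eq * a_h / ka
}

#' Per-site potential-flux table
#'
#' Computes the potential diffusive flux of each of the six substrate forms
#' (CO2, formic acid, acetic acid and their anions) to a cell-sized sphere at
#' every site. The bulk concentration is the species' activity treated
#' numerically as molarity (dilute fluids); the boundary concentration is
#' either the metabolic-equilibrium lower bound (`boundary = "equilibrium"`,
#' which requires a CH4 activity) or zero (`boundary = "zero"`, the pure
#' upper bound). Missing inputs yield blank cells.
#'
#' @param samples A `fluid_samples` data frame.
#' @param db A [thermo_db()].
#' @param config A [run_config()]; supplies the cell radius.
#' @param boundary `"equilibrium"` or `"zero"`.
#' @param d Diffusion coefficient table, see [diffusion_coefficients()].
#' @return A data frame of class `flux_results`: `site_id`, `si_molal`, then
#'   one `flux_<species>` column (amol/day) per substrate form.
#' @export
flux_table <- function(samples, db = thermo_db(), config = run_config(),
                       boundary = c("equilibrium", "zero"),
                       d = diffusion_coefficients()) {
  validate_samples(samples)
  boundary <- match.arg(boundary)
  species <- names(.flux_metabolism)
  missing_d <- setdiff(species, d$species)
  if (length(missing_d) > 0) {
    stop("no diffusion coefficient for species: ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  }
  d_of <- stats::setNames(d$d_m2_s, d$species)
  rows <- lapply(seq_len(nrow(samples)), function(k) {
    sm <- samples[k, ]
    fl <- speciate(sm, db, config)
    out <- list(site_id = sm$site_id, si_molal = sm$si_molal)
    for (sp in species) {
      c_inf <- unname(activity_of(fl, sp))  # activity ~ molarity
      c_r <- if (boundary == "zero") 0
             else .equilibrium_flux_activity(sp, fl, db)
      j <- if (is.na(c_inf) || is.na(c_r)) NA_real_
           else if (c_inf <= c_r) 0
           else potential_flux(d_of[[sp]], config$cell_radius, c_inf, c_r)
      out[[paste0("flux_", sp)]] <- j
    }
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("flux_results", class(res))
  res
}
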