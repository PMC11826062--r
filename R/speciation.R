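# Distribution of measured totals (DIC, formate, acetate) into aqueous
# species with Davies activity corrections. The species activities feed the
# reaction quotients of the energetics module.

#' Ionic strength of a sample
#'
#' `I = 1/2 sum(m_i z_i^2)`. When the sample carries explicit major-ion data
#' (a named list `major_ions` of ion molalities, with charges inferred from
#' trailing `+`/`-` signs or supplied via `charges`), those ions plus the
#' measured charged analytes (formate and acetate as mono-anions, and the DIC
#' total counted as bicarbonate) are summed. Without major-ion data the
#' configured default ionic strength is used - these are dilute fluids and the
#' activity model is insensitive at that level.
#'
#' @param sample A single fluid sample (one-row data frame or list). May
#'   carry a `major_ions` element: named numeric vector of molalities with
#'   ion names like `"Na+"`, `"Cl-"`, `"Ca+2"`.
#' @param config A [run_config()].
#' @return Ionic strength in mol/kg.
#' @examples
#' ionic_strength(list(major_ions = c("Na+" = 0.01, "Cl-" = 0.01)))
#' @export
ionic_strength <- function(sample, config = run_config()) {
  ions <- sample[["major_ions"]]
  if (is.data.frame(sample) && !is.null(ions)) ions <- ions[[1]]
  if (is.null(ions) || length(ions) == 0) {
    return(config$default_ionic_strength)
  }
  if (any(ions < 0, na.rm = TRUE)) {
    stop("negative major-ion molality", call. = FALSE)
  }
  z <- .ion_charge(names(ions))
  i <- 0.5 * sum(ions * z^2, na.rm = TRUE)
  # measured charged analytes ride along as mono-anions
  for (col in c("formate_molal", "acetate_molal", "dic_molal")) {
    v <- .field(sample, col)
    if (!is.na(v)) i <- i + 0.5 * v
  }
  i
}

# charge from an ion label: "Ca+2" -> 2, "Cl-" -> -1, "Na+" -> 1
.ion_charge <- function(labels) {
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexpr("[+-][0-9]*$", lab))
    if (length(m) == 0) return(0)
    n <- sub("^[+-]", "", m)
    mag <- if (nzchar(n)) as.numeric(n) else 1
    if (startsWith(m, "-")) -mag else mag
  }, numeric(1))
}

#' Davies activity coefficient
#'
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)`, with the
#' Debye-Huckel A parameter interpolated at the fluid temperature. Neutral
#' species are assigned `gamma = 1` (dilute-solution approximation). The
#' Davies form is valid only for `I <= 0.5` mol/kg.
#'
#' @param charge Integer ionic charge, `|charge| <= 2`.
#' @param i Ionic strength, mol/kg (0 to 0.5).
#' @param t_c Temperature, degC.
#' @param db A [thermo_db()].
#' @return Activity coefficient gamma (molality basis).
#' @examples
#' activity_coefficient(1, 0.01, 25)  # ~0.902
#' @export
activity_coefficient <- function(charge, i, t_c = 25, db = thermo_db()) {
  .check(all(abs(charge) <= 2), "Davies model supported for |charge| <= 2")
  .check(all(i >= 0), "ionic strength must be non-negative")
  if (any(i > 0.5)) {
    stop("ionic strength ", max(i), " exceeds the Davies validity limit 0.5",
         call. = FALSE)
  }
  a <- davies_a_parameter(t_c, db)
  log_gamma <- -a * charge^2 * (sqrt(i) / (1 + sqrt(i)) - 0.3 * i)
  ifelse(charge == 0, 1, 10^log_gamma)
}

# mass-action partition of a total over species linked by successive
# dissociations. ratios[k] = m[k+1]/m[k]; returns molalities summing to total.
.partition_total <- function(total, ratios) {
  if (is.na(total)) return(rep(NA_real_, length(ratios) + 1))
  weights <- cumprod(c(1, ratios))
  weights * (total / sum(weights))
}

#' Speciate dissolved inorganic carbon
#'
#' Distributes a DIC total over CO2(aq), HCO3- and CO3-2 at fixed pH using the
#' mass-action relations `a(HCO3-)/a(CO2) = Ka1/a(H+)` and
#' `a(CO3-2)/a(HCO3-) = Ka2/a(H+)` with activity corrections, such that the
#' three molalities sum to the measured total.
#'
#' @param dic_total DIC molality (mol/kg); `NA` propagates.
#' @param ph Fluid pH (defines `a(H+) = 10^-ph`).
#' @param t_c Temperature, degC.
#' @param gamma Named numeric vector of activity coefficients for charges
#'   `"0"`, `"1"`, `"2"` (magnitudes; e.g. `c("0" = 1, "1" = 0.9, "2" = 0.66)`).
#' @param db A [thermo_db()].
#' @return Data frame with columns species, charge, molality, gamma, activity.
#' @examples
#' speciate_dic(3.4e-5, 11.33, 25, c("0" = 1, "1" = 1, "2" = 1))
#' @export
speciate_dic <- function(dic_total, ph, t_c = 25,
                         gamma = c("0" = 1, "1" = 1, "2" = 1),
                         db = thermo_db()) {
  .check(is.na(dic_total) || dic_total >= 0, "dic_total must be >= 0")
  a_h <- 10^(-ph)
  ka1 <- exp(acid_ln_k("carbonic1", t_c, db))
  ka2 <- exp(acid_ln_k("carbonic2", t_c, db))
  g <- gamma[c("0", "1", "2")]
  # molality ratios from activity ratios: m2/m1 = (a2/a1) * g1/g2
  r1 <- (ka1 / a_h) * g[["0"]] / g[["1"]]
  r2 <- (ka2 / a_h) * g[["1"]] / g[["2"]]
  m <- .partition_total(dic_total, c(r1, r2))
  gg <- c(g[["0"]], g[["1"]], g[["2"]])
  data.frame(species = c("CO2", "HCO3-", "CO3-2"),
             charge = c(0L, -1L, -2L),
             molality = m, gamma = gg, activity = m * gg,
             stringsAsFactors = FALSE)
}

#' Speciate a monoprotic acid pool
#'
#' Distributes a measured total over the neutral acid and its anion using
#' `a(A-)/a(HA) = Ka/a(H+)` with activity corrections.
#'
#' @param total Pool molality (mol/kg); `NA` propagates.
#' @param pk_name Acid identity: `"formic"` or `"acetic"` (constants derived
#'   from the formation properties), or a numeric pKa.
#' @param ph Fluid pH.
#' @param t_c Temperature, degC.
#' @param gamma Named activity coefficients for charges `"0"` and `"1"`.
#' @param db A [thermo_db()].
#' @param species Optional character(2) naming the acid/anion species.
#' @return Data frame with columns species, charge, molality, gamma, activity.
#' @examples
#' speciate_monoprotic(3e-6, "formic", 11.33)
#' @export
speciate_monoprotic <- function(total, pk_name, ph, t_c = 25,
                                gamma = c("0" = 1, "1" = 1),
                                db = thermo_db(), species = NULL) {
  .check(is.na(total) || total >= 0, "total must be >= 0")
  if (is.numeric(pk_name)) {
    ka <- 10^(-pk_name)
    if (is.null(species)) species <- c("HA", "A-")
  } else {
    ka <- exp(acid_ln_k(pk_name, t_c, db))
    if (is.null(species)) {
      species <- switch(pk_name,
                        formic = c("HCOOH", "HCOO-"),
                        acetic = c("CH3COOH", "CH3COO-"),
                        c("HA", "A-"))
    }
  }
  a_h <- 10^(-ph)
  r <- (ka / a_h) * gamma[["0"]] / gamma[["1"]]
  m <- .partition_total(total, r)
  gg <- c(gamma[["0"]], gamma[["1"]])
  data.frame(species = species, charge = c(0L, -1L),
             molality = m, gamma = gg, activity = m * gg,
             stringsAsFactors = FALSE)
}

#' Speciate a fluid sample
#'
#' Orchestrates the full speciation of one sample: ionic strength, Davies
#' activity coefficients at the fluid temperature, DIC partition, formate and
#' acetate partitions, dissolved H2 and CH4 carried as neutral species at
#' their measured molalities (`gamma = 1`), `a(H+) = 10^-pH`, OH- from the
#' water dissociation constant, and `a(H2O) = 1`. Pools never interconvert:
#' DIC, formate, acetate, H2 and CH4 are independent (redox reactions among
#' C species are suppressed). `NA` inputs yield `NA` species entries.
#'
#' @param sample One fluid sample (one-row `fluid_samples` data frame or
#'   named list).
#' @param db A [thermo_db()].
#' @param config A [run_config()].
#' @return An object of class `speciated_fluid`: list with `site_id`, `ph`,
#'   `temperature_c`, `ionic_strength` and `species` (data frame with
#'   molality, gamma and activity per species).
#' @examples
#' s <- list(site_id = "demo", ph = 11.3, temperature_c = 32,
#'           dic_molal = 3.4e-5, h2_molal = 2.3e-4, ch4_molal = 1e-5,
#'           formate_molal = 3e-6, acetate_molal = 3.2e-6)
#' speciate(s)
#' @export
speciate <- function(sample, db = thermo_db(), config = run_config()) {
  if (is.data.frame(sample)) {
    .check(nrow(sample) == 1, "speciate() expects a single sample row")
  }
  ph <- .field(sample, "ph")
  t_c <- .field(sample, "temperature_c")
  .check(!is.na(ph) && !is.na(t_c), "sample must carry pH and temperature")
  i <- ionic_strength(sample, config)
  g <- c("0" = 1,
         "1" = activity_coefficient(1, i, t_c, db),
         "2" = activity_coefficient(2, i, t_c, db))

  dic <- speciate_dic(.field(sample, "dic_molal"), ph, t_c, g, db)
  formate <- speciate_monoprotic(.field(sample, "formate_molal"), "formic",
                                 ph, t_c, g[c("0", "1")], db)
  acetate <- speciate_monoprotic(.field(sample, "acetate_molal"), "acetic",
                                 ph, t_c, g[c("0", "1")], db)

  a_h <- 10^(-ph)
  kw <- exp(acid_ln_k("water", t_c, db))
  a_oh <- kw / a_h
  m_h2 <- .field(sample, "h2_molal")
  m_ch4 <- .field(sample, "ch4_molal")
  rest <- data.frame(
    species = c("H2", "CH4", "H+", "OH-", "H2O"),
    charge = c(0L, 0L, 1L, -1L, 0L),
    molality = c(m_h2, m_ch4, a_h / g[["1"]], a_oh / g[["1"]], NA_real_),
    gamma = c(1, 1, g[["1"]], g[["1"]], 1),
    activity = c(m_h2, m_ch4, a_h, a_oh, 1),
    stringsAsFactors = FALSE)

  species <- rbind(dic, formate, acetate, rest)
  rownames(species) <- species$species
  structure(list(site_id = as.character(sample[["site_id"]] %||% NA),
                 ph = ph, temperature_c = t_c, ionic_strength = i,
                 species = species),
            class = "speciated_fluid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.speciated_fluid <- function(x, ...) {
  cat("<speciated_fluid> site ", x$site_id, ": pH ", x$ph, ", ",
      x$temperature_c, " degC, I = ", signif(x$ionic_strength, 3),
      " mol/kg\n", sep = "")
  print(within(x$species, {
    molality <- signif(molality, 4); activity <- signif(activity, 4)
    gamma <- signif(gamma, 4)
  }), row.names = FALSE)
  invisible(x)
}

#' Activity of a species in a speciated fluid
#'
#' @param fluid A `speciated_fluid`.
#' @param species Species id(s), e.g. `"HCO3-"`.
#' @return Numeric activity (or `NA` if the underlying total was missing).
#' @export
activity_of <- function(fluid, species) {
  stopifnot(inherits(fluid, "speciated_fluid"))
  unknown <- setdiff(species, fluid$species$species)
  if (length(unknown) > 0) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stats::setNames(fluid$species[species, "activity"], species)
}
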