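# Reading, validating and writing per-site fluid chemistry and result tables.

# canonical column -> accepted header aliases (all matched case-insensitively,
# after stripping non-alphanumeric characters)
.column_aliases <- list(
  site_id       = c("site_id", "site", "sample", "sample_id", "id"),
  location      = c("location", "fluid_location", "site_location"),
  source        = c("source", "setting"),
  fluid_type    = c("fluid_type", "type", "fluid", "fluidtype"),
  ph            = c("ph"),
  temperature_c = c("temperature_c", "temperature", "temp", "temp_c", "t_c"),
  si_molal      = c("si_molal", "si", "si_molality", "silica"),
  pct_serp_printed = c("pct_serp_printed", "pct_serp", "percent_serp"),
  dic_molal     = c("dic_molal", "dic", "dic_molality"),
  h2_molal      = c("h2_molal", "h2", "h2_molality", "hydrogen"),
  ch4_molal     = c("ch4_molal", "ch4", "ch4_molality", "methane"),
  formate_molal = c("formate_molal", "formate", "formate_total", "hcoo"),
  acetate_molal = c("acetate_molal", "acetate", "acetate_total", "ch3coo")
)

.analyte_columns <- c("si_molal", "dic_molal", "h2_molal", "ch4_molal",
                      "formate_molal", "acetate_molal")

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.match_columns <- function(header) {
  normed <- .norm_header(header)
  out <- rep(NA_character_, length(header))
  for (canon in names(.column_aliases)) {
    hits <- which(normed %in% .norm_header(.column_aliases[[canon]]))
    if (length(hits) > 0) out[hits[1]] <- canon
  }
  out
}

.norm_fluid_type <- function(x) {
  n <- .norm_header(x)
  out <- rep(NA_character_, length(x))
  out[n %in% c("type1", "typei", "1", "i")] <- "type1"
  out[n %in% c("type2", "typeii", "2", "ii")] <- "type2"
  out[n %in% c("mix", "mixed")] <- "mixed"
  out
}

#' Validate a fluid-sample table
#'
#' Checks the schema invariants: mandatory columns present, all molalities
#' non-negative (missing measurements are `NA`, never zero), pH within (0, 14)
#' and temperature within \[-5, 100\] degC.
#'
#' @param samples A data frame of fluid samples.
#' @return The validated table, invisibly, with class `fluid_samples`.
#' @export
validate_samples <- function(samples) {
  mandatory <- c("site_id", "ph", "temperature_c")
  missing <- setdiff(mandatory, names(samples))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(.analyte_columns, names(samples))) {
    bad <- which(!is.na(samples[[col]]) & samples[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative concentration in column '", col, "' at row(s): ",
           paste(samples$site_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  bad_ph <- which(!is.na(samples$ph) & (samples$ph <= 0 | samples$ph >= 14))
  if (length(bad_ph) > 0) {
    stop("pH outside (0, 14) at row(s): ",
         paste(samples$site_id[bad_ph], collapse = ", "), call. = FALSE)
  }
  bad_t <- which(!is.na(samples$temperature_c) &
                   (samples$temperature_c < -5 | samples$temperature_c > 100))
  if (length(bad_t) > 0) {
    stop("temperature outside [-5, 100] degC at row(s): ",
         paste(samples$site_id[bad_t], collapse = ", "), call. = FALSE)
  }
  if (!inherits(samples, "fluid_samples")) {
    class(samples) <- c("fluid_samples", class(samples))
  }
  invisible(samples)
}

#' Read a per-site fluid chemistry table
#'
#' Reads a delimited table (TSV or CSV) of per-site fluid chemistry with one
#' row per sampling site. Header names are matched case-insensitively against
#' a set of aliases (e.g. `DIC`, `dic_molal`). Blank cells become `NA` (an
#' unmeasured or below-detection value, never coerced to 0), and scientific
#' notation is parsed. All concentrations are molalities (mol per kg water).
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) infers tab for `.tsv`/`.txt`
#'   and comma for `.csv`.
#' @return A `fluid_samples` data frame with canonical columns `site_id`,
#'   `location`, `source`, `fluid_type`, `ph`, `temperature_c`, `si_molal`,
#'   `dic_molal`, `h2_molal`, `ch4_molal`, `formate_molal`, `acetate_molal`.
#' @examples
#' path <- system.file("extdata", "samail_fluid_chemistry.tsv",
#'                     package = "serpenergy")
#' head(read_samples(path))
#' @export
read_samples <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, fill = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "",
                           quote = "\"")
  canon <- .match_columns(names(raw))
  keep <- !is.na(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]
  absent <- setdiff(c("site_id", "ph", "temperature_c"), names(raw))
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  out <- data.frame(site_id = as.character(raw[["site_id"]]),
                    stringsAsFactors = FALSE)
  out$location <- if ("location" %in% names(raw))
    as.character(raw$location) else NA_character_
  out$source <- if ("source" %in% names(raw))
    as.character(raw$source) else NA_character_
  out$fluid_type <- if ("fluid_type" %in% names(raw))
    .norm_fluid_type(raw$fluid_type) else NA_character_
  for (col in c("ph", "temperature_c", "pct_serp_printed", .analyte_columns)) {
    out[[col]] <- if (col %in% names(raw))
      suppressWarnings(as.numeric(raw[[col]])) else NA_real_
  }
  if (!"pct_serp_printed" %in% names(raw)) {
    out$pct_serp_printed <- NULL
  }
  out <- validate_samples(out)
  out
}

#' Write a fluid-sample table
#'
#' Writes the canonical schema as a delimited table; `NA` values become blank
#' cells. `write_samples` followed by [read_samples()] is the identity on
#' parsed values.
#'
#' @param samples A `fluid_samples` data frame.
#' @param path Output path; delimiter inferred from the extension.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, delim = NULL) {
  validate_samples(samples)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::write.table(samples, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write a result table in tabular scientific notation
#'
#' Writes a homogeneous table of energy or flux results with a deterministic
#' column order. Numeric result columns are rendered in scientific notation at
#' a configurable number of significant figures (default 2, round-half-even);
#' `NA` values are written as empty cells. Identifier and small-magnitude
#' descriptor columns (`site_id`, `ph`, affinity columns, `species`, counts)
#' are written at full precision.
#'
#' @param results A data frame of class `energy_results` or `flux_results`
#'   (as produced by [energetics_table()] / [flux_table()]), or any data
#'   frame.
#' @param path Output path.
#' @param digits Significant figures for scientific-notation columns.
#' @param sci_cols Character vector of columns to format scientifically;
#'   defaults to concentration/supply/flux columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 2, sci_cols = NULL) {
  if (!is.data.frame(results)) stop("results must be a data frame",
                                    call. = FALSE)
  classes <- intersect(c("energy_results", "flux_results"), class(results))
  if (length(classes) > 1) {
    stop("mixed result types: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  out <- results
  if (is.null(sci_cols)) {
    sci_cols <- grep("^(supply|flux|si_molal|m_lim|c_inf|c_r|d_m2_s|j_)",
                     names(out), value = TRUE)
  }
  for (col in intersect(sci_cols, names(out))) {
    out[[col]] <- format_sci(out[[col]], digits)
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Run configuration
#'
#' Collects the tunable scalar parameters of the pipeline.
#'
#' @param cell_radius Radius of the model spherical cell, m (default 5e-7,
#'   i.e. 0.5 um).
#' @param default_ionic_strength Ionic strength (mol/kg) assumed when a sample
#'   carries no major-ion data (default 0.01, a dilute ground water).
#' @param si_type1_endmember Si molality of the unreacted (Type I) end member
#'   used by the conservative mixing model (default 8.5e-4).
#' @param si_type2_endmember Si molality of the pristine serpentinized
#'   (Type II) end member (default 1.4e-6).
#' @param atp_cost Energetic cost of ADP -> ATP phosphorylation, kJ/mol
#'   (default 45).
#' @param thermo_source Optional path to a thermodynamic constants YAML file
#'   (see [thermo_db()]).
#' @param seed Optional integer seed for stochastic components.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cell_radius = 5e-7,
                       default_ionic_strength = 0.01,
                       si_type1_endmember = 8.5e-4,
                       si_type2_endmember = 1.4e-6,
                       atp_cost = 45,
                       thermo_source = NULL,
                       seed = NULL) {
  .check(cell_radius > 0, "cell_radius must be positive")
  .check(default_ionic_strength >= 0, "default_ionic_strength must be >= 0")
  .check(si_type1_endmember != si_type2_endmember,
         "mixing end-member Si values must be distinct")
  .check(si_type1_endmember > 0 && si_type2_endmember > 0,
         "mixing end-member Si values must be positive")
  .check(atp_cost > 0, "atp_cost must be positive")
  structure(list(cell_radius = cell_radius,
                 default_ionic_strength = default_ionic_strength,
                 si_type1_endmember = si_type1_endmember,
                 si_type2_endmember = si_type2_endmember,
                 atp_cost = atp_cost,
                 thermo_source = thermo_source,
                 seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  cell radius:        ", x$cell_radius, "m\n")
  cat("  default I:          ", x$default_ionic_strength, "mol/kg\n")
  cat("  Si end members:     ", x$si_type1_endmember, "(type1) /",
      x$si_type2_endmember, "(type2) molal\n")
  cat("  ATP cost:           ", x$atp_cost, "kJ/mol\n")
  invisible(x)
}

#' Compiled Samail Ophiolite field chemistry
#'
#' Loads the compiled per-site chemistry of surface-expressed and well fluids
#' from the Samail Ophiolite (Oman): pH, temperature and molalities of Si,
#' DIC, H2, formate and acetate, plus the fluid-type classification
#' (`type1` = unreacted Mg-HCO3 water, `type2` = pristine serpentinized Ca-OH
#' water, `mixed` = intermediate). Blank cells are measurements not made or
#' below detection. CH4 was not measured in this compilation, so affinity
#' calculations on these samples require externally supplied CH4 activities.
#'
#' @return A `fluid_samples` data frame (one row per site).
#' @examples
#' f <- samail_fluids()
#' table(f$fluid_type)
#' @export
samail_fluids <- function() {
  read_samples(system.file("extdata", "samail_fluid_chemistry.tsv",
                           package = "serpenergy", mustWork = TRUE))
}

#' Published energy-availability reference table for the Samail fluids
#'
#' Loads the published per-site chemical affinities (kJ per mole CH4) and
#' energy supplies (J per kg fluid) for hydrogenotrophic, formatotrophic and
#' acetoclastic methanogenesis in the [samail_fluids()] sites, as reported
#' from a full EQ3/6 speciation of those fluids. Used as reference values for
#' the package's limiting-reactant arithmetic and summary statistics.
#'
#' @return A data frame with columns `site_id`, `ph`, `si_molal`,
#'   `affinity_*` and `supply_*` for the three metabolisms; blanks are `NA`.
#' @export
samail_energy_published <- function() {
  path <- system.file("extdata", "samail_energy_published.tsv",
                      package = "serpenergy", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", fill = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
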