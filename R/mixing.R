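# Conservative Si mixing model, grouped affinity statistics, per-site
# metabolism ranking, and the ATP-cost feasibility check.

#' Conservative mixing model
#'
#' Two-end-member mixing with Si as the conservative tracer: a fluid's
#' percent serpentinized composition is the linear position of its Si
#' molality between the unreacted (type 1) and pristine serpentinized
#' (type 2) end members.
#'
#' @param si_type1 Si molality of the unreacted end member.
#' @param si_type2 Si molality of the pristine serpentinized end member.
#' @return An object of class `mixing_model`.
#' @export
mixing_model <- function(si_type1 = 8.5e-4, si_type2 = 1.4e-6) {
  .check(si_type1 > 0 && si_type2 > 0, "end-member Si must be positive")
  .check(si_type1 != si_type2, "end-member Si values must be distinct")
  structure(list(si_type1 = si_type1, si_type2 = si_type2),
            class = "mixing_model")
}

#' Percent serpentinized fluid from Si
#'
#' `100 (si_type1 - si) / (si_type1 - si_type2)`, clipped to \[0, 100\].
#' Affine and monotone decreasing in Si between the end members.
#'
#' @param si Si molality (vectorized), `>= 0`.
#' @param model A [mixing_model()].
#' @return Percent serpentinized fluid in \[0, 100\].
#' @examples
#' pct_serpentinized(c(8.5e-4, 2.0e-4, 1.4e-06))
#' @export
pct_serpentinized <- function(si, model = mixing_model()) {
  .check(all(si >= 0, na.rm = TRUE), "si must be >= 0")
  pct <- 100 * (model$si_type1 - si) / (model$si_type1 - model$si_type2)
  pmin(pmax(pct, 0), 100)
}

.reaction_ids <- c("hydrogenotrophic", "formatotrophic", "acetoclastic")

#' Grouped affinity summary statistics
#'
#' Arithmetic mean, sample (n-1) standard deviation, min and max of the
#' non-missing affinities per reaction, over all sites or grouped by fluid
#' type. The standard deviation is `NA` for singleton groups.
#'
#' @param results A data frame with `affinity_<reaction>` columns (an
#'   `energy_results` table or the published reference table), optionally a
#'   `fluid_type` column.
#' @param group_by `"all"` or `"fluid_type"`.
#' @param reaction_id Reactions to summarize (default all three).
#' @return Data frame with columns `group`, `reaction_id`, `n`,
#'   `mean_affinity`, `sd_affinity`, `min_affinity`, `max_affinity`.
#' @examples
#' summarize_affinity(samail_energy_published(),
#'                    reaction_id = "acetoclastic")
#' @export
summarize_affinity <- function(results, group_by = c("all", "fluid_type"),
                               reaction_id = .reaction_ids) {
  group_by <- match.arg(group_by)
  reaction_id <- match.arg(reaction_id, .reaction_ids, several.ok = TRUE)
  groups <- if (group_by == "all") {
    list(all = seq_len(nrow(results)))
  } else {
    .check("fluid_type" %in% names(results),
           "results lack a fluid_type column")
    split(seq_len(nrow(results)), results$fluid_type)
  }
  rows <- list()
  for (g in names(groups)) {
    for (r in reaction_id) {
      col <- paste0("affinity_", r)
      .check(col %in% names(results), "results lack column ", col)
      a <- results[[col]][groups[[g]]]
      a <- a[!is.na(a)]
      if (length(a) == 0) {
        stop("no non-missing '", r, "' affinities in group '", g, "'",
             call. = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = g, reaction_id = r, n = length(a),
        mean_affinity = mean(a),
        sd_affinity = if (length(a) > 1) stats::sd(a) else NA_real_,
        min_affinity = min(a), max_affinity = max(a),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Rank metabolisms at a site
#'
#' Orders the three methanogenic reactions by decreasing affinity or energy
#' supply at one site. Missing metrics are excluded from the ranking and
#' reported separately.
#'
#' @param site_results A one-row data frame (or named list) with
#'   `affinity_<reaction>` and/or `supply_<reaction>` entries.
#' @param metric `"affinity"` or `"energy_supply"`.
#' @return List with `ranking` (named numeric vector, decreasing) and
#'   `missing` (character vector of reactions without the metric). `NULL`
#'   if every metric is missing.
#' @examples
#' tbl <- samail_energy_published()
#' rank_metabolisms(tbl[tbl$site_id == "140115Z", ])
#' @export
rank_metabolisms <- function(site_results,
                             metric = c("affinity", "energy_supply")) {
  metric <- match.arg(metric)
  prefix <- if (metric == "affinity") "affinity_" else "supply_"
  vals <- vapply(.reaction_ids,
                 function(r) .field(site_results, paste0(prefix, r)),
                 numeric(1))
  if (all(is.na(vals))) return(NULL)
  list(ranking = sort(vals[!is.na(vals)], decreasing = TRUE),
       missing = names(vals)[is.na(vals)])
}

#' ATP-yield feasibility of an affinity
#'
#' How many whole ATP could be made from the energy released per mole CH4,
#' and whether a metabolism needing `n_required` ATP-equivalents of
#' activation energy is feasible (acetate activation via acetyl-CoA
#' synthetase, for instance, costs two ATP).
#'
#' @param affinity_kj_mol Affinity, kJ per mole CH4.
#' @param atp_cost Cost of one ADP -> ATP phosphorylation, kJ/mol
#'   (default 45).
#' @param n_required ATP count the metabolism must recoup (default 1).
#' @return List with `max_whole_atp` (`floor(max(A, 0)/atp_cost)`) and
#'   `feasible` (`A >= n_required * atp_cost`).
#' @examples
#' atp_feasibility(38, n_required = 2)  # infeasible
#' @export
atp_feasibility <- function(affinity_kj_mol, atp_cost = 45, n_required = 1) {
  .check(atp_cost > 0, "atp_cost must be positive")
  list(max_whole_atp = floor(pmax(affinity_kj_mol, 0) / atp_cost),
       feasible = affinity_kj_mol >= n_required * atp_cost)
}
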