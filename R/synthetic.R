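# Seeded generator of realistic fluid chemistries so every pipeline stage is
# testable without field data. Distributions emulate the compiled field
# ranges: hyperalkaline, carbon-poor type 2 fluids; circumneutral,
# carbon-rich type 1 fluids; and conservative mixtures of the two.

.default_type2 <- list(
  ph_mean = 11.4, ph_sd = 0.12, ph_bounds = c(11.2, 11.65),
  si = c(median = 3e-6, gsd = 1.8),
  dic = c(median = 4e-5, gsd = 2),
  h2 = c(median = 5e-5, gsd = 10),
  ch4 = c(median = 1e-5, gsd = 5),
  formate = c(median = 1.5e-6, gsd = 2),
  acetate = c(median = 2e-6, gsd = 1.6))

.default_type1 <- list(
  ph_mean = 7.9, ph_sd = 0.3, ph_bounds = c(7.2, 8.6),
  si = c(median = 5e-4, gsd = 1.4),
  dic = c(median = 3e-3, gsd = 1.5),
  h2 = c(median = 3e-8, gsd = 3),
  ch4 = c(median = 1e-8, gsd = 3),
  formate = c(median = 1e-6, gsd = 1.8),
  acetate = c(median = 6e-7, gsd = 1.8))

.default_endmembers <- list(
  type1 = c(ph = 7.9, si = 8.5e-4, dic = 3e-3, h2 = 3e-8, ch4 = 1e-8,
            formate = 1e-6, acetate = 6e-7),
  type2 = c(ph = 11.5, si = 1.4e-6, dic = 4e-5, h2 = 2e-4, ch4 = 1e-5,
            formate = 1.5e-6, acetate = 2e-6))

#' Configuration of the synthetic-fluid generator
#'
#' Per-type analyte distributions: pH is truncated normal, temperature
#' uniform on \[19, 36\] degC, and every concentration lognormal (specified
#' by median and geometric standard deviation - concentrations span orders of
#' magnitude and are strictly positive). Mixed fluids are conservative blends
#' of the two end members (see [endmember_mix()]) with multiplicative
#' lognormal noise.
#'
#' @param seed Integer seed; the generator is deterministic given
#'   `(seed, config)`.
#' @param n_type1,n_type2,n_mixed Sample counts per fluid type.
#' @param type1,type2 Per-type distribution lists (see defaults in the
#'   package source); each holds `ph_mean`, `ph_sd`, `ph_bounds` and
#'   `c(median, gsd)` pairs for si, dic, h2, ch4, formate, acetate.
#' @param endmembers List with `type1` and `type2` end-member analyte
#'   vectors for mixed-fluid construction.
#' @param temperature_range degC bounds of the uniform temperature draw.
#' @param mix_noise_gsd Geometric sd of the multiplicative noise applied to
#'   mixed-fluid analytes.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_type1 = 0, n_type2 = 10, n_mixed = 0,
                             type1 = .default_type1, type2 = .default_type2,
                             endmembers = .default_endmembers,
                             temperature_range = c(19, 36),
                             mix_noise_gsd = 1.2) {
  for (ty in list(type1, type2)) {
    for (an in c("si", "dic", "h2", "ch4", "formate", "acetate")) {
      .check(ty[[an]][["median"]] > 0, "analyte medians must be positive")
      .check(ty[[an]][["gsd"]] > 1, "geometric sd must exceed 1")
    }
  }
  .check(n_type1 >= 0 && n_type2 >= 0 && n_mixed >= 0, "counts must be >= 0")
  structure(list(seed = as.integer(seed), n_type1 = n_type1,
                 n_type2 = n_type2, n_mixed = n_mixed,
                 type1 = type1, type2 = type2, endmembers = endmembers,
                 temperature_range = temperature_range,
                 mix_noise_gsd = mix_noise_gsd),
            class = "synthetic_config")
}

# truncated normal by rejection; fine for the mild truncations used here
.rtruncnorm <- function(n, mean, sd, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

.rlognorm <- function(n, spec) {
  stats::rlnorm(n, meanlog = log(spec[["median"]]), sdlog = log(spec[["gsd"]]))
}

#' Conservative two-end-member mix
#'
#' Linear blend of the analyte vectors: each conservative analyte is
#' `f * type2 + (1 - f) * type1`, where `f` is the serpentinized-fluid
#' fraction. pH is interpolated on the same line - a declared
#' non-conservative approximation (true mixed-fluid pH would require
#' titration modeling).
#'
#' @param f Fraction of type 2 (pristine serpentinized) fluid, in \[0, 1\].
#' @param type1_endmember,type2_endmember Named analyte vectors including
#'   `ph`.
#' @return Named numeric vector of mixed analytes.
#' @examples
#' endmember_mix(0.765,
#'               c(ph = 7.9, si = 8.5e-4),
#'               c(ph = 11.5, si = 1.4e-6))
#' @export
endmember_mix <- function(f, type1_endmember, type2_endmember) {
  if (any(f < 0 | f > 1)) {
    stop("mixing fraction must lie in [0, 1]", call. = FALSE)
  }
  .check(setequal(names(type1_endmember), names(type2_endmember)),
         "end-member vectors must share analytes")
  nm <- names(type1_endmember)
  out <- f * type2_endmember[nm] + (1 - f) * type1_endmember[nm]
  stats::setNames(as.numeric(out), nm)
}

#' Generate synthetic fluid samples
#'
#' Deterministic given `(seed, config)`. Type 1 and type 2 samples are
#' independent per-type draws; mixed samples are conservative end-member
#' blends at `f ~ U(0, 1)` with multiplicative lognormal noise, which gives
#' mixed fluids the positive Si-DIC covariance seen in real conservative
#' mixing (both analytes scale with the unreacted-fluid fraction).
#'
#' @param config A [synthetic_config()].
#' @return A `fluid_samples` data frame.
#' @examples
#' generate_fluids(synthetic_config(seed = 7, n_type2 = 3, n_mixed = 2))
#' @export
generate_fluids <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  draw_type <- function(n, ty, label, prefix) {
    if (n == 0) return(NULL)
    data.frame(
      site_id = sprintf("%s%03d", prefix, seq_len(n)),
      location = "synthetic", source = "synthetic", fluid_type = label,
      ph = .rtruncnorm(n, ty$ph_mean, ty$ph_sd, ty$ph_bounds),
      temperature_c = stats::runif(n, config$temperature_range[1],
                                   config$temperature_range[2]),
      si_molal = .rlognorm(n, ty$si),
      dic_molal = .rlognorm(n, ty$dic),
      h2_molal = .rlognorm(n, ty$h2),
      ch4_molal = .rlognorm(n, ty$ch4),
      formate_molal = .rlognorm(n, ty$formate),
      acetate_molal = .rlognorm(n, ty$acetate),
      stringsAsFactors = FALSE)
  }

  draw_mixed <- function(n) {
    if (n == 0) return(NULL)
    em <- config$endmembers
    rows <- lapply(seq_len(n), function(k) {
      f <- stats::runif(1)
      mix <- endmember_mix(f, em$type1, em$type2)
      analytes <- setdiff(names(mix), "ph")
      noise <- stats::rlnorm(length(analytes), 0,
                             log(config$mix_noise_gsd))
      mix[analytes] <- mix[analytes] * noise
      data.frame(
        site_id = sprintf("MIX%03d", k),
        location = "synthetic", source = "synthetic", fluid_type = "mixed",
        ph = unname(mix[["ph"]]),
        temperature_c = stats::runif(1, config$temperature_range[1],
                                     config$temperature_range[2]),
        si_molal = unname(mix[["si"]]), dic_molal = unname(mix[["dic"]]),
        h2_molal = unname(mix[["h2"]]), ch4_molal = unname(mix[["ch4"]]),
        formate_molal = unname(mix[["formate"]]),
        acetate_molal = unname(mix[["acetate"]]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  out <- rbind(draw_type(config$n_type1, config$type1, "type1", "SYN1-"),
               draw_type(config$n_type2, config$type2, "type2", "SYN2-"),
               draw_mixed(config$n_mixed))
  out <- validate_samples(out)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct a sample with a prescribed limiting reactant
#'
#' Builds a fluid sample whose candidate pools guarantee that
#' [limiting_reactant()] selects the requested pool, with at least the given
#' margin between the limiting and every competing `m/|v|` ratio. Useful as a
#' test fixture for the limitation logic.
#'
#' @param reaction_id `"hydrogenotrophic"`, `"formatotrophic"` or
#'   `"acetoclastic"`.
#' @param target_limiting Pool to force limiting: one of the reaction's
#'   candidates (`"h2"`, `"dic"`, `"formate"`, `"acetate"`).
#' @param seed Integer seed.
#' @param margin Minimum factor between competing ratios (default 2).
#' @return A one-row `fluid_samples` data frame.
#' @examples
#' s <- make_limiting_scenario("hydrogenotrophic", "h2", seed = 3)
#' limiting_reactant(methanogenesis_reactions()$hydrogenotrophic, s)$pool
#' @export
make_limiting_scenario <- function(reaction_id, target_limiting, seed = 1,
                                   margin = 2) {
  rxn <- methanogenesis_reactions()[[match.arg(reaction_id, .reaction_ids)]]
  pools <- rxn$pools
  if (!target_limiting %in% names(pools)) {
    stop("'", target_limiting, "' is not a limiting-reactant candidate of ",
         reaction_id, " (candidates: ",
         paste(names(pools), collapse = ", "), ")", call. = FALSE)
  }
  .check(margin >= 1, "margin must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  v <- stats::setNames(abs(rxn$stoich[pools]), names(pools))
  m <- stats::setNames(rep(NA_real_, length(pools)), names(pools))
  m[target_limiting] <- stats::rlnorm(1, log(3e-5), log(2))
  ratio_target <- m[target_limiting] / v[target_limiting]
  for (p in setdiff(names(pools), target_limiting)) {
    m[p] <- ratio_target * v[p] * margin * stats::runif(1, 1, 3)
  }
  out <- data.frame(
    site_id = sprintf("LIM-%s-%s-%d", reaction_id, target_limiting, seed),
    location = "synthetic", source = "synthetic", fluid_type = "type2",
    ph = 11.4, temperature_c = 25,
    si_molal = 3e-6,
    dic_molal = if ("dic" %in% names(m)) unname(m["dic"]) else 4e-5,
    h2_molal = if ("h2" %in% names(m)) unname(m["h2"]) else 5e-5,
    ch4_molal = 1e-5,
    formate_molal = if ("formate" %in% names(m)) unname(m["formate"])
                    else 1.5e-6,
    acetate_molal = if ("acetate" %in% names(m)) unname(m["acetate"])
                    else 2e-6,
    stringsAsFactors = FALSE)
  out <- validate_samples(out)
  out
}
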