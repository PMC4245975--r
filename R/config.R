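# Run configuration: every tunable with its default, serializable to JSON so
# reports can embed the exact parameter snapshot they were produced under.

#' Default run configuration
#'
#' All pipeline tunables with their defaults:
#' * `seed_span` / `extended_seed_span`: guide seed definitions (2-7 / 2-8).
#' * `include_6mer`: report 6mer sites in profiles (default off; profiles
#'   focus on 7-8mer sites).
#' * `gu_spec` / `mm_spec`: relaxed-scan per-seed-length G:U and mismatch
#'   budgets, default `"6;0,7;1,8;1"`.
#' * `protect_position2`: forbid imperfections opposite guide position 2.
#' * `thermo`: `flank` (accessibility window flank, nt), `threshold`
#'   (likely-functional ddG cutoff, kcal/mol), `bulge_max` (duplex DP loop
#'   size), `k_terminal` (asymmetry-score terminal pairs).
#' * `context`: coefficients of the simplified context-like score (type
#'   baselines, local-AU weight and flank width, 3'-pairing weight and
#'   guide span, position weight and scale).
#' * `retention`: the variant-ranking rule table -- per-seed-position
#'   retention ranks (positions 5-6 best, 2 and 7 disruptive) and
#'   mismatch-class orders for retention (G:U wobble most tolerated) and
#'   for off-target discrimination ("detox"; purine:purine best). Encodes
#'   empirical findings, hence data rather than code.
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed_span = c(2L, 7L),
    extended_seed_span = c(2L, 8L),
    include_6mer = FALSE,
    gu_spec = "6;0,7;1,8;1",
    mm_spec = "6;0,7;1,8;1",
    protect_position2 = FALSE,
    thermo = list(flank = 50L, threshold = -10, bulge_max = 3L,
                  k_terminal = 4L),
    context = list(
      baseline = c("8mer" = -0.31, "7mer-m8" = -0.16, "7mer-A1" = -0.10,
                   "6mer" = -0.02),
      au_weight = -0.30, au_flank = 30L,
      pairing_weight = -0.03, pairing_span = c(13L, 16L),
      pairing_search = 16L,
      position_weight = 0.10, position_scale = 1500L),
    retention = list(
      position_rank = c("2" = 3L, "3" = 2L, "4" = 2L, "5" = 1L, "6" = 1L,
                        "7" = 3L, "8" = 2L),
      class_retention = c(gu_wobble = 1L, pyr_pyr = 2L,
                          pur_pyr_mismatch = 3L, pur_pur = 4L),
      class_detox = c(pur_pur = 1L, pur_pyr_mismatch = 2L, pyr_pyr = 3L,
                      gu_wobble = 4L)),
    guide_length_bounds = c(16L, 30L)
  )
}

# merge user overrides into the default tree (shallow per branch)
merge_config <- function(config = list()) {
  base <- default_config()
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      for (k2 in names(config[[k]])) base[[k]][[k2]] <- config[[k]][[k2]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  base
}

config_json <- function(config) {
  jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
}
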