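# Seed detoxification: enumerate single-nucleotide seed variants of a
# guide, recompute off-target profiles, apply exclusion rules (position-8
# overlap, CpG disruption), quantify profile divergence and ddG relief, and
# rank variants by predicted on-target retention.

variant_label <- function(pos, nt) sprintf("v%d%s", pos, nt)

#' Enumerate single-nucleotide seed variants of a guide
#'
#' For each requested position, all three non-identical nucleotides are
#' substituted; the rest of the sequence is untouched. Variants are named
#' `v<position><new_nt>` (e.g. `v5U`, `v6A`), appended to the parent name.
#'
#' @param guide A [guide()].
#' @param positions Seed positions to mutate; default 2-7. Positions must
#'   lie within the extended seed span.
#' @param include_pos8 Append position 8 to `positions`.
#' @return Named list of [guide()] objects (names are the variant labels).
#' @export
enumerate_seed_variants <- function(guide, positions = 2:7,
                                    include_pos8 = FALSE) {
  guide <- as_guide(guide)
  positions <- sort(unique(as.integer(positions)))
  if (include_pos8) positions <- sort(unique(c(positions, 8L)))
  if (any(positions < 1L | positions > nchar(guide$sequence))) {
    stop("variant position outside guide", call. = FALSE)
  }
  out <- list()
  for (p in positions) {
    ref <- substr(guide$sequence, p, p)
    for (nt in setdiff(RNA_ALPHABET, ref)) {
      lab <- variant_label(p, nt)
      seq2 <- guide$sequence
      substr(seq2, p, p) <- nt
      v <- guide(paste0(guide$name, ".", lab), seq2,
                 seed_span = guide$seed_span,
                 extended_seed_span = guide$extended_seed_span)
      v$variant <- list(label = lab, position = p, ref = ref, alt = nt)
      out[[lab]] <- v
    }
  }
  out
}

# exclusion reason for one variant of a parent guide:
#  - position8_overlap: position-8 mutants keep every 7mer-A1/6mer parent
#    site (those types depend only on positions 2-7), so their off-target
#    profile extensively overlaps the parent's
#  - cpg_disruption: the mutation removes a CG dinucleotide from the
#    (extended) seed; CG-requiring seeds match few mammalian 3'UTR sites,
#    so disrupting one inflates the off-target count
exclusion_reason <- function(parent, variant_pos, variant_nt,
                             span = c(2L, 8L)) {
  if (variant_pos == 8L) return("position8_overlap")
  seq_p <- as_guide(parent)$sequence
  seq_v <- seq_p
  substr(seq_v, variant_pos, variant_pos) <- variant_nt
  for (d in c(variant_pos - 1L, variant_pos)) {
    if (d < span[1] || d + 1L > span[2]) next
    if (substr(seq_p, d, d + 1L) == "CG" && substr(seq_v, d, d + 1L) != "CG") {
      return("cpg_disruption")
    }
  }
  "none"
}

#' Annotate variant reports with exclusion rules
#'
#' Flags are annotations, not drops: position-8 variants are flagged
#' `position8_overlap`, variants whose mutation removes a CG dinucleotide
#' from the extended seed are flagged `cpg_disruption`. The caller chooses
#' whether flagged variants are discarded.
#'
#' @param parent_profile The parent's `offtarget_profile` (supplies the
#'   parent guide).
#' @param variant_reports A `variant_screen` data.frame (or any data.frame
#'   with `position` and `alt` columns).
#' @return The reports with `excluded` (logical) and `exclusion_reason`
#'   columns filled in.
#' @export
apply_exclusion_rules <- function(parent_profile, variant_reports) {
  parent <- if (inherits(parent_profile, "offtarget_profile")) {
    parent_profile$guide
  } else as_guide(parent_profile)
  reasons <- vapply(seq_len(nrow(variant_reports)), function(i) {
    exclusion_reason(parent, variant_reports$position[i],
                     variant_reports$alt[i],
                     span = parent$extended_seed_span)
  }, character(1))
  variant_reports$exclusion_reason <- reasons
  variant_reports$excluded <- reasons != "none"
  variant_reports
}

#' Compare a variant's off-target profile with its parent's
#'
#' Gene-level sharing (`n_shared`, `shared_fraction = n_shared / parent
#' genes`) and site-level sharing (identical deduplication keys), plus the
#' mean ddG shift: each parent site window is rescored with the variant
#' guide and the mean of (variant ddG - parent ddG) reported. Rescoring
#' reuses the parent's windows (the question is how much weaker the parent's
#' predicted sites become), so the opening energy cancels and only the
#' duplex term shifts; any seed mismatch makes the shift strictly positive.
#'
#' @param parent_profile,variant_profile `offtarget_profile`s built on the
#'   same UTRome with identical options.
#' @param utrome The [utrome()] both profiles were built on (for windows).
#' @param model An `energy_model`.
#' @return List: `n_shared`, `shared_fraction`, `n_shared_sites`,
#'   `mean_ddg_shift`, `per_site` (data.frame of per-site shifts).
#'   `shared_fraction` is `NA` when the parent profile is empty.
#' @export
compare_profiles <- function(parent_profile, variant_profile, utrome,
                             model = default_energy_model()) {
  stopifnot(inherits(parent_profile, "offtarget_profile"),
            inherits(variant_profile, "offtarget_profile"))
  pg <- parent_profile$genes$gene_id
  vg <- variant_profile$genes$gene_id
  n_shared <- length(intersect(pg, vg))
  frac <- if (length(pg)) n_shared / length(pg) else NA_real_

  key <- function(s) {
    paste(s$transcript_id, s$start, s$end, s$site_type, sep = ":")
  }
  n_shared_sites <- length(intersect(key(parent_profile$sites),
                                     key(variant_profile$sites)))

  ps <- parent_profile$sites
  shifts <- numeric(0)
  if (nrow(ps)) {
    cfg <- merge_config(parent_profile$params[
      intersect(names(parent_profile$params), names(default_config()))])
    seqs <- setNames(utrome$sequence, utrome$transcript_id)
    glen <- nchar(parent_profile$guide$sequence)
    shifts <- vapply(seq_len(nrow(ps)), function(i) {
      win <- duplex_window(seqs[[ps$transcript_id[i]]], ps$start[i],
                           ps$end[i], ps$site_type[i], glen,
                           cfg$thermo$bulge_max)
      dv <- duplex_energy(variant_profile$guide, win, model = model,
                          bulge_max = cfg$thermo$bulge_max)
      dv - ps$dg_duplex[i]
    }, numeric(1))
  }
  list(n_shared = n_shared, shared_fraction = frac,
       n_shared_sites = n_shared_sites,
       mean_ddg_shift = if (length(shifts)) mean(shifts) else NA_real_,
       per_site = data.frame(gene_id = ps$gene_id,
                             transcript_id = ps$transcript_id,
                             start = ps$start, ddg_shift = shifts,
                             stringsAsFactors = FALSE))
}

#' Rank variant reports by predicted on-target retention
#'
#' The rule table (see `default_config()$retention`) encodes the empirical
#' picture: mismatches at seed positions 5-6 retain silencing best,
#' positions 2 and 7 disrupt it; within a position, a G:U wobble opposition
#' retains the most residual silencing, then pyrimidine:pyrimidine, then
#' purine:purine -- which is also why purine:purine discriminates
#' off-targets best and leads the separate detox ranking. Final ordering:
#' non-excluded variants first, then lexicographic on (retention_rank,
#' n_offtargets, shared_fraction, detox_rank, variant).
#'
#' @param reports A `variant_screen` data.frame (annotated by
#'   [apply_exclusion_rules()]).
#' @param rules Retention rule table; default from [default_config()].
#' @return The reports with `retention_rank` and `detox_rank` columns,
#'   reordered.
#' @export
rank_variants <- function(reports, rules = default_config()$retention) {
  pos_rank <- rules$position_rank[as.character(reports$position)]
  pos_rank[is.na(pos_rank)] <- max(rules$position_rank) + 1L
  cls_ret <- rules$class_retention[reports$mismatch_class]
  cls_det <- rules$class_detox[reports$mismatch_class]
  reports$retention_rank <- as.integer(pos_rank) * 10L + as.integer(cls_ret)
  reports$detox_rank <- as.integer(cls_det)
  ord <- order(reports$excluded, reports$retention_rank,
               reports$n_offtargets, reports$shared_fraction,
               reports$detox_rank, reports$variant)
  out <- reports[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen all single-nucleotide seed variants of a guide
#'
#' The full detoxification table: enumerates variants, builds each one's
#' off-target profile on the same UTRome, compares it with the parent's
#' (overall and expressed counts, shared genes/sites, mean ddG shift over
#' the parent's sites), applies exclusion rules and ranks by retention.
#'
#' @param parent A [guide()].
#' @param utrome A [utrome()].
#' @param expression Optional [expression_set()].
#' @param positions Seed positions to mutate; default 2-8 so position-8
#'   mutants appear in the table (flagged) as well.
#' @param config,model As in [build_profile()].
#' @param verbose Progress messages.
#' @return Object of class `"variant_screen"`: a data.frame with one row
#'   per variant plus the parent profile in `attr(, "parent_profile")` and
#'   all variant profiles in `attr(, "profiles")`.
#' @export
variant_screen <- function(parent, utrome, expression = NULL,
                           positions = 2:8, config = list(),
                           model = default_energy_model(),
                           verbose = FALSE) {
  parent <- as_guide(parent)
  cfg <- merge_config(config)
  parent_profile <- build_profile(parent, utrome, expression, cfg, model)
  variants <- enumerate_seed_variants(parent, positions = positions)
  rows <- list(); profiles <- list()
  for (lab in names(variants)) {
    v <- variants[[lab]]
    if (verbose) message("profiling variant ", lab)
    vp <- build_profile(v, utrome, expression, cfg, model)
    cmp <- compare_profiles(parent_profile, vp, utrome, model)
    # the opposition the variant creates at parent-complementary targets:
    # target nt opposite position p is the complement of the parent's nt
    tgt_nt <- comp_nt(v$variant$ref)
    rows[[lab]] <- data.frame(
      variant = lab, position = v$variant$position, ref = v$variant$ref,
      alt = v$variant$alt,
      mismatch_class = classify_mismatch(v$variant$alt, tgt_nt),
      n_offtargets = nrow(vp$genes),
      n_expressed = sum(vp$genes$expressed),
      n_shared = cmp$n_shared, n_shared_sites = cmp$n_shared_sites,
      shared_fraction = cmp$shared_fraction,
      mean_ddg_shift = cmp$mean_ddg_shift,
      stringsAsFactors = FALSE)
    profiles[[lab]] <- vp
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- apply_exclusion_rules(parent_profile, tab)
  tab <- rank_variants(tab, rules = cfg$retention)
  structure(tab, class = c("variant_screen", "data.frame"),
            parent_profile = parent_profile, profiles = profiles)
}

#' @export
print.variant_screen <- function(x, ...) {
  pp <- attr(x, "parent_profile")
  cat(sprintf("<variant_screen> parent %s: %d off-target genes (%d expressed)\n",
              pp$guide$name, nrow(pp$genes), sum(pp$genes$expressed)))
  cols <- c("variant", "mismatch_class", "n_offtargets", "n_expressed",
            "n_shared", "shared_fraction", "mean_ddg_shift",
            "exclusion_reason")
  df <- as.data.frame(x)[, cols]
  df$shared_fraction <- round(df$shared_fraction, 3)
  df$mean_ddg_shift <- round(df$mean_ddg_shift, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
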