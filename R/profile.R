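# The per-guide off-target pipeline: canonical scan -> relaxed scan ->
# intersection -> ddG + context scoring -> genomic dedup -> gene
# aggregation -> expression filter -> ranking; plus cross-species
# conservation of off-target genes.

#' Simplified context-like site score
#'
#' A dimensionless site score with TargetScan-like ranking semantics (more
#' negative = stronger), built from four documented terms: a site-type
#' baseline (8mer < 7mer-m8 < 7mer-A1 < 6mer), a local-AU term (AU fraction
#' in 30-nt flanks, centered and weighted negatively: AU-rich context is
#' favorable), a 3'-pairing term (longest complementary run of guide
#' positions 13-16 against the target flank 5' of the site), and a position
#' term (sites near the UTR ends are favorable). Coefficients live in
#' `config$context`. This is deliberately not a reimplementation of the
#' published context+ regression; only the ranking semantics are preserved.
#'
#' @param site A list or one-row data.frame with `site_type`, `start`, `end`.
#' @param utr_sequence The UTR sequence the site lies on.
#' @param guide A [guide()].
#' @param config See [default_config()].
#' @return Numeric score.
#' @export
context_score <- function(site, utr_sequence, guide,
                          config = default_config()) {
  cfg <- config$context
  s <- normalize_sequence(utr_sequence)
  n <- nchar(s)
  start <- as.integer(site$start); end <- as.integer(site$end)
  base <- cfg$baseline[[site$site_type]]

  fl1 <- substr(s, max(1L, start - cfg$au_flank), start - 1L)
  fl2 <- substr(s, end + 1L, min(n, end + cfg$au_flank))
  fl <- paste0(fl1, fl2)
  au <- if (nzchar(fl)) {
    mean(strsplit(fl, "", fixed = TRUE)[[1]] %in% c("A", "U"))
  } else 0.5
  au_term <- cfg$au_weight * (au - 0.5)

  g3 <- substr(as_guide(guide)$sequence, cfg$pairing_span[1],
               cfg$pairing_span[2])
  up <- substr(s, max(1L, start - cfg$pairing_search), start - 1L)
  pair_term <- cfg$pairing_weight * longest_comp_run(g3, up)

  d <- min(start - 1L, n - end)
  pos_term <- cfg$position_weight * min(d, cfg$position_scale) /
    cfg$position_scale

  unname(base + au_term + pair_term + pos_term)
}

# longest run of consecutive complementary oppositions between a guide 3'
# fragment (5'->3') and a target fragment (5'->3'), over all offsets
longest_comp_run <- function(gfrag, tfrag) {
  if (!nzchar(gfrag) || !nzchar(tfrag)) return(0L)
  grc <- revcomp(gfrag)
  gc <- strsplit(grc, "", fixed = TRUE)[[1]]
  tc <- strsplit(tfrag, "", fixed = TRUE)[[1]]
  lg <- length(gc); lt <- length(tc)
  best <- 0L
  for (off in seq_len(lt - 1L + lg) - lg) {
    run <- 0L
    for (k in seq_len(lg)) {
      tpos <- off + k
      if (tpos >= 1L && tpos <= lt && gc[k] == tc[tpos]) {
        run <- run + 1L
        if (run > best) best <- run
      } else {
        run <- 0L
      }
    }
  }
  best
}

#' Build a per-guide off-target profile over a UTRome
#'
#' Executes, in order: canonical seed-site scan; relaxed scan; intersection
#' (relaxed evidence must overlap a canonical site by at least one
#' nucleotide, otherwise the site is dropped -- accessibility-based calls
#' without a canonical seed match are not trusted); ddG and context-like
#' scoring of each surviving site; genomic deduplication across isoforms;
#' aggregation to gene records (site count, strongest context score,
#' strongest ddG); expression marking; and ranking of genes ascending by
#' minimum ddG, tie-broken by minimum context score then gene id.
#'
#' @param guide A [guide()].
#' @param utrome A [utrome()].
#' @param expression Optional [expression_set()]; genes in it are marked
#'   expressed and counted in the expressed subset.
#' @param config See [default_config()]; partial overrides allowed.
#' @param model An `energy_model`.
#' @param verbose Log stage counts via `message()`.
#' @return Object of class `"offtarget_profile"`.
#' @export
build_profile <- function(guide, utrome, expression = NULL,
                          config = list(), model = default_energy_model(),
                          verbose = FALSE) {
  guide <- as_guide(guide)
  cfg <- merge_config(config)
  if (!inherits(utrome, "utrome")) utrome <- as_utr_records(utrome)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!nrow(utrome)) {
    warning("empty UTRome: returning empty profile", call. = FALSE)
    return(new_profile(guide, utrome, empty_scored_df(), expression, cfg,
                       model, c(canonical = 0L, relaxed = 0L,
                                intersected = 0L, deduped = 0L)))
  }

  canon <- scan_canonical(guide, utrome, include_6mer = cfg$include_6mer)
  relax <- scan_relaxed(guide, utrome, gu_spec = cfg$gu_spec,
                        mm_spec = cfg$mm_spec,
                        protect_position2 = cfg$protect_position2)
  say("canonical sites: %d; relaxed sites: %d", nrow(canon), nrow(relax))

  sites <- intersect_sites(canon, relax)
  n_int <- nrow(sites)
  say("sites after intersection: %d", n_int)

  sites <- dedupe_genomic(sites)
  say("sites after genomic dedup: %d", nrow(sites))

  sites <- score_sites(sites, guide, utrome, cfg, model)

  counts <- c(canonical = nrow(canon), relaxed = nrow(relax),
              intersected = n_int, deduped = nrow(sites))
  new_profile(guide, utrome, sites, expression, cfg, model, counts)
}

empty_scored_df <- function() {
  df <- empty_sites_df()
  df$seed_len <- integer(0); df$n_mm <- integer(0); df$n_gu <- integer(0)
  df$mm_positions <- character(0)
  df$dg_duplex <- numeric(0); df$dg_open <- numeric(0)
  df$ddg <- numeric(0); df$likely_functional <- logical(0)
  df$context_score <- numeric(0); df$expressed <- logical(0)
  df
}

# keep canonical sites overlapped (>= 1 nt, same transcript) by a relaxed
# site; annotate each kept site with its best-supporting relaxed record
intersect_sites <- function(canon, relax) {
  if (!nrow(canon)) {
    out <- canon
    out$seed_len <- integer(0); out$n_mm <- integer(0)
    out$n_gu <- integer(0); out$mm_positions <- character(0)
    return(out)
  }
  keep <- logical(nrow(canon))
  seed_len <- integer(nrow(canon)); n_mm <- integer(nrow(canon))
  n_gu <- integer(nrow(canon)); mm_pos <- character(nrow(canon))
  rx_by_tx <- split(seq_len(nrow(relax)), relax$transcript_id)
  for (i in seq_len(nrow(canon))) {
    idx <- rx_by_tx[[canon$transcript_id[i]]]
    if (is.null(idx)) next
    ov <- idx[relax$start[idx] <= canon$end[i] &
                relax$end[idx] >= canon$start[i]]
    if (!length(ov)) next
    keep[i] <- TRUE
    best <- ov[order(-relax$seed_len[ov],
                     relax$n_mm[ov] + relax$n_gu[ov],
                     relax$start[ov])][1]
    seed_len[i] <- relax$seed_len[best]
    n_mm[i] <- relax$n_mm[best]; n_gu[i] <- relax$n_gu[best]
    mm_pos[i] <- relax$mm_positions[best]
  }
  out <- canon[keep, , drop = FALSE]
  out$seed_len <- seed_len[keep]; out$n_mm <- n_mm[keep]
  out$n_gu <- n_gu[keep]; out$mm_positions <- mm_pos[keep]
  rownames(out) <- NULL
  out
}

score_sites <- function(sites, guide, utrome, cfg, model) {
  n <- nrow(sites)
  sites$dg_duplex <- numeric(n); sites$dg_open <- numeric(n)
  sites$ddg <- numeric(n); sites$likely_functional <- logical(n)
  sites$context_score <- numeric(n)
  if (!n) return(sites)
  seqs <- setNames(utrome$sequence, utrome$transcript_id)
  glen <- nchar(guide$sequence)
  for (i in seq_len(n)) {
    s <- seqs[[sites$transcript_id[i]]]
    win <- duplex_window(s, sites$start[i], sites$end[i],
                         sites$site_type[i], glen, cfg$thermo$bulge_max)
    dgd <- duplex_energy(guide, win, model = model,
                         bulge_max = cfg$thermo$bulge_max)
    dgo <- opening_energy(s, c(sites$start[i], sites$end[i]),
                          flank = cfg$thermo$flank, model = model)
    d <- ddg(dgd, dgo, functional_threshold = cfg$thermo$threshold)
    sites$dg_duplex[i] <- dgd; sites$dg_open[i] <- dgo
    sites$ddg[i] <- d$ddg; sites$likely_functional[i] <- d$likely_functional
    sites$context_score[i] <- context_score(sites[i, ], s, guide, cfg)
  }
  sites
}

# target window for the guide:target duplex: the seed-pairing region plus
# enough upstream target flank for the guide 3' region (the A1 adenine is
# unpaired and excluded)
duplex_window <- function(seq, start, end, site_type, guide_len, bulge_max) {
  pe <- end - (site_type %in% c("8mer", "7mer-A1"))
  ws <- max(1L, pe - (guide_len + bulge_max) + 1L)
  substr(seq, ws, pe)
}

new_profile <- function(guide, utrome, sites, expression, cfg, model,
                        counts) {
  genes <- aggregate_genes(sites)
  expr_ids <- if (is.null(expression)) character(0) else expression$gene_ids
  sites$expressed <- normalize_gene_id(sites$gene_id) %in% expr_ids
  genes$expressed <- normalize_gene_id(genes$gene_id) %in% expr_ids
  genes <- genes[order(genes$min_ddg, genes$min_context_score,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(
    guide = guide, species = attr(utrome, "species"), sites = sites,
    genes = genes,
    expressed_subset = genes$gene_id[genes$expressed],
    params = c(cfg, list(energy_model = model$version)),
    stage_counts = counts), class = "offtarget_profile")
}

aggregate_genes <- function(sites) {
  if (!nrow(sites)) {
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      n_transcripts = integer(0),
                      min_context_score = numeric(0), min_ddg = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(sites)), sites$gene_id)
  data.frame(
    gene_id = names(sp),
    n_sites = vapply(sp, length, integer(1)),
    n_transcripts = vapply(sp, function(i) {
      length(unique(sites$transcript_id[i]))
    }, integer(1)),
    min_context_score = vapply(sp, function(i) {
      min(sites$context_score[i])
    }, numeric(1)),
    min_ddg = vapply(sp, function(i) min(sites$ddg[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Summary counts for an off-target profile
#'
#' Both gene- and transcript-granularity counts are reported so totals can
#' be read either way.
#'
#' @param profile An `offtarget_profile`.
#' @return List: `n_offtarget_genes`, `n_offtarget_transcripts`, `n_sites`,
#'   `n_expressed_genes`, `n_expressed_transcripts`.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "offtarget_profile"))
  s <- profile$sites
  list(n_offtarget_genes = nrow(profile$genes),
       n_offtarget_transcripts = length(unique(s$transcript_id)),
       n_sites = nrow(s),
       n_expressed_genes = sum(profile$genes$expressed),
       n_expressed_transcripts =
         length(unique(s$transcript_id[s$expressed])))
}

#' @method summary offtarget_profile
#' @export
summary.offtarget_profile <- function(object, ...) {
  structure(profile_summary(object), class = "offtarget_profile_summary")
}

#' @export
print.offtarget_profile_summary <- function(x, ...) {
  cat(sprintf(paste0("off-target genes: %d (expressed: %d)\n",
                     "off-target transcripts: %d (expressed: %d)\n",
                     "sites: %d\n"),
              x$n_offtarget_genes, x$n_expressed_genes,
              x$n_offtarget_transcripts, x$n_expressed_transcripts,
              x$n_sites))
  invisible(x)
}

#' @export
print.offtarget_profile <- function(x, ...) {
  cat(sprintf("<offtarget_profile> guide %s%s\n", x$guide$name,
              if (!is.null(x$species) && !is.na(x$species)) {
                paste0(" on ", x$species)
              } else ""))
  print(summary(x))
  if (nrow(x$genes)) {
    cat("top genes by ddG:\n")
    print(head(x$genes, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @method plot offtarget_profile
#' @export
plot.offtarget_profile <- function(x, ...) {
  s <- x$sites
  if (!nrow(s)) {
    graphics::plot.new(); graphics::title("empty profile")
    return(invisible(x))
  }
  graphics::plot(s$context_score, s$ddg,
       col = ifelse(s$expressed, "firebrick", "grey40"),
       pch = 19, xlab = "context-like score", ylab = "ddG (kcal/mol)",
       main = paste("off-target sites:", x$guide$name), ...)
  graphics::abline(h = x$params$thermo$threshold, lty = 2)
  invisible(x)
}

#' Cross-species conservation of off-target genes
#'
#' A gene in profile A is conserved iff at least one of its orthologs
#' carries at least one site in profile B (anywhere in the ortholog's
#' 3'UTR). Genes without a map entry are excluded from the mapped
#' denominator and counted separately; both directions are reported.
#' `fraction` is conserved / all off-target genes (matching how overlap is
#' usually quoted); `fraction_mapped` restricts the denominator to mapped
#' genes.
#'
#' @param profile_a,profile_b `offtarget_profile`s built for the same guide
#'   (identical seed) on two species' UTRomes.
#' @param map An [ortholog_map()] from A-species ids to B-species ids.
#' @return Object of class `"conservation_report"`.
#' @export
conserved_offtargets <- function(profile_a, profile_b, map) {
  stopifnot(inherits(profile_a, "offtarget_profile"),
            inherits(profile_b, "offtarget_profile"),
            inherits(map, "ortholog_map"))
  if (seed_of(profile_a$guide) != seed_of(profile_b$guide)) {
    stop("profiles were built for guides with different seeds",
         call. = FALSE)
  }
  one_dir <- function(ga, gb, m) {
    ga_n <- normalize_gene_id(ga); gb_n <- normalize_gene_id(gb)
    mapped <- ga[ga_n %in% normalize_gene_id(m$pairs$a)]
    conserved <- mapped[vapply(mapped, function(g) {
      any(normalize_gene_id(orthologs_of(m, g)) %in% gb_n)
    }, logical(1))]
    list(mapped = mapped, conserved = conserved)
  }
  ga <- profile_a$genes$gene_id; gb <- profile_b$genes$gene_id
  ab <- one_dir(ga, gb, map)
  ba <- one_dir(gb, ga, invert_ortholog_map(map))
  structure(list(
    species = c(profile_a$species, profile_b$species),
    guide = profile_a$guide$name,
    n_a = length(ga), n_b = length(gb),
    conserved_genes = ab$conserved,
    conserved_genes_b = ba$conserved,
    n_unmapped_a = length(ga) - length(ab$mapped),
    n_unmapped_b = length(gb) - length(ba$mapped),
    fraction = if (length(ga)) length(ab$conserved) / length(ga) else NA_real_,
    fraction_mapped = if (length(ab$mapped)) {
      length(ab$conserved) / length(ab$mapped)
    } else NA_real_), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> guide %s: %s (%d genes) vs %s (%d genes)\n",
              x$guide, ifelse(is.na(x$species[1]), "A", x$species[1]), x$n_a,
              ifelse(is.na(x$species[2]), "B", x$species[2]), x$n_b))
  cat(sprintf(" conserved: %d (fraction %.3f; of mapped %.3f); unmapped: %d\n",
              length(x$conserved_genes), x$fraction, x$fraction_mapped,
              x$n_unmapped_a))
  invisible(x)
}
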