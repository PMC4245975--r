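# Deterministic synthetic-data generator: UTRomes with controllable
# length/GC/CpG composition, planted seed sites with known coordinates,
# multi-species fixtures with known conservation structure, and transcript
# models with planted retargeting sites. Background sequence is scrubbed so
# fixtures advertise zero unintended canonical sites for their guide,
# making pipeline tests exact rather than statistical.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

new_truth <- function(rng_seed, params = list()) {
  structure(list(rng_seed = rng_seed,
                 planted = data.frame(gene_id = character(0),
                                      transcript_id = character(0),
                                      site_type = character(0),
                                      start = integer(0), end = integer(0),
                                      mm_position = integer(0),
                                      stringsAsFactors = FALSE),
                 params = params, conserved = list()),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> seed %d; %d planted site(s)\n",
              x$rng_seed, nrow(x$planted)))
  invisible(x)
}

random_rna <- function(n, gc, cpg_depletion) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  s <- sample(RNA_ALPHABET, n, replace = TRUE, prob = p)
  if (cpg_depletion > 0 && n > 1L) {
    kept <- logical(n)  # CG at i already passed the thinning draw
    repl_p <- p[c("A", "C", "U")] / sum(p[c("A", "C", "U")])
    for (iter in 1:20) {
      cg <- which(s[-n] == "C" & s[-1L] == "G" & !kept[-n])
      if (!length(cg)) break
      u <- runif(length(cg))
      keep <- u >= cpg_depletion
      kept[cg[keep]] <- TRUE
      kill <- cg[!keep]
      if (length(kill)) {
        s[kill + 1L] <- sample(c("A", "C", "U"), length(kill),
                               replace = TRUE, prob = repl_p)
      }
    }
    cg <- which(s[-n] == "C" & s[-1L] == "G" & !kept[-n])
    if (length(cg)) s[cg + 1L] <- "A"
  }
  paste(s, collapse = "")
}

#' Generate a synthetic UTRome
#'
#' Emulates a mammalian 3'UTR collection: AU-rich composition (default GC
#' 0.44) with CpG-depleted dinucleotide structure (default depletion 0.8,
#' i.e. CG occurs at roughly 20% of its expected-under-independence
#' frequency, matching the rarity of CG in mammalian 3'UTRs). Fully
#' deterministic given `rng_seed`.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param length_range Integer pair of min/max UTR length; default
#'   500-1500 nt.
#' @param gc Target GC fraction in `[0, 1]`; default 0.44.
#' @param cpg_depletion Probability that a nascent CG dinucleotide is
#'   thinned away; default 0.8. `gc = 1` with `cpg_depletion = 1` is
#'   rejected as infeasible.
#' @param rng_seed Mandatory RNG seed.
#' @param species Optional species label carried on the UTRome.
#' @param gene_prefix Prefix for generated gene ids.
#' @return List with elements `utrome` (a [utrome()]) and `truth`
#'   (a `synth_truth` with no planted sites yet).
#' @export
generate_utrome <- function(n_genes, length_range = c(500L, 1500L),
                            gc = 0.44, cpg_depletion = 0.8, rng_seed,
                            species = NA_character_, gene_prefix = "g") {
  stopifnot(n_genes >= 0L, length(length_range) == 2L,
            length_range[1] >= 20L, length_range[1] <= length_range[2])
  if (gc < 0 || gc > 1 || cpg_depletion < 0 || cpg_depletion > 1) {
    stop("gc and cpg_depletion must lie in [0, 1]", call. = FALSE)
  }
  if (gc >= 1 && cpg_depletion >= 1) {
    stop("infeasible composition: gc = 1 with full CpG depletion",
         call. = FALSE)
  }
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  params <- list(n_genes = n_genes, length_range = length_range, gc = gc,
                 cpg_depletion = cpg_depletion)
  truth <- new_truth(rng_seed, params)
  if (n_genes == 0L) {
    return(list(utrome = utrome(character(0), character(0), character(0),
                                species = species),
                truth = truth))
  }
  with_seed(rng_seed, {
    lens <- sample.int(length_range[2] - length_range[1] + 1L, n_genes,
                       replace = TRUE) + length_range[1] - 1L
    seqs <- vapply(lens, random_rna, "", gc = gc,
                   cpg_depletion = cpg_depletion)
    gene_ids <- sprintf("%s%04d", gene_prefix, seq_len(n_genes))
    offs <- cumsum(c(0L, head(lens + 1000L, -1L)))
    ut <- utrome(gene_id = gene_ids,
                 transcript_id = paste0(gene_ids, "_t1"), sequence = seqs,
                 chrom = "chr1", gstart = offs, gend = offs + lens,
                 strand = "+", species = species)
    list(utrome = ut, truth = truth)
  })
}

# target window (5'->3') pairing guide positions 2..L+1, with an optional
# self-nucleotide mismatch opposite guide position mm_position
relaxed_motif <- function(guide, seed_len, mm_position = NA_integer_) {
  w <- revcomp(seed_of(guide, c(2L, seed_len + 1L)))
  if (!is.na(mm_position)) {
    j <- seed_len + 2L - mm_position  # window pos pairing guide mm_position
    substr(w, j, j) <- substr(guide$sequence, mm_position, mm_position)
  }
  w
}

# mutate one unprotected pairing position of an unintended site so that it
# no longer pairs its guide partner (self-nucleotide: never WC, never G:U)
break_site <- function(seqchars, start, end, site_type, guide, protected) {
  gseq <- guide$sequence
  # guide position paired by window offset j (1-based within the site)
  width <- end - start + 1L
  pos8 <- site_type %in% c("7mer-m8", "8mer")
  pair_len <- width - (site_type %in% c("7mer-A1", "8mer"))
  for (j in order(abs(seq_len(pair_len) - ceiling(pair_len / 2)))) {
    p <- start + j - 1L
    if (p %in% protected) next
    gpos <- (if (pos8) 9L else 8L) - j
    seqchars[p] <- substr(gseq, gpos, gpos)
    return(seqchars)
  }
  NULL
}

scrub_canonical <- function(seqchars, guide, protected, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    s <- paste(seqchars, collapse = "")
    sites <- scan_canonical(guide, s, include_6mer = TRUE)
    if (nrow(sites)) {
      # a site is intended iff its span matches a planted span exactly
      unint <- vapply(seq_len(nrow(sites)), function(i) {
        !any(protected$start == sites$start[i] &
               protected$end == sites$end[i])
      }, logical(1))
      sites <- sites[unint, , drop = FALSE]
    }
    if (!nrow(sites)) return(seqchars)
    prot_pos <- unlist(mapply(seq, protected$start, protected$end,
                              SIMPLIFY = FALSE))
    fixed <- FALSE
    for (i in seq_len(nrow(sites))) {
      out <- break_site(seqchars, sites$start[i], sites$end[i],
                        sites$site_type[i], guide, prot_pos)
      if (!is.null(out)) { seqchars <- out; fixed <- TRUE; break }
    }
    if (!fixed) return(NULL)
  }
  NULL
}

scrub_relaxed <- function(seqchars, guide, protected, gu_spec, mm_spec,
                          max_iter = 50L) {
  gu_allow <- parse_allowance_spec(gu_spec)
  mm_allow <- parse_allowance_spec(mm_spec)
  for (it in seq_len(max_iter)) {
    s <- paste(seqchars, collapse = "")
    hits <- scan_relaxed(guide, s, gu_spec = gu_spec, mm_spec = mm_spec)
    if (nrow(hits)) {
      unint <- vapply(seq_len(nrow(hits)), function(i) {
        !any(protected$start <= hits$end[i] &
               protected$end >= hits$start[i])
      }, logical(1))
      hits <- hits[unint, , drop = FALSE]
    }
    if (!nrow(hits)) return(seqchars)
    prot_pos <- unlist(mapply(seq, protected$start, protected$end,
                              SIMPLIFY = FALSE))
    h <- hits[1, ]
    budget <- max(mm_allow[as.character(h$seed_len)],
                  gu_allow[as.character(h$seed_len)], na.rm = TRUE)
    need <- budget + 1L - h$n_mm
    done <- 0L
    for (j in seq_len(h$seed_len)) {
      if (done >= need) break
      p <- h$start + j - 1L
      if (p %in% prot_pos) next
      gpos <- h$seed_len + 2L - j
      cur <- seqchars[p]
      tgt <- substr(guide$sequence, gpos, gpos)
      if (cur == tgt) next  # already a self-mismatch
      seqchars[p] <- tgt
      done <- done + 1L
    }
    if (done == 0L) return(NULL)
  }
  NULL
}

#' Plant seed sites into a synthetic UTRome
#'
#' Writes the requested motifs at randomized non-overlapping positions and
#' re-edits the background so a canonical scan finds exactly the planted
#' canonical sites and nothing else (verified at generation time by
#' scanning; over-constrained placements are rejected after bounded
#' retries). Canonical plants fix their flanking bases so the planted type
#' is exact (e.g. a planted 7mer-A1 is not silently upgradeable to an
#' 8mer). Relaxed plants (`site_type = "relaxed"`) carry a single
#' self-nucleotide mismatch at `mm_position` (guide coordinate 2-7) and are
#' invisible to the canonical scan; with `scrub = "relaxed"` the background
#' is additionally scrubbed of unintended relaxed hits under the given
#' budgets.
#'
#' @param utrome A [utrome()] (typically from [generate_utrome()]).
#' @param guide A [guide()].
#' @param spec data.frame with columns `gene_id`, `site_type` (one of
#'   `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"relaxed"`); optional
#'   `seed_len` (default 7) and `mm_position` for relaxed plants.
#' @param rng_seed Mandatory RNG seed.
#' @param scrub `"canonical"` (default) or `"relaxed"` (implies canonical).
#' @param gu_spec,mm_spec Budgets used when `scrub = "relaxed"`.
#' @param max_retries Placement retries before rejecting; default 1000.
#' @return List with `utrome` (edited) and `truth` (planted coordinates).
#' @export
plant_sites <- function(utrome, guide, spec, rng_seed,
                        scrub = c("canonical", "relaxed"),
                        gu_spec = "6;0,7;1,8;1", mm_spec = "6;0,7;1,8;1",
                        max_retries = 1000L) {
  scrub <- match.arg(scrub)
  guide <- as_guide(guide)
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  if (!nrow(spec)) {
    truth <- new_truth(rng_seed)
    return(list(utrome = utrome, truth = truth))
  }
  if (is.null(spec$seed_len)) spec$seed_len <- 7L
  if (is.null(spec$mm_position)) spec$mm_position <- NA_integer_
  bad_mm <- spec$site_type == "relaxed" &
    (is.na(spec$mm_position) | spec$mm_position < 2L | spec$mm_position > 7L)
  if (any(bad_mm)) {
    stop("relaxed plants need mm_position in 2..7", call. = FALSE)
  }
  truth <- new_truth(rng_seed)
  with_seed(rng_seed, {
    seqs <- strsplit(utrome$sequence, "", fixed = TRUE)
    names(seqs) <- utrome$transcript_id
    planted_by_rec <- setNames(vector("list", nrow(utrome)),
                               utrome$transcript_id)
    rows <- list()
    for (i in seq_len(nrow(spec))) {
      gi <- which(utrome$gene_id == spec$gene_id[i])[1]
      if (is.na(gi)) {
        stop("gene not in UTRome: ", spec$gene_id[i], call. = FALSE)
      }
      tx <- utrome$transcript_id[gi]
      ty <- spec$site_type[i]
      motif <- if (ty == "relaxed") {
        relaxed_motif(guide, spec$seed_len[i], spec$mm_position[i])
      } else {
        canonical_motifs(guide)[[ty]]
      }
      L <- nchar(motif)
      len <- length(seqs[[tx]])
      if (len < L + 2L) {
        stop("UTR too short to plant a site in gene ", spec$gene_id[i],
             call. = FALSE)
      }
      prior <- planted_by_rec[[tx]]
      placed <- FALSE
      for (r in seq_len(max_retries)) {
        s0 <- sample.int(len - L - 1L, 1L) + 1L  # keep 1-nt flanks free
        e0 <- s0 + L - 1L
        clash <- !is.null(prior) &&
          any(prior$start <= e0 + 1L & prior$end >= s0 - 1L)
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place site in gene ", spec$gene_id[i],
             " after bounded retries", call. = FALSE)
      }
      seqs[[tx]][s0:e0] <- strsplit(motif, "", fixed = TRUE)[[1]]
      # pin flanks so the planted type is exact
      g8c <- comp_nt(substr(guide$sequence, 8L, 8L))
      if (ty %in% c("6mer", "7mer-A1") && s0 > 1L &&
          seqs[[tx]][s0 - 1L] == g8c) {
        seqs[[tx]][s0 - 1L] <- setdiff(c("C", "G", "A"), g8c)[1]
      }
      if (ty %in% c("6mer", "7mer-m8") && e0 < len &&
          seqs[[tx]][e0 + 1L] == "A") {
        seqs[[tx]][e0 + 1L] <- "C"
      }
      rec <- data.frame(gene_id = spec$gene_id[i], transcript_id = tx,
                        site_type = ty, start = s0, end = e0,
                        mm_position = spec$mm_position[i],
                        stringsAsFactors = FALSE)
      planted_by_rec[[tx]] <- rbind(prior, rec)
      rows[[length(rows) + 1L]] <- rec
    }
    # scrub every record's background
    for (tx in utrome$transcript_id) {
      prot <- planted_by_rec[[tx]]
      if (is.null(prot)) prot <- data.frame(start = integer(0),
                                            end = integer(0))
      out <- scrub_canonical(seqs[[tx]], guide, prot)
      if (!is.null(out) && scrub == "relaxed") {
        out <- scrub_relaxed(out, guide, prot, gu_spec, mm_spec)
      }
      if (is.null(out)) {
        stop("could not scrub background around planted sites in ", tx,
             call. = FALSE)
      }
      seqs[[tx]] <- out
    }
    utrome$sequence <- vapply(utrome$transcript_id, function(tx) {
      paste(seqs[[tx]], collapse = "")
    }, "", USE.NAMES = FALSE)
    truth$planted <- do.call(rbind, rows)
    # generation-time verification of the no-contamination guarantee
    chk <- scan_canonical(guide, utrome, include_6mer = TRUE)
    want <- truth$planted[truth$planted$site_type != "relaxed", ,
                          drop = FALSE]
    ok <- nrow(chk) == nrow(want) &&
      (!nrow(chk) || all(paste(chk$transcript_id, chk$start, chk$site_type) %in%
                           paste(want$transcript_id, want$start,
                                 want$site_type)))
    if (!ok) {
      stop("planted-truth verification failed after scrubbing",
           call. = FALSE)
    }
    list(utrome = utrome, truth = truth)
  })
}

#' Generate a three-species fixture with known conservation structure
#'
#' Copies a planted UTRome into three species; planted sites survive only
#' in the species named by `conserve_in`, and are broken elsewhere by a
#' single substitution inside the seed match. Gene ids are prefixed per
#' species and pairwise ortholog maps connect them.
#'
#' @param planted Output of [plant_sites()] (list with `utrome`, `truth`).
#' @param guide The [guide()] the sites were planted for.
#' @param conserve_in Named list: for each planted gene id, the character
#'   vector of species (from `species`) in which its site is conserved.
#'   The first species always keeps every planted site (it is the
#'   reference); genes absent from the list are conserved nowhere else.
#' @param species Length-3 species labels; default
#'   `c("hsa", "mmu", "mml")`.
#' @param rng_seed Mandatory RNG seed.
#' @return List: `utromes` (named list of three [utrome()]s), `maps`
#'   (named list of pairwise [ortholog_map()]s, e.g. `"hsa_mmu"`), and
#'   `truth` (with `conserved` filled in).
#' @export
generate_species_trio <- function(planted, guide,
                                  conserve_in = list(),
                                  species = c("hsa", "mmu", "mml"),
                                  rng_seed) {
  stopifnot(length(species) == 3L)
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  guide <- as_guide(guide)
  base <- planted$utrome
  truth <- planted$truth
  truth$conserved <- conserve_in
  truth$rng_seed <- rng_seed
  utromes <- list()
  with_seed(rng_seed, {
    for (sp in species) {
      u <- base
      u$gene_id <- paste0(sp, "_", base$gene_id)
      u$transcript_id <- paste0(sp, "_", base$transcript_id)
      attr(u, "species") <- sp
      if (sp != species[1]) {
        seqs <- strsplit(u$sequence, "", fixed = TRUE)
        pl <- truth$planted
        for (i in seq_len(nrow(pl))) {
          keep <- sp %in% conserve_in[[pl$gene_id[i]]]
          if (keep) next
          ri <- which(base$transcript_id == pl$transcript_id[i])[1]
          sc <- break_site(seqs[[ri]], pl$start[i], pl$end[i],
                           if (pl$site_type[i] == "relaxed") "6mer" else
                             pl$site_type[i],
                           guide, integer(0))
          if (is.null(sc)) {
            stop("could not break site for species ", sp, call. = FALSE)
          }
          seqs[[ri]] <- sc
        }
        u$sequence <- vapply(seqs, paste, "", collapse = "")
      }
      utromes[[sp]] <- u
    }
  })
  maps <- list()
  combs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (cb in combs) {
    a <- species[cb[1]]; b <- species[cb[2]]
    maps[[paste(a, b, sep = "_")]] <-
      ortholog_map(paste0(a, "_", base$gene_id),
                   paste0(b, "_", base$gene_id), species = c(a, b))
  }
  list(utromes = utromes, maps = maps, truth = truth)
}

#' Generate a transcript model with planted retargeting sites
#'
#' Emulates an mRNA screened for seed-complementary windows: a multi-exon
#' spliced transcript with a CDS and UTRs, carrying planted hexamer windows
#' complementary to the given seed with specified single mismatches
#' (self-nucleotide oppositions at the requested guide seed coordinate),
#' placed in requested regions, optionally spanning an exon junction. The
#' background is scrubbed of windows within `scrub_mismatch` non-WC
#' oppositions, so a retargeting scan reports exactly the planted hits.
#'
#' @param seed Hexamer seed (or a [guide()]).
#' @param plants data.frame with columns `mm_position` (2-7, or NA for a
#'   perfect complement), `region` (`"5utr"`, `"cds"`, `"3utr"`) and
#'   optionally `junction` (logical; plant across an exon boundary).
#' @param n_exons Number of exons; default 6.
#' @param exon_length_range Per-exon length range; default 200-400 nt.
#' @param utr5_length,utr3_length UTR lengths; defaults 150 and 600 nt.
#' @param gc Background GC fraction; default 0.45.
#' @param scrub_mismatch Background windows within this many non-WC
#'   oppositions are removed; default 1.
#' @param rng_seed Mandatory RNG seed.
#' @return List with `transcript` (a [transcript_model()]) and `truth`.
#' @export
generate_transcript_model <- function(seed, plants = NULL, n_exons = 6L,
                                      exon_length_range = c(200L, 400L),
                                      utr5_length = 150L,
                                      utr3_length = 600L, gc = 0.45,
                                      scrub_mismatch = 1L, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  seed_s <- if (inherits(seed, "guide")) seed_of(seed) else
    normalize_sequence(seed)
  if (nchar(seed_s) != 6L) stop("seed must be a hexamer", call. = FALSE)
  # pseudo-guide wrapper so shared helpers can address guide coordinates
  pg <- guide("seedwrap", paste0("U", seed_s, "AAAAAAAAAAAAAAA"))
  if (is.null(plants)) {
    plants <- data.frame(mm_position = integer(0), region = character(0),
                         junction = logical(0))
  }
  if (is.null(plants$junction)) plants$junction <- FALSE
  with_seed(rng_seed, {
    exlens <- sample.int(exon_length_range[2] - exon_length_range[1] + 1L,
                         n_exons, replace = TRUE) + exon_length_range[1] - 1L
    n <- sum(exlens)
    if (n <= utr5_length + utr3_length + 100L) {
      stop("transcript too short for the requested UTRs", call. = FALSE)
    }
    exon_ends <- cumsum(exlens)
    cds_span <- c(utr5_length + 1L, n - utr3_length)
    chars <- strsplit(random_rna(n, gc, 0), "", fixed = TRUE)[[1]]
    region_span <- list("5utr" = c(1L, utr5_length), cds = cds_span,
                        "3utr" = c(cds_span[2] + 1L, n))
    placed <- data.frame(start = integer(0), end = integer(0))
    rows <- list()
    for (i in seq_len(nrow(plants))) {
      sp <- region_span[[plants$region[i]]]
      if (isTRUE(plants$junction[i])) {
        inner <- exon_ends[-length(exon_ends)]
        cand <- inner[inner >= sp[1] + 2L & inner <= sp[2] - 3L]
        if (!length(cand)) {
          stop("no exon boundary available in region ", plants$region[i],
               call. = FALSE)
        }
        b <- cand[sample.int(length(cand), 1L)]
        s0 <- b - 2L
      } else {
        inner <- exon_ends[-length(exon_ends)]
        ok <- FALSE
        for (r in 1:1000) {
          s0 <- sample.int(sp[2] - sp[1] - 4L, 1L) + sp[1] - 1L
          clash <- any(placed$start <= s0 + 6L & placed$end >= s0 - 1L) ||
            any(inner >= s0 & inner < s0 + 5L)  # stay off exon junctions
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place retarget site", call. = FALSE)
      }
      w <- relaxed_motif(pg, 6L, plants$mm_position[i])
      chars[s0:(s0 + 5L)] <- strsplit(w, "", fixed = TRUE)[[1]]
      placed <- rbind(placed, data.frame(start = s0, end = s0 + 5L))
      rows[[i]] <- data.frame(gene_id = "synthetic_target",
                              transcript_id = "synthetic_target_t1",
                              site_type = "retarget", start = s0,
                              end = s0 + 5L,
                              mm_position = plants$mm_position[i],
                              stringsAsFactors = FALSE)
    }
    # scrub background windows within the mismatch budget
    prot_pos <- unlist(mapply(seq, placed$start, placed$end,
                              SIMPLIFY = FALSE))
    for (it in 1:50) {
      s <- paste(chars, collapse = "")
      hits <- find_retarget_sites(seed_s, s, max_mismatch = scrub_mismatch)
      unint <- !(hits$start %in% placed$start)
      hits <- hits[unint, , drop = FALSE]
      if (!nrow(hits)) break
      h <- hits[1, ]
      done <- 0L
      for (j in seq_len(6L)) {
        if (done >= scrub_mismatch + 1L - h$n_mismatch) break
        p <- h$start + j - 1L
        if (p %in% prot_pos) next
        gpos <- 8L - j
        tgt <- substr(pg$sequence, gpos, gpos)
        if (chars[p] == tgt) next
        chars[p] <- tgt
        done <- done + 1L
      }
      if (done == 0L) {
        stop("could not scrub retarget background", call. = FALSE)
      }
    }
    tm <- transcript_model("synthetic_target_t1",
                           paste(chars, collapse = ""), exon_ends, cds_span)
    truth <- new_truth(rng_seed,
                       params = list(n_exons = n_exons,
                                     cds_span = cds_span, gc = gc))
    if (length(rows)) truth$planted <- do.call(rbind, rows)
    list(transcript = tm, truth = truth)
  })
}
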