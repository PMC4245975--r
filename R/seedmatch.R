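# Canonical (TargetScan-style) and relaxed (PITA-style) seed-site discovery.
#
# Canonical site types on the target, 5'->3':
#   6mer     = revcomp(seed 2-7)
#   7mer-A1  = revcomp(seed 2-7) + "A"   (literal A opposite guide position 1)
#   7mer-m8  = revcomp(seed 2-8)
#   8mer     = revcomp(seed 2-8) + "A"
# Matching is literal string matching on the transcript strand only.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

seq_to_codes <- function(s) {
  # A=1 C=2 G=3 U=4, anything else 5
  m <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_ALPHABET)
  m[is.na(m)] <- 5L
  m
}

# pair class codes: 1 = watson_crick, 2 = gu_wobble, 3 = mismatch, 4 = invalid
PAIR_CLASS_CODE <- local({
  m <- matrix(3L, 5, 5)
  wc <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2))
  m[wc] <- 1L
  m[rbind(c(3, 4), c(4, 3))] <- 2L
  m[5, ] <- 4L
  m[, 5] <- 4L
  m
})

MISMATCH_CLASS_NAMES <- local({
  pur <- c(1, 3); pyr <- c(2, 4)
  m <- matrix("pur_pyr_mismatch", 4, 4)
  for (i in pur) for (j in pur) m[i, j] <- "pur_pur"
  for (i in pyr) for (j in pyr) m[i, j] <- "pyr_pyr"
  m[PAIR_CLASS_CODE[1:4, 1:4] == 1L] <- "watson_crick"
  m[PAIR_CLASS_CODE[1:4, 1:4] == 2L] <- "gu_wobble"
  m
})

#' Classify a guide:target nucleotide opposition
#'
#' Total function on \{A,C,G,U\}^2: Watson-Crick pairs, the thermodynamically
#' stable G:U wobble, purine:purine, pyrimidine:pyrimidine, and mixed
#' purine:pyrimidine mismatches. The class matters for variant ranking:
#' purine:purine mismatches (e.g. A:G) discriminate off-targets best, while
#' pyrimidine:pyrimidine (e.g. U:U) and especially G:U oppositions retain
#' more residual silencing.
#'
#' @param guide_nt,target_nt Single nucleotides (vectorized).
#' @return Character vector of classes.
#' @examples
#' classify_mismatch("U", "U")  # pyr_pyr
#' classify_mismatch("A", "G")  # pur_pur
#' @export
classify_mismatch <- function(guide_nt, target_nt) {
  g <- match(toupper(guide_nt), RNA_ALPHABET)
  t <- match(toupper(target_nt), RNA_ALPHABET)
  if (anyNA(g) || anyNA(t)) stop("invalid nucleotide", call. = FALSE)
  MISMATCH_CLASS_NAMES[cbind(g, t)]
}

#' Extract the seed of a guide
#'
#' @param guide A [guide()].
#' @param span 1-based inclusive positions, default the guide's `seed_span`
#'   (2-7); use `c(2, 8)` for the extended seed.
#' @return Seed string 5'->3'.
#' @export
seed_of <- function(guide, span = guide$seed_span) {
  guide <- as_guide(guide)
  span <- as.integer(span)
  if (span[1] < 1L || span[2] > nchar(guide$sequence) || span[1] > span[2]) {
    stop("seed span outside guide sequence", call. = FALSE)
  }
  substr(guide$sequence, span[1], span[2])
}

#' Canonical target motifs for a guide
#'
#' @param guide A [guide()].
#' @return Named character vector mapping site type to target motif (5'->3').
#' @examples
#' canonical_motifs(guide("let7a", "UGAGGUAGUAGGUUGUAUAGUU"))
#' @export
canonical_motifs <- function(guide) {
  guide <- as_guide(guide)
  s27 <- revcomp(seed_of(guide, c(2L, 7L)))
  s28 <- revcomp(seed_of(guide, c(2L, 8L)))
  c("8mer" = paste0(s28, "A"), "7mer-m8" = s28,
    "7mer-A1" = paste0(s27, "A"), "6mer" = s27)
}

empty_sites_df <- function() {
  data.frame(guide = character(0), gene_id = character(0),
             transcript_id = character(0), site_type = character(0),
             start = integer(0), end = integer(0), site_seq = character(0),
             chrom = character(0), gstart = numeric(0), gend = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

as_utr_records <- function(utr) {
  if (inherits(utr, "utrome")) return(utr)
  if (is.character(utr)) {
    return(utrome(gene_id = if (is.null(names(utr))) {
      paste0("seq", seq_along(utr))
    } else names(utr),
    transcript_id = if (is.null(names(utr))) {
      paste0("seq", seq_along(utr))
    } else names(utr),
    sequence = utr))
  }
  stop("expected a utrome or character sequence(s)", call. = FALSE)
}

# anchor = target position opposite guide position 1 (the A1 position)
site_anchor <- function(site_type, end) {
  end + ifelse(site_type %in% c("6mer", "7mer-m8"), 1L, 0L)
}

# concatenate a record collection into one code vector with invalid
# separators so one vectorized pass covers the whole collection
concat_codes <- function(recs, sep = 8L) {
  lens_rec <- nchar(recs$sequence)
  codes <- integer(sum(lens_rec) + length(lens_rec) * sep)
  offs <- cumsum(c(0L, head(lens_rec + sep, -1L)))
  for (i in seq_len(nrow(recs))) {
    if (lens_rec[i] > 0L) {
      codes[(offs[i] + 1L):(offs[i] + lens_rec[i])] <-
        seq_to_codes(recs$sequence[i])
    }
  }
  codes[codes == 0L] <- 5L
  list(codes = codes, offs = offs, lens = lens_rec)
}

#' Scan for canonical seed-complementary sites
#'
#' Finds every occurrence of the guide's canonical motifs in the given
#' UTR(s). Overlapping occurrences sharing a target-A1 anchor are resolved to
#' the single strongest applicable type (8mer > 7mer-m8 > 7mer-A1 > 6mer),
#' so one physical site is never double-counted. 6mer sites are only
#' reported when `include_6mer = TRUE` (profiles focus on 7-8mer sites by
#' default).
#'
#' @param guide A [guide()].
#' @param utr A [utrome()], or a (named) character vector of UTR sequences.
#' @param include_6mer Report 6mer sites too? Default `FALSE`.
#' @return data.frame of sites with local 1-based spans, the matched site
#'   sequence and genomic spans where available, sorted by record and
#'   position.
#' @export
scan_canonical <- function(guide, utr, include_6mer = FALSE) {
  guide <- as_guide(guide)
  recs <- as_utr_records(utr)
  if (!nrow(recs)) return(empty_sites_df())
  cc <- concat_codes(recs)
  codes <- cc$codes
  gcodes <- seq_to_codes(guide$sequence)
  comp_code <- c(4L, 3L, 2L, 1L, 5L)
  n <- length(codes)
  S <- n - 6L + 1L
  if (S < 1L) return(empty_sites_df())
  # perfect 6mer core (literal complement of seed 2-7; G:U does not count)
  core <- rep(TRUE, S)
  for (k in 0:5) {
    idx <- seq_len(S) + (5L - k)
    core <- core & (codes[idx] == comp_code[gcodes[2L + k]])
  }
  s6 <- which(core)
  if (!length(s6)) return(empty_sites_df())
  # m8 extension one base 5' of the core; A1 adenine one base 3' of it
  has_m8 <- s6 > 1L & codes[pmax(s6 - 1L, 1L)] == comp_code[gcodes[8L]]
  has_a1 <- s6 + 6L <= n & codes[pmin(s6 + 6L, n)] == 1L
  site_type <- ifelse(has_m8 & has_a1, "8mer",
                      ifelse(has_m8, "7mer-m8",
                             ifelse(has_a1, "7mer-A1", "6mer")))
  start <- ifelse(has_m8, s6 - 1L, s6)
  end <- ifelse(has_a1 & has_m8, s6 + 6L,
                ifelse(has_a1 | has_m8, s6 + 5L + has_a1, s6 + 5L))
  cand <- data.frame(site_type = site_type, start = start, end = end,
                     stringsAsFactors = FALSE)
  cand$rec <- findInterval(cand$start, cc$offs + 1L)
  # drop candidates whose span leaks outside their record
  within <- cand$start >= cc$offs[cand$rec] + 1L &
    cand$end <= cc$offs[cand$rec] + cc$lens[cand$rec]
  cand <- cand[within, , drop = FALSE]
  cand$start <- cand$start - cc$offs[cand$rec]
  cand$end <- cand$end - cc$offs[cand$rec]
  if (!include_6mer) cand <- cand[cand$site_type != "6mer", , drop = FALSE]
  if (!nrow(cand)) return(empty_sites_df())
  cand <- cand[order(cand$rec, cand$start, cand$end), , drop = FALSE]
  g <- local_to_genomic(cand$start, cand$end, recs$gstart[cand$rec],
                        recs$gend[cand$rec], recs$strand[cand$rec])
  out <- data.frame(guide = guide$name, gene_id = recs$gene_id[cand$rec],
                    transcript_id = recs$transcript_id[cand$rec],
                    site_type = cand$site_type, start = cand$start,
                    end = cand$end,
                    site_seq = substr(recs$sequence[cand$rec], cand$start,
                                      cand$end),
                    chrom = recs$chrom[cand$rec], gstart = g$gstart,
                    gend = g$gend, strand = recs$strand[cand$rec],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parse a relaxed-scan allowance specification
#'
#' The specification is a comma-separated list of `length;budget` pairs, one
#' per seed length, e.g. the default `"6;0,7;1,8;1"` allows zero
#' imperfections for 6-nt seeds and one for 7- and 8-nt seeds. GU and
#' mismatch budgets are specified independently with the same syntax.
#'
#' @param spec Specification string.
#' @return Named integer vector (names are seed lengths).
#' @export
parse_allowance_spec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    kv <- strsplit(p, ";", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !grepl("^[0-9]+$", kv[1]) ||
        !grepl("^[0-9]+$", kv[2])) {
      stop(sprintf("malformed allowance spec fragment '%s'", p),
           call. = FALSE)
    }
    out[kv[1]] <- as.integer(kv[2])
  }
  out
}

#' Scan for relaxed (mismatch/G:U-tolerant) seed sites
#'
#' For each seed length L in the allowance specification (guide positions 2
#' to L+1), reports every target window whose antiparallel pairing to the
#' seed stays within the per-length G:U and mismatch budgets. Exact mismatch
#' and G:U positions are recorded in guide coordinates. A perfect canonical
#' site is always also reported as its own relaxed site with zero
#' imperfections.
#'
#' @param guide A [guide()].
#' @param utr A [utrome()] or character vector of sequences.
#' @param gu_spec,mm_spec Allowance specifications (see
#'   [parse_allowance_spec()]); defaults `"6;0,7;1,8;1"` for both.
#' @param protect_position2 Disallow any imperfection opposite guide
#'   position 2 (the seed anchor). Off by default.
#' @return data.frame of relaxed sites (`seed_len`, spans, `n_mm`, `n_gu`,
#'   comma-separated `mm_positions`/`gu_positions` in guide coordinates).
#' @export
scan_relaxed <- function(guide, utr, gu_spec = "6;0,7;1,8;1",
                         mm_spec = "6;0,7;1,8;1",
                         protect_position2 = FALSE) {
  guide <- as_guide(guide)
  recs <- as_utr_records(utr)
  gu_allow <- parse_allowance_spec(gu_spec)
  mm_allow <- parse_allowance_spec(mm_spec)
  lens <- sort(unique(as.integer(union(names(gu_allow), names(mm_allow)))))
  if (!nrow(recs)) return(empty_relaxed_df())

  cc <- concat_codes(recs)
  codes <- cc$codes; offs <- cc$offs
  gcodes <- seq_to_codes(guide$sequence)

  out <- list()
  for (L in lens) {
    if (L + 1L > nchar(guide$sequence)) next
    gu_b <- if (as.character(L) %in% names(gu_allow)) {
      gu_allow[[as.character(L)]]
    } else 0L
    mm_b <- if (as.character(L) %in% names(mm_allow)) {
      mm_allow[[as.character(L)]]
    } else 0L
    S <- length(codes) - L + 1L
    if (S < 1L) next
    mm <- integer(S); gu <- integer(S); bad <- logical(S)
    cls_k <- vector("list", L)
    for (k in 0:(L - 1L)) {
      idx <- seq_len(S) + (L - 1L - k)
      cc <- PAIR_CLASS_CODE[gcodes[2L + k], codes[idx]]
      cls_k[[k + 1L]] <- cc
      mm <- mm + (cc == 3L)
      gu <- gu + (cc == 2L)
      bad <- bad | cc == 4L
      if (protect_position2 && k == 0L) bad <- bad | cc != 1L
    }
    hit <- which(!bad & mm <= mm_b & gu <= gu_b)
    if (!length(hit)) next
    rec <- findInterval(hit, offs + 1L)
    start_loc <- hit - offs[rec]
    mm_pos <- character(length(hit)); gu_pos <- character(length(hit))
    need <- which(mm[hit] > 0L | gu[hit] > 0L)
    for (j in need) {
      cl <- vapply(seq_len(L), function(k1) cls_k[[k1]][hit[j]], integer(1))
      mm_pos[j] <- paste(1L + which(cl == 3L), collapse = ",")
      gu_pos[j] <- paste(1L + which(cl == 2L), collapse = ",")
    }
    out[[as.character(L)]] <- data.frame(
      rec = rec, seed_len = L, start = start_loc,
      end = start_loc + L - 1L, n_mm = mm[hit], n_gu = gu[hit],
      mm_positions = mm_pos, gu_positions = gu_pos,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_relaxed_df())
  out <- do.call(rbind, out)
  out <- out[order(out$rec, out$start, out$seed_len), , drop = FALSE]
  g <- local_to_genomic(out$start, out$end, recs$gstart[out$rec],
                        recs$gend[out$rec], recs$strand[out$rec])
  res <- data.frame(guide = guide$name, gene_id = recs$gene_id[out$rec],
                    transcript_id = recs$transcript_id[out$rec],
                    seed_len = out$seed_len, start = out$start,
                    end = out$end, n_mm = out$n_mm, n_gu = out$n_gu,
                    mm_positions = out$mm_positions,
                    gu_positions = out$gu_positions,
                    site_seq = substr(recs$sequence[out$rec], out$start,
                                      out$end),
                    chrom = recs$chrom[out$rec], gstart = g$gstart,
                    gend = g$gend, strand = recs$strand[out$rec],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

empty_relaxed_df <- function() {
  data.frame(guide = character(0), gene_id = character(0),
             transcript_id = character(0), seed_len = integer(0),
             start = integer(0), end = integer(0), n_mm = integer(0),
             n_gu = integer(0), mm_positions = character(0),
             gu_positions = character(0), site_seq = character(0),
             chrom = character(0), gstart = numeric(0), gend = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Remove sites that are genomically redundant across transcript isoforms
#'
#' Sites are unique by (chrom, genomic start, genomic end, strand, type);
#' the representative retains the lexicographically smallest transcript id.
#' Sites without genomic coordinates are keyed by transcript coordinates
#' instead. Idempotent and order-insensitive.
#'
#' @param sites data.frame from [scan_canonical()] or [scan_relaxed()].
#' @return The deduplicated data.frame.
#' @export
dedupe_genomic <- function(sites) {
  if (!nrow(sites)) return(sites)
  type_col <- if ("site_type" %in% names(sites)) {
    sites$site_type
  } else paste0("L", sites$seed_len)
  has_g <- !is.na(sites$chrom)
  key <- ifelse(has_g,
                paste(sites$chrom, sites$gstart, sites$gend, sites$strand,
                      type_col, sep = ":"),
                paste("tx", sites$transcript_id, sites$start, sites$end,
                      type_col, sep = ":"))
  ord <- order(key, sites$transcript_id, sites$start)
  sites <- sites[ord, , drop = FALSE]
  key <- key[ord]
  out <- sites[!duplicated(key), , drop = FALSE]
  out <- out[order(out$gene_id, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize sites to TSV
#'
#' Stable column order with a mandatory header line:
#' guide, gene_id, transcript_id, site_type, start, end, chrom, gstart,
#' gend, strand, seed_len, n_mm, n_gu, mm_positions.
#'
#' @param sites Site data.frame (canonical or relaxed; absent fields are
#'   written as NA).
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  cols <- c("guide", "gene_id", "transcript_id", "site_type", "start",
            "end", "chrom", "gstart", "gend", "strand", "seed_len",
            "n_mm", "n_gu", "mm_positions")
  for (cn in setdiff(cols, names(sites))) sites[[cn]] <- NA
  write.table(sites[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
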