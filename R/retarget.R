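# Retargeting a trusted low-off-target seed against a new transcript: scan
# the spliced mRNA for windows complementary to the seed allowing at most
# one seed mismatch, classify each hit's transcript region, and assemble a
# full-length candidate guide whose 3' region is fully complementary to the
# target flank.

#' Construct a transcript model
#'
#' A spliced transcript with exon boundaries in cumulative 1-based spliced
#' coordinates and a CDS span; the 3'UTR is derived as everything after the
#' CDS.
#'
#' @param transcript_id Label.
#' @param sequence Spliced sequence (DNA accepted, normalized to RNA).
#' @param exon_ends Strictly increasing cumulative 1-based exon end
#'   positions; the last must equal the sequence length.
#' @param cds_span 1-based inclusive CDS span.
#' @return Object of class `"transcript_model"`.
#' @export
transcript_model <- function(transcript_id, sequence, exon_ends, cds_span) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  exon_ends <- as.integer(exon_ends)
  if (any(diff(exon_ends) <= 0L)) {
    stop("exon ends must be strictly increasing", call. = FALSE)
  }
  if (exon_ends[length(exon_ends)] != n) {
    stop("last exon end must equal sequence length", call. = FALSE)
  }
  cds_span <- as.integer(cds_span)
  if (cds_span[1] < 1L || cds_span[2] > n || cds_span[1] > cds_span[2]) {
    stop("cds span outside sequence", call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, sequence = sequence,
                 exon_ends = exon_ends, cds_span = cds_span,
                 utr3_span = c(cds_span[2] + 1L, n),
                 utr5_span = c(1L, cds_span[1] - 1L)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d nt, %d exons, CDS %d-%d, 3'UTR %d-%d\n",
              x$transcript_id, nchar(x$sequence), length(x$exon_ends),
              x$cds_span[1], x$cds_span[2], x$utr3_span[1], x$utr3_span[2]))
  invisible(x)
}

#' Read/write a transcript model as JSON
#' @param path JSON file path.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(path) {
  j <- jsonlite::fromJSON(path)
  transcript_model(j$transcript_id, j$sequence, j$exon_ends, j$cds_span)
}

#' @rdname read_transcript_model
#' @param x A [transcript_model()].
#' @export
write_transcript_model <- function(x, path) {
  jsonlite::write_json(list(transcript_id = x$transcript_id,
                            sequence = x$sequence,
                            exon_ends = x$exon_ends,
                            cds_span = x$cds_span),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify the transcript region of a site span
#'
#' Region is assigned by majority overlap with the 5'UTR / CDS / 3'UTR
#' spans (ties resolved to CDS); `junction_spanning` is `TRUE` iff an exon
#' boundary lies strictly inside the span.
#'
#' @param span Integer pair, 1-based inclusive spliced coordinates.
#' @param transcript A [transcript_model()].
#' @return List with `region` (`"5utr"`, `"cds"` or `"3utr"`) and
#'   `junction_spanning`.
#' @export
classify_region <- function(span, transcript) {
  span <- as.integer(span)
  n <- nchar(transcript$sequence)
  if (span[1] < 1L || span[2] > n || span[1] > span[2]) {
    stop("span outside transcript", call. = FALSE)
  }
  ov <- function(sp) {
    if (sp[1] > sp[2]) return(0L)
    max(0L, min(span[2], sp[2]) - max(span[1], sp[1]) + 1L)
  }
  o <- c("5utr" = ov(transcript$utr5_span), cds = ov(transcript$cds_span),
         "3utr" = ov(transcript$utr3_span))
  region <- if (o[["cds"]] >= max(o)) "cds" else names(o)[which.max(o)]
  inner <- transcript$exon_ends[-length(transcript$exon_ends)]
  junction <- any(inner >= span[1] & inner < span[2])
  list(region = region, junction_spanning = junction)
}

#' Find seed-complementary sites on a transcript, allowing seed mismatches
#'
#' Scans every window of the spliced sequence for antiparallel pairing to
#' the hexamer seed (guide positions 2-7) with at most `max_mismatch`
#' non-Watson-Crick oppositions. G:U wobbles count toward the mismatch
#' budget during search (conservative), but each hit records the opposition
#' class so downstream ranking can prefer them. With `max_mismatch = 0`
#' only perfect complements are returned.
#'
#' @param seed Hexamer seed (guide positions 2-7, 5'->3'), or a [guide()]
#'   (its seed is extracted).
#' @param transcript A [transcript_model()] or a plain sequence (then
#'   region/junction are `NA`).
#' @param max_mismatch 0 or 1.
#' @return data.frame of hits sorted by position: `start`, `end`,
#'   `n_mismatch`, `mismatch_position` (guide seed coordinate 2-7, NA for
#'   perfect hits), `mismatch_class`, `region`, `junction_spanning`,
#'   `target_window`.
#' @export
find_retarget_sites <- function(seed, transcript, max_mismatch = 1L) {
  if (inherits(seed, "guide")) seed <- seed_of(seed)
  seed <- normalize_sequence(seed)
  if (nchar(seed) != 6L) stop("seed must be a hexamer", call. = FALSE)
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("max_mismatch must be 0 or 1", call. = FALSE)
  }
  tm <- if (inherits(transcript, "transcript_model")) transcript else NULL
  s <- if (is.null(tm)) normalize_sequence(transcript) else tm$sequence
  n <- nchar(s)
  L <- 6L
  if (n < L) return(empty_retarget_df())
  sc <- seq_to_codes(seed)
  tc <- seq_to_codes(s)
  S <- n - L + 1L
  nonwc <- integer(S)
  cls_k <- vector("list", L)
  for (k in 0:(L - 1L)) {
    # window position j = L - k pairs seed position k+1 (guide pos k+2)
    idx <- seq_len(S) + (L - 1L - k)
    cc <- PAIR_CLASS_CODE[sc[k + 1L], tc[idx]]
    cls_k[[k + 1L]] <- cc
    nonwc <- nonwc + (cc != 1L)
  }
  hit <- which(nonwc <= max_mismatch)
  if (!length(hit)) return(empty_retarget_df())
  mm_pos <- integer(length(hit)); mm_cls <- character(length(hit))
  for (j in seq_along(hit)) {
    cl <- vapply(seq_len(L), function(k1) cls_k[[k1]][hit[j]], integer(1))
    bad <- which(cl != 1L)
    if (length(bad)) {
      mm_pos[j] <- bad[1] + 1L  # guide coordinate
      g_nt <- RNA_ALPHABET[sc[bad[1]]]
      t_nt <- substr(s, hit[j] + L - bad[1], hit[j] + L - bad[1])
      mm_cls[j] <- classify_mismatch(g_nt, t_nt)
    } else {
      mm_pos[j] <- NA_integer_; mm_cls[j] <- "watson_crick"
    }
  }
  region <- rep(NA_character_, length(hit))
  junction <- rep(NA, length(hit))
  if (!is.null(tm)) {
    for (j in seq_along(hit)) {
      cr <- classify_region(c(hit[j], hit[j] + L - 1L), tm)
      region[j] <- cr$region; junction[j] <- cr$junction_spanning
    }
  }
  out <- data.frame(
    transcript_id = if (is.null(tm)) NA_character_ else tm$transcript_id,
    start = hit, end = hit + L - 1L,
    n_mismatch = as.integer(nonwc[hit] > 0L),
    mismatch_position = mm_pos, mismatch_class = mm_cls,
    region = region, junction_spanning = junction,
    target_window = substr(rep(s, length(hit)), hit, hit + L - 1L),
    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("retarget_hits", "data.frame")
  out
}

empty_retarget_df <- function() {
  structure(data.frame(transcript_id = character(0), start = integer(0),
                       end = integer(0), n_mismatch = integer(0),
                       mismatch_position = integer(0),
                       mismatch_class = character(0), region = character(0),
                       junction_spanning = logical(0),
                       target_window = character(0),
                       stringsAsFactors = FALSE),
            class = c("retarget_hits", "data.frame"))
}

#' @export
print.retarget_hits <- function(x, ...) {
  cat(sprintf("<retarget_hits> %d hit(s)\n", nrow(x)))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Assemble a full-length candidate guide around a retarget hit
#'
#' Positions 2-7 carry the parent seed unchanged (including its mismatch
#' against the target); positions 8..L are the reverse complement of the
#' target flank immediately 5' of the seed-pairing window (full 3'
#' complementarity); position 1 is set to `pos1` (default U, the widely
#' assumed loading preference) regardless of the target. The implied
#' guide:passenger 5' asymmetry score is attached as attribute
#' `"asymmetry"`.
#'
#' @param seed_parent The parent [guide()] (or a hexamer seed string) whose
#'   seed is being reused.
#' @param hit One row of [find_retarget_sites()] output (or a list with
#'   `start`).
#' @param target The [transcript_model()] (or sequence) the hit lies on.
#' @param guide_length Assembled guide length; default 22.
#' @param pos1 Nucleotide for position 1; default `"U"`.
#' @param model An `energy_model` (for the asymmetry score).
#' @return A [guide()] with attribute `"asymmetry"`.
#' @export
assemble_guide <- function(seed_parent, hit, target, guide_length = 22L,
                           pos1 = "U", model = default_energy_model()) {
  seed <- if (inherits(seed_parent, "guide")) {
    seed_of(seed_parent)
  } else normalize_sequence(seed_parent)
  if (nchar(seed) != 6L) stop("parent seed must be a hexamer", call. = FALSE)
  s <- if (inherits(target, "transcript_model")) {
    target$sequence
  } else normalize_sequence(target)
  start <- as.integer(hit$start)
  need <- guide_length - 7L
  if (start - need < 1L) {
    stop(sprintf("insufficient target flank: need %d nt 5' of the site",
                 need), call. = FALSE)
  }
  flank <- substr(s, start - need, start - 1L)
  gseq <- paste0(pos1, seed, revcomp(flank))
  nm <- if (inherits(seed_parent, "guide")) {
    paste0(seed_parent$name, ".ss", start)
  } else paste0("retarget.ss", start)
  g <- guide(nm, gseq)
  attr(g, "asymmetry") <- asymmetry_score(g, model = model)
  g
}

#' Compare binding stability of two guides sharing a seed
#'
#' Both guides are rescored on identical target-site windows (e.g. the
#' off-target sites of either guide's profile); per-site and mean
#' ddG(a) - ddG(b) are reported. Because the windows are identical the
#' opening energy cancels and the difference is the duplex term, i.e. how
#' much the 3' regions differ in compensatory pairing.
#'
#' @param guide_a,guide_b [guide()]s with identical seeds (positions 2-7).
#' @param site_windows Character vector of target windows (5'->3', site
#'   plus upstream flank), e.g. from a profile's sites.
#' @param model An `energy_model`.
#' @param bulge_max Duplex DP loop allowance.
#' @return List with `per_site` (data.frame: `window`, `ddg_a`, `ddg_b`,
#'   `difference`) and `mean_difference` (NA for an empty site list).
#' @export
compare_binding_stability <- function(guide_a, guide_b, site_windows,
                                      model = default_energy_model(),
                                      bulge_max = 3L) {
  guide_a <- as_guide(guide_a); guide_b <- as_guide(guide_b)
  if (seed_of(guide_a) != seed_of(guide_b)) {
    stop("guides do not share a seed (positions 2-7)", call. = FALSE)
  }
  ea <- vapply(site_windows, function(w) {
    duplex_energy(guide_a, w, model = model, bulge_max = bulge_max)
  }, numeric(1), USE.NAMES = FALSE)
  eb <- vapply(site_windows, function(w) {
    duplex_energy(guide_b, w, model = model, bulge_max = bulge_max)
  }, numeric(1), USE.NAMES = FALSE)
  diff <- ea - eb
  list(per_site = data.frame(window = as.character(site_windows),
                             ddg_a = ea, ddg_b = eb, difference = diff,
                             stringsAsFactors = FALSE),
       mean_difference = if (length(diff)) mean(diff) else NA_real_)
}
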