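# Domain types and readers/writers: guides, UTR records, expression sets,
# ortholog maps. Local coordinates are 1-based inclusive (transcript
# orientation); genomic intervals are 0-based half-open (BED convention).

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U (DNA input is accepted everywhere -- UTR FASTA
#' files are DNA-alphabet) and validates against A/C/G/U. Ambiguity codes and
#' non-nucleotide characters are rejected with the offending character and
#' 1-based position named.
#'
#' @param raw Non-empty character scalar.
#' @param expect `"RNA"` or `"DNA"`; informational only, both alphabets are
#'   accepted and the result is always RNA.
#' @return RNA string (character scalar over A/C/G/U).
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw, expect = c("RNA", "DNA")) {
  expect <- match.arg(expect)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  }
  s <- chartr("acgut", "ACGUU", raw)
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Reverse complement of an RNA string
#'
#' @param x RNA string (already normalized).
#' @return Reverse complement, 5'->3'.
#' @export
revcomp <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

comp_nt <- function(x) chartr("ACGU", "UGCA", x)

#' Construct a guide strand
#'
#' A guide is the RISC-loaded strand of an RNAi duplex, written 5'->3' with
#' 1-based positions; position 1 is the 5'-most nucleotide. The seed
#' (positions 2-7 by default) is the primary determinant of miRNA-like
#' target recognition; the extended seed adds position 8.
#'
#' @param name Label.
#' @param sequence Guide sequence 5'->3'; DNA input is normalized to RNA.
#' @param seed_span Integer pair, 1-based inclusive; default `c(2, 7)`.
#' @param extended_seed_span Integer pair; default `c(2, 8)`.
#' @param length_bounds Allowed sequence length range; default 16-30
#'   (typical guides are 21-22 nt).
#' @return Object of class `"guide"`.
#' @examples
#' g <- guide("let7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' seed_of(g)
#' @export
guide <- function(name, sequence, seed_span = c(2L, 7L),
                  extended_seed_span = c(2L, 8L),
                  length_bounds = c(16L, 30L)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n < length_bounds[1] || n > length_bounds[2]) {
    stop(sprintf("guide '%s' length %d outside bounds [%d, %d]",
                 name, n, length_bounds[1], length_bounds[2]), call. = FALSE)
  }
  seed_span <- as.integer(seed_span)
  extended_seed_span <- as.integer(extended_seed_span)
  for (sp in list(seed_span, extended_seed_span)) {
    if (sp[1] < 1L || sp[2] > n || sp[1] > sp[2]) {
      stop("seed span outside guide sequence", call. = FALSE)
    }
  }
  structure(list(name = name, sequence = sequence, seed_span = seed_span,
                 extended_seed_span = extended_seed_span),
            class = "guide")
}

#' @export
print.guide <- function(x, ...) {
  cat(sprintf("<guide> %s  (%d nt)\n", x$name, nchar(x$sequence)))
  cat(" 5'-", x$sequence, "-3'\n", sep = "")
  cat(sprintf(" seed %d-%d: %s\n", x$seed_span[1], x$seed_span[2],
              seed_of(x, x$seed_span)))
  invisible(x)
}

as_guide <- function(x) {
  if (inherits(x, "guide")) return(x)
  if (is.character(x) && length(x) == 1L) return(guide("guide", x))
  stop("expected a guide object or a sequence string", call. = FALSE)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that normalizes all
#' sequences to the RNA alphabet, preserves file order, rejects duplicate
#' record names and tolerates CRLF line endings and trailing blank lines.
#' An empty file yields an empty list with a warning.
#'
#' @param path File path.
#' @return Named character vector of RNA sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.info(path)$size == 0L ||
      !any(startsWith(trimws(readLines(path, warn = FALSE)), ">"))) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- gsub("[\r ]", "", seqs)
  setNames(vapply(seqs, normalize_sequence, "", USE.NAMES = FALSE), nm)
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; default 60 columns.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Assemble a UTRome from per-record fields
#'
#' A UTRome is the collection of 3'UTR sequences for a species' protein-coding
#' transcripts. Sequences are stored in transcript (spliced) orientation;
#' genomic intervals, when present, are 0-based half-open and used only for
#' genomic deduplication of sites.
#'
#' @param gene_id,transcript_id,sequence Character vectors (recycled to a
#'   common length); sequences are normalized to RNA.
#' @param chrom,gstart,gend,strand Optional genomic interval columns; strand
#'   in `+`/`-`. When present, `gend - gstart` must equal sequence length.
#' @param species Optional species label.
#' @return Object of class `"utrome"` (a data.frame).
#' @export
utrome <- function(gene_id, transcript_id, sequence, chrom = NA_character_,
                   gstart = NA_integer_, gend = NA_integer_,
                   strand = NA_character_, species = NA_character_) {
  sequence <- vapply(sequence, normalize_sequence, "", USE.NAMES = FALSE)
  n <- length(sequence)
  chrom <- rep_len(chrom, n); gstart <- rep_len(gstart, n)
  gend <- rep_len(gend, n); strand <- rep_len(strand, n)
  df <- data.frame(gene_id = as.character(gene_id),
                   transcript_id = as.character(transcript_id),
                   sequence = sequence, chrom = chrom,
                   gstart = as.numeric(gstart), gend = as.numeric(gend),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  has_g <- !is.na(df$chrom)
  if (any(has_g)) {
    if (any(!df$strand[has_g] %in% c("+", "-"))) {
      stop("strand must be '+' or '-'", call. = FALSE)
    }
    bad <- has_g & (df$gend - df$gstart != nchar(df$sequence))
    if (any(bad)) {
      stop("genomic interval length != sequence length for: ",
           paste(df$transcript_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  attr(df, "species") <- species
  class(df) <- c("utrome", "data.frame")
  df
}

#' @export
print.utrome <- function(x, ...) {
  cat(sprintf("<utrome> %d transcripts / %d genes; median length %d nt\n",
              nrow(x), length(unique(x$gene_id)),
              if (nrow(x)) as.integer(stats::median(nchar(x$sequence))) else 0L))
  invisible(x)
}

#' Read a 3'UTR collection from a BED-like table plus FASTA
#'
#' The BED-like table has six columns (chrom, start, end, name, score,
#' strand) with `name` holding `gene_id|transcript_id`; the FASTA is keyed by
#' transcript id. Records lacking a sequence are dropped with a logged count;
#' an interval whose length differs from its sequence length is an error.
#' Non-`NM_`-prefixed (non-protein-coding-style) ids are flagged via a
#' message when `flag_non_nm = TRUE` (never rejected).
#'
#' @param bed_path Path to the BED6-like table (tab-separated, no header).
#' @param fasta_path Path to the FASTA of spliced UTR sequences.
#' @param flag_non_nm Message a count of ids without an `NM_` prefix.
#' @return A [utrome()].
#' @export
read_utr_table <- function(bed_path, fasta_path, flag_non_nm = FALSE) {
  bed <- read.table(bed_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "character", "character"))
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[1]
    stop(sprintf("malformed name field '%s' (expected gene_id|transcript_id)",
                 bed$name[bad]), call. = FALSE)
  }
  bed$gene_id <- vapply(parts, `[`, "", 1L)
  bed$transcript_id <- vapply(parts, `[`, "", 2L)
  seqs <- read_fasta(fasta_path)
  have <- bed$transcript_id %in% names(seqs)
  if (any(!have)) {
    message(sum(!have), " BED record(s) without a FASTA sequence dropped")
  }
  bed <- bed[have, , drop = FALSE]
  if (flag_non_nm) {
    n_non <- sum(!startsWith(bed$transcript_id, "NM_"))
    if (n_non > 0L) message(n_non, " transcript id(s) without NM_ prefix")
  }
  utrome(gene_id = bed$gene_id, transcript_id = bed$transcript_id,
         sequence = unname(seqs[bed$transcript_id]), chrom = bed$chrom,
         gstart = bed$start, gend = bed$end, strand = bed$strand)
}

#' Write a UTRome as BED6 + FASTA
#'
#' @param x A [utrome()].
#' @param bed_path,fasta_path Output paths.
#' @export
write_utr_table <- function(x, bed_path, fasta_path) {
  stopifnot(inherits(x, "utrome"))
  bed <- data.frame(x$chrom, x$gstart, x$gend,
                    paste(x$gene_id, x$transcript_id, sep = "|"),
                    0L, x$strand)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_fasta(setNames(x$sequence, x$transcript_id), fasta_path)
  invisible(x)
}

normalize_gene_id <- function(ids) sub("\\.\\d+$", "", ids)

#' Read an expressed-gene list
#'
#' One gene id per line (e.g. genes expressed above background in a tissue
#' RNA-seq experiment). Ids are deduplicated and version suffixes (".N")
#' stripped; membership tests downstream are exact string matches on the
#' normalized ids. A line containing internal whitespace is rejected with its
#' line number; an empty file yields an empty set with a warning.
#'
#' @param path File path.
#' @param species Optional species label.
#' @return Object of class `"expression_set"`.
#' @export
read_gene_set <- function(path, species = NA_character_) {
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines)
  bad <- which(keep & grepl("\\s", lines))
  if (length(bad)) {
    stop(sprintf("malformed line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  }
  ids <- unique(normalize_gene_id(lines[keep]))
  if (!length(ids)) warning("empty gene list: ", path, call. = FALSE)
  expression_set(ids, species = species)
}

#' Construct an expression set
#'
#' @param gene_ids Character vector of gene ids (deduplicated, version
#'   suffixes stripped).
#' @param species Optional label.
#' @return Object of class `"expression_set"`.
#' @export
expression_set <- function(gene_ids, species = NA_character_) {
  structure(list(species = species,
                 gene_ids = unique(normalize_gene_id(as.character(gene_ids)))),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %s: %d genes\n",
              ifelse(is.na(x$species), "?", x$species), length(x$gene_ids)))
  invisible(x)
}

#' Read a two-column ortholog map
#'
#' Tab-separated `species-A id <TAB> species-B id` pairs (e.g. high-confidence
#' ortholog annotations exported from an annotation mart). Duplicate pairs are
#' collapsed; a line without exactly two fields is rejected with its line
#' number. The map is losslessly invertible via [invert_ortholog_map()].
#'
#' @param path File path.
#' @param species Optional length-2 character of species labels.
#' @return Object of class `"ortholog_map"`.
#' @export
read_ortholog_map <- function(path, species = c(NA, NA)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d: expected two tab-separated ids", bad[1]),
         call. = FALSE)
  }
  a <- normalize_gene_id(trimws(vapply(fields, `[`, "", 1L)))
  b <- normalize_gene_id(trimws(vapply(fields, `[`, "", 2L)))
  ortholog_map(a, b, species = species)
}

#' Construct an ortholog map from paired id vectors
#'
#' @param a,b Character vectors of equal length (species A and B ids).
#' @param species Optional length-2 labels.
#' @return Object of class `"ortholog_map"`.
#' @export
ortholog_map <- function(a, b, species = c(NA, NA)) {
  stopifnot(length(a) == length(b))
  pairs <- unique(data.frame(a = as.character(a), b = as.character(b),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) && any(!nzchar(pairs$a) | !nzchar(pairs$b))) {
    stop("empty id in ortholog pair", call. = FALSE)
  }
  structure(list(pairs = pairs, species = species), class = "ortholog_map")
}

#' Invert an ortholog map (swap species A and B)
#' @param map An [ortholog_map()].
#' @return The reversed [ortholog_map()].
#' @export
invert_ortholog_map <- function(map) {
  stopifnot(inherits(map, "ortholog_map"))
  ortholog_map(map$pairs$b, map$pairs$a, species = rev(map$species))
}

#' Orthologs of a gene id under a map
#' @param map An [ortholog_map()].
#' @param id Species-A gene id.
#' @return Character vector of species-B ids (possibly empty).
#' @export
orthologs_of <- function(map, id) {
  map$pairs$b[map$pairs$a == normalize_gene_id(id)]
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %s -> %s: %d pairs (%d source genes)\n",
              ifelse(is.na(x$species[1]), "A", x$species[1]),
              ifelse(is.na(x$species[2]), "B", x$species[2]),
              nrow(x$pairs), length(unique(x$pairs$a))))
  invisible(x)
}

#' Write an ortholog map as two-column TSV
#' @param map An [ortholog_map()].
#' @param path Output path.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(map$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Local (1-based transcript) -> genomic (0-based half-open) span conversion.
local_to_genomic <- function(start, end, gstart, gend, strand) {
  plus <- strand == "+"
  gs <- ifelse(plus, gstart + start - 1, gend - end)
  ge <- ifelse(plus, gstart + end, gend - start + 1)
  list(gstart = gs, gend = ge)
}
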