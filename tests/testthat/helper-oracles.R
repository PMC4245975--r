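# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's scanning/energy code paths: string
# slicing, per-window loops and Biostrings reverse-complements only.

rna_bases <- c("A", "C", "G", "U")

random_rna_str <- function(n, prob = NULL) {
  paste(sample(rna_bases, n, replace = TRUE, prob = prob), collapse = "")
}

random_guide <- function(len = 22L) {
  guide(paste0("rg", sample.int(1e6, 1)), random_rna_str(len))
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# naive sliding-window canonical scan: literal comparison of every window
# against each motif, then per-anchor precedence (8mer > 7mer-m8 >
# 7mer-A1 > 6mer)
oracle_scan_canonical <- function(guide_seq, utr, include_6mer = TRUE) {
  s27 <- oracle_revcomp(substr(guide_seq, 2, 7))
  s28 <- oracle_revcomp(substr(guide_seq, 2, 8))
  motifs <- list("8mer" = paste0(s28, "A"), "7mer-m8" = s28,
                 "7mer-A1" = paste0(s27, "A"), "6mer" = s27)
  found <- list()
  for (ty in names(motifs)) {
    m <- motifs[[ty]]
    L <- nchar(m)
    if (nchar(utr) < L) next
    for (s in 1:(nchar(utr) - L + 1)) {
      if (substr(utr, s, s + L - 1) == m) {
        e <- s + L - 1L
        anchor <- e + ifelse(ty %in% c("6mer", "7mer-m8"), 1L, 0L)
        found[[length(found) + 1]] <-
          data.frame(site_type = ty, start = s, end = e, anchor = anchor)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- do.call(rbind, found)
  df$rank <- match(df$site_type, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  df <- df[order(df$anchor, df$rank), ]
  df <- df[!duplicated(df$anchor), ]
  if (!include_6mer) df <- df[df$site_type != "6mer", ]
  df <- df[order(df$start, df$end), c("site_type", "start", "end")]
  rownames(df) <- NULL
  df
}

oracle_pair_class <- function(g, t) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (wc[[g]] == t) return("wc")
  if ((g == "G" && t == "U") || (g == "U" && t == "G")) return("gu")
  "mm"
}

# naive relaxed scan: for each seed length, loop every window and count
# pair classes per position
oracle_scan_relaxed <- function(guide_seq, utr, gu_allow, mm_allow) {
  out <- list()
  for (L in as.integer(names(mm_allow))) {
    if (nchar(utr) < L) next
    seed <- substr(guide_seq, 2, L + 1)
    for (s in 1:(nchar(utr) - L + 1)) {
      n_mm <- 0L; n_gu <- 0L
      for (k in 0:(L - 1)) {
        g_nt <- substr(seed, k + 1, k + 1)
        t_nt <- substr(utr, s + L - 1 - k, s + L - 1 - k)
        cl <- oracle_pair_class(g_nt, t_nt)
        if (cl == "mm") n_mm <- n_mm + 1L
        if (cl == "gu") n_gu <- n_gu + 1L
      }
      if (n_mm <= mm_allow[[as.character(L)]] &&
          n_gu <= gu_allow[[as.character(L)]]) {
        out[[length(out) + 1]] <-
          data.frame(seed_len = L, start = s, end = s + L - 1L,
                     n_mm = n_mm, n_gu = n_gu)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seed_len = integer(0), start = integer(0),
                      end = integer(0), n_mm = integer(0),
                      n_gu = integer(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$seed_len), ]
  rownames(df) <- NULL
  df
}

# naive retarget scan: every hexamer window, count non-Watson-Crick
# oppositions (G:U counts as a mismatch for search purposes)
oracle_retarget <- function(seed, transcript_seq, max_mm) {
  out <- list()
  n <- nchar(transcript_seq)
  if (n < 6) return(data.frame(start = integer(0), n_mismatch = integer(0)))
  for (s in 1:(n - 5)) {
    nonwc <- 0L
    for (k in 0:5) {
      g_nt <- substr(seed, k + 1, k + 1)
      t_nt <- substr(transcript_seq, s + 5 - k, s + 5 - k)
      if (oracle_pair_class(g_nt, t_nt) != "wc") nonwc <- nonwc + 1L
    }
    if (nonwc <= max_mm) {
      out[[length(out) + 1]] <- data.frame(start = s, n_mismatch = nonwc)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), n_mismatch = integer(0)))
  }
  do.call(rbind, out)
}

# hand-summed stacking energy of a fully complementary helix: sum of the
# WC doublet table over consecutive pairs plus terminal penalties
oracle_helix_energy <- function(seq, model = default_energy_model()) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  e <- 0
  for (i in 1:(n - 1)) {
    e <- e + model$stack[[paste0(chars[i], chars[i + 1])]]
  }
  term <- function(nt) if (nt %in% c("A", "U")) model$terminal_au else 0
  e + term(chars[1]) + term(chars[n])
}

# study-conditions fixture shared by profile/variant tests: a guide whose
# seed carries a CG dinucleotide at seed positions 3-4 (synthetic stand-in
# for a CG-containing therapeutic seed)
study_guide <- function() guide("miSYN1", "UUCGACUCAUUGAUGAUACGAU")
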