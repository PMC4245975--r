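# Nearest-neighbor duplex hybridization energy, target-site accessibility
# (opening) energy, the ddG site score, and 5'-end loading asymmetry.
# All energies are free energies at 37 C in kcal/mol; more negative = more
# stable.

#' Load a nearest-neighbor energy model
#'
#' The model is a versioned key/value TSV shipped with the package
#' (`nn_stack_37C_v1.tsv`): the 16 Watson-Crick stacking doublets (published
#' 37 C nearest-neighbor constants; key `stack:XY` is the top-strand
#' dinucleotide 5'->3' over its complement), a flat stacking value for any
#' doublet involving a G:U pair, terminal AU/GU penalty, duplex initiation,
#' a flat per-mismatch internal penalty, and the loop/multiloop parameters
#' used by the folding engine. Coarse in its loop and G:U treatment but
#' monotone, which is what site ranking needs.
#'
#' @param path Path to the model TSV; default the shipped table.
#' @return Object of class `"energy_model"`.
#' @export
load_energy_model <- function(path = system.file("extdata",
                                                 "nn_stack_37C_v1.tsv",
                                                 package = "mirdetox")) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
  kv <- setNames(tab$value, tab$key)
  stack_keys <- grep("^stack:", names(kv), value = TRUE)
  stack <- setNames(as.numeric(kv[stack_keys]),
                    sub("^stack:", "", stack_keys))
  need <- as.vector(outer(RNA_ALPHABET, RNA_ALPHABET, paste0))
  if (!all(need %in% names(stack))) {
    stop("energy table missing WC stacking doublet(s): ",
         paste(setdiff(need, names(stack)), collapse = ", "), call. = FALSE)
  }
  num <- function(k) as.numeric(kv[[k]])
  m <- list(version = kv[["version"]], stack = stack,
            gu_stack = num("gu_stack"), terminal_au = num("terminal_au"),
            duplex_init = num("duplex_init"),
            mismatch_penalty = num("mismatch_penalty"),
            asym_penalty = num("asym_penalty"),
            hairpin_base = num("hairpin_base"),
            hairpin_slope = num("hairpin_slope"),
            bulge_base = num("bulge_base"), bulge_per = num("bulge_per"),
            intloop_base = num("intloop_base"),
            intloop_per = num("intloop_per"),
            intloop_asym = num("intloop_asym"), ml_init = num("ml_init"),
            ml_branch = num("ml_branch"), ml_unpaired = num("ml_unpaired"))
  m$stack4 <- build_stack4(m)
  class(m) <- "energy_model"
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %s (37 C, kcal/mol); GC/GC stack %.2f, G:U %.2f\n",
              x$version, x$stack[["GC"]], x$gu_stack))
  invisible(x)
}

the_model <- new.env(parent = emptyenv())

#' Default (shipped) energy model, cached
#' @return An `energy_model`.
#' @export
default_energy_model <- function() {
  if (is.null(the_model$m)) the_model$m <- load_energy_model()
  the_model$m
}

is_pair_code <- function(a, b) {
  (a == 1L & b == 4L) | (a == 4L & b == 1L) | (a == 2L & b == 3L) |
    (a == 3L & b == 2L) | (a == 3L & b == 4L) | (a == 4L & b == 3L)
}

is_gu_code <- function(a, b) (a == 3L & b == 4L) | (a == 4L & b == 3L)

# 4x4x4x4 stack energy: top doublet (t1,t2) 5'->3' over bottom (b1,b2) read
# 3'->5' (b1 pairs t1, b2 pairs t2). NA where not a stackable doublet.
build_stack4 <- function(m) {
  arr <- array(NA_real_, c(4, 4, 4, 4))
  for (t1 in 1:4) for (t2 in 1:4) for (b1 in 1:4) for (b2 in 1:4) {
    if (!is_pair_code(t1, b1) || !is_pair_code(t2, b2)) next
    if (is_gu_code(t1, b1) || is_gu_code(t2, b2)) {
      arr[t1, t2, b1, b2] <- m$gu_stack
    } else {
      arr[t1, t2, b1, b2] <-
        m$stack[[paste0(RNA_ALPHABET[t1], RNA_ALPHABET[t2])]]
    }
  }
  arr
}

term_penalty <- function(a, b, m) {
  # terminal penalty for AU and GU closing pairs
  if ((a == 2L && b == 3L) || (a == 3L && b == 2L)) 0 else m$terminal_au
}

#' Guide:target duplex hybridization energy
#'
#' Minimum free energy of the hybrid between a guide strand and a target
#' window under the nearest-neighbor model: a dynamic program over
#' antiparallel pairings (guide 5'->3' against target 3'->5') allowing
#' Watson-Crick and G:U pairs, with mismatches and small internal
#' loops/bulges (up to `bulge_max` unpaired bases per side) absorbed at a
#' flat per-base penalty. No multiloops: guide:target hybrids are short.
#'
#' @param guide A [guide()] or sequence string.
#' @param target_window Target sequence 5'->3' (the site plus upstream
#'   flank, so the guide 3' region can pair).
#' @param model An `energy_model`; default [default_energy_model()].
#' @param bulge_max Maximum unpaired bases per strand between consecutive
#'   pairs; default 3.
#' @param min_window Reject windows shorter than this (default 6).
#' @return Free energy in kcal/mol (<= 0; 0 means no stable duplex).
#' @export
duplex_energy <- function(guide, target_window,
                          model = default_energy_model(), bulge_max = 3L,
                          min_window = 6L) {
  g <- if (inherits(guide, "guide")) guide$sequence else
    normalize_sequence(guide)
  t <- normalize_sequence(target_window)
  if (nchar(t) < min_window) {
    stop(sprintf("target window shorter than %d nt", min_window),
         call. = FALSE)
  }
  gc <- seq_to_codes(g); tc <- seq_to_codes(t)
  m <- length(gc); n <- length(tc)
  H <- matrix(Inf, m, n)
  init <- model$duplex_init
  mmp <- model$mismatch_penalty; asym <- model$asym_penalty
  st <- model$stack4
  for (i in seq_len(m)) {
    for (j in n:1) {
      if (!is_pair_code(gc[i], tc[j])) next
      best <- init + term_penalty(gc[i], tc[j], model)
      i0 <- max(1L, i - bulge_max - 1L)
      j1 <- min(n, j + bulge_max + 1L)
      if (i > 1L && j < n) {
        for (i2 in i0:(i - 1L)) {
          l1 <- i - i2 - 1L
          for (j2 in (j + 1L):j1) {
            h <- H[i2, j2]
            if (!is.finite(h)) next
            l2 <- j2 - j - 1L
            if (l1 == 0L && l2 == 0L) {
              e <- st[gc[i2], gc[i], tc[j2], tc[j]]
            } else {
              e <- mmp * max(l1, l2) + asym * abs(l1 - l2)
            }
            if (h + e < best) best <- h + e
          }
        }
      }
      H[i, j] <- best
    }
  }
  fin <- Inf
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (is.finite(H[i, j])) {
      e <- H[i, j] + term_penalty(gc[i], tc[j], model)
      if (e < fin) fin <- e
    }
  }
  min(0, fin)
}

#' Minimum free energy of a sequence window (optionally constrained)
#'
#' @param sequence RNA string.
#' @param force_unpaired Integer positions (1-based) forced single-stranded.
#' @param model An `energy_model`.
#' @return MFE in kcal/mol (<= 0).
#' @export
fold_mfe <- function(sequence, force_unpaired = integer(0),
                     model = default_energy_model()) {
  s <- normalize_sequence(sequence)
  codes <- seq_to_codes(s) - 1L
  if (any(codes > 3L)) stop("invalid nucleotide in fold window", call. = FALSE)
  mask <- rep(FALSE, length(codes))
  mask[force_unpaired] <- TRUE
  par <- model[c("hairpin_base", "hairpin_slope", "bulge_base", "bulge_per",
                 "intloop_base", "intloop_per", "intloop_asym", "ml_init",
                 "ml_branch", "ml_unpaired", "terminal_au")]
  fold_mfe_cpp(codes, mask, as.numeric(model$stack4), par)
}

#' Target-site opening (accessibility) energy
#'
#' Cost of making the site single-stranded within its local secondary
#' structure: `dg_open = MFE(window, unconstrained) - MFE(window, site
#' forced unpaired)` over the site plus `flank` nt on each side. By
#' construction `dg_open <= 0`; 0 means a fully accessible site. More
#' negative dg_open = more structure to open = weaker site after the
#' ddG = dGduplex - dGopen subtraction.
#'
#' @param utr_sequence Full UTR (or transcript) sequence.
#' @param site_span Integer pair, 1-based inclusive site span.
#' @param flank Flank width on each side; default 50 nt.
#' @param model An `energy_model`.
#' @return dg_open in kcal/mol (<= 0).
#' @export
opening_energy <- function(utr_sequence, site_span, flank = 50L,
                           model = default_energy_model()) {
  s <- normalize_sequence(utr_sequence)
  n <- nchar(s)
  site_span <- as.integer(site_span)
  if (site_span[1] < 1L || site_span[2] > n || site_span[1] > site_span[2]) {
    stop("site span outside sequence", call. = FALSE)
  }
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  w1 <- max(1L, site_span[1] - flank)
  w2 <- min(n, site_span[2] + flank)
  win <- substr(s, w1, w2)
  rel <- (site_span[1] - w1 + 1L):(site_span[2] - w1 + 1L)
  g_u <- fold_mfe(win, model = model)
  g_c <- fold_mfe(win, force_unpaired = rel, model = model)
  g_u - g_c
}

#' The ddG site-strength score
#'
#' `ddg = dg_duplex - dg_open`: the hybridization gain minus the
#' accessibility cost. Lower (more negative) ddG = stronger site; sites
#' below about -10 kcal/mol are considered likely functional for
#' endogenous-level miRNAs (an overexpressed trigger may act above that).
#'
#' @param dg_duplex,dg_open Finite energies in kcal/mol.
#' @param functional_threshold Classification threshold; default -10.
#' @return List with `dg_duplex`, `dg_open`, `ddg`, `likely_functional`.
#' @export
ddg <- function(dg_duplex, dg_open, functional_threshold = -10) {
  stopifnot(is.finite(dg_duplex), is.finite(dg_open))
  d <- dg_duplex - dg_open
  list(dg_duplex = dg_duplex, dg_open = dg_open, ddg = d,
       likely_functional = d < functional_threshold)
}

# sum of stacking energies over the k terminal base pairs at the 5' end of
# `top`, paired against `bottom` in the full antiparallel register
end_stability <- function(top, bottom, k, model) {
  if (k <= 0L) return(0)
  tc <- seq_to_codes(top); bc <- seq_to_codes(bottom)
  n <- min(length(tc), length(bc))
  if (k > n) stop("k exceeds duplex length", call. = FALSE)
  e <- 0
  for (i in seq_len(k - 1L)) {
    b1 <- bc[length(bc) - i + 1L]; b2 <- bc[length(bc) - i]
    v <- model$stack4[tc[i], tc[i + 1L], b1, b2]
    e <- e + if (is.na(v)) model$mismatch_penalty else v
  }
  e
}

#' 5'-end thermodynamic loading asymmetry
#'
#' RISC preferentially loads the strand whose 5' duplex end is less stable.
#' The score is (stacking stability of the `k` terminal pairs at the guide
#' 5' end) minus (same at the passenger 5' end): a positive score means the
#' guide 5' end is less stable and predicts guide-strand loading.
#'
#' @param guide A [guide()] or sequence string.
#' @param passenger Passenger strand 5'->3'; default the full reverse
#'   complement of the guide.
#' @param k Number of terminal pairs; default 4. `k = 0` scores 0.
#' @param model An `energy_model`.
#' @return Score in kcal/mol; positive favors guide loading.
#' @export
asymmetry_score <- function(guide, passenger = NULL, k = 4L,
                            model = default_energy_model()) {
  g <- if (inherits(guide, "guide")) guide$sequence else
    normalize_sequence(guide)
  p <- if (is.null(passenger)) revcomp(g) else normalize_sequence(passenger)
  e_guide <- end_stability(g, p, k, model)
  e_pass <- end_stability(p, g, k, model)
  e_guide - e_pass
}
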