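test_that("energy model ships complete and versioned", {
  m <- default_energy_model()
  doublets <- as.vector(outer(rna_bases, rna_bases, paste0))
  expect_true(all(doublets %in% names(m$stack)))
  expect_true(all(m$stack < 0))
  expect_identical(m$version, "nn37-v1")
  # stack table symmetry: 5'XY/3'X'Y' reversed is 5'Y'X'... the doublet and
  # its reverse-complement doublet carry the same energy
  for (d in doublets) {
    rc <- oracle_revcomp(chartr("T", "U", d))
    expect_equal(m$stack[[d]], m$stack[[rc]], info = d)
  }
})

test_that("duplex energy of perfect helices equals the hand-summed table", {
  m <- default_energy_model()
  set.seed(7)
  for (i in 1:25) {
    s <- random_rna_str(sample(8:22, 1))
    got <- duplex_energy(s, oracle_revcomp(s), min_window = 6)
    expect_equal(got, min(0, oracle_helix_energy(s, m)), tolerance = 1e-9,
                 info = s)
  }
})

test_that("duplex energy orders GC-rich below AU-rich and penalizes mismatches", {
  gc_rich <- "GCGCGCGCGCGC"
  au_rich <- "AUAUAUAUAUAU"
  e_gc <- duplex_energy(gc_rich, oracle_revcomp(gc_rich))
  e_au <- duplex_energy(au_rich, oracle_revcomp(au_rich))
  expect_lt(e_gc, e_au)
  set.seed(8)
  for (i in 1:15) {
    s <- random_rna_str(16)
    t_perf <- oracle_revcomp(s)
    t_mm <- t_perf
    # break one central pair with a self-nucleotide (never WC, never G:U)
    substr(t_mm, 8, 8) <- substr(s, 9, 9)
    expect_lt(duplex_energy(s, t_perf), duplex_energy(s, t_mm))
  }
})

test_that("degenerate duplex windows behave as specified", {
  expect_equal(duplex_energy("GCGCGCGCGCGCGCGC", "A", min_window = 1), 0)
  expect_error(duplex_energy("GCGCGCGCGCGCGCGC", "ACG"), "shorter")
  # appending a Watson-Crick pair at the helix edge never raises the energy
  set.seed(9)
  for (i in 1:20) {
    s <- random_rna_str(12)
    for (nt in rna_bases) {
      e0 <- duplex_energy(s, oracle_revcomp(s))
      s2 <- paste0(s, nt)
      e1 <- duplex_energy(s2, oracle_revcomp(s2))
      expect_lte(e1, e0 + 1e-9)
    }
  }
})

test_that("opening energy is zero for unstructured sites and negative in stems", {
  polyA <- paste(rep("A", 140), collapse = "")
  expect_equal(opening_energy(polyA, c(60, 67)), 0)
  # site buried in a designed perfect hairpin stem; the purine-only arm
  # cannot pair with itself or with the A flanks
  stem5 <- "GGAGGAGGAGGA"
  loop <- "AAAA"
  hairpin <- paste0(paste(rep("A", 40), collapse = ""), stem5, loop,
                    oracle_revcomp(stem5), paste(rep("A", 40), collapse = ""))
  site <- c(41, 48)  # inside the 5' arm of the stem
  dg_stem <- opening_energy(hairpin, site, flank = 50)
  # the same site sequence in a structure-free window
  flat <- paste0(paste(rep("A", 40), collapse = ""), stem5,
                 paste(rep("A", 56), collapse = ""))
  dg_flat <- opening_energy(flat, site, flank = 50)
  expect_lt(dg_stem, dg_flat)
  expect_equal(dg_flat, 0, tolerance = 1e-6)
  # flank 0 with an all-unpaired window
  expect_equal(opening_energy(polyA, c(1, 140), flank = 0), 0)
})

test_that("forcing more bases unpaired never relaxes the constrained fold", {
  set.seed(10)
  for (i in 1:10) {
    s <- random_rna_str(90, prob = c(0.2, 0.3, 0.3, 0.2))
    m1 <- fold_mfe(s, force_unpaired = 40:45)
    m2 <- fold_mfe(s, force_unpaired = 35:50)
    expect_gte(m2, m1 - 1e-9)
    expect_gte(m1, fold_mfe(s) - 1e-9)
  }
})

test_that("ddG is the exact duplex-minus-open difference with a threshold", {
  d <- ddg(-20.4, -10.0)
  expect_equal(d$ddg, -10.4)
  expect_true(d$likely_functional)
  d2 <- ddg(-5.0, 0.0)
  expect_equal(d2$ddg, -5.0)
  expect_false(d2$likely_functional)
  expect_error(ddg(NA, 0), "finite")
})

test_that("hairpin-buried sites always score weaker ddG than open ones", {
  g <- study_guide()
  motif <- canonical_motifs(g)[["8mer"]]
  stem <- paste0(motif, "GCAAAAGC", oracle_revcomp(motif))
  ctx_open <- paste0(paste(rep("A", 50), collapse = ""), motif,
                     paste(rep("A", 50), collapse = ""))
  ctx_stem <- paste0(paste(rep("A", 50), collapse = ""), stem,
                     paste(rep("A", 42), collapse = ""))
  win <- function(seqstr) substr(seqstr, 51 - 15, 50 + nchar(motif) - 1)
  site <- c(51, 50 + nchar(motif))
  dd_open <- ddg(duplex_energy(g, win(ctx_open)),
                 opening_energy(ctx_open, site))$ddg
  dd_stem <- ddg(duplex_energy(g, win(ctx_stem)),
                 opening_energy(ctx_stem, site))$ddg
  expect_lt(dd_open, dd_stem)
})

test_that("asymmetry score favors the strand with the weaker 5' end", {
  # guide 5' end A:U-rich, passenger 5' end G:C-rich
  g <- "AUAUAUCGCAUUGGCGCGCGCC"
  expect_gt(asymmetry_score(g), 0)
  # symmetric ends cancel exactly
  sym <- paste0("GCGC", "AUAUCGAUAUCGAU", "GCGC")
  expect_equal(asymmetry_score(sym), 0)
  expect_equal(asymmetry_score(g, k = 0), 0)
  expect_error(asymmetry_score(g, k = 40), "exceeds")
})

test_that("fold direction agrees with an independent folding implementation", {
  # RNAfold (ViennaRNA) as an external directional oracle: our coarse model
  # is not expected to match kcal values, but structured windows must score
  # clearly below unstructured ones and the cross-window ranking should
  # broadly agree
  rnafold <- Sys.which("RNAfold")
  expect_true(nzchar(rnafold))
  set.seed(12)
  windows <- c(
    vapply(1:5, function(i) {
      stem <- random_rna_str(14, prob = c(0.1, 0.4, 0.4, 0.1))
      paste0(random_rna_str(20), stem, "GAAA", oracle_revcomp(stem),
             random_rna_str(20))
    }, ""),
    vapply(1:5, function(i) {
      random_rna_str(72, prob = c(0.45, 0.05, 0.05, 0.45))
    }, ""))
  ours <- vapply(windows, fold_mfe, numeric(1), USE.NAMES = FALSE)
  theirs <- vapply(windows, function(w) {
    out <- system2(rnafold, args = c("--noPS"), input = w, stdout = TRUE)
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", out[2]))
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(ours[1:5] < -5))           # hairpins fold
  expect_true(all(theirs[1:5] < -5))
  expect_true(all(ours[6:10] > -3))          # AU-soup barely folds
  expect_gt(cor(ours, theirs, method = "spearman"), 0.7)
})
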