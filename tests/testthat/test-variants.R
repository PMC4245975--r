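test_that("variant enumeration is exhaustive, duplicate-free and confined", {
  g <- study_guide()
  vs <- enumerate_seed_variants(g, positions = 2:7)
  expect_length(vs, 18)
  expect_equal(anyDuplicated(vapply(vs, function(v) v$sequence, "")), 0)
  for (v in vs) {
    diffs <- which(strsplit(v$sequence, "")[[1]] !=
                     strsplit(g$sequence, "")[[1]])
    expect_length(diffs, 1)
    expect_true(diffs >= 2 && diffs <= 7)
  }
  # position 5 of the parent is A: variants are C, G, U
  expect_identical(substr(g$sequence, 5, 5), "A")
  v5 <- enumerate_seed_variants(g, positions = 5)
  expect_setequal(names(v5), c("v5C", "v5G", "v5U"))
  expect_error(enumerate_seed_variants(g, positions = 30), "position")
})

test_that("exclusion rules flag position-8 and CpG-disrupting variants", {
  g <- study_guide()  # seed UCGACU: CG at guide positions 3-4
  tab <- data.frame(position = c(8L, 3L, 6L), alt = c("U", "A", "A"),
                    stringsAsFactors = FALSE)
  out <- apply_exclusion_rules(g, tab)
  expect_identical(out$exclusion_reason,
                   c("position8_overlap", "cpg_disruption", "none"))
  expect_identical(out$excluded, c(TRUE, TRUE, FALSE))
  # CG-free seed: no CpG flags anywhere in 2-7
  g2 <- guide("nocg", "UACAGUACAUUGAUGAUACGAU")
  tab2 <- data.frame(position = 2:7, alt = "A")
  out2 <- apply_exclusion_rules(g2, tab2)
  expect_true(all(out2$exclusion_reason == "none"))
})

test_that("comparing a profile with itself is the exact identity", {
  g <- study_guide()
  gen <- generate_utrome(8, c(250L, 400L), rng_seed = 91)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:4], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 92)
  p <- build_profile(g, pl$utrome)
  cmp <- compare_profiles(p, p, pl$utrome)
  expect_equal(cmp$n_shared, 4)
  expect_equal(cmp$shared_fraction, 1.0)
  expect_equal(cmp$n_shared_sites, 4)
  expect_equal(cmp$mean_ddg_shift, 0)
})

test_that("seed mismatches strictly weaken every parent site duplex", {
  g <- study_guide()
  gen <- generate_utrome(8, c(250L, 400L), rng_seed = 93)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:4],
                   site_type = c("8mer", "7mer-m8", "8mer", "7mer-A1"))
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 94)
  p <- build_profile(g, pl$utrome)
  for (lab in c("v5U", "v6A", "v2G")) {
    v <- enumerate_seed_variants(g, positions = 2:7)[[lab]]
    vp <- build_profile(v, pl$utrome)
    cmp <- compare_profiles(p, vp, pl$utrome)
    expect_gt(cmp$mean_ddg_shift, 0)
    expect_true(all(cmp$per_site$ddg_shift > 0))
  }
})

test_that("an empty parent profile reports a missing shared fraction", {
  g <- study_guide()
  gen <- generate_utrome(3, c(250L, 300L), rng_seed = 95)
  pl <- plant_sites(gen$utrome, g,
                    data.frame(gene_id = character(0),
                               site_type = character(0)),
                    rng_seed = 96)
  p_empty <- build_profile(g, pl$utrome)
  expect_equal(nrow(p_empty$genes), 0)
  cmp <- compare_profiles(p_empty, p_empty, pl$utrome)
  expect_true(is.na(cmp$shared_fraction))
})

test_that("position-8 variants retain every 7mer-A1 and 6mer parent site", {
  # those site types depend only on seed positions 2-7, which position-8
  # variants leave untouched -- the mechanism behind their overlapping
  # off-target profiles
  set.seed(101)
  for (i in 1:15) {
    g <- random_guide()
    utr <- random_rna_str(sample(100:300, 1),
                          prob = c(0.3, 0.2, 0.2, 0.3))
    parent_sites <- scan_canonical(g, utr, include_6mer = TRUE)
    weak <- parent_sites[parent_sites$site_type %in% c("7mer-A1", "6mer"), ]
    # compare at seed-core anchors: a parent 7mer-A1 may be reported by the
    # variant as an upgraded 8mer covering the same core
    anchors <- function(x) x$end + (x$site_type %in% c("6mer", "7mer-m8"))
    for (v in enumerate_seed_variants(g, positions = 8)) {
      v_sites <- scan_canonical(v, utr, include_6mer = TRUE)
      if (nrow(weak)) {
        expect_true(all(anchors(weak) %in% anchors(v_sites)),
                    info = paste("case", i, v$name))
      }
    }
  }
})

test_that("CG-containing seeds match fewer CpG-depleted UTR sites than CG-free shuffles", {
  # same nucleotide multiset, one seed needing a CG match on the target
  g_cg <- guide("cgseed", "UACGGAUCAUUGAUGAUACGAU")   # seed ACGGAU -> rc has CG
  g_free <- guide("cgfree", "UAGGAUCCAUUGAUGAUACGAU")  # seed AGGAUC, CG-free rc
  expect_identical(sort(strsplit(seed_of(g_cg), "")[[1]]),
                   sort(strsplit(seed_of(g_free), "")[[1]]))
  expect_true(grepl("CG", canonical_motifs(g_cg)[["6mer"]]))
  expect_false(grepl("CG", canonical_motifs(g_free)[["6mer"]]))
  wins <- 0L
  n_fix <- 25L
  for (i in seq_len(n_fix)) {
    gen <- generate_utrome(30, c(800L, 1200L), gc = 0.44,
                           cpg_depletion = 0.9, rng_seed = 1100 + i)
    n_cg <- nrow(scan_canonical(g_cg, gen$utrome, include_6mer = TRUE))
    n_free <- nrow(scan_canonical(g_free, gen$utrome, include_6mer = TRUE))
    if (n_cg < n_free) wins <- wins + 1L
  }
  expect_gte(wins / n_fix, 0.95)
})

test_that("variant ranking follows the retention and detox rule tables", {
  base <- data.frame(
    variant = c("v5U", "v6A", "v2G"), position = c(5L, 6L, 2L),
    ref = c("A", "C", "U"), alt = c("U", "A", "G"),
    mismatch_class = c("pyr_pyr", "pur_pur", "gu_wobble"),
    n_offtargets = 3L, n_expressed = 1L, n_shared = 0L,
    n_shared_sites = 0L, shared_fraction = 0, mean_ddg_shift = 4,
    excluded = FALSE, exclusion_reason = "none",
    stringsAsFactors = FALSE)
  r <- rank_variants(base)
  # positions 5/6 outrank position 2
  expect_identical(r$variant[3], "v2G")
  # the detox key prefers the purine:purine opposition
  expect_lt(r$detox_rank[r$variant == "v6A"],
            r$detox_rank[r$variant == "v5U"])
  # all-excluded input keeps flags and a deterministic order
  allex <- base
  allex$excluded <- TRUE
  allex$exclusion_reason <- "position8_overlap"
  r2 <- rank_variants(allex)
  expect_true(all(r2$excluded))
  expect_equal(nrow(r2), 3)
})

test_that("the full variant screen reproduces the detox table semantics", {
  g <- study_guide()
  gen <- generate_utrome(12, c(300L, 500L), rng_seed = 111)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:5], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 112)
  expr <- expression_set(gen$utrome$gene_id[c(1, 2)])
  scr <- variant_screen(g, pl$utrome, expr, positions = 2:8)
  expect_s3_class(scr, "variant_screen")
  expect_equal(nrow(scr), 21)
  p8 <- scr[scr$position == 8, ]
  expect_true(all(p8$exclusion_reason == "position8_overlap"))
  # planted 8mers keep pairing positions 2-7 intact for position-8 variants,
  # so every parent gene is shared
  expect_true(all(p8$shared_fraction == 1))
  cpg <- scr[scr$position %in% c(3, 4), ]
  expect_true(all(cpg$exclusion_reason == "cpg_disruption"))
  expect_true(all(scr$mean_ddg_shift > 0))
  expect_true(all(!scr$excluded[1] ))
  parent <- attr(scr, "parent_profile")
  expect_equal(nrow(parent$genes), 5)
  expect_equal(sum(parent$genes$expressed), 2)
})
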