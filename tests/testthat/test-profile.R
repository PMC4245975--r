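test_that("context-like score preserves the documented term orderings", {
  g <- study_guide()
  utr <- paste0(paste(rep("C", 100), collapse = ""),
                paste(rep("G", 100), collapse = ""))
  s8 <- list(site_type = "8mer", start = 90, end = 97)
  s7 <- list(site_type = "7mer-A1", start = 90, end = 96)
  expect_lt(context_score(s8, utr, g), context_score(s7, utr, g))

  au_ctx <- paste0(paste(rep("A", 60), collapse = ""), "GGGGGGGG",
                   paste(rep("U", 60), collapse = ""))
  gc_ctx <- paste0(paste(rep("G", 60), collapse = ""), "GGGGGGGG",
                   paste(rep("C", 60), collapse = ""))
  site <- list(site_type = "8mer", start = 61, end = 68)
  expect_lt(context_score(site, au_ctx, g), context_score(site, gc_ctx, g))

  long_utr <- paste(rep("C", 1200), collapse = "")
  near <- list(site_type = "8mer", start = 15, end = 22)
  center <- list(site_type = "8mer", start = 600, end = 607)
  expect_lt(context_score(near, long_utr, g),
            context_score(center, long_utr, g))
})

test_that("profiles recover planted truth exactly across randomized fixtures", {
  g <- study_guide()
  for (i in 1:20) {
    n_genes <- 6 + (i %% 5)
    gen <- generate_utrome(n_genes, c(250L, 450L), rng_seed = 500 + i)
    n_plant <- 2 + (i %% 4)
    types <- c("8mer", "7mer-m8", "7mer-A1")
    sp <- data.frame(gene_id = gen$utrome$gene_id[seq_len(n_plant)],
                     site_type = types[1 + (seq_len(n_plant) %% 3)])
    pl <- plant_sites(gen$utrome, g, sp, rng_seed = 900 + i)
    prof <- build_profile(g, pl$utrome)
    expect_setequal(prof$genes$gene_id, sp$gene_id)
    expect_equal(nrow(prof$sites), n_plant)
    got <- paste(prof$sites$transcript_id, prof$sites$start,
                 prof$sites$site_type)
    want <- paste(pl$truth$planted$transcript_id, pl$truth$planted$start,
                  pl$truth$planted$site_type)
    expect_setequal(got, want)
  }
})

test_that("expression marking filters membership without touching scores", {
  g <- study_guide()
  gen <- generate_utrome(10, c(250L, 400L), rng_seed = 21)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:5], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 22)
  expr <- expression_set(gen$utrome$gene_id[c(1, 3, 5)])
  p0 <- build_profile(g, pl$utrome)
  p1 <- build_profile(g, pl$utrome, expr)
  expect_length(p1$expressed_subset, 3)
  expect_setequal(p1$expressed_subset, gen$utrome$gene_id[c(1, 3, 5)])
  m0 <- p0$sites[order(p0$sites$transcript_id), ]
  m1 <- p1$sites[order(p1$sites$transcript_id), ]
  expect_equal(m0$ddg, m1$ddg)
  expect_equal(m0$context_score, m1$context_score)
})

test_that("relaxed-only evidence never enters a profile", {
  g <- study_guide()
  gen <- generate_utrome(6, c(250L, 350L), rng_seed = 31)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1], site_type = "relaxed",
                   mm_position = 5L)
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 32, scrub = "relaxed")
  expect_equal(nrow(scan_canonical(g, pl$utrome)), 0)
  rx <- scan_relaxed(g, pl$utrome)
  expect_equal(nrow(rx), 1)
  expect_equal(rx$n_mm, 1)
  prof <- build_profile(g, pl$utrome)
  expect_equal(nrow(prof$sites), 0)
  expect_equal(nrow(prof$genes), 0)
})

test_that("gene aggregation minima equal the per-site minima exactly", {
  g <- study_guide()
  gen <- generate_utrome(5, c(400L, 500L), rng_seed = 41)
  sp <- data.frame(gene_id = gen$utrome$gene_id[c(1, 1, 2)],
                   site_type = c("8mer", "7mer-m8", "8mer"))
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 42)
  prof <- build_profile(g, pl$utrome)
  expect_equal(nrow(prof$sites), 3)
  for (gene in prof$genes$gene_id) {
    sub <- prof$sites[prof$sites$gene_id == gene, ]
    row <- prof$genes[prof$genes$gene_id == gene, ]
    expect_identical(row$min_ddg, min(sub$ddg))
    expect_identical(row$min_context_score, min(sub$context_score))
    expect_equal(row$n_sites, nrow(sub))
  }
  sm <- profile_summary(prof)
  expect_equal(sm$n_sites, 3)
  expect_equal(sm$n_offtarget_genes, 2)
  # ranking is ascending by min ddG
  expect_false(is.unsorted(prof$genes$min_ddg))
})

test_that("tightening the relaxed allowance only removes sites, loosening only adds", {
  g <- study_guide()
  gen <- generate_utrome(12, c(300L, 500L), rng_seed = 51)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:4],
                   site_type = c("8mer", "7mer-m8", "7mer-A1", "8mer"))
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 52)
  key <- function(p) paste(p$sites$transcript_id, p$sites$start,
                           p$sites$site_type)
  base <- build_profile(g, pl$utrome)
  tight <- build_profile(g, pl$utrome,
                         config = list(gu_spec = "6;0,7;0,8;0",
                                       mm_spec = "6;0,7;0,8;0"))
  loose <- build_profile(g, pl$utrome,
                         config = list(gu_spec = "6;1,7;2,8;2",
                                       mm_spec = "6;1,7;2,8;2"))
  expect_true(all(key(tight) %in% key(base)))
  expect_true(all(key(base) %in% key(loose)))
})

test_that("an empty UTRome yields an empty profile with a warning", {
  g <- study_guide()
  empty <- utrome(character(0), character(0), character(0))
  expect_warning(p <- build_profile(g, empty), "empty")
  expect_equal(nrow(p$sites), 0)
  s <- profile_summary(p)
  expect_equal(unlist(s, use.names = FALSE), rep(0L, 5))
})

test_that("conservation follows the ortholog map in both directions", {
  g <- study_guide()
  mk_profile <- function(genes, sp) {
    gen <- generate_utrome(4, c(250L, 350L), rng_seed = 61 + nchar(sp),
                           species = sp, gene_prefix = paste0(sp, "_g"))
    spdf <- data.frame(gene_id = gen$utrome$gene_id[seq_along(genes)],
                       site_type = "8mer")
    pl <- plant_sites(gen$utrome, g, spdf, rng_seed = 71 + nchar(sp))
    list(profile = build_profile(g, pl$utrome),
         genes = gen$utrome$gene_id)
  }
  a <- mk_profile(1:2, "aa")   # off-targets aa_g0001, aa_g0002
  b <- mk_profile(1, "bbb")    # off-target bbb_g0001
  # disjoint map: nothing conserved
  m0 <- ortholog_map("aa_g0009", "bbb_g0009")
  r0 <- conserved_offtargets(a$profile, b$profile, m0)
  expect_length(r0$conserved_genes, 0)
  # g1 -> h1 mapped: conserved {g1}, fraction over all A genes = 0.5
  m1 <- ortholog_map("aa_g0001", "bbb_g0001")
  r1 <- conserved_offtargets(a$profile, b$profile, m1)
  expect_identical(r1$conserved_genes, "aa_g0001")
  expect_equal(r1$fraction, 0.5)
  expect_equal(r1$fraction_mapped, 1.0)
  expect_equal(r1$n_unmapped_a, 1)
  # guides must share a seed
  other <- build_profile(guide("other", "UAAAAAACACUUGUAUAGUUGG"),
                         utrome("x", "x", random_rna_str(100)))
  expect_error(conserved_offtargets(a$profile, other, m1), "seed")
})

test_that("a planted three-species fixture reports exactly the conserved gene", {
  g <- study_guide()
  gen <- generate_utrome(6, c(250L, 400L), rng_seed = 81)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:3], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 82)
  trio <- generate_species_trio(pl, g,
                                conserve_in = list(g0001 = c("mmu", "mml")),
                                rng_seed = 83)
  profs <- lapply(trio$utromes, function(u) build_profile(g, u))
  r_ab <- conserved_offtargets(profs$hsa, profs$mmu, trio$maps$hsa_mmu)
  r_ac <- conserved_offtargets(profs$hsa, profs$mml, trio$maps$hsa_mml)
  expect_identical(r_ab$conserved_genes, "hsa_g0001")
  expect_identical(r_ac$conserved_genes, "hsa_g0001")
  r_bc <- conserved_offtargets(profs$mmu, profs$mml, trio$maps$mmu_mml)
  expect_identical(r_bc$conserved_genes, "mmu_g0001")
})
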