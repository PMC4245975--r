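test_that("generation is byte-identical under a fixed seed", {
  a <- generate_utrome(25, c(200L, 400L), gc = 0.4, rng_seed = 7)
  b <- generate_utrome(25, c(200L, 400L), gc = 0.4, rng_seed = 7)
  expect_identical(a$utrome$sequence, b$utrome$sequence)
  expect_identical(a$utrome$gstart, b$utrome$gstart)
  c <- generate_utrome(25, c(200L, 400L), gc = 0.4, rng_seed = 8)
  expect_false(identical(a$utrome$sequence, c$utrome$sequence))
  # planting is deterministic too
  g <- study_guide()
  sp <- data.frame(gene_id = a$utrome$gene_id[1:3], site_type = "8mer")
  p1 <- plant_sites(a$utrome, g, sp, rng_seed = 9)
  p2 <- plant_sites(b$utrome, g, sp, rng_seed = 9)
  expect_identical(p1$utrome$sequence, p2$utrome$sequence)
  expect_identical(p1$truth$planted, p2$truth$planted)
})

test_that("composition controls hit their targets", {
  gen <- generate_utrome(40, c(600L, 1000L), gc = 0.44,
                         cpg_depletion = 0.9, rng_seed = 17)
  seqs <- gen$utrome$sequence
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  gc_obs <- mean(chars %in% c("C", "G"))
  expect_lt(abs(gc_obs - 0.44), 0.05)
  # per-record GC within tolerance for lengths >= 500
  per_gc <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("C", "G"))
  }, numeric(1))
  expect_true(all(abs(per_gc - 0.44) < 0.07))
  # CpG frequency under 20% of the independence expectation
  di <- paste0(chars[-length(chars)], chars[-1])
  cpg_obs <- mean(di == "CG")
  p_c <- mean(chars == "C"); p_g <- mean(chars == "G")
  expect_lt(cpg_obs, 0.2 * p_c * p_g)
  # degenerate and infeasible inputs
  expect_equal(nrow(generate_utrome(0, rng_seed = 1)$utrome), 0)
  expect_error(generate_utrome(5, gc = 1, cpg_depletion = 1, rng_seed = 1),
               "infeasible")
  expect_error(generate_utrome(5, gc = 1.4, rng_seed = 1), "\\[0, 1\\]")
})

test_that("planting writes exactly the requested truth", {
  g <- study_guide()
  gen <- generate_utrome(10, c(250L, 400L), rng_seed = 27)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:5], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 28)
  sc <- scan_canonical(g, pl$utrome, include_6mer = TRUE)
  expect_equal(nrow(sc), 5)
  expect_true(all(sc$site_type == "8mer"))
  expect_setequal(paste(sc$transcript_id, sc$start),
                  paste(pl$truth$planted$transcript_id,
                        pl$truth$planted$start))
  # planted motif really sits at the truth coordinates
  for (i in 1:5) {
    tr <- pl$truth$planted[i, ]
    seqrow <- pl$utrome$sequence[pl$utrome$transcript_id ==
                                   tr$transcript_id]
    expect_identical(substr(seqrow, tr$start, tr$end),
                     canonical_motifs(g)[["8mer"]])
  }
  # empty spec leaves the UTRome untouched
  pl0 <- plant_sites(gen$utrome, g,
                     data.frame(gene_id = character(0),
                                site_type = character(0)), rng_seed = 29)
  expect_identical(pl0$utrome$sequence, gen$utrome$sequence)
})

test_that("relaxed-only plants are invisible to the canonical scan", {
  g <- study_guide()
  gen <- generate_utrome(5, c(250L, 350L), rng_seed = 37)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1], site_type = "relaxed",
                   mm_position = 6L)
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 38, scrub = "relaxed")
  expect_equal(nrow(scan_canonical(g, pl$utrome, include_6mer = TRUE)), 0)
  rx <- scan_relaxed(g, pl$utrome)
  expect_equal(nrow(rx), 1)
  expect_equal(rx$start, pl$truth$planted$start)
  expect_identical(rx$mm_positions, "6")
  expect_error(plant_sites(gen$utrome, g,
                           data.frame(gene_id = gen$utrome$gene_id[1],
                                      site_type = "relaxed",
                                      mm_position = 9L),
                           rng_seed = 39), "2..7")
})

test_that("species trios conserve exactly what they are told to", {
  g <- study_guide()
  gen <- generate_utrome(6, c(250L, 400L), rng_seed = 47)
  sp <- data.frame(gene_id = gen$utrome$gene_id[1:2], site_type = "8mer")
  pl <- plant_sites(gen$utrome, g, sp, rng_seed = 48)
  trio <- generate_species_trio(pl, g,
                                conserve_in = list(g0001 = c("mmu", "mml")),
                                rng_seed = 49)
  counts <- vapply(trio$utromes, function(u) {
    nrow(scan_canonical(g, u))
  }, integer(1))
  expect_equal(unname(counts), c(2L, 1L, 1L))
  # conserving nothing leaves only the reference species with sites
  trio0 <- generate_species_trio(pl, g, conserve_in = list(),
                                 rng_seed = 50)
  counts0 <- vapply(trio0$utromes, function(u) {
    nrow(scan_canonical(g, u))
  }, integer(1))
  expect_equal(unname(counts0), c(2L, 0L, 0L))
  # ortholog maps invert losslessly
  m <- trio$maps$hsa_mmu
  rr <- invert_ortholog_map(invert_ortholog_map(m))
  expect_setequal(paste(rr$pairs$a, rr$pairs$b),
                  paste(m$pairs$a, m$pairs$b))
})

test_that("transcript models plant retarget sites with exact mismatch labels", {
  g <- study_guide()
  gen <- generate_transcript_model(
    g, plants = data.frame(mm_position = c(7, 6, 5, 4),
                           region = c("3utr", "cds", "cds", "3utr"),
                           junction = c(FALSE, TRUE, FALSE, FALSE)),
    rng_seed = 57)
  hits <- find_retarget_sites(g, gen$transcript, max_mismatch = 1)
  expect_equal(nrow(hits), 4)
  expect_setequal(hits$mismatch_position, c(7, 6, 5, 4))
  expect_setequal(hits$region[hits$mismatch_position %in% c(6, 5)], "cds")
  expect_setequal(hits$region[hits$mismatch_position %in% c(7, 4)], "3utr")
  expect_true(hits$junction_spanning[hits$mismatch_position == 6])
  expect_equal(nrow(find_retarget_sites(g, gen$transcript,
                                        max_mismatch = 0)), 0)
  # no plants: nothing to find at zero mismatches
  gen0 <- generate_transcript_model(g, rng_seed = 58)
  expect_equal(nrow(find_retarget_sites(g, gen0$transcript,
                                        max_mismatch = 0)), 0)
})
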