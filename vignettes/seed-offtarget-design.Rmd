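---
title: "Seed-mediated off-target prediction and guide redesign with mirdetox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-mediated off-target prediction and guide redesign with mirdetox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdetox)
```

## The problem

An RNAi trigger (siRNA, shRNA or artificial miRNA) silences its intended
target through extensive complementarity, but the RISC-loaded guide strand
also represses unintended transcripts through partial, seed-driven pairing:
nucleotides 2-7 from the guide's 5' end binding sites in 3'UTRs, exactly as
an endogenous miRNA would. Because 3'UTRs diverge quickly between species,
a guide optimized for low off-targeting in one species can be toxic in
another — off-target repertoires are species-specific, which matters
whenever a human-optimized therapeutic sequence must pass rodent safety
testing. mirdetox implements the computational workflow for diagnosing such
seed-mediated off-targeting and repairing it: scanning a UTRome for seed
sites, scoring them thermodynamically, comparing repertoires across
species, designing single-nucleotide seed variants that shed the off-target
set, and retargeting a trusted low-off-target seed against a new transcript.

## Site discovery

`scan_canonical()` finds the four canonical seed-site types on a target
UTR, written 5'→3' on the target strand:

| type    | target motif                          |
|---------|---------------------------------------|
| 6mer    | revcomp(seed 2-7)                     |
| 7mer-A1 | revcomp(seed 2-7) + A                 |
| 7mer-m8 | revcomp(seed 2-8)                     |
| 8mer    | revcomp(seed 2-8) + A                 |

The trailing A is the target nucleotide opposite guide position 1 and is
required to be a literal A regardless of the guide's first base (it is read
by the silencing complex, not paired). Every core match corresponds to one
"anchor" (the A1 position); overlapping matches at a shared anchor are
resolved to the strongest applicable type (8mer > 7mer-m8 > 7mer-A1 >
6mer), so one physical site is never double-counted. 6mer sites are
excluded from profiles by default (`include_6mer` exposes them): they are
weak, numerous, and dominated by noise at profile granularity.

`scan_relaxed()` is the accessibility-style complement: for each seed
length L in {6, 7, 8} it reports every window pairing the seed with at most
a budgeted number of G:U wobbles and mismatches. Budgets are given as
`"length;count"` pairs — the default `"6;0,7;1,8;1"` for both budgets
allows one wobble and one mismatch for 7- and 8-nt seeds and none for
6-nt seeds. Positional restrictions (no imperfection opposite guide
position 2) exist as an off-by-default switch, since reference relaxed
scanners do not document one.

Both scanners match on the transcript strand only and run as one vectorized
pass over the code-mapped, separator-joined record collection, which keeps
whole-UTRome scans in milliseconds.

## Thermodynamic scoring

Each site gets a `ddg = dg_duplex - dg_open` score (kcal/mol, 37 °C):

* `duplex_energy()` — nearest-neighbor minimum free energy of the
  guide:target hybrid, from a dynamic program over antiparallel pairings
  that allows Watson-Crick and G:U pairs and absorbs mismatches and small
  internal loops (up to 3 unpaired bases per strand) at a flat per-base
  penalty. No multiloops: guide:target hybrids are short.
* `opening_energy()` — the accessibility cost of the site:
  MFE(local window) − MFE(window with the site forced single-stranded),
  computed by a compiled Zuker-style folder over the site plus a 50-nt
  flank per side. By this sign convention `dg_open ≤ 0`, 0 meaning a fully
  accessible site, so the subtraction penalizes inaccessible sites and
  lower ddG always means a stronger site.

Sites below about −10 kcal/mol are flagged `likely_functional`, the
conventional threshold for endogenous-level miRNAs; an overexpressed
trigger can act above it, which is why the threshold is a config knob
(`thermo.threshold`) rather than a filter.

The energy model ships as a versioned key/value table
(`inst/extdata/nn_stack_37C_v1.tsv`). The 16 Watson-Crick stacking doublets
carry the published 37 °C nearest-neighbor constants; everything else is
deliberately coarse: a single flat stacking value for any G:U-containing
doublet, a flat +1 kcal/mol per-mismatch internal penalty, log-linear
hairpin/bulge/internal-loop penalties and an affine multiloop term. The
design goal is monotone ranking, not kcal-accurate folding — perfect-helix
energies match the published table exactly (and are tested against a
hand-summed oracle), while whole-window MFEs agree with a reference folder
(ViennaRNA's RNAfold, exercised directionally in the test suite) in sign
and ordering but not within fractions of a kcal/mol. Reproducing any
specific published ddG value additionally depends on the window/flank
defaults of the tool that printed it; `thermo.flank` is the knob to tune
when calibrating against external numbers.

MFE rather than partition-function accessibility is used throughout: it is
cheaper, deterministic, and ranking-equivalent for the designed fixtures;
ensemble opening energies are a known refinement this package does not
attempt.

Strand-loading asymmetry (`asymmetry_score()`) is the difference in
stacking stability of the k = 4 terminal pairs at the two 5' ends of the
guide:passenger duplex; positive scores (guide end less stable) predict
correct guide-strand loading.

## From sites to profiles

`build_profile()` chains the pipeline: canonical scan → relaxed scan →
intersection → ddG + context-like scoring → genomic deduplication → gene
aggregation → expression marking → ranking. Two steps deserve comment.

*Intersection.* Relaxed evidence that does not overlap a canonical site by
at least one nucleotide is dropped. Overlap rather than span identity is
used because the two scanners delimit windows differently; requiring exact
coincidence would discard agreeing calls on a technicality.

*The context-like score.* A simplified, configurable site score with the
reference ranking semantics — type baseline (8mer < 7mer-m8 < 7mer-A1 <
6mer), a local-AU term over 30-nt flanks, a 3'-pairing term (longest
complementary run of guide positions 13-16 against the upstream flank) and
a position term favoring sites near UTR ends. It is explicitly *not* a
refit of any published context regression: coefficients are package
defaults documented in `default_config()`, and only orderings, never
absolute values, are asserted anywhere.

Gene records carry the site count and the minima (strongest values) of
context score and ddG over the gene's sites; genes rank ascending by
`min_ddg` with `min_context_score` then `gene_id` as deterministic
tie-breaks. Expression filtering is externalized: a plain gene list
(`read_gene_set()`) marks genes expressed; no expression-threshold logic
lives in the package. `conserved_offtargets()` asks, per gene and through
a precomputed ortholog table, whether any ortholog carries at least one
site in the other species' profile; unmapped genes are counted separately
and the conserved fraction is reported against both denominators (the
worked toy in the tests pins 1 conserved of 2 genes with 1 unmapped to
`fraction = 0.5`, `fraction_mapped = 1`).

## Seed-variant design

`variant_screen()` enumerates every single-nucleotide seed variant
(positions 2-7 by default, 2-8 in the full screen), rebuilds each profile
under identical options and reports, per variant: off-target and expressed
counts, genes and sites shared with the parent (both granularities, since
"shared off-target" can be read either way), the shared fraction, and the
mean ddG shift obtained by rescoring the *parent's* site windows with the
variant guide — the question being how much weaker the parent's predicted
sites become, so the windows are reused and the opening term cancels.

Exclusion rules are annotations, never drops, so the full screen table can
always be produced:

* `position8_overlap` — position-8 variants leave positions 2-7 untouched,
  hence retain every 7mer-A1 and 6mer parent site (a structural superset
  property the tests assert exactly) and their profiles overlap the
  parent's extensively.
* `cpg_disruption` — a mutation that removes a CG dinucleotide from the
  seed. CG is rare in mammalian 3'UTRs, so a CG-requiring seed matches few
  sites; disrupting the CG inflates the off-target count severalfold (the
  synthetic screens reproduce this).

Ranking encodes empirical regularities as *data* (an editable rule table in
`default_config()$retention`), because they come from silencing-efficacy
observations that may not generalize to every guide: mismatches at seed
positions 5-6 retain on-target silencing best and positions 2 and 7
disrupt it; within a position, a G:U wobble opposition retains the most
residual (off-target) silencing, then pyrimidine:pyrimidine, then
purine:purine. The same class order, reversed, is the "detox" key:
purine:purine oppositions discriminate off-targets best. Both ranks are
emitted; the final ordering puts non-excluded variants first, then sorts
lexicographically on (retention rank, off-target count, shared fraction).

## Retargeting

`find_retarget_sites()` screens a spliced transcript for hexamer windows
pairing a trusted seed with at most one non-Watson-Crick opposition. G:U
counts against the mismatch budget during search — the conservative choice,
since a wobble still pairs — but its class is recorded so downstream
ranking can prefer wobble hits. Hits are classified by majority overlap
into 5'UTR/CDS/3'UTR (ties to CDS, since a boundary-straddling site that
half-covers coding sequence behaves like a CDS site) and flagged when they
span an exon junction. `assemble_guide()` builds the full candidate:
parent seed at positions 2-7 (mismatch and all), positions 8..L the exact
reverse complement of the target flank 5' of the window, and position 1
fixed to U — the widely assumed 5'-U loading preference, configurable
because it is a convention, not a measurement. The implied 5'-asymmetry
score is attached to the result, and `compare_binding_stability()`
rescores two seed-sharing guides over identical site windows to isolate
what the 3' region contributes.

## The synthetic-data generator

Every pipeline stage is testable without downloads because `generate_*`
functions build fixtures with *planted, verified* ground truth:

* `generate_utrome()` emulates a mammalian 3'UTR collection: lengths
  uniform on 500-1500 nt, GC 0.44, and CpG depletion 0.8 — each nascent CG
  dinucleotide survives with probability 0.2, reproducing the ~0.2
  observed/expected CpG ratio of mammalian sequence. These defaults are
  the package's study conditions; with a CG-containing seed they put
  off-target incidence at roughly 1-2% of genes, the scale reported for
  real transcriptome scans.
* `plant_sites()` writes requested canonical or single-mismatch relaxed
  motifs at random non-overlapping positions, pins the flanking bases so a
  planted type cannot silently upgrade (e.g. 7mer-A1 → 8mer), then
  *scrubs* the background: every unintended canonical match is broken by a
  self-nucleotide substitution (never Watson-Crick, never G:U) at an
  unprotected pairing position, iterating until a verification scan finds
  exactly the planted truth. Rejection is bounded (default 1000 placement
  retries) so over-constrained requests fail loudly naming the gene.
* `generate_species_trio()` copies a planted UTRome into three species
  with pairwise ortholog maps, breaking each planted site by a single
  seed-match substitution in every species not named in its conservation
  spec.
* `generate_transcript_model()` builds a multi-exon mRNA with planted
  single-mismatch retargeting windows at requested regions (optionally
  junction-spanning; non-junction plants avoid exon boundaries), with the
  background scrubbed of any window within the mismatch budget.

All generation runs under a single seeded RNG stream per fixture
(Mersenne-Twister with fixed sample semantics), so fixtures are
byte-identical across runs and platforms; the seed is recorded in the
returned truth object and echoed by the `simulate` CLI subcommand.

What the generator does *not* emulate: real 3'UTRs have length and
composition heterogeneity, repeat content, conserved regulatory elements
and phylogenetically structured divergence. Passing the planted-truth and
property suites therefore demonstrates algorithmic correctness — exact
scanning, exact aggregation, correct thermodynamic orderings — not
predictive accuracy on biological annotation, which additionally depends on
the annotation snapshot and the score calibrations discussed above.

## Worked example

```{r example, eval = FALSE}
g <- guide("miSYN1", "UUCGACUCAUUGAUGAUACGAU")  # seed UCGACU, CG at 3-4
gen <- generate_utrome(500, c(500, 1500), gc = 0.44, cpg_depletion = 0.8,
                       rng_seed = 1)
expr <- expression_set(gen$utrome$gene_id[1:425])
prof <- build_profile(g, gen$utrome, expr)
summary(prof)
scr <- variant_screen(g, gen$utrome, expr, positions = 2:8)
print(scr)
```

## Numerical choices and degenerate inputs

* Local coordinates are 1-based inclusive in every report; genomic
  intervals are 0-based half-open (BED) and used only for deduplication;
  conversion happens at the boundary, once.
* DNA input is accepted everywhere and normalized to RNA (UTR FASTA files
  are DNA-alphabet); ambiguity codes are rejected with position and
  character named.
* Duplex initiation defaults to 0 so that the degenerate single-nucleotide
  "duplex" scores exactly 0 and any two stacked pairs score ≤ 0; the
  published initiation constant is available as `thermo.duplex_init` for
  calibration work.
* Empty inputs degrade to empty outputs with warnings (empty FASTA, empty
  UTRome, empty site lists); an empty parent profile makes shared
  fractions `NA` rather than 0, since "none shared of none" is not
  evidence of divergence.
* All orderings are fully tie-broken (final keys on gene or variant
  labels) so reruns and diffs are stable.
* Problem sizes in the shipped tests and acceptance study — 2000-gene
  UTRomes for the screen, 1000-instance oracle sweeps, 100 planted
  fixtures — were chosen as the smallest sizes at which the binomial
  quantities being checked (shared fractions of a few percent over ~40
  off-target genes) are stable; they complete in a few minutes on one
  core.

## Known limitations

* The loop/G:U energy model is coarse by design; absolute ddG values are
  comparable within a run, not against other tools' printouts.
* Accessibility is MFE-based, not ensemble-based.
* Conservation consumes precomputed ortholog tables; no coordinate
  lift-over or synteny inference is performed.
* Antisense-strand motif matching, centered sites, bulged seed sites and
  3'-supplementary-only sites are out of scope.
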