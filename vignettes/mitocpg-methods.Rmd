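---
title: "Detecting CpG islands and CpG-rich regions in mitochondrial genomes"
author: "mitocpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CpG islands and CpG-rich regions in mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocpg)
```

## The problem

Animal mitochondrial genomes are small (~13–20 kb), circular, gene-dense
molecules. Whether and where their cytosines are methylated is contested, but
any CpG methylation requires CpG dinucleotides, so the *theoretical* CpG
landscape of a mitogenome — where CpG sites cluster, and whether any stretch
qualifies as a CpG island — is the natural starting point for comparative
epigenomics of mtDNA. `mitocpg` computes that landscape strand-awarely: the
deposited reference sequence is the light (L) strand; the heavy (H) strand is
its reverse complement, scanned separately and mapped back to reference
coordinates for annotation.

Two complementary detectors are implemented.

**Sliding-window island caller.** For a window of $N$ bases containing
$N_C$ cytosines, $N_G$ guanines and $N_{CpG}$ CG dinucleotides, the
observed/expected CpG ratio is

$$\mathrm{obs/exp} = \frac{N_{CpG} \cdot N}{N_C \cdot N_G},$$

the classical enrichment measure relative to base composition. A 100 bp
window slides 1 bp at a time; an island is a maximal run of bases, at least
200 bp long, whose attributed window values satisfy obs/exp ≥ 0.6 **and**
%C+%G ≥ 50. Island-level statistics (length, C+G sum, %C+%G, obs/exp) are
then recomputed over the island subsequence.

**Running-sum region detector.** Every position scores $+17$ when a CG
dinucleotide starts there and $-1$ otherwise. Maximal-scoring segments with
total score at least the threshold (default 17) are reported recursively:
the best segment first, then the same search on both flanks, so reported
regions are disjoint by construction. This finds much smaller CpG clusters
than the island definition — deliberately over-sensitive, which is what
makes sparse tRNA-gene clusters visible — and each region carries its CpG
count, C+G sum and obs/exp. The per-strand sum of region CpG counts is the
"CpG sites per strand" statistic of comparative tables.

## Decisions where the definitions are under-determined

* **Threshold inclusivity.** Published island tables contain a 200 bp island
  and a 50.00 %C+%G island, so all three island bounds are inclusive
  (≥ 200 bp, ≥ 50%, ≥ 0.6). Likewise the running-sum threshold is inclusive
  (score ≥ 17), which makes a single isolated CpG (score exactly 17) a
  decidable, documented edge case; `seek_params(strict = TRUE)` switches to
  a strict comparison.
* **Window-to-base attribution.** Per-window %C+%G and obs/exp are invariant
  under reverse complement, yet published island sets differ between
  strands; the difference can only come from how window values are
  attributed to bases at run boundaries, a detail sliding-window
  implementations rarely document. `call_islands()` exposes two rules:
  `"cover"` (default; a base is flagged when *any* covering window passes —
  this is also exactly what the brute-force oracle tests) and `"midpoint"`
  (each window flags only its centre base, giving tighter boundaries).
  Results that disagree between conventions should be treated as boundary
  ambiguity, not signal; the acceptance tests compare both rules.
* **Aggregate post-filter.** Under the cover rule a run of flagged bases
  could, in principle, have aggregate statistics slightly below the
  per-window thresholds; candidate islands whose recomputed aggregate values
  fail any threshold are dropped, so every reported island satisfies the
  definition as written.
* **Ties in the running sum.** Equal-scoring segments are resolved leftmost
  first, then shortest. Segments necessarily begin and end on scoring
  positions, so every region starts at the C and ends at the G of a CpG.
* **Linear scanning.** Sequences are treated as linear by default, matching
  how the classical tools process a linearized circular record: a CpG
  spanning the origin is not counted, and no window spans it.
  `circular = TRUE` additionally evaluates origin-spanning windows in the
  island caller and reports an origin-wrapping island as `start > end`.
* **Rounding.** Reported %C+%G and obs/exp are rounded half-up to 2 decimal
  places, matching table formatting conventions; all internal comparisons
  use unrounded values.

## Annotation and comparative tables

Detections are attributed to annotated features (protein genes, tRNAs,
rRNAs, D-loop, replication origin, intergenic spacers) by ≥ 1 bp overlap.
Features wrapping the sequence origin (the vertebrate D-loop) are split into
two spans for overlap testing and counted as one feature. A region
overlapping two or more named features contributes its whole CpG count to
the multi-feature table only; single-feature regions feed the per-gene
matrix; every region is counted exactly once, so per-strand totals are
conserved (an optional proportional-split mode divides multi-feature counts
by overlap length instead). Locus names are canonicalized
(`tRNA-Trp` → `TRNW`, `COII` → `COX2`, ...) so cross-species tables align;
unmapped names pass through with a warning. The alternative of attributing a
region by majority overlap was rejected because the small tRNA genes that
motivate the multi-feature table would then almost never be credited.

## The synthetic-data generator

Synthetic genomes make every stage testable without downloads, and their
defaults define the conditions under which the pipeline is validated:

* **Background**: 16.5 kb, 40% GC, obs/exp 0.25 — the composition regime of
  a typical vertebrate mitogenome, which is GC-poor and strongly
  CpG-depleted. The background is a *first-order Markov* dinucleotide chain,
  not i.i.d. bases: CpG depletion is a dinucleotide property, and only a
  chain can hold GC fixed while suppressing CG transitions. The C→G
  transition probability is set to `obs_exp × πG` and a short fixed-point
  iteration corrects the stationary distribution, so realized GC and
  obs/exp match their targets (mean over 50 seeds within ±0.01 / ±0.03;
  `obs_exp = 0` provably emits no CG at all).
* **Planted islands**: two per genome by default, 300–320 bp, 55% GC,
  obs/exp 1.2 — comfortably above all three island criteria, with length
  margin for boundary attribution — one inside the protein-gene cluster and
  one in the D-loop. Island planting *replaces* sequence in place so all
  coordinates stay stable. Because the truth table asserts each island's
  composition, island pieces are redrawn (inside the same seeded stream,
  hence still deterministic) until their realized GC is within 0.015 and
  obs/exp within 10% of nominal: a single finite draw from the chain can
  otherwise realize, say, 49.7% GC from a 55% target, producing a "planted
  island" that genuinely lacks the property the caller detects.
* **Feature layout**: the canonical vertebrate gene order (tRNA-Phe, 12S
  rRNA, ..., CYTB, tRNA-Thr, tRNA-Pro) at realistic locus lengths, with a
  D-loop filling the tail and optionally wrapping the origin; genomes
  shorter than the canonical ~15.7 kb span (compact invertebrate-like
  mitogenomes) scale locus lengths down proportionally.
* **Determinism**: every random draw happens under a locally-scoped seed
  recorded in the truth table; the caller's RNG state is never touched, and
  identical specs yield byte-identical FASTA and truth output.

What the generator does *not* emulate: codon structure, strand-specific
skew, tRNA secondary-structure constraints, NUMT-like repeats, and the
D-loop's internal repeat architecture. Passing the synthetic suite therefore
demonstrates that the detectors and bookkeeping are correct, not that any
particular real genome will show a given island set.

```{r example}
out <- generate_mito_genome(synth_spec(seed = 42))
scan <- scan_genome(out$genome, ft = out$features)
island_report(scan$islands, out$features, genome_length = out$genome$length)
out$truth
```

## Validation strategy and problem sizes

The test suite validates each operation against an independent
re-computation: both detectors are compared with brute-force oracles (direct
per-window substring statistics for the island caller; exhaustive
enumeration of all segments for the running sum) on hundreds of random
genomes of 120–600 bp; strand symmetry of CpG counts is checked on 1,000
random sequences; planted-island recovery uses 20 full-size (16.5 kb)
genomes at the default composition, requiring every planted island back
within 100 bp (one window) of its true boundaries and at most 10% spurious
calls; the comparative stage runs a 12-genome cohort (nine vertebrate-like,
three AT-rich invertebrate-like) through the full file-based pipeline.
These sizes keep the whole suite to well under two minutes while giving the
oracles enough room to catch off-by-one and attribution errors, which is
where sliding-window implementations actually fail.

## Reproducing the published reference analysis

`reproduce_reference_tables()` scans the twelve reference mitogenomes of the
comparative study (manifest in
`system.file("extdata", "reference_manifest.tsv", package = "mitocpg")`)
from a local directory of FASTA files; `scripts/fetch_references.R`
downloads them from NCBI. The package itself never downloads. Exact
reproduction of published island coordinates depends on the
window-attribution convention discussed above; run the function under both
`attribution = "cover"` and `"midpoint"` before attributing any discrepancy
to the statistics.

## Known limitations

* The H-strand is scanned as a full reverse complement of a *linearized*
  sequence; genuine origin-spanning biology is only approximated by the
  optional circular mode.
* The running-sum detector is intentionally over-sensitive; its region count
  is not an island count and should be read together with the score and CpG
  count columns.
* No statistical test is attached to vertebrate/invertebrate contrasts; the
  comparative tables are descriptive.
* GenBank parsing covers the feature keys used by organelle records (gene,
  tRNA, rRNA, D-loop, rep_origin, CDS, misc_feature) — it is not a general
  GenBank reader.
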