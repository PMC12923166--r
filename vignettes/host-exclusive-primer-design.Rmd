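---
title: "Designing host-exclusive metabarcoding primers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing host-exclusive metabarcoding primers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcprimer)
```

## The problem

Amplicon sequencing of a host-associated community — endophytic fungi
in a plant, for instance — competes with the host's own copies of the
marker locus. Because rDNA is conserved, a universal primer amplifies
host and microbes alike, and the host, present in every cell of the
sampled tissue, can dominate the library. The remedy is a primer that
sits in a region conserved *within* the target taxa but divergent
*from* the host: a discriminative, host-exclusive primer. Finding such
regions by eye in a multiple sequence alignment is slow and
error-prone; `mbcprimer` automates it.

## The model

### Input and preprocessing

The input is a user-supplied MSA in FASTA containing both sets, with a
designation of which records are targets (an integer prefix count or an
id list — both are supported because curated reference sets are often
concatenated FASTAs, while arbitrary inputs need explicit ids).
Residues are uppercased and U→T normalized, since rRNA reference
databases deliver RNA-alphabet, mixed-case records; `.` is accepted as
a gap alias.

Two artefacts of marker databases are handled explicitly:

* **Terminal gaps.** Partial records produce long leading/trailing gap
  runs that are alignment padding, not biology. Each record's first and
  last non-gap columns are recorded, and positions outside that range
  are excluded from *both* the numerator and denominator of column
  statistics and from window coverage. The alternative — counting
  terminal gaps as gaps — would let a handful of partial records delete
  genuinely conserved columns; the coverage-aware rule avoids that at
  the cost of estimating some columns from fewer records.

* **Gappy/ambiguous columns.** A column is trimmed when its fraction of
  internal gaps plus non-ACGT characters among covering records exceeds
  `max_frac` (default 0.20, strictly greater, so a column at exactly
  20% is kept). Trimmed coordinates are mapped back to the input
  alignment in every report, since users must locate sites in their own
  MSA.

### The scan

For every window of `window_length` columns (default 20 bp, the typical
primer length; rerun with other lengths rather than searching lengths
jointly), records whose terminal span fully covers the window are
extracted and degapped. The most abundant target variant becomes the
candidate; ties break to the variant seen first in record order, making
the scan deterministic. Edit distances (Levenshtein; insertions and
deletions cost 1, so indel variants are handled gracefully) from every
variant to the candidate are binned at 0, 1, 2, 3, ≥4 mismatches and
abundance-weighted into a target and an exclusion **mismatch profile**.
Weighting by sequence abundance rather than by unique variant count is
deliberate: claims like "80% coverage of fungi" are statements about
sequences, not about distinct window haplotypes. (A per-variant
weighting would over-emphasize rare haplotypes in skewed sets.)

### The score

With $t_i$, $e_i$ the fraction of the target/exclusion set at exactly
$i-1$ mismatches,

$$\mathrm{score} = \frac{1}{mm}\sum_{k=1}^{mm}\left(\sum_{i=1}^{k} t_i - \sum_{i=1}^{k} e_i\right)$$

The indexing ($i = 1$ ↔ 0 mismatches) is forced by the score's defining
anchor: all targets at 0 mismatches and all exclusions at ≥ `mm`
mismatches must give exactly 1 at the default `mm = 2`:

```{r anchor}
discriminative_score(c(1, 0, 0, 0, 0), c(0, 0, 0, 0, 1), mm = 2)
discriminative_score(c(0.9, 0.1, 0, 0, 0), c(0, 0, 0.1, 0.2, 0.7), mm = 2)
```

The score is the average, over cumulative depths $k \le mm$, of how
much more of the target set than of the exclusion set lies within $k-1$
mismatches of the candidate. It is mathematically confined to
$[-1, 1]$; negative values (exclusion matches better than target) are
reported unclamped by the raw scan and removed by the default filter,
so filtered output lies in $[0.5, 1]$. The filter boundary is
inclusive (score ≥ `min_score` is kept) — the plain reading of a
"minimum score" — and the defaults (`mm = 2`, `min_score = 0.5`,
no gaps, no ambiguous bases in a candidate) are the tool's published
operating point. Windows with no covered target or no covered exclusion
records are skipped rather than scored: a profile over zero sequences
is undefined. Overlapping surviving windows are grouped into connected
components (half-open intervals; abutting windows do not overlap) so a
long conserved region reads as one locus.

## Primer evaluation

* **GC content** weights each IUPAC position by the G/C share of its
  ambiguity set (S = 1, Y = ½), which equals the mean GC over all
  degenerate expansions.
* **Melting temperature** offers the Wallace rule for quick screens and
  a nearest-neighbor model (unified Allawi–SantaLucia stack parameters,
  entropy salt correction $0.368\,(N-1)\ln[\mathrm{Na}^+]$, defaults
  50 mM Na⁺ and 25 nM per strand — recorded in the function signature).
  Degenerate primers are averaged over expansions up to degeneracy 64,
  beyond which the expectation of ΔH and ΔS over the per-position base
  distributions is used. The thermodynamic duplex calculators used
  interactively in primer design are external web tools; the in-package
  model keeps evaluation scriptable and reproducible.
* **3′-end discrimination**: the criterion "at least one mismatch at
  the 3′ end against the host" is encoded as the terminal base
  mismatching a configurable fraction (default 100%) of exclusion
  variants, IUPAC-aware and right-aligned; the mismatch fractions of
  the last 3 positions are reported alongside for manual judgment,
  since how many bases constitute "the 3′ end" is a judgment call.
  Variants whose length differs from the primer by more than 2 cannot
  be compared positionally and are refused with a flag.
* **Degenerate consensus**: starting from the candidate, positions are
  generalized greedily — always the substitution that buys the most
  exact-match target coverage per unit of added degeneracy, ties to the
  leftmost position then alphabetically — until the coverage goal or
  the degeneracy cap (64). Positions where all targets agree are never
  touched, and coverage never decreases.
* **In-silico coverage** re-implements probe-style matching: Hamming
  sliding comparison (no indels) of the primer and its reverse
  complement over each reference, a position matching when the
  reference base lies in the primer's IUPAC set; `cov[k]` is the
  fraction of references with a best hit at ≤ k mismatches, cumulative
  by construction. The exact matching rules of public database probe
  servers are not published, so absolute coverage values from those
  services are not reproduced here — the matcher is this package's
  documented definition.
* **Pair screening** reports ΔTm, the predicted amplicon length from
  the two binding-site coordinates on the ungapped consensus, and a
  heterodimer heuristic: the longest perfect reverse-complementary run
  between the two primers, with the 3′-anchored variant (a primer's 3′
  suffix complementary to its partner) thresholded separately
  (default < 5 bp) because 3′ duplexes are the extension-competent,
  most inhibitory ones. This is a sequence heuristic, not a free-energy
  model; borderline pairs should still be checked thermodynamically.

## The simulator

`generate_planted_alignment()` is the package's ground-truth harness.
Background columns are drawn from one consensus with identical 2%
noise in both sets, so background windows are non-discriminative by
construction; planted windows receive *exactly* the prescribed
mismatch-count composition (largest-remainder apportionment; each
mutated row is verified to sit at its prescribed edit distance and
redrawn if substitutions accidentally collapse), so the expected
profiles — and therefore the expected score — are analytic, not
estimated. Internal gaps (default 1% per position) fall outside planted
windows, and 10% of records are truncated at the ends to exercise
terminal-gap masking without touching a planted site. Defaults mirror a
realistic use case: 118 target versus 46 exclusion records of an
rDNA-scale locus.

What the simulator does *not* emulate: phylogenetic correlation between
sequences (every record is an independent draw from the consensus),
compositional bias, alignment errors, and chimeric records. Passing
tests on these fixtures therefore demonstrate algorithmic correctness —
profile arithmetic, masking, trimming, scoring, recovery of known
sites — not performance on real, phylogenetically structured databases,
where conserved-region structure is the empirical question the scan
answers.

## Numerical and design choices

* Score fractions are exact ratios of integer counts; the only
  tolerance in the package is the 1e-9 normalization check on profiles.
* Determinism is a contract: identical input and configuration give a
  byte-identical report (fixed tie-breaks, fixed number formatting with
  4-decimal scores and 1-decimal percentages, binary-mode writes for
  stable line endings).
* Edit distances come from base R's C implementation of generalized
  Levenshtein distance; the test suite holds it against an independent
  dynamic-programming oracle on 10,000 random string pairs.
* Window coverage requires a record's terminal span to cover the whole
  window; partially covering records are excluded from that window's
  denominator rather than padded.
* Candidate gap/ambiguity caps default to 0: a primer is synthesized as
  a plain oligo, so by default no gap or ambiguous character may enter
  the candidate; both caps are configurable for exploratory scans.
* The problem sizes used in the test suite and acceptance script
  (alignments of 100–164 records × 140–600 columns, 10,000-pair
  property sweeps) were chosen to exercise every code path at
  realistic marker-gene scale while keeping a full run in tens of
  seconds.

## Known limitations

* One window length per scan; length optimization (trimming/extending
  a candidate by a few bases to balance Tm) is manual, via
  `melting_temperature()` on edited sequences.
* The heterodimer screen is sequence-based; it flags long perfect
  complements but does not rank marginal cases energetically.
* Coverage evaluation assumes ungapped references; genomes with
  introns inside the binding site would need splice-aware matching.
* The 20% column-trim rule and the 0.5 score floor are sensible
  defaults, not universal constants; loci with extreme indel content
  may warrant a higher trim threshold (at the cost of sparser
  coordinate maps).
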