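---
title: "Compartment contrasts on read-tracked assemblies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment contrasts on read-tracked assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartscan)
```

## The problem

The triatomine bug *Rhodnius prolixus* digests blood in a gut that is split
into three compartments — anterior midgut (AM), posterior midgut (PM) and
rectum (RE) — each with its own physiology. When cDNA libraries from each
compartment and from a pooled whole-body (WB) reference are sequenced and
co-assembled with an assembler that tracks which library each read came from,
every contig carries a per-library read count. Those counts are the raw
material for everything this package does: compartment-enrichment tests,
functional classification of the enriched transcripts, coding-sequence
deduction, motif scanning of the deduced proteins, and confirmation of those
proteins against gel-fractionated MS peptide identifications.

The package is organised as a pipeline of small, separately testable steps;
the `analysis/` scripts in the repository string them together on synthetic
data generated to have the same statistical structure as a real ledger.

## The read ledger

A `catalog` couples per-library sequencing totals `T_L` with the per-contig
counts. Totals are declared independently of the count table: reads that did
not make it into the retained assembly (short contigs, singletons — 16% of
reads in the reference dataset) still contribute to a library's depth, and the
χ² expected values must be computed against that depth. A convenience flag
(`infer_totals`) sums the columns instead, for ledgers known to be complete.

Length thresholds are strict everywhere ("above 250 nt" keeps 251 and up),
matching how assembly summaries of this kind are phrased; `filter_by_length`
and `assembly_summary` both use `>`.

## The contrast model

For contig *i* and a contrast of library set *A* against disjoint set *B*,
counts and totals are pooled by summation (`a = Σ_L a_iL`, `T_A = Σ_L T_L`)
and laid out as the 2×2 table

|             | set A     | set B     |
|-------------|-----------|-----------|
| this contig | a         | b         |
| all others  | T_A − a   | T_B − b   |

The test statistic is the Pearson χ² with one degree of freedom, in
cross-product form `N(ad − bc)² / (r₁ r₂ c₁ c₂)`, computed in doubles (the
cross product overflows 32-bit integers at realistic depths). No continuity
correction is applied by default: the test is only run when the smallest of
the four expected cell values strictly exceeds `min_expected = 5`, which is
precisely the regime where the Yates correction is unnecessary; a `correct`
flag enables it for sensitivity analyses. Below the gate the statistic and
p-value are undefined (`NA`) and the contig can never be called significant —
the gate is a hard admissibility condition, not a soft penalty.

Effect size is the **normalized fold ratio**

```
fold = (a · T_B / T_A) / (b + 1)
```

— the numerator count rescaled to the denominator's depth, over the
denominator count with a single pseudocount so contigs absent from *B* get a
finite ratio. The pseudocount sits only on the denominator and the depth
adjustment only on the numerator; `fold` is zero exactly when `a` is. Three
thresholds are carried: `alpha = 0.05` for significance, `interest_fold = 2`
for calls worth inspecting, and `table_fold = 10` for the stringent summary
tables. No multiple-testing correction is applied by default — the per-contig
raw p-value convention of EST-era count comparisons — but a Benjamini–Hochberg
flag is available.

Fold ratios are printed to one decimal in output tables; in memory they keep
full precision.

### What the fold statistic can and cannot reach

Because of the `b + 1` pseudocount, a contig whose true enrichment is exactly
*f* has `E[fold] ≈ f·λ/(λ+1) < f`, where λ is its expected denominator count.
Even for strongly expressed contigs, `P(fold ≥ f)` is bounded near 0.45 when
the realized enrichment is exactly *f* (it is the probability that a Poisson
contrast exceeds its mean). Consequently a 10-fold spike is recovered at the
10-fold *table* threshold only about 40–50% of the time, while recovery at
the 2-fold *interest* threshold is essentially complete (the package's
recovery experiment measures ≈0.43 and 1.00 respectively over ten seeds).
This is a property of the statistic, not a bug: the stringent table threshold
deliberately under-selects contigs sitting exactly at the boundary, and
callers who need calibrated recovery at a fold boundary should test one
threshold below it.

### Worked numbers

Two printed facts from the reference dataset serve as fixed arithmetic
checks: the per-compartment read sums of two proteases (RP-2217: 1,113 +
609 + 1,135 = 2,857 gut reads; RP-2259: 1 + 504 + 2,346 = 2,851) and the
lysozyme RP-3602 fold ratio. With the raw printed run totals the formula
gives `normalized_fold(7966, 473331, 619, 862980) = 23.4`, against a
published value of 23.1; the 1.4% discrepancy is consistent with the
published figure having used per-library totals restricted to the assembled
subset, which were never printed. Both totals conventions are supported
(declared totals vs `infer_totals`); the package does not guess which was
used and reports the raw-totals value.

## Functional classification

Hit descriptions from several databases (KOG, CDD, SwissProt, GO, NR) are
lowercased, tokenized on non-alphanumeric characters, and scanned against a
vocabulary of words and phrases mapped to functional categories. A word found
in a description contributes

```
weight × 1/(1 + first token index) × 1/(1 + database rank)
```

to its category, and the highest-scoring category wins. The two factors are
harmonic decays: an implementation choice (the design space is any
monotonically decreasing weighting; harmonic is smooth, parameter-free and
keeps early tokens dominant without zeroing late ones). The database
precedence — KOG, CDD, SwissProt, GO, NR — orders curated before bulk
sources and is configurable, as is the vocabulary itself. Ties break toward
the category whose best-contributing hit has the lower e-value, then
lexicographically, so classification is deterministic and hit-order
invariant.

Two categories are structural, not vocabulary-driven: a contig with no hits
at all is **Unknown**; one with hits but no vocabulary match is **Unknown,
conserved** (matched something in a database, but nothing with an assignable
function).

The vocabulary shipped in `inst/extdata/default_vocab.tsv` is a
**reconstruction**: the curated ~280-word vocabulary behind the reference
dataset was never published, so the default was rebuilt from the 31 class
labels of the published summary tables (29 assignable categories plus the
two Unknowns) with common synonyms. It makes the pipeline runnable and the
synthetic tests meaningful; it does not reproduce the original curation, and
per-category membership of real tables should not be expected to match.

Organism-origin assignment of deduced proteins follows a two-gate rule on
per-database best blastp scores: the top origin is assigned only when its
bitscore beats the runner-up by a ratio strictly above 1.25 **and** its own
e-value is below 1e-15; anything else is `ambiguous` and stays under the
host/invertebrate default in summaries. The e-value gate is applied to the
top-scoring origin's own e-value, which generalizes the published phrasing
(pathogen-or-vertebrate) to any non-host origin.

Class summary tables report, per category, member contigs, their numerator
reads, reads per contig and percent of the scope's reads, both derived
columns to one decimal. Rounding is **half away from zero** — the convention
of the published tables (139.25 prints as 139.3) — via `round_half_up()`,
not base R's round-half-even. All 97 class rows of the four published tables
reproduce exactly under this convention.

## CDS extraction

Two routes, tried in order:

1. **similarity** — when a hit carries query coordinates, the best hit
   (highest bitscore, then lowest e-value) anchors the call: its aligned
   region is extended in-frame to the ATG at or nearest upstream of the
   region and forward to the next stop. How a homology window should be
   extended is genuinely underdetermined; nearest-Met-upstream plus
   next-stop is this package's choice, and records missing either end are
   flagged incomplete rather than dropped.
2. **orf_signal** — otherwise the longest ORF (maximal ATG→stop per
   stop-free stretch, all six frames) is emitted only if its protein carries
   a positive signal-peptide call: an unknown ORF is only trusted when it
   looks secreted. Ties for longest break toward the most 5′ start on the
   plus strand.

Coordinates are 0-based half-open on the plus strand with a strand flag,
everywhere. Codons containing N translate as X and never act as start or
stop. The default `min_aa = 50` is a conventional floor for deduced proteins
in EST pipelines (below it, spurious ORFs from random sequence dominate:
random codons are stop-free for a geometric ~20-codon stretch). Signal
peptide calls are consumed from an external table — prediction itself is
upstream software — and the built-in `signal_stub()` (an N-terminal
hydrophobic-run regex) exists only so the synthetic tests are self-contained;
it is labeled non-predictive and must not be used for annotation. The >90%
best-hit coverage filter is strict: exactly 0.90 fails.

## Motif scanning

Peritrophins are defined by a six-cysteine chitin-binding domain with the
spacing consensus `C X15–17 C X5–6 C X9 C X12 C X6–7 C`. The scanner
enumerates the twelve admissible spacing combinations as zero-width-lookahead
regular expressions, so **every** match at every start and every gap
combination is reported, overlaps included — multi-domain peritrophins yield
one row per domain instance. X is any residue including cysteine (a
`strict_gaps` mode excludes C from gaps); the two fixed spacings (9 and 12)
are implemented as printed, with no tolerance. The test suite holds the
scanner against an independent nested-enumeration oracle over hundreds of
seeded random sequences.

Mucin-type (vertebrate-like) mucins are Ser/Thr-rich, heavily O-glycosylated
secreted proteins. Glycosylation-site prediction is out of scope, so the
implementable proxy is Ser+Thr density: whole-protein S/T fraction, the
maximum S/T count in a 100-residue window (a glycosylation-cluster size
proxy), and a mucin-like flag at `st_threshold = 0.30`. The threshold is a
package default chosen to sit well above the background S+T frequency
(~12%) and near the density of annotated mucin domains; it is not a
literature constant.

## Proteomic confirmation

Peptides identified by MS in gel fractions are matched as exact substrings
against the deduced proteome (every occurrence reported). An optional
I/L-equivalence mode exists because the two residues are isobaric, but it is
off by default — the reference workflow's pattern search was sequence-exact.
A protein is **confirmed** by at least two distinct peptide sequences
("ions"); a peptide seen in several bands counts once toward the ion count
and once per observation toward the fragment total, and both numbers are
reported. Coverage is the union length of matched intervals — residues
counted once, however many peptides overlap them. The best gel fraction is
the one whose own matches cover the most residues, ties to the
lexicographically smallest label, and is assigned only for confirmed
proteins.

## The synthetic-data generators

The generators exist so every step above can be exercised and tested with no
external data, at the statistical structure the methods assume:

* `simulate_catalog()` draws baseline contig abundances from a symmetric
  Dirichlet (concentration 0.5, giving the long right tail of EST abundance
  profiles) and per-library counts from a multinomial at the declared total,
  so column sums conserve totals exactly, as a read-tracked assembly does.
  Spiked contigs have their probability multiplied by the fold in the
  designated libraries. Renormalization defaults to `"preserve"`: spiked
  contigs keep exactly fold× their baseline probability and the unspiked
  majority absorbs the compensation, so the recorded truth equals the
  realized enrichment. The alternative `"flat"` divides everything by the
  common normalizer, which silently compresses a nominal 10-fold spike to
  ~6.9× when 5% of contigs are spiked. Either way, spiking is compositional:
  enriching 5% of the transcriptome 10-fold genuinely depletes the remaining
  95% in those libraries, and the χ² contrast correctly flags that
  depletion — visible in the end-to-end scripts as a large number of
  significant *down* contigs.
* `simulate_proteome()` plants valid CBD spacing instances and signal flags
  in background-composition proteins, then reverse-translates each into a
  contig (random synonymous codons, an upstream in-frame stop, random flanks,
  random strand) so ORF finding can recover the planted frame exactly.
* `simulate_hits()` writes one description per contig containing a
  true-category vocabulary word at an early token position, with optional
  later-position decoys from other categories — classification must then be
  exact at zero noise, and position weighting is what keeps it ≥90% accurate
  at 20% decoy rate.
* `simulate_peptides()` samples non-overlapping 7–15-mers preferring K/R
  C-termini (tryptic-like) and assigns gel fractions.

All generators are seed-deterministic (same seed, identical output). What
they deliberately do **not** model: cDNA normalization (the reference
libraries were normalized before sequencing, compressing true ratios — a
kit-chemistry effect with no defensible generative model, and the reason the
published fold ratios are described as understated), 454 homopolymer errors,
and assembly artifacts. Passing tests therefore demonstrate correctness of
the ledger arithmetic and the statistical machinery under clean multinomial
sampling, not robustness to those upstream distortions.

## Problem sizes and test design

The statistical checks run at deliberately modest scale, chosen so the whole
suite completes in seconds while keeping Monte-Carlo error small relative to
the tested margins: null calibration and spike recovery use 2,000 contigs
over two libraries of 100,000 reads (the null test expects the flagged
fraction among testable contigs in [0.03, 0.07] at α = 0.05); recovery
averages ten seeded replicates (~750 well-expressed spiked contigs); the
motif scanner is checked against its brute-force oracle on 500 random
sequences of up to 200 residues with cysteine-enriched composition so that
matches actually occur. The end-to-end `analysis/` scripts use the reference
sequencing depths (up to 862,980 reads per library) to show the pipeline at
realistic scale.

## Known limitations

* The default vocabulary is a reconstruction (above); real-data category
  membership will differ from any curated original.
* `find_orfs` reports maximal ORFs (most upstream ATG per stop-free
  stretch); internal-Met truncations of the same stop are not enumerated.
* The similarity route requires hit query coordinates; hit tables without
  them fall back to the ORF+signal route.
* Fold ratios on normalized cDNA libraries understate true expression
  differences; no correction is attempted.
* The origin rule compares bitscores across databases of very different
  sizes; it reproduces the published decision procedure rather than a
  calibrated classifier.
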