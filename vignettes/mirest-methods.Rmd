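---
title: "mirEST: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirEST: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirEST)
```

`mirEST` re-implements, as a tested pipeline, the classical homology-based
strategy for cataloguing miRNAs, their precursors, their targets and
polymorphisms at miRNA functional sites in an EST collection. This
vignette documents the models behind each stage, the tunable parameters
with their defaults and rationale, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real data.

## Homology scan

Plant mature miRNAs are short (~18-24 nt) and conserved nearly base-for-base
across species, so homology search needs to tolerate only a few
substitutions. Instead of a heuristic local aligner, `scan_homology()`
performs an exhaustive, deterministic comparison of every full-length
ungapped window of every EST, on both strands, against every non-redundant
mature sequence. The default cap of `max_mm = 3` encodes "fewer than 4
mismatches"; `N` in an EST always counts as a mismatch, and U/T are
equivalent. Gapped (indelled) alignments are deliberately not considered:
they are rare in genuine mature-miRNA homology at this length scale, and
excluding them keeps the mapping from window positions to miRNA
coordinates exact, which everything downstream (site profiling, variant
coordinates) relies on. This is a documented deviation from BLAST-style
search; there are no e-values, and a hit is always exactly mature-length.

Internally all coordinates are 0-based half-open on the EST forward
strand; antisense hits (the EST carries a target-type site) report
mismatch positions in mature coordinates, counted from the 5' end.
The scanner is validated in the test suite against an independently coded
naive quadratic oracle on random cases.

## Species representation statistic

Matched mature sequences are re-expanded over the redundant reference set
(identical sequences removed during deduplication are re-included) and
classified by the species prefix of their IDs. For a species with `m` of
`M` reference records and `k` of `K` matched records, with `q = m/M`, the
default statistic is the exact binomial point probability

$$P(X = k) = \binom{K}{k} q^k (1-q)^{K-k},$$

evaluated in log space (`lchoose` + `log1p`), with direction assigned by
comparing `k/K` to `q`. Two modes exist because a point mass is not a
calibrated tail probability: `mode = "tail"` returns the one-sided tail
(`P(X >= k)` or `P(X <= k)`) and is what the null-calibration simulation
exercises. The point mass is the default because it is the form under
which the published species-representation tables this statistic is
modelled on are exactly reproducible, including the closed-form zero-match
rows `(1 - 1/M)^K`; the calibration caveat is documented rather than
silently "fixed". No multiple-testing correction is applied — the
stage reports raw thresholds (0.05, 0.01, 0.005, 0.001), and the
threshold sweep is monotone by construction. Percentages are rounded
half-away-from-zero to one decimal, matching how such tables are printed.

## Cluster assembly

EST clusters are near-identical copies of one transcript, so a star
alignment is sufficient and easy to verify: the longest member is the
backbone and every other member is aligned to it end-gap-free
(match +1, mismatch −1, gap −2 per gapped base, end gaps free, via
Biostrings). Members whose alignment identity over their full length falls
below 60% are excluded with a warning — a guard against chimeric clusters.
Identity is computed over the member length rather than the aligned span
only, because end-gap-free alignment would otherwise let a chimera match a
short segment at high local identity.

Columns are indexed by backbone position plus an insertion ordinal.
The consensus takes the most frequent base per column; ties pick the
alphabetically smallest base and flag the column low-confidence
(determinism over aesthetics); gap-majority columns are dropped from the
consensus string but retained for indel calling. With zero noise the
consensus of a simulated cluster equals its template exactly, and this is
asserted in the tests.

## Folding engine

The minimum-free-energy folding engine is bundled rather than delegated to
an external program, so results are reproducible from the package sources
alone. The model is a simplified nearest-neighbour scheme: stacking
energies for the 36 ordered pairs of adjacent base pairs (all negative;
GU wobble allowed; lonely pairs allowed), tabulated hairpin-loop
penalties (minimum loop 3), logarithmic bulge and internal-loop penalties
(capped at 30 unpaired nt in the dynamic programme), and a linear
multiloop model `a + b·branches + c·unpaired` with `a = 3.4`, `b = 0.4`,
`c = 0.1` kcal/mol. All parameters live in `energy_model()` and are
user-replaceable; every downstream index (AMFE, MFEI, ΔΔG) is
engine-agnostic.

Three independent code paths keep the engine honest:

* `fold_rna()` — the Zuker-style dynamic programme (C++), deterministic
  traceback (interior extensions before hairpins before multiloop splits,
  smallest indices first on ties);
* `structure_energy()` — a pure-R re-scorer that decomposes an explicit
  dot-bracket structure into loops and sums their energies;
* `brute_force_mfe()` — exhaustive enumeration of every nested structure
  (C++ as well, but sharing only the parameter tables, not the
  recursions), itself cross-checked against a pure-R enumeration at tiny
  sizes.

The acceptance suite verifies `fold_rna` against `brute_force_mfe` on 200
random sequences of 10-30 nt (up to ~1.5 million structures each) and
`structure_energy(fold_rna(s)$structure) == fold_rna(s)$dG` throughout.

Because the parameter set is deliberately small, absolute ΔG values are
*not* comparable to full Turner-parameter programs; published per-hairpin
ΔG/MFEI values are therefore used only as internal-consistency checks of
the MFEI formula (MFEI = AMFE/GC% with AMFE = |ΔG|·100/L, positive
convention), never as numeric reproduction targets.

## Precursor extraction and screening

A genuine pre-miRNA carries the mature on one hairpin arm and a paired
passenger (miRNA*) on the opposite arm. `extract_candidate()` folds up to
`fold_window = 250` nt of context on each side of a sense hit, finds the
partners of the mature positions, trims the precursor to the duplex ends
extended by `flank = 13` nt pri-extensions (clamped at sequence
boundaries), and re-folds the trimmed region to populate the candidate
record (ΔG, GC%, MFEI, NM, ML, PL, arm).

Two open design points were resolved as follows. First, the 13-nt
extensions are measured from the outer ends of the mature/star duplex —
the hairpin's two ends — matching the "pri-extension region of the
hairpin" concept. Second, the star span is defined by the *dominant side*:
partners of mature positions are partitioned into those 5' and 3' of the
mature, the side with more partners is the star arm, and mature positions
pairing to the other side (or within the mature itself) count as unpaired.
The naive alternative — the hull of all partners — lets a single stray
long-range pair abort extraction of an otherwise perfect hairpin; with the
dominant-side rule, seeded recovery of designed duplex mismatch counts
rises from 97/100 to 100/100.

Screening (`validate_candidate()`): MFEI strictly greater than 0.85
(a candidate at exactly 0.85 is rejected), at most `max_star_mm = 4`
unpaired mature positions in the duplex, and "few and small asymmetric
bulges" quantified as at most 2 bulges of at most 3 nt each. The bulge
quantification is this package's choice (the classical screen gives no
numbers); both limits are exposed in the configuration. NM counts every
unpaired mature position — internal loops and bulged mature bases alike —
a structure-level reading of "mismatches between the mature and the
passenger".

## Target profiling and variant analysis

Target candidacy requires an antisense hit on a protein-coding cluster
(classification is a configurable keyword rule over the annotation text;
"transcribed"-only annotations mark precursor candidates instead). Sites
are profiled per miRNA position — position `i` sits at consensus
coordinate `end − i` — and mismatches at positions 2-12 raise the critical
flag, at 10/11 the cleavage-site flag, reflecting the canonical
plant-miRNA cleavage geometry. Overlapping sites of different families are
reported as combined multi-miRNA controls ("1128+1133"-style labels).
Ontology-based functional slimming is out of scope; `category_tally()`
accepts any term-to-category map so category summaries remain producible.

Variant calls come from alignment columns with two or more observed
alleles inside miRNA-relevant regions. The reference allele is the
majority symbol (bases beat gap on ties, then alphabetical order). The
support classification encodes the EST-mining heuristic that a
polymorphism carried by two or more independent copies is a good
candidate for a true positive: the strongest alternative allele needs
`min_support = 2` copies for `candidate_true`, singletons are reported but
flagged `low_support`. "Independent" is operationalised as distinct
cluster members. Insertion columns anchor to the preceding consensus
coordinate with an insertion ordinal, so reports are stable without a
reference genome. For variants inside a precursor, both alleles are
folded and ΔΔG = ΔG(alt) − ΔG(ref) is reported (positive =
destabilising); the sign convention makes label swaps exactly antisymmetric,
which the tests assert to floating-point exactness.

## Synthetic data generator

The generator emulates the statistical structure of the real inputs — a
multi-species mature set, EST clusters replicating one template transcript,
planted antisense target sites, planted hairpins, planted variants — with
a manifest recording every planted feature and its expected verdict.
Defaults: 6 species contributing 40/30/20/15/10/5 matures of 20-22 nt
(with 3 cross-species duplicate pairs to exercise the redundant-set
bookkeeping), 300-nt templates at 45% GC (cereal-EST-like), clusters of
4-8 members, and a 0.1% per-base substitution error rate typical of
single-pass cDNA reads. Background sequence is i.i.d.; there is no codon
structure, no chimeras, no vector contamination, and no
chromatogram-style indel hotspots — so passing tests demonstrate
correctness of the algorithms under controlled conditions, not robustness
to every artefact of real EST data.

Hairpin construction builds the star as the reverse complement of the
mature with the requested number of planted non-complementary positions,
joins the arms with a low-complementarity loop, and folds the construct;
if the realized duplex deviates from the design it resamples flanks and
loop up to 50 times and then records the *realized* mismatch count — the
folding engine, not the generator, is the arbiter, which keeps recovery
tests honest. Clusters carrying a planted variant draw at least
`2·support + 1` members so the planted allele stays in the minority and
reference/alternative labels are unambiguous.

## Problem sizes and determinism

The shipped test-and-acceptance workload uses desk-scale sizes chosen to
exercise every code path: 200 random sequences for the folding oracle
(10-30 nt; enumeration reaches ~1.5 million structures), 100 cases for
the scanner oracle, 1000 replicates for the null calibration of the tail
statistic, one full pipeline run on a ~18-cluster/~110-EST dataset, and
100 seeded hairpins for duplex-mismatch recovery. Every stochastic step is
seed-driven; re-running any stage with identical inputs and seed produces
byte-identical output tables (numeric formatting is fixed at the stated
precisions).

## Known limitations

* The energy model is intentionally small: suboptimal ensembles,
  partition functions, temperature dependence, coaxial stacking and
  pseudoknots are out of scope, and absolute ΔG values are engine-specific.
* The scanner's full-length ungapped definition will miss genuinely
  indelled homologues; at mature-miRNA length scales this is rare but not
  impossible.
* The point-mass representation statistic reproduces the classical table
  form but is not a calibrated p-value; use `mode = "tail"` for
  calibrated decisions.
* Star assembly assumes cluster members are near-identical copies; deeply
  diverged paralogues within one cluster would be excluded (or distort
  the consensus) rather than haplotype-resolved.
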