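---
title: "Methods: mitogenome characterization with mitocomp"
author: "mitocomp"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome characterization with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# Scope

`mitocomp` characterizes small circular mitochondrial genomes of the
canonical animal type: 37 genes (13 protein-coding genes, 22 tRNAs, two
rRNAs) plus one A+T-rich control region on a ~15–16 kb circle. The package
covers the statistics that mitogenome descriptions report — base
composition and AT/GC skew per feature class, gene overlaps and intergenic
spacers, codon usage and RSCU under the invertebrate mitochondrial code,
tRNA cloverleaf structures, control-region motifs and tandem repeats — and
a distance-based phylogeny stage over concatenated gene alignments. A
synthetic genome generator produces data with all of these structures
planted, so every analysis stage can be verified end to end without
database access.

# Coordinates and the circular layout

All coordinates are 1-based and fully inclusive: a feature `start..end`
has length `end − start + 1`. Features spanning the circular origin are
rejected rather than wrapped; the canonical gene order places the control
region flush against the origin, so wrapping is never required for the
layouts this package targets, and rejecting keeps every downstream
computation an honest linear-substring operation.

For consecutive features the signed neighbor gap is
`start(next) − end(prev) − 1`; negative values are overlaps, positive
values spacers, and the circular wrap pair (last feature back to the
first) uses `start(first) + L − end(last) − 1`. Feature lengths and all
signed gaps, including the wrap, tile the circle exactly:
`Σ lengths + Σ gaps = L`. This closure identity is asserted on every
annotation the generator produces and on the shipped reference layout
(15,214 + 162 = 15,376).

Published annotation tables carry a *declared* intergenic column that may
disagree with the printed coordinates — the shipped reference table
disagrees at two adjacencies, which changes the aggregate counts (10
overlaps/196 spacer bp/17 regions computed vs 11/192/16 declared).
Neither view is privileged: `layout_summary()` supports both modes as
first-class inputs and every report is labeled with the mode that
produced it.

# Composition and skew

`AT skew = (A − T)/(A + T)` and `GC skew = (G − C)/(G + C)`. `N` bases are
excluded from counts and denominators. Class summaries concatenate member
features *as printed on the forward strand* (no reverse-complementing):
published composition tables count this way, and the option
`gene_sense = TRUE` provides the alternative. Overlapping features
contribute their shared bases to each containing feature, by design, and
this is logged.

Values are carried at full precision; rounding is applied only for
display, half away from zero (base R's `round()` is half-to-even), with 2
decimals for percentages and 3 for skews — the convention needed to
reproduce printed tables from printed inputs. When a sequence has no G+C
(or no A+T), the corresponding skew is undefined and reported as `NA`
inside a composition object; the standalone `at_skew()`/`gc_skew()`
functions treat a zero denominator as a hard error so silent zeros can
never propagate.

# Codon usage

The invertebrate mitochondrial genetic code (NCBI table 5: `ATA`=Met,
`TGA`=Trp, `AGA`/`AGG`=Ser, stops `TAA`/`TAG`) defines translation and
synonymous families. Coding sequences are split into non-overlapping
triplets; a trailing 1–2 nt remainder is the incomplete stop, completed
in vivo by polyadenylation. Start codons matching `ATN` are canonical;
anything else (the `CGA` start typical of lepidopteran *cox1*) is flagged
but accepted. Where a declared stop codon contradicts the length
arithmetic of its own coordinates, the sequence is trusted: the stop is
whatever the length implies.

Counting by default includes only sense codons — the trailing fragment is
never counted and a final complete stop triplet is excluded unless
`include_stops = TRUE`. Published codon totals for mitogenomes are often
irreconcilable with the printed gene lengths, so both modes exist and
every report states its mode. `RSCU(c)` is the observed count divided by
the family mean (the uniform-usage expectation); an unused family scores
0 for all members and is flagged. `CDspT` normalizes counts to 1000
codons. Amino-acid rankings break ties alphabetically on the three-letter
name so results are deterministic.

# tRNA cloverleaf folding

The cloverleaf topology is fixed, so folding is posed as an exhaustive
search over arm boundaries rather than free-energy minimization:
sequences are 55–80 nt and the admissible layouts number in the
thousands, so exhaustive search is tractable, exactly reproducible, and
free of thermodynamic parameter choices. Each admissible partition into

```
[acceptor 5'][link1][D 5'][D loop][D 3'][link2]
[AC 5'][anticodon loop (7)][AC 3'][variable loop][T 5'][T loop][T 3'][acceptor 3']
```

is scored +2 per Watson–Crick pair, +1 per G-U wobble, −1 per mismatch.
Default ranges reflect canonical tRNA architecture: acceptor stem 6–7 bp,
D stem 3–4 bp (loop 4–11 nt), anticodon stem 4–5 bp with a loop of
exactly 7 nt (anticodon at loop positions 3–5), T stem 4–5 bp (loop 3–9
nt), variable loop 3–23 nt, linkers 0–3 and 0–2 nt. All ranges are
configurable via `cloverleaf_constraints()`; `allow_missing_d_arm = TRUE`
admits D-stem-less structures seen in some mitochondrial trnS1 genes and
is off by default. Ties are broken by more WC pairs, then by the first
layout in a fixed lexicographic enumeration of the element sizes, making
folding a pure function of the sequence. A score floor (default 10)
separates genuine cloverleafs from unfoldable input such as
homopolymers.

# Control region

The scanner implements the conserved grammar of the lepidopteran A+T-rich
region: `ATAGA` followed (within a configurable 0–5 nt gap) by a poly-T
tract of at least 10 nt, `ATTTA` followed by an `(AT)n` microsatellite of
at least 4 copies, and a terminal poly-A of at least 6 nt. Tract lengths
are reported exclusive of the motif; the gap tolerance is configurable
because published figures rarely pin the exact spacing. Coordinates are
local to the region, with the genome offset carried as metadata.

Tandem repeats are found by an identity-threshold detector: for every
period, every left-maximal run of at least two full copies of the leading
unit (per-copy identity ≥ 0.9 by default against the first copy, not a
consensus) is a candidate; overlapping candidates are collapsed to the
highest-scoring (score = aligned matching positions), ties going to the
leftmost start and then the smallest period. Partial trailing copies are
not reported. This deliberately reproduces the *presence and extent* of
repeats rather than any particular alignment-scoring model; in exact-match
mode the call set provably equals brute-force enumeration, which the test
suite checks against an independent oracle on short strings.

# Phylogeny stage

The pipeline takes pre-aligned per-gene FASTA files (alignment itself is
out of scope), concatenates them into a partitioned supermatrix, masks
poorly conserved blocks, computes pairwise distances, and builds a
neighbor-joining tree with column-resampling bootstrap.

Full maximum-likelihood inference under empirical amino-acid models is
deliberately replaced by this distance pipeline: the published role of the
tree — recovering superfamily groupings — is served at desk scale by a
fully specified, deterministic method, which is also honest about what the
package verifies (topology-level claims only; no likelihoods). Block
masking uses a three-parameter rule in the spirit of conserved-block
filters: keep maximal runs of ≥ 5 contiguous columns whose gap fraction is
≤ 0 and whose majority-character frequency is ≥ 0.5. These defaults are
strictly simpler than any particular external tool's and fully printed
here.

Distances implement the standard closed forms (`p`, JC69, K2P) with
pairwise deletion — chosen over complete deletion so small synthetic
matrices stay informative — and treat saturation (a non-positive log
argument) as an error naming the pair, never as infinity. NJ delegates to
the Saitou–Nei implementation in **ape** with taxa pre-sorted
alphabetically, so results are invariant to input order; negative branch
lengths are clamped to zero with a warning. Bootstrap resamples columns
with replacement under a single integer seed, skips saturated replicates
(adjusting the denominator), and reports per-edge support as the
percentage of replicates containing the bipartition. An all-zero distance
matrix yields an explicit star tree rather than an arbitrary resolved
topology.

# The synthetic generator

The generator is the package's source of ground truth. Its defaults
emulate a strongly A+T-biased lepidopteran mitogenome: the shipped
38-feature reference layout; per-class base frequencies of roughly 78%
A+T in PCGs, 82% in tRNAs, 84.5% in rRNAs, 96.5% in the control region
and the whole-genome average in spacers; a codon profile proportional to
the product of PCG base frequencies over non-stop codons; and a
control-region grammar of `ATAGA` + 19 nt poly-T, `ATTTA` + (AT)×6, a
25 bp unit duplicated in tandem, and a terminal 8 nt poly-A.

Generation is two-pass. Hard constraints — PCG start codons, stops
realized from each gene's length arithmetic, and the full control-region
string — are written first with conflict detection (two constraints
demanding different bases at one position abort generation; on the
reference layout all overlap-induced constraints are mutually
consistent). Feature bodies are then sampled i.i.d. per class (codon-wise
for PCGs), with the earlier feature in table order owning shared
positions, and spacers fill the rest. R-strand genes are generated in
gene sense and reverse-complemented into place, so strand-aware
extraction is genuinely exercised. The spec's whole-genome A+T target is
the length-weighted mixture of the class targets, using the codon
profile's letter marginal for PCG segments (stop-codon exclusion shifts
it off the nominal class frequency).

tRNA templates plant all-WC stems plus requested wobble/mismatch pairs
and sample loops from tRNA-like frequencies. Four positions adjacent to
planted stems are guarded against forming opportunistic extra pairs (a
same-base substitution, which can never pair); the assembled sequence is
then verified by `fold_cloverleaf()` and resampled from a derived seed if
the planted structure is not the recovered optimum, erroring after a
bounded number of attempts — this makes the generator's "planted fold is
optimal" contract explicit rather than probabilistic. Sequence evolution
along trees uses JC69 (equal frequencies, site-independent, no indels,
no rate heterogeneity) via **phangorn**'s simulator under derived seeds.

Everything is a pure function of (spec, seed); per-stream seeds are
derived from the master seed with a fixed linear map computed in doubles
and kept below 2^31.

## What the generator does not emulate

No Markov/neighbor dependence in composition, no indel evolution, no
rate heterogeneity, no secondary-structure-aware rRNA simulation, no
sequencing error. Passing tests therefore demonstrate algorithmic
correctness on data satisfying the package's structural assumptions, not
robustness to the full messiness of real GenBank records.

# Problem sizes and determinism

The test and verification runs use sizes chosen to make statistical
checks sharp while staying desk-scale: 15.4 kb genomes (20 seeds for
composition recovery, mean absolute error bound 0.01), 10 kb two-taxon
alignments for JC69 branch-length recovery at 3 binomial standard
errors, a 21-taxon tree (19 ingroup, 2 outgroup) with 13 × 150 nt
partitions and 100 bootstrap replicates for the clade-recovery check, and
brute-force oracle comparisons on strings up to 30 nt with periods up to
10. Every stochastic step is governed by one integer seed.

# Known limitations

Origin-spanning features and compound GenBank locations are rejected, not
modeled. The GenBank reader handles simple single-interval features only.
The folder reports a single best structure, not an ensemble, and its
score is a pairing count, not an energy. The tandem detector compares
copies to the leading unit, so a long degraded array whose consensus
drifts may be truncated. The phylogeny stage is not a substitute for
model-based inference when branch-length accuracy or support calibration
matters.
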