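---
title: "Detecting diversity-generating retroelements with dgrscope"
author: "dgrscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversity-generating retroelements with dgrscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscope)
```

## The biological problem

Diversity-generating retroelements (DGRs) are genetic cassettes that mutagenize
a defined region of a target gene at enormous rates while leaving the rest of
the genome untouched. The machinery is compact: a reverse transcriptase (RT)
copies the RNA of a non-coding **template repeat (TR)** into cDNA with
adenine-specific infidelity — every adenine of the template may be read as any
base — and the mutagenized cDNA replaces the homologous **variable repeat
(VR)** inside the target-protein (TP) gene ("retrohoming"). The footprint this
leaves in genomic sequence is distinctive: two proximal repeats that differ
almost exclusively at positions where one copy (the template) carries an
adenine.

`dgrscope` turns that footprint into a detection pipeline for genomes, contigs
and viral assemblies, characterizes the cassette's cis-acting elements, and
quantifies how many protein variants the element can theoretically generate.
A synthetic-genome generator with planted cassettes provides ground truth for
every stage, so the whole pipeline is testable without any external data.

## Detection model

### RT anchors

DGR discovery is anchored on RT-like ORFs. A six-frame ORF scan
(`find_orfs()`; start codons ATG/GTG/TTG, genetic code table 11 — common
archaeal/bacterial usage) feeds a deterministic motif filter
(`scan_rt_candidates()`): by default, proteins of at least 100 residues
containing the retroelement catalytic box `[YF]x[DA]D`. A motif scan is used
instead of database homology search so that results are reproducible offline
and independent of database versions; genuinely known RT loci can be supplied
directly as BED intervals (`--rt-bed` / the `anchors` argument), which
bypasses the motif heuristic entirely. The default 100-residue floor for RT
candidates is a configurable scanning choice, not an empirical constant.

### Repeat pairs

Within ±5 kb of each anchor, `find_repeat_pairs()` performs a seed-and-extend
search for direct and inverted repeats: exact 12-mer seed matches are extended
ungapped along their diagonal under X-drop scoring (match +1, mismatch −2,
drop-off 20), and the alignment is reported between its maximum-scoring
columns. Extension is ungapped deliberately: the adenine-mismatch criteria are
defined per aligned column, known TR/VR pairs are equal-length, and indels
within these repeats are rare.

The boundary rule deserves a note. An extension rule that simply continues
while the running mismatch fraction stays below 25% systematically overshoots
the true repeat: in random flanking sequence about one column in four matches
by chance, so the running fraction can stay acceptable for tens of bases past
the end of real homology. Ending the alignment at its score maximum pins the
boundary to the edge of homology; the mismatch-fraction cap (default 0.25) is
retained as a filter on the reported alignment. The scoring was calibrated on
the planted-cassette recovery task: a milder −1 mismatch penalty rescues
occasional dense mismatch clusters at repeat edges but lets boundaries drift
several bases into flanking sequence far more often, which costs more recovery
(at ±3 bp tolerance) than it gains.

### TR/VR classification

`classify_tr_vr()` applies the adenine rule to each repeat pair: a copy
qualifies as template when the alignment shows **at least 10 mismatch columns
where that copy carries an adenine** and **no more than 2 non-adenine
mismatches per 100 bp** of aligned sequence. Both copies are tested ("with
respect to one strand" is read as: with respect to either repeat copy); if
exactly one passes it is the TR and the other the VR. Both copies passing is
only arithmetically possible for long, mismatch-rich alignments (an A–A
column is not a mismatch, so the two adenine counts share the mismatch
budget); such calls are resolved toward the copy with more adenine-specific
mismatches, with ties rejected as `ambiguous-template`. The 10-mismatch floor
is absolute; the non-adenine allowance scales linearly with aligned length
(`2 × len/100`, real-valued).

### Cassette assembly

For each passing call, the TP gene is the ORF that contains VR (longest wins
when nested ORFs qualify; no codon-phase restriction is imposed on the VR
start because detected repeat boundaries carry a few bases of noise — the
reading frame is taken from the ORF itself). Calls whose TR falls inside the
chosen TP are rejected: a template inside the coding sequence contradicts the
DGR architecture and usually indicates an ordinary tandem duplication.
Cassettes sharing a VR interval are merged, VR-only elements without an RT
anchor are flagged `partial-DGR`, and completeness is defined as RT present
plus a passing TR/VR call.

## Cis-acting elements

Three accessory features are located relative to the assembled cassette:

* **IMH/IMH\*** (`find_imh()`): retrohoming initiation motifs at the 3′ ends
  of VR and TR. The default motif pair TGGGGT (IMH, in VR) / TGGAAT (IMH\*,
  in TR) is scanned within ±40 bp of each repeat's 3′ boundary; both motifs
  must occur at alignment-consistent offsets (difference ≤ 5 bp), and the
  3′-most consistent hit wins. Anchoring at the 3′ boundary makes the result
  independent of how much 5′ context is supplied. The 40-bp span and 5-bp
  slack are scanning choices; the motif content and 3′ placement are the
  biology.
* **Stem-loop** (`find_hairpins()`): all maximal exact-reverse-complement
  stem-loops (arms 4–12 bp, loops 3–8 nt) in the TP gene downstream of VR,
  with loops classified GRA (3 nt), GRNA (4 nt) or other. Stems are exact
  complements with no G·U wobble or thermodynamic scoring — the element is
  described structurally, and an exact-arm definition makes the enumeration
  checkable against a brute-force oracle. "Maximal" means the stem cannot be
  grown one step outward (same loop) or inward (loop shrinks by 2) within the
  bounds.
* **Avd-like ORFs** (`find_avd_candidates()`): the accessory variability
  determinant is a small, strongly basic protein; ORFs between RT and TP are
  kept when their isoelectric point is 9 ± 1 and molecular weight 10 ± 5 kDa.
  pI is solved by bisection on the Henderson–Hasselbalch net charge with a
  fixed pKa table (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5,
  K 10.8, R 12.5, Y 10.1) to |charge| < 1e-4; a fixed table makes the
  computation exactly reproducible and testable against an independent
  root-finder. The MW window is interpreted in kDa, consistent with the size
  of known Avd-class proteins.

## Diversification potential

`summarize_diversity()` quantifies what the element can do to its target.
Each template adenine may be read as any of the four bases, so a TR segment
with $A$ adenines defines $4^A$ nucleotide variants. Per codon of the
VR-overlapping reading frame, `codon_diversity()` enumerates all $4^k$
substitutions of its $k$ adenine positions and records the set of reachable
amino acids, whether a stop is reachable, whether the codon is AAY (AAT/AAC —
adenines at the first two positions make asparagine codons the maximally
diversifiable case, reaching 15 amino acids), and whether it is
*diversifiable* (at least one adenine and at least two reachable amino
acids — codons where adenine substitution is purely synonymous are not
counted). The protein-level variant count is the product over codons of the
reachable-set sizes, stops excluded; because per-codon choices are
independent, this equals the number of distinct stop-free translations over
all $4^A$ variants, which is exactly how the test suite verifies it
(exhaustive enumeration up to 12 adenines). Nonsense risk is reported as a
flag (any codon can reach a stop), not a count adjustment.

All counts are exact: the package carries its own decimal big-integer
arithmetic (`bigint_*`), since $4^A$ overflows doubles beyond $A = 26$ and
reports must print exact decimal strings, never scientific notation.

```{r diversity-example}
cd <- codon_diversity("AATGCAAAC")
cd[, c("tr_codon", "n_reachable_aa", "stop_reachable", "is_aay", "diversifiable")]
bigint_str(protein_variant_count(cd))
```

## Tetranucleotide composition analysis

To ask whether cassette components (particularly RT genes) compositionally
match their host genome — the signature question for horizontal acquisition —
`dgrscope` implements the classic genome-signature workflow: sequences are
fragmented with a 5-kb sliding window (500-bp step; windows shorter than 5 kb
are dropped), and each window is profiled by zero-order-Markov odds ratios of
its 256 tetranucleotides (`tetra_odds()`): observed 4-mer counts divided by
the expectation under the window's own mononucleotide frequencies. Observed
and expected totals both equal the number of counted 4-mer positions, a
conservation identity asserted by the tests. Dispersed features (cassettes,
RT genes, TP genes) are concatenated before windowing (`concat_and_profile()`)
so that flanking sequence does not dilute their signal. Counting is
single-strand and odds ratios are used raw (no log transform), as the
odds-ratio construction is defined; strand symmetrization and log transforms
are deliberately out of the default path. Euclidean distances between odds
vectors are embedded by non-metric multidimensional scaling (`nmds()`,
Kruskal stress-1, 20 random starts behind a fixed seed, via vegan), and per
group a 95% confidence ellipse is drawn from the eigendecomposition of the
2×2 coordinate covariance scaled by the chi-square(2) quantile
(`confidence_ellipse()`). `outlier_report()` flags windows outside the genome
core's ellipse; a feature class whose windows are flagged far above the 5%
nominal rate (RT genes, in the motivating analyses) is compositionally
foreign to the host.

## The synthetic-genome generator

`generate_genome()` plants complete cassettes in an i.i.d. background
(default 50 kb at GC 0.45). Each cassette occupies a 10-kb span on the
forward strand in the order TP … TR(+IMH\*) … Avd … RT, the architecture of
multi-DGR archaeal genomes: a TP gene whose 3′ region is the VR followed by
IMH (TGGGGT) and a stem-6/GAA-loop hairpin, an intergenic TR copy followed by
IMH\* (TGGAAT), a small engineered basic ORF in the Avd pI/MW window, and an
RT-like ORF carrying YADD. The template is built codon-wise with an exact
adenine count (default 30% of 114 bp = 34 adenines) from a codon pool in
which no adenine substitution can produce a stop (`plant_no_nonsense = TRUE`,
mirroring the no-nonsense-risk property of natural templates and making the
risk flag testable in both states). VR is derived from TR by the mutagenesis
model (`mutate_vr()`): each adenine is redrawn uniformly from the four bases
with probability 0.4 (so 3/4 of redraws change the base), non-adenine
positions substitute at a configurable background rate (default 0).

The defaults are the package's reference study conditions. Note their
statistical consequence: the expected adenine-specific mismatch count is
$114 × 0.30 × 0.40 × 3/4 ≈ 10.3$, sitting essentially on the classifier's
≥ 10 floor, with binomial standard deviation ≈ 2.7. Roughly 40% of simulated
cassettes therefore genuinely fail the detection criterion — not because the
pipeline misses them but because the realized footprint does not meet the
published rule. The acceptance suite measures recovery at exactly these
conditions and reports it as observed (about half of planted cassettes at
±3 bp boundary tolerance); matched negative genomes yield zero complete
cassettes. Detection is near-certain once the realized mismatch count clears
the floor, as the elevated-substitution settings used in the unit tests show.

What the generator does **not** emulate: real gene structure and codon usage
in the background (it is i.i.d.), compositional heterogeneity (so tetra
ordinations of synthetic genomes are a null model, not a positive control),
gapped repeat divergence, and sequencing artifacts beyond uniform
substitution errors, quality noise and injected Ns in `generate_reads()`.
Passing tests on synthetic data therefore demonstrate correctness of the
detection arithmetic and geometry, not robustness to every property of real
assemblies.

## Read quality control

`qc_filter_reads()` reproduces a standard four-stage read-cleaning chain in
a fixed order: (1) drop reads containing N; (2) drop the shortest 2.5% and
longest 2.5% of the survivors — `floor(0.025 n)` reads per tail, ties broken
by input order; (3) drop reads whose mean quality is more than 2 standard
deviations below the mean of per-read means; (4) exact-duplicate removal
(first occurrence kept), a deterministic stand-in for clustering-based
dereplication, which is out of scope. Counts removed per stage are reported.
Because the tail trim removes a fixed count per pass, the chain is not a
fixed point: re-filtering an already-filtered set trims further tails by
construction. The per-stage behaviours, not whole-chain idempotence, are the
tested contract.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 output converts to
  1-based inclusive.
* `N` matches nothing anywhere: ORFs cannot span an N codon, repeat seeds and
  extensions treat N as a mismatch, tetranucleotide counting skips
  N-containing 4-mers.
* Zero-expected / zero-observed tetranucleotide odds are set to 1 (neutral):
  a 4-mer absent for lack of its constituent bases carries no deviation
  signal.
* NMDS with fewer than k + 2 points, hairpin regions shorter than
  2·stem_min + loop_min, and confidence ellipses for groups of fewer than 3
  points are refused or skipped with a warning rather than silently computed.
* All variant counts use exact integer arithmetic; no floating point touches
  a count.
* Problem sizes in the test and acceptance suites (50 positive + 50 negative
  genomes of 50 kb, 200 exhaustively enumerated templates capped at 12
  adenines, 100 hairpin oracle regions of 300 nt, a 100-kb conservation
  genome, n = 10,000 ellipse coverage draws) are the package's reference
  validation sizes, chosen so each property is measured with comfortable
  statistical margin.

## Known limitations

* Ungapped repeat alignment: a TR/VR pair that has acquired an indel since
  diverging is reported as the longer of its two collinear halves, or missed
  if both fall below `min_repeat_len`.
* The motif-based RT scan trades sensitivity for reproducibility; diverged
  RTs without a recognizable `[YF]x[DA]D` box require user-supplied anchors.
* Repeat boundaries are score-maximal, so a mismatch at the extreme edge of a
  real repeat (which can be an adenine-specific position) may fall outside
  the reported alignment; classifications sitting exactly at the 10-mismatch
  floor can flip accordingly.
* Tetranucleotide profiles use 256 raw dimensions; with few windows the NMDS
  is under-determined and stress should be read with care.
* The pI model uses one fixed pKa table; absolute pI values shift by a few
  tenths under alternative published tables, which matters only at the edges
  of the Avd acceptance window.
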