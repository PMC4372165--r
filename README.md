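# dgrscope

Discovery and characterization of **diversity-generating retroelements
(DGRs)** in genomes, contigs and viral assemblies.

DGRs mutagenize a defined region of a target gene at extraordinary rates: a
reverse transcriptase (RT) copies the RNA of a non-coding template repeat
(TR) into cDNA, misreading every template **adenine** as a random base, and
the mutagenized cDNA replaces the homologous variable repeat (VR) inside the
target-protein (TP) gene. The genomic footprint is two proximal repeats that
differ almost only at positions where the template carries an A. `dgrscope`
detects that footprint and measures what it implies:

* **Detection** — six-frame ORF scan, RT candidate scan (`[YF]x[DA]D`
  catalytic motif, or user-supplied BED loci), seed-and-extend repeat search
  within ±5 kb of each anchor, and TR/VR classification by the
  adenine-mismatch rule: ≥ 10 adenine-specific mismatches with respect to one
  copy and ≤ 2 non-adenine mismatches per 100 bp of aligned sequence.
* **Cis elements** — IMH/IMH\* terminal motifs (TGGGGT/TGGAAT) at the VR/TR
  3′ ends, maximal stem-loops with GRA/GRNA loop classification inside the TP
  gene, and Avd-like accessory ORFs selected by isoelectric point (9 ± 1) and
  molecular weight (10 ± 5 kDa).
* **Diversification potential** — exact counts: a template with $A$ adenines
  defines $4^A$ nucleotide variants; per codon, all $4^k$ adenine
  substitutions are enumerated to give reachable amino-acid sets, AAY and
  diversifiable codon censuses, the protein-level variant count
  $\prod_c |\mathrm{reachable}(c)|$ (stops excluded), and a nonsense-risk
  flag. Arbitrary-precision integers throughout.
* **Tetranucleotide composition** — 5-kb sliding windows (500-bp step),
  zero-order-Markov odds ratios over the 256 tetranucleotides, NMDS on
  Euclidean distances (Kruskal stress-1), 95% chi-square confidence
  ellipses per group, and outlier flagging of feature windows against the
  genome core — the standard test for horizontally acquired components.
* **Synthetic data** — `generate_genome()` plants complete cassettes
  (TP+VR+IMH+hairpin … TR+IMH\* … Avd … RT) with full ground truth, and
  `generate_reads()` + `qc_filter_reads()` exercise the read-QC chain
  (N removal, 2.5% length tails, 2-s.d. quality filter, dereplication).

## Worked example

Simulate a genome with one planted cassette, detect it, and summarize its
diversification potential:

```r
library(dgrscope)

g   <- generate_genome(sim_config(seed = 3))
det <- detect_dgr(g$record)
cc  <- Filter(function(x) x$complete, det$cassettes)[[1]]

cc$trvr$profile$n_adenine_wrt_B   # adenine-specific mismatches wrt the template
#> [1] 10
summarize_diversity(cc)
#> <diversity_summary> 34 adenines; 4^34 = 295147905179352825856 nucleotide variants
#>   17/39 codons diversifiable (2 AAY); 2812500000000 protein variants; nonsense risk: FALSE
```

Reading the output: the detected template carries 34 adenines, so error-prone
reverse transcription can emit $4^{34} \approx 2.95\times10^{20}$ distinct
cDNAs; after translation in the target gene's frame these collapse to
$2.8\times10^{12}$ distinct proteins (17 of the 39 VR codons can change amino
acid, including 2 maximally diversifiable AAY codons), and no variant can
introduce a stop codon — the element diversifies its target with no nonsense
risk.

`run_pipeline()` orchestrates detection, cis elements, diversity and
(optionally) the tetranucleotide ordination over whole FASTA files and writes
JSON/GFF3/TSV reports via `write_report()`. A thin command-line front-end
with `simulate` / `detect` / `tetra` / `run` verbs is installed at
`inst/exec/dgrscope`.

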