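---
title: "Targeted bisulfite amplicon analysis with hepityper: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted bisulfite amplicon analysis with hepityper: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepityper)
```

## The problem

Sodium bisulfite deaminates unmethylated cytosine to uracil, read as
thymine after PCR, while 5-methylcytosine is protected. Sequencing PCR
amplicons of bisulfite-converted DNA therefore encodes the methylation
state of every CpG cytosine directly in the base calls: `C` means
methylated, `T` unmethylated. `hepityper` implements the full desk side of
a targeted assay built on this chemistry:

1. **Panel design** on in-silico converted target DNA: highly redundant
   primer panels for massively parallel singleplex (microdroplet) PCR.
2. **Read mapping** against ambiguity-coded predicted amplicons, with
   approximate primer matching and identity filters.
3. **Per-CpG quantification** of methylation with coverage and
   polymorphism flags.
4. **Hepityping**: phased methylation patterns read from single molecules
   that span a whole region, their frequency spectra, unrooted
   maximum-parsimony trees, and an exact test for asymmetry of
   methylation-maintenance errors.
5. A **seeded simulator** that generates every input needed to validate
   the above, with ground truth.

## Coordinates and representations

All internal coordinates are 0-based half-open; every user-facing report
(panel TSV, site tables) prints 1-based inclusive positions, the
genome-browser convention. Conversion of the plus strand maps `C -> T`;
conversion of the minus strand, re-expressed on plus-strand coordinates,
maps `G -> A`. The *ambiguity-coded amplicon* leaves the methylation-readable
base open: CpG cytosines become `Y` (C or T) on forward-strand amplicons and
CpG guanines become `R` (G or A) on reverse-strand amplicons, with all other
convertible bases fully converted. CpG context is decided on the original,
unconverted reference only. `N` bases pass through conversion unchanged;
regions containing `N` are excluded from design.

## Primer design

Regions are fragmented into overlapping windows of 200, 300 and 400 bp
advancing in 5 bp steps. Candidate primers are enumerated exhaustively per
window (length 18–25, optimum 20; the left primer starts within the first
50 bp of the window, the right primer ends within the last 50 bp; product
length within window size − 50 … window size).

**Melting temperature.** Because the design operates on three-letter
(converted) DNA, the Tm model must be explicit and reproducible: we use
unified nearest-neighbor thermodynamics at 50 mM monovalent cation and
50 nM total strand concentration (the CT/4 convention for
non-self-complementary duplexes), with the entropic salt correction
`dS' = dS + 0.368 (L−1) ln[Na+]`. Hard constraints are Tm 56 ± 2 °C,
inter-primer ΔTm ≤ 2 °C and GC between 20 % and 90 %. Each surviving pair
is scored by the penalty

```
|Tm_left − 56| + |Tm_right − 56| + 0.5 (|len_left − 20| + |len_right − 20|) + |ΔTm|
```

which is monotone in each of the optimality criteria above; the five
lowest-penalty pairs per window enter the pool. The penalty constants are
package constants, not fitted quantities.

**Masking.** Pairs are removed when a primer footprint overlaps a variant
with minor allele frequency > 0.1 (allelic amplification bias) or covers
the methylation-readable base of a CpG on its design strand (such primer
bases would have methylation-dependent sequence). Masking at the
resolution of individual CpG dinucleotides is a conservative superset of
masking whole CpG islands.

**Off-target screening.** Both conversion strands of the entire supplied
genome form the in-silico PCR background. A primer binds where its fifteen
3'-terminal bases match exactly and at most two mismatches occur over its
full length — classical e-PCR word-match semantics chosen to remain
brute-forceable, since the original tool's parameters are not part of the
method definition. Any convergent placement of the pair's primers (either
primer in either role) yielding a product of ≤ 2 kb anywhere other than
the intended locus removes the pair. The test suite re-verifies survivors
with an independent full-position scan.

**Selection.** Per size class, deduplicated pairs (exact left+right
sequence equality) are taken in order of increasing primer GC content
(mean of the two primers, ties broken lexicographically by sequence) and a
pair is kept whenever any base of its product is still below the class's
fold target: 2-fold for 300 bp windows, 3-fold for 200 and 400 bp, i.e.
8-fold aggregate redundancy. Windows left uncovered after this pass are
re-designed once with the Tm window widened to 56 ± 6 °C; such pairs are
tagged `relaxed`. On converted (cytosine-free, hence AT-rich) DNA the
strict window is satisfiable mainly in guanine-dense stretches, so the
relaxation pass carries real weight — this is a property of converted-DNA
design under an explicit thermodynamic model, not of any particular
genome.

The expected product-size histogram (`calculated_peak_profile()`) assumes
equimolar amplicon representation and is the design-time analogue of an
electrophoretic trace of a successful library.

## Read processing

Primers are located in reads (both orientations) by unit-cost edit
distance ≤ 2, computed by a row-wise dynamic program vectorized across
reads. The primer hits nominate candidate amplicons and fix the read's
orientation; the read is then aligned to each candidate's ambiguity-coded
reference — read-global, reference-local, match +1, mismatch −1, linear
gap −2, free end gaps on the reference, with `Y`/`R` matching either of
their bases so that methylation state itself never costs identity.
`matching_bases` counts ambiguity-compatible aligned columns; `identity`
divides by all aligned columns, gap columns included. A read is `mapped`
when it has ≥ 50 matching bases and identity strictly above 95 %;
equal-best alignments within one region resolve to the lowest amplicon
identifier, while best (or passing) alignments in two different regions
mark the read `ambiguous`. Accounting is exact:
`mapped + no_primer + low_identity + ambiguous` equals the input reads.
Primer footprints are trimmed before any scoring.

## Methylation calling

Per CpG site and sample, aligned read bases in the trimmed span are
tallied: `C`/`T` on forward-strand amplicons, `G`/`A` (mapped to C/T) on
reverse-strand amplicons. Methylation is the proportion
`n_C / (n_C + n_T)` — the percent scale of the output forces the
proportion reading of a "C to T ratio", not the odds. Bases other than the
two informative ones count toward depth but never toward methylation, so
isolated sequencing errors dilute rather than bias; reads with an
alignment gap at a site contribute nothing there. Sites with no reads
export as `"-"`; depth below 20 sets a `low_coverage` flag; genotype-aware
annotation marks sites absent from a sample's alleles as `"NA"`.
Cross-strand (or cross-method) agreement is summarized by Spearman rank
correlation with average-rank ties, over sites defined in both series,
undefined below three shared sites.

## Hepityping

Only reads whose trimmed alignment covers *every* CpG of a region with an
informative base contribute a hepitype; the pattern string uses `C` for
methylated and `T` for unmethylated. Frequencies are relative to all
spanning reads and are deliberately **not** renormalized after the strict
1 % frequency filter, so tree and figure annotations keep observed-read
semantics.

**Parsimony trees.** Tree length is Fitch parsimony on the binary
characters. Search is exhaustive over all unrooted binary topologies for
up to 7 leaves; above that, stepwise addition (leaves in descending
frequency, ties lexicographic) followed by steepest-descent
nearest-neighbor-interchange, restarted deterministically from every
rotation of the addition order, with ties always broken by first
discovery in the documented enumeration order. The threshold of 7 keeps
tree construction interactive (10k–135k topologies at 8–9 leaves cost
tens of seconds in interpreted R) and the suite verifies on hundreds of
randomized instances that the heuristic attains the exhaustive minimum;
`method = "exhaustive"` and `exhaustive_max` remain available. Branch
lengths are not estimated: Newick output carries per-edge change counts
of one arbitrary most-parsimonious assignment, for display only.
Bootstrap support resamples site columns with replacement under a single
seeded RNG stream and reports, per internal split of the observed tree,
the fraction of replicate trees containing the same bipartition.

**Deviating-site test.** At dichotomous loci (imprinting being the
archetype), each spanning read is assigned to the nearer of the all-C and
all-T backgrounds by Hamming distance; exact ties are excluded and
counted. The 2×2 table — rows methylated/unmethylated background, columns
exact match / ≥ 1 deviating site — is tested with a two-sided Fisher exact
test implemented by full hypergeometric enumeration (p = sum of
probabilities of tables no more probable than the observed one at fixed
margins; a zero margin yields p = 1). Reads, not distinct hepitypes,
populate the table — aggregation to patterns would discard the count
information the test relies on — and sub-1 % patterns are included; a
hepitype-level table can be produced by passing the filtered table
explicitly.

## The simulator

The generator emulates the assay end to end: a random background contig
with embedded CpG islands (requested number of CpGs planted at spaced
positions; island base composition defaults to GC-rich with a guanine
skew on the design strand, `A .18, C .25, G .37, T .20` — GC skew is a
documented feature of CpG islands around transcription starts, and on
converted DNA guanine-dense windows are precisely where thermodynamically
valid primers live), CpG-free primer pads at region ends, optional decoy
contigs carrying verbatim copies of a region's core (for off-target and
ambiguity tests), clonal mixtures with per-site maintenance noise (C→T
at `loss_rate`, T→C at `gain_rate`), bisulfite conversion with
configurable efficiency (default 0.99), strand-balanced amplicons, random
read orientation, reads of normally distributed length (mean 204 bp,
reflecting long-read amplicon sequencing) truncated at their own 3' end,
and substitution errors. Homopolymer indels exist but default to off so
that exact-identity assertions hold; in `clean_primer` mode (default)
errors never fall inside primer footprints, which keeps primer-matching
tolerance a separately testable property. Every run is bit-reproducible
from its seed and emits per-read ground truth.

Three presets mirror the archetypal architectures: `imprinted` (50/50
fully methylated / fully unmethylated founders, asymmetric maintenance
failure 0.05 vs 0.005 per site), `demethylating` and `methylating` (two
pseudo-timepoints with the minority epiallele expanding from 20 % to
70–80 %, symmetric noise 0.01).

**What the simulator does not model** — and hence what green tests do not
show about real data: flowgram/homopolymer chemistry beyond the optional
indel mode, PCR amplification bias between alleles or amplicons, chimeric
reads, incomplete-conversion correlation along a molecule (failures are
independent per site), SNP-containing reads beyond the genotype-presence
annotation, and real CpG-island sequence structure.

## Validation-study sizes and choices

The shipped tests run the pipeline at deliberately compact sizes chosen to
make each property measurable: two 600 bp regions with 15 CpGs for design
audits; depth 200 over 8 sites across 20 seeds for methylation recovery
(binomial 3-SD bands); depth 500 and 8 sites with 100 seeded replicates
for the power/size of the deviating-site test; four regions × 25 sites at
depth 500 for cross-strand concordance. For concordance, true per-site
levels come from 16-clone mixtures: rank correlation needs a gradient of
true levels, and with only a handful of distinct levels the statistic is
dominated by tie-breaking noise rather than by pipeline error. These are
study-design choices of the validation suite, stated here once; none of
them is a tuning knob of the method itself.

## Known limitations

* Non-CpG (CHG/CHH) methylation contexts are out of scope, as are
  whole-genome conversion indexes for alignment-based protocols.
* Primer thermodynamics ignore secondary structure, dimers and multiplex
  compatibility; the panel is designed for singleplex droplet PCR where
  these matter less.
* The identity filter operates on unit-cost columns; quality-aware or
  homopolymer-aware realignment is not attempted.
* SNP alleles are consumed only for CpG presence/absence; joint
  SNP-plus-methylation pattern strings are not built.
* The deviating-site test presumes a dichotomous locus; at loci without
  two clear backgrounds the Hamming assignment is still computed but the
  test's null is no longer meaningful.
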