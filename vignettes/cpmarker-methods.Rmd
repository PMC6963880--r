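---
title: "Methods: plastome diversity scanning and InDel-marker assays"
author: "cpmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome diversity scanning and InDel-marker assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmarker)
```

## The problem

Dried and powdered herbal products made from closely related plants — the
motivating case is the Korean spices sancho (*Zanthoxylum schinifolium*) and
chopi (*Z. piperitum*) — cannot be told apart visually, and commercial
products are frequently mixtures. Complete chloroplast (plastid) genomes
provide a practical route to diagnostic DNA markers: the genomes are small
(~156–159 kb), highly conserved, and maternally inherited, so the few
hypervariable intergenic regions that do diverge between species carry most
of the discriminating signal. `cpmarker` implements the comparative workflow
end to end: locate hypervariable regions by a sliding-window nucleotide
diversity scan, extract the length polymorphisms (InDels and tandem-repeat
copy-number differences) they contain, define PCR markers whose product
sizes separate species on a gel, and predict PCR-RFLP assays where a
restriction site present in only one species splits its amplicon.

## Nucleotide diversity

For a gapped multiple alignment of $N$ haplotypes, the per-site nucleotide
diversity is

$$\pi = \binom{N}{2}^{-1} \sum_{i<j} d_{ij},$$

where $d_{ij}$ is the pairwise p-distance: mismatches over comparable sites.
Two conventions for "comparable" are implemented and exposed everywhere:
*pairwise deletion* (a site counts for a pair when both rows hold an
unambiguous base; the MEGA default for pairwise distances) and *complete
deletion* (a site counts only when every row of the block holds an
unambiguous base; the DnaSP default). Pairwise deletion is the package
default. The classical $n/(n-1)$ sample-size correction is **off** by
default: for a four-taxon interspecific alignment the quantity of interest
is the plain mean pairwise distance, which makes the per-window statistic
identical to the "mean pairwise distance" reported per marker locus —
`mean_pairwise_distance()` and `nucleotide_diversity()` agree to $10^{-12}$
by construction, and the test suite asserts it. A `bias_correction` flag
exposes the corrected variant.

Pairs with zero comparable sites yield an undefined (`NA`) distance that is
excluded from means and never coerced to zero.

## The sliding-window scan

Windows are 600 alignment columns wide and advance by 300 — 600 bp because
that is the typical length of a usable PCR marker, 300 bp so adjacent
windows overlap by half and hotspot edges are positioned to half a window.
Windows start at columns $1, 301, 601, \dots$ while a full window fits; a
trailing partial window is dropped, so the count is
$\lfloor (L - w)/s \rfloor + 1$. Window coordinates are alignment columns;
mapping to reference-genome positions (for partition labels and locus
naming) goes through the reference row's ungapped-position index, because
scans run on the alignment but loci are reported on a genome.

Hotspots are maximal runs of consecutive windows with $\pi$ strictly greater
than 0.025 (an isolated window qualifies); adjacent supra-threshold windows
merge into one region that keeps every member window's value. The strict
inequality and the merge rule are both fuzz-tested.

## Quadripartite partitioning

Plastomes have a large and a small single-copy region separated by two
inverted repeats. The partitioner seeds exact 300-mer matches between the
forward strand and its reverse complement at 300 bp spacing, extends each
seed in both directions (a mismatch is crossed only when 20 consecutive
matches resume within 50 bases and the overall mismatch fraction stays
below 1%), and reports the longest disjoint pair as IRa/IRb; the longer
intervening single-copy stretch is the LSC. The boundary rules matter for
testability: the synthetic generator adjusts the single base flanking each
planted repeat so the pair is *maximal* — otherwise a chance-matching
flanking base makes the genuinely maximal repeat one base longer than the
construction and no detector could return the planted boundaries. With that
guarantee, noise-free constructions are recovered exactly (100-replicate
property test); diverged repeats (99.7–99.9% identity, the realistic range)
are recovered to within a few bases, and only interval-sum invariants are
asserted there. A genome without a repeat of at least `min_ir_len` returns
a degenerate all-LSC partition with a warning, never an error.

Partition-wise averages are reported under two conventions side by side:
the mean over all windows, and the mean over windows with $\pi > 0$ only.
The headline value uses the nonzero convention for the inverted repeats —
IR windows are predominantly invariant, and the nonzero mean separates
residual variability from pure conservation — and the all-window convention
for LSC, SSC and overall.

## InDel events and tandem repeats

An InDel event is a maximal run of alignment columns sharing one
gap-presence pattern, with gaps in at least one but not all rows. Adjacent
or nested length polymorphisms with different haplotype patterns therefore
come out as separate events with their individual lengths, which is what a
marker developer needs. Substitutions cannot change gap patterns, so event
coordinates and lengths are exactly noise-invariant (tested).

Tandem repeats are found per haplotype on the ungapped sequence with the
rolling comparison $s_i = s_{i-k}$ for unit lengths $k = 1..60$. Long
perfect runs seed candidates which are extended across isolated single
mismatches, at most one per unit copy. Calls need at least 2 copies and a
total full-copy span of at least 8 bp (`min_span`), which suppresses the
dinucleotide/homopolymer noise that saturates any genome; overlapping calls
resolve to the longer span, then the smaller unit. A repeat whose unit
equals (up to rotation and one mismatch) the non-gap allele of an adjacent
InDel is flagged *slippage-linked*: the copy-number difference explains the
length polymorphism.

## In-silico PCR and PCR-RFLP

Primer binding uses a standard in-silico PCR convention: at most 2
mismatches overall and an exactly matching 5-base 3' terminus (polymerases
do not extend a mismatched 3' end). Both parameters are configurable; IUPAC
codes in a primer match their expansion sets. Every forward-site/minus-
strand-reverse-site combination within 50–5000 bp yields a predicted
amplicon (multi-band prediction), with coordinates including both primer
footprints, as capillary electrophoresis measures.

Restriction enzymes live in a packaged, editable TSV
(`inst/extdata/enzymes.tsv`): recognition sequence plus signed top/bottom
cut offsets from the site's 3' end, which accommodates Type IIS offset
cutters — PleI (GAGTC 4/5) cuts 4 nt downstream on the recognition strand.
Fragment lengths are distances between successive *top-strand* cut
positions, so they sum exactly to the amplicon length (fuzz-tested over
1000 random cases); the 1-nt 5' overhang of a sticky-end cutter is ignored,
matching gel-observable sizes to within 1 nt. A consequence worth stating:
digesting a sequence and its reverse complement yields identical fragment
multisets only for blunt cutters — for an asymmetric cutter like PleI the
two strands' fragment sets differ by the overhang. The strand-symmetry
property is therefore asserted for blunt enzymes (AluI, EcoRV, MlyI).

Species classification compares observed fragment lengths per marker with
each species' expected pattern within a 5 bp tolerance (configurable; gel
reading error). A marker votes for a species, for *both* (mixture evidence
— the "double band" case), or for none; any both-vote yields `mixture`,
unanimous votes yield the species, disagreement yields `unresolved` with
the per-marker evidence retained.

## The synthetic-data generator

`simulate_quartet()` emulates the statistical structure of an
interspecific plastome comparison, not any particular sequence: an ancestor
drawn uniformly per block, independent descent of each haplotype (star
phylogeny — the analyses tested here do not depend on tree shape),
Jukes–Cantor-style substitutions at block-specific rates, planted deletions
and insertions, and tandem-repeat expansions that replicate the carrier's
own unit. The generator emits the *true* alignment from construction plus
raw FASTA, and a truth record (event coordinates in both ancestral and
alignment frames, per-block closed-form expected pairwise distance
$2r(1-r) + \tfrac{2}{3}r^2$) that tests score against. All randomness
derives from one integer seed; outputs are bit-reproducible and the
caller's RNG stream is restored.

Two deliberate realism choices:

- **Protected flanks.** Substitutions are suppressed in 40 bp windows
  offset 20 bp from each planted event, emulating the conserved
  primer-binding flanks that real diagnostic markers are designed in; the
  exact product-size recovery properties place their primers there.
- **Maximal planted repeats** (see partitioning above).

`default_quartet_spec()` fixes the study-scale conditions used by the
acceptance script: four haplotypes, ~156.3 kb ancestral genomes (LSC
85.3 kb carrying four hypervariable blocks of 1 kb, SSC 18 kb, two 26.5 kb
IRs), which yields a 520-window scan at 600/300. Background substitution
rates (LSC 0.004, SSC 0.0052, IR 0.00065 per lineage) were set so realized
pairwise diversity lands at typical interspecific plastome values (LSC
≈ 0.008–0.010, SSC ≈ 0.010, IR ≈ 0.0015). Hotspot-block rates (0.019,
0.042, 0.0445, 0.024) were derived by inverting the dilution caused by
protected flanks and planted events, targeting realized window diversities
of roughly 0.028–0.055 — the range observed for plastome mutational
hotspots. The planted InDel lengths (3–59 bp) and tandem-repeat units
(8–40 bp) mirror the length spectrum of published diagnostic plastid
markers. The mildest hotspot (realized $\pi \approx 0.028$ against the
0.025 threshold) sits close to the calling threshold by construction, so
its detection is genuinely borderline at some seeds — which is the
realistic behaviour of a near-threshold locus, and the recovery *tests*
instead use well-separated conditions (hotspots at rate 0.04 on a 0.003
background) where 100% recall with zero false calls is the correct
expectation.

What the generator does **not** emulate: tree-structured descent,
alignment error (truth tests use the constructed alignment precisely to
isolate scan/extraction error from aligner error), rate heterogeneity
within a block, realistic indel length distributions beyond the plan, and
base composition bias. Passing tests therefore validate the scan, event
extraction, marker logic and assay prediction — not the behaviour of any
external aligner on real genomes.

`simulate_market_panel()` draws pure or 50:50-mixture samples and emits
per-marker band tables with ±2 bp uniform jitter, with truth labels for
scoring the classifier. With patterns separated by ≥15 bp and a 5 bp
matching tolerance, pure samples classify perfectly and mixtures are
flagged by their double-band signature.

## Numerical and design notes

- Coordinates are 1-based inclusive in every user-facing interface (GenBank
  convention); BED export converts to 0-based half-open, and the conversion
  is tested. Plastomes are treated as linear strings; features spanning the
  circular origin are split into two intervals at load time.
- Ambiguity codes other than the unambiguous bases are retained on input
  but score as mismatches-to-everything in `align_small()` and are excluded
  from distance comparisons (conservative on both counts).
- `align_small()` is a convenience for test-scale sequences (≤50 kb); a gap
  run of length $L$ scores $g_\text{open} + L\,g_\text{extend}$, and its
  optima match an exhaustive enumeration oracle on 200 random short pairs.
  Whole-plastome alignment is deliberately delegated to external aligners
  via `load_alignment()`.
- Primer Tm uses the unified nearest-neighbor parameters at 50 mM
  monovalent salt and 0.25 µM primer, with the Wallace rule below 14 bases.
- Ties at the hotspot threshold: strictly greater than, never ≥.
- Pipeline reports contain no timestamps; rerunning an identical
  configuration produces byte-identical JSON (asserted), and every number
  in the report is a stage output, not a report-side computation.

## Problem sizes used by the shipped validation

The packaged test-and-acceptance runs use: 500 random blocks (2–6 rows,
≤400 columns) for the diversity oracle; 100 noise-free and one diverged
partition construction; 50 recovery quartets of 24 kb (two 1.5 kb planted
hotspots at rate 0.04 on a 0.003 background, four planted InDels, one TR
expansion); 1000 fuzzed digests; a 200-sample market panel; and one
study-scale (~156 kb) quartet for the headline scan quantities. These sizes
were chosen so the full validation completes in a few minutes on one CPU
while every statistical check retains comfortable power.

## Known limitations

- The genic/intergenic status of a hotspot is taken from whatever reference
  annotation is supplied; the package does not adjudicate conflicting
  labels.
- PCR efficiency, primer dimers and secondary structure are not modelled;
  a predicted amplicon is a geometric statement, not a yield prediction.
- Single-enzyme digests only; compose double digests by piping fragments.
- The accession-based regression (four public *Zanthoxylum* plastomes)
  requires the user to supply the GenBank records locally; the package
  ships synthetic stand-ins that reproduce the assay geometry (543 bp
  amplicon cut into 436+107 vs 562 bp uncut) and labels them as synthetic
  wherever they appear.
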