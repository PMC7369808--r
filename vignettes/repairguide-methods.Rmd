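---
title: "Designing and quality-controlling site-directed A-to-I editing of premature stop codons"
author: "repairguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quality-controlling site-directed A-to-I editing of premature stop codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairguide)
```

## The problem

Nonsense mutations replace a sense codon with a premature termination
codon (PTC), truncating the protein. When the PTC arose from a G>A
transition — as in the opal mutations W190X (an H2BGFP reporter) and
W1282X (CFTR, the second most common nonsense allele in cystic
fibrosis) — the damage is reversible at the RNA level: ADAR deaminates
adenosine to inosine, and the ribosome reads inosine as guanosine, so
editing the PTC's adenosine converts UGA back to UGG (tryptophan) in the
transcript without touching the genome.

dCas13b/ADAR2-DD platforms (REPAIRv2) direct that deamination with a
guide RNA consisting of a *spacer* — an antisense sequence, 25–80 nt,
complementary to the mRNA around the target adenosine — followed 3' by
the scaffold hairpin that dCas13b binds. The spacer deliberately places
a cytidine opposite the target adenosine; this C:A mismatch is what
licenses efficient ADAR deamination at that position, and its distance
from the spacer 3' end (equivalently, from the first scaffold
nucleotide) selects *which* adenosine is contacted.

`repairguide` implements the desk half of such an experiment: finding
and classifying editable PTCs, constructing spacers with explicit
geometry, emitting cloning-ready oligos, enumerating bystander
adenosines, predicting the translated outcome, and modelling the Sanger
electropherogram read-out used to verify editing.

## Coordinate conventions

All interfaces are 1-based and inclusive. A `TranscriptRecord` carries
an `orfStart`; codon *i* spans transcript bases
`orfStart + 3(i-1) … orfStart + 3(i-1) + 2`. With `orfStart = 1`, the
third base of codon 190 is transcript position 570 and of codon 1282 is
position 3846 — the two worked coordinates the scanner reproduces:

```{r}
gfp <- fixturePreset("h2bgfp-opal")    # 400 codons, TGA at codon 190
scanPtcs(gfp)[[1]]
```

The `g.<pos>G>A` notation names the presumed DNA-level origin of the
stop in record-relative coordinates; an ORF-relative `c.` form is also
stored (they coincide when `orfStart = 1`).

Stops are classified opal (TGA), amber (TAG) or ochre (TAA). Opal and
amber are single-edit rescuable — in each case exactly one A→G
conversion yields TGG/Trp, which is forced by the genetic code. Ochre
needs both of its adenosines edited and is therefore reported but
refused by the outcome predictor unless explicitly overridden: paired
C:A-mismatch guides edit one site.

The terminal stop of the ORF (the last in-frame stop) is never reported
as a PTC; `includeTerminal = TRUE` exists for completeness.

## Spacer geometry

The central, deliberately documented convention: **the 3'-terminal
spacer base is position 1, and the mismatched C sits at position `d`
from the 3' end.** Because the scaffold abuts the spacer's 3' end, `d`
equals the distance between the target adenine and the first scaffold
nucleotide. An off-by-one here silently shifts the edited base, so the
package asserts the geometry with an independent antiparallel pairing
check in its test-suite rather than assuming it.

With spacer length `L` and mismatch distance `d`, the covered window in
transcript coordinates is

```
window = [targetA − d + 1, targetA + L − d]
```

and the spacer is the reverse complement of that window with the base
opposite the target A replaced by C (5'→3' string index `L − d + 1`).
The worked parameter sets are available as `presetDesignGrids()`: four
guides for the reporter system (50/32, 50/34, 50/35, 30/25) and three
for the CFTR system (50/32, 50/34, 50/35).

A 5'-terminal guanine improves transcription from the U6 promoter. How
the original guides obtained it is not recorded, so the package offers
three policies; `substitute` is the default because it preserves the
printed lengths (30/50 nt):

* `substitute` — overwrite the 5' base with G (flagged when it acted).
  Refused when `d = L`, where the mismatch C *is* the 5' base.
* `prepend` — add a G, length `L + 1`.
* `require` — error unless the window already yields a 5' G.

Designs attach advisory warnings (internal BbsI site, homopolymer run
≥ 6, target not in a stop codon) that `validateDesign()` surfaces as
machine-readable issues alongside hard bound checks (25–80 nt guide
length).

`emitOligoPair()` produces the two single-strand oligos that anneal
into the spacer insert for golden-gate cloning into a BbsI-digested
guide backbone. The original overhang sequences are not published
("different 5' overhangs allowing directional cloning"), so the
defaults (`CACC`/`CAAC`) follow common BbsI practice, are explicitly
provisional, and are configurable; what the package actually guarantees
and tests is the structural invariant — stripping the overhangs and
annealing reconstructs the spacer duplex exactly.

## Bystander enumeration

Every adenosine under the spacer is a potential collateral ADAR
substrate. `assessBystanders()` substitutes G at each window adenosine
*one at a time*, re-translates its codon, and classifies the
consequence (intended-PTC-repair / synonymous / missense /
stop-introducing / noncoding). No probability of bystander editing is
assigned: sequence-preference models for the hyperactive ADAR2-DD
(E488Q/T375G) are not part of this package's evidence base, so the
report is pure consequence enumeration, and combinatorial multi-site
editing is out of scope for the same reason.

## The Sanger trace model and the ~30 % detection limit

Editing in a cell population is conventionally checked by RT-PCR and
Sanger sequencing: a partially edited template shows a double A/G peak
at the target position. The practical question is how much edited
transcript is needed before the minor G peak is distinguishable from
baseline noise — empirically, roughly 30 %.

`simulateTrace()` models peak heights at base-call resolution (a
scan-point-level Gaussian renderer would add nothing to the A/G ratio
logic). Per position, in units of the mean called-peak height:

* the called channel draws a height from Normal(1, `peakHeightCv`),
  default CV 0.10;
* at the edited site the signal splits: channel A gets `(1 − f)` and
  channel G gets `f` of an (independent) called-height draw;
* every channel adds a uniform baseline on `[0, noiseFloor]`;
* a fraction `crosstalk` (default 0.02) of each real signal bleeds into
  the other channels;
* heights are clipped at zero.

`estimateEditedFraction()` estimates the noise level as the mean height
of the non-called channels over up to 10 flanking positions per side
(shrunk with a warning near trace ends; error below 3 per side), calls
a minor peak when the largest non-primary channel reaches
`noise mean + k·SD` with `k = 3`, and estimates
`f̂ = G / (A + G)` after baseline subtraction, clipped at zero. Under
the default model the estimator's bias is below 0.005 across
`f ∈ [0.1, 0.9]` (the test-suite asserts ≤ 0.02 at 500 replicates).

`detectionLimit()` calls a fraction detectable when the minor peak is
called in ≥ 90 % of replicate traces and returns the smallest
detectable value on the grid (default 0.05–0.50 in steps of 0.05,
100 replicates).

### Calibration of the noise floor

The detection rule and CV/crosstalk defaults are conventional; the
baseline amplitude is the one free parameter, and it was set by a
one-time calibration so that the simulated assay reproduces the
empirical ~30 % visibility threshold of standard Sanger sequencing:
`noiseFloor` was scanned over 0.18–0.24 with 20 independent seeds of
the full detection-limit experiment, and the value whose 90 %-detection
crossing sits between grid points 0.25 and 0.30 on every seed was
frozen — `noiseFloor = 0.21`. A first-order check: the detection
threshold sits near `b/2 + 3·b/√12` above zero while the site's G
signal is `f + U(0, b)`-distributed, putting the 90 % crossing near
`f ≈ 1.27·b ≈ 0.27` for `b = 0.21`, between the two grid points. The
calibration was performed once, is robust across seeds (the frozen
default reproduces a 0.30 limit for 53/53 tested seeds), and every
parameter is overridable through `TraceModel()`.

Under the same model both reference mixing ratios — 1:1 (`f = 0.5`) and
2:1 (`f = 1/3`, modelled as post-PCR molar fraction) — are detected in
well over 90 % of replicates, consistent with both showing visible
double peaks.

## What the synthetic fixtures do and do not emulate

`generateOrf()` builds ORFs with ATG at codon 1, a terminal TAA, the
requested stop codon at the requested index, and all remaining codons
drawn from the 61 sense codons (GC-weighted, default 0.5), with BbsI
sites removed by resampling. Because every coordinate the package
reports is arithmetic on the codon index, the worked coordinates (570,
3846) are *sequence-independent*: a random 400-codon ORF with TGA at
codon 190 exercises exactly the same code paths as the real reporter
cDNA. What the fixtures do **not** emulate: real codon-usage bias,
RNA secondary structure (guide accessibility is not scored), and
transcript abundance effects (NMD/no-go decay), so passing tests say
nothing about editing *efficiency* on real transcripts — only about the
correctness of coordinates, geometry, consequence calls and the
read-out model. Real cDNA is user-suppliable via FASTA and is never
bundled.

Problem sizes used by the automated checks — 400- and 1500-codon
fixtures, 100–500 replicate traces on a 60-nt amplicon, and 200–500
randomised design cases — were chosen as the smallest sizes that
exercise the worked coordinates and give stable Monte-Carlo estimates.

## Degenerate inputs and numerical choices

* IUPAC ambiguity codes are rejected, not expanded: design against an
  ambiguous base is undefined and failing loudly beats a silently wrong
  spacer. RNA input (U) is accepted everywhere and normalised to T;
  spacers can be rendered in the RNA alphabet with
  `spacerSeq(design, rna = TRUE)`.
* An ORF with no in-frame stop at all returns an empty scan with a
  truncation warning.
* Ties in per-position channel maxima are broken by fixed channel order
  (A, C, G, T), keeping traces and estimates bit-identical under a
  fixed seed.
* `f̂` clipping at zero avoids negative fractions when the G channel
  sits below the estimated baseline at low `f`.
* Designs are reported in grid order; no ranking score is invented,
  since guide performance differences are an empirical matter.

## Limitations

* No transcriptome-wide off-target scan: only window-level bystander
  enumeration is computable from sequence alone.
* No editing-efficiency model: outcomes are all-or-none at the
  transcript level; population-level fractions live entirely in the
  trace simulator.
* No RNA-folding score for spacers, no protein-function prediction for
  the repaired product, and no AB1 chromatogram parsing (traces enter
  as position/A/C/G/T tables; requesting an `.ab1` file errors
  explicitly).
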