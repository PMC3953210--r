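---
title: "Discovering balanced rearrangements from mate-pair read clusters"
author: "svpairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering balanced rearrangements from mate-pair read clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpairs)
```

## The discovery model

A mate-pair library circularises genomic fragments of roughly one insert
length (here ~5 kb) and sequences the joined ends as a short read pair.
After alignment to the reference, a pair from an unrearranged region is
*concordant*: both reads on one chromosome, outer span close to the insert
length, strands in the library's expected order (outward-facing "RF" after
circularisation). A rearrangement junction crossed by the fragment breaks
one of these properties, and each rearrangement class leaves a
characteristic signature:

* **deletion** — concordant strand order but a span exceeding the distance
  cutoff, because the fragment silently skips the deleted bases;
* **inversion** — both reads on the same reference strand (`++` near one
  junction, `--` near the other), because one read lies inside the
  inverted segment;
* **translocation** — reads on different chromosomes; a *reciprocal*
  exchange produces two junctions with complementary strand signatures.

The caller therefore works junction-by-junction: classify pairs, cluster
the discordant ones, demand a minimum number of independent fragments per
cluster, and reconstruct each junction's breakpoints from read geometry.
Its core statistical assumption is that fragments sample the derived
genome roughly uniformly, so the number of pairs spanning any junction is
about the spanning coverage `n_pairs × insert / genome_size`; with ~25-fold
spanning coverage a 6-pair support threshold is met with large margin by
real junctions and essentially never by scattered artefacts.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `median_insert` / estimated median | estimated | bp | sets the scale of every distance rule; estimated as the median outer span (`posB − posA + read_length`) of concordant pairs, excluding spans above 10× the kit nominal |
| cutoff | 2 × median | bp | a pair is `long_span` beyond it; it also bounds cluster linkage and the refined-interval width. A 5 kb library gives ~10 kb, hence the ">10 kb" sensitivity floor for intra-chromosomal events |
| `min_support` | 6 | pairs | clusters below it are discarded (and logged); the sharpness of this threshold is tested explicitly |
| `mapq_threshold` | 20 | phred | pairs with a low-quality end are set aside before clustering; short-read aligners misplace reads in repeats and this is the only guard the pipeline has |
| `orientation` | `"RF"` | — | concordant strand convention of the preparation; every strand-based rule (classification, junction direction, contaminant detection) derives from it, and `"FR"` flips them all consistently |
| `min_reciprocal_overlap` | 0.5 | fraction | call-set matching criterion for validation |

## Breakpoint-interval refinement

Every supporting read constrains its junction twice: the read must lie
entirely on the retained flank, and its fragment must still fit within the
library bound (taken as the cutoff). Under RF a `-` read is the fragment's
left end, so the junction lies to its right; with reads starting at
positions `p` and read length `L` the junction's reference coordinate lies
in `[max(p) + L, min(p) + cutoff]`, and mirrored for right-flank sides.
The interval is the intersection over members, so its width is at most the
cutoff and never grows as support accumulates.

The reported coordinate convention is the *departure base*: the first
reference base, approached along the supporting reads, that is no longer
shared with the derived chromosome. The simulator writes its ground-truth
junction table in the same convention, so recovery tests compare like with
like. For a deletion the two departure bases are exactly the first and
last deleted base. When two clusters merge into one inversion or
reciprocal-translocation call, the call's interval is the envelope of the
two clusters' intervals: the two junctions of a balanced event sit on
opposite flanks of each breakpoint, so the envelope (unlike the
intersection) provably contains the planted coordinate from both sides.

Breakpoint *point* estimates are interval midpoints. Spans are
`|bp2 − bp1|` over those estimates, which for a deletion is biased a few
kilobases low relative to the true event size; validated base-pair
positions (e.g. from sequencing a junction amplicon) can be substituted
with `apply_breakpoint_overrides()`, after which spans are exact. Spans
are always reported from coordinates, never from rounded prose.

## Junction micro-indels

Capillary sequence across a junction is reconciled against the two
reference flanks by maximal exact extension (`junction_delta()`): the
signed length difference distinguishes balanced joins, small losses and
duplications where the same base appears on both derivatives. Gains are
called duplications only when the extra sequence copies a flank adjacent
to the junction; anything else is reported as a novel insertion. At least
10 bp must match each flank or the junction is rejected as not belonging
to those references.

## What the simulator emulates — and what it does not

`apply_sv_plan()` builds derivative chromosomes as ordered reference
segments (forward or inverted), applying planted SVs in list order with
reference-coordinate breakpoints, and supports ±10 bp junction indels
applied on the derived strand at each junction's left side. The liftover
map is exact and is verified in the tests against an independent per-base
walk oracle. `simulate_pairs()` then draws fragments uniformly over the
derived genome with log-normal insert lengths (median `m`, sd `s`;
`meanlog = log m`, `sdlog` solved in closed form from
`s² = m² t(t−1)`, `t = e^{sdlog²}`), truncated to
`[2 × read_length, 4 × median]` by rejection. Sequencing reports for such
libraries typically state only the median insert, so the default
dispersion (500 bp, ~10% CV) is a modelling choice typical of 5 kb
preparations, not a claim about any particular dataset.

Two deliberate simplifications matter for interpreting green tests:

* Reads that straddle a derived-segment boundary are dropped, emulating a
  short-read aligner that cannot place junction-spanning 36-mers. Real
  aligners sometimes *mis*place such reads instead; the simulator never
  produces misaligned coordinates, so the tests do not probe
  repeat-driven false clusters, and on real data the mapping-quality
  filter has to carry that weight.
* Contaminating non-mate-pair fragments are modelled as short-insert
  pairs with the opposite (inward-facing) orientation — the signature of
  paired-end chemistry surviving mate-pair enrichment. After
  canonicalisation they classify as `orientation_aberrant` with an
  *everted* strand order, and because clustering keys on the strand
  signature they can never merge with inversion (`++`/`--`) or deletion
  clusters. Everted clusters are discarded at typing with reason
  `everted_orientation` in the curation log; this is what keeps the
  SV-free specificity suite at zero calls under 5% contamination. The
  price is that true tandem duplications, which share the everted
  signature, are out of scope here (as is read-depth CNV calling
  generally).

Uniform sampling also means no GC or chimera bias, no PCR duplicates
beyond exact-coordinate collisions, and mapping quality fixed at 37 —
duplicate marking and the `low_quality` path are exercised by constructed
records instead.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere inside the package; BED
  and BEDPE convert to 0-based half-open only in the writers/readers, VCF
  stays 1-based. Cytoband files (0-based half-open) become 1-based closed
  bands with boundary ties going to the earlier band.
* Classification precedence is fixed (`duplicate > low_quality >
  interchromosomal > long_span > orientation_aberrant > concordant`) so
  the function is total and order-independent; pairs with identical end
  coordinates and strands are collapsed before support counting.
* "Overlapping" read pairs are interpreted as single linkage with the
  cutoff on both ends; the implementation is tested for exact agreement
  with a brute-force connected-components oracle. Reciprocal merging
  resolves ties by the smallest combined interval distance.
* A single-linkage chain can grow wider than the cutoff, making the
  per-member interval intersection empty; refinement then falls back to
  the innermost member's own bound and flags the cluster `chained`. In
  practice only everted contaminant chains trigger this.
* Gene annotation uses one transcript per gene (the longest), numbering
  exons 5′→3′ on the coding strand; a breakpoint interval's midpoint
  decides the primary label while all overlapping genes are retained.
  Fusion prediction works at exon granularity and does not assess reading
  frame.
* The everted-cluster discard plus per-cluster reason codes replace the
  interactive curation a human would apply; every decision is in the JSON
  curation log.

## Problem sizes used by the tests and scripts

The recovery study simulates a 2 × 10 Mb genome carrying one 15 kb
deletion, one pericentric and one paracentric inversion and one reciprocal
translocation with 1 bp junction indels, sequenced to 100,000 pairs
(25-fold spanning coverage) with 2% contamination, across five seeds; the
specificity suite runs twenty SV-free seeds at 20,000 pairs; the
clustering oracle runs fifty random instances of up to 300 discordant
pairs. These sizes give every junction ~25 spanning fragments — the same
support regime as a genome-scale 28-million-pair library — while keeping
the whole suite fast on a laptop.

## Known limitations

* The theoretical spanning depth is reported as the plain formula
  `n_pairs × median_insert / genome_size` with no hidden filtering;
  28.2 M pairs × 5,012 bp over GRCh37 gives ≈45.7-fold. Published
  spanning-depth figures sometimes apply unstated read filtering first
  and can be substantially lower; this package deliberately reports the
  unfiltered arithmetic.
* Breakpoint resolution is bounded by the insert distribution (intervals
  of a few kb at 20–30× junction support); base-pair precision requires
  junction amplicon sequencing, which enters via breakpoint overrides.
* Events smaller than the cutoff (~10 kb) are invisible by construction,
  and insertions, tandem duplications and copy-number changes are out of
  scope.
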