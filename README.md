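# svpairs — structural-variant discovery from mate-pair read clusters

Balanced chromosome abnormalities (BCAs) — reciprocal translocations and
inversions without net gain or loss of material — disrupt genes in a
substantial fraction of carriers but are invisible to read-depth CNV
analysis and poorly resolved by karyotyping. Long-insert *mate-pair*
libraries solve this cheaply: distant genomic ends (~5 kb apart) are
circularised and sequenced as a read pair, so even a shallow library gives
each genomic position a high *spanning coverage*
(`n_pairs × insert / genome_size`), and any rearrangement junction is
crossed by many inserts whose read pairs then align discordantly.

`svpairs` is an R implementation of this discovery strategy for people who
want a tested, scriptable caller and a fully synthetic test-bed:

* **Classification.** Each aligned pair is classified with fixed precedence
  (`duplicate > low_quality > interchromosomal > long_span >
  orientation_aberrant > concordant`). The distance cutoff is `2 × median
  insert` estimated from the concordant pairs (a 5 kb library gives a
  ~10 kb cutoff).
* **Clustering.** Discordant pairs cluster by single linkage within a
  signature (chromosome pair, strand pair); two pairs link iff both end
  positions fall within the cutoff. Clusters need **≥ 6 supporting pairs**;
  everything discarded is logged with a machine-readable reason (the
  replacement for manual curation).
* **Breakpoint refinement.** Each cluster side gets the interval
  `[max(p)+L, min(p)+cutoff]` (junction right of the reads) or its mirror
  — the intersection of every member's geometric constraint, guaranteed to
  contain the junction and at most one cutoff wide.
* **Typing.** Long-span clusters in concordant orientation are deletions;
  `++`/`--` clusters are inversion junctions (merged pairwise, classed
  pericentric when the centromere lies between the breakpoints);
  complementary inter-chromosomal clusters merge into reciprocal
  translocations. `span = |bp2 − bp1|` over the breakpoint point estimates
  (validated positions can be substituted).
* **Annotation.** Intron/exon localisation in transcript order, fusion
  prediction (a fusion is emitted only when one gene's 5′ portion
  transcribes *into* the junction and the other's 3′ portion *out* of it),
  ISCN-style karyotype tokens such as `t(2;7)(p25.1;q33)`, and a
  per-breakpoint disrupted-gene report.
* **Metrics.** Spanning coverage, flow-sort chromosome enrichment folds,
  and call-set validation at ≥ 0.5 reciprocal overlap.
* **Simulator.** Derivative chromosomes built from planted SVs (deletions,
  inversions, reciprocal translocations, ±bp junction indels) with an
  exact liftover map and ground-truth junction table; mate pairs drawn
  from a truncated log-normal insert distribution with configurable
  short-insert contamination. Every caller stage is tested against it.

## Worked example

```r
library(svpairs)

ref <- toy_reference(c(chr1 = 10e6, chr2 = 10e6),
                     centromeres = data.frame(chrom = c("chr1", "chr2"),
                                              start = c(4.5e6, 4.8e6),
                                              end   = c(5.0e6, 5.2e6)))
plan <- apply_sv_plan(ref, list(
  planted_sv("deletion", "chr1", 1000000, 1015000),
  planted_sv("inversion", "chr1", 6000000, 7500000),
  planted_sv("inversion", "chr2", 3000000, 8000000),
  planted_sv("reciprocal_translocation", "chr1", 2500000, posB = 9200000,
             chromB = "chr2", junction_indel = c(1L, -1L))))
pairs <- simulate_pairs(plan, library_model(median_insert = 5000,
                                            n_pairs = 100000L,
                                            contamination_fraction = 0.02,
                                            seed = 7L))
res <- call_svs(pairs, pipeline_config(), ref$centromeres)
res
```

```
sv_callset: 4 call(s) from 80 retained cluster(s); 722 cluster(s) discarded
insert_stats: median 4,998 bp (MAD 334, n = 97864), cutoff 9,996 bp
  call_id                  sv_type chrom1    pos1 chrom2    pos2 support
1    sv01                 deletion   chr1 1002529   chr1 1012509      21
2    sv02 reciprocal_translocation   chr1 2500337   chr2 9200087      56
3    sv03                inversion   chr1 5999931   chr1 7499998      46
4    sv04                inversion   chr2 3000018   chr2 7999939      44
     span inversion_class
1    9980            <NA>
2      NA            <NA>
3 1500067     paracentric
4 4999921     pericentric
```

All four planted events come back with the right type, the pericentric /
paracentric split is decided by the centromere intervals, the true
junctions lie inside every reported confidence interval, and the ~2,000
contaminant pairs end up discarded in the curation log (reason
`everted_orientation`) rather than in the call set. Support counts are the
number of junction-spanning read pairs, i.e. roughly the spanning
coverage per junction (two junctions for the merged inversion and
translocation calls).

The same flow, split into narrative stages that write their tables under
`results/`, is in `analysis/01_simulate.R` … `analysis/04_validate.R`.

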