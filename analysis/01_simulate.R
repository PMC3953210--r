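#!/usr/bin/env Rscript
# Stage 1 — build the rearranged study genome and its mate-pair library.
#
# A two-chromosome 20 Mb toy genome carries the four rearrangement classes
# under study: a 15 kb deletion, a pericentric and a paracentric inversion,
# and a reciprocal translocation with 1 bp junction indels (one base
# duplicated on one derivative, one base lost on the other). The library
# emulates a 5 kb-median mate-pair preparation read as 2 x 36 bp with 2%
# short-insert paired-end contamination.

suppressPackageStartupMessages(library(svpairs))
dir.create("results", showWarnings = FALSE)
seed <- 1L

ref <- toy_reference(c(chr1 = 10e6, chr2 = 10e6),
                     centromeres = data.frame(chrom = c("chr1", "chr2"),
                                              start = c(4.5e6, 4.8e6),
                                              end = c(5.0e6, 5.2e6)))
planted <- list(
  planted_sv("deletion", "chr1", 1000000, 1015000),
  planted_sv("inversion", "chr1", 6000000, 7500000),       # paracentric
  planted_sv("inversion", "chr2", 3000000, 8000000),       # pericentric
  planted_sv("reciprocal_translocation", "chr1", 2500000, posB = 9200000,
             chromB = "chr2", junction_indel = c(1L, -1L)))
plan <- apply_sv_plan(ref, planted)

message("planted ", length(planted), " SVs -> ", nrow(plan$junctions),
        " derived junctions")
print(plan$junctions)

lib <- library_model(median_insert = 5000, insert_sd = 500,
                     n_pairs = 100000L, contamination_fraction = 0.02,
                     seed = seed)
pairs <- simulate_pairs(plan, lib)
message("simulated ", nrow(pairs), " aligned pairs (",
        sum(pairs$source_tag == "contaminant"), " contaminants)")

write_pairs(pairs, "results/pairs.tsv", "tsv")
write_truth(plan, "results/truth_junctions.bedpe", "results/truth_plan.json")
message("wrote results/pairs.tsv, results/truth_junctions.bedpe, ",
        "results/truth_plan.json")
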