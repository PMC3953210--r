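# Fusion-transcript prediction from junction adjacencies.

# Enumerate the junctions of a call as breakend pairs. `orient*` gives the
# retained flank at each breakpoint for junction 1; a two-junction call
# (reciprocal translocation, inversion) has a second junction joining the
# complementary flanks at the same positions.
call_junctions <- function(call) {
  flip <- function(o) ifelse(o == "tail", "head", "tail")
  j1 <- data.frame(jct = 1L, chrom1 = call$chrom1, pos1 = call$pos1,
                   orient1 = call$orient1, chrom2 = call$chrom2,
                   pos2 = call$pos2, orient2 = call$orient2)
  if (call$n_junctions == 2L) {
    j2 <- data.frame(jct = 2L, chrom1 = call$chrom1, pos1 = call$pos1,
                     orient1 = flip(call$orient1), chrom2 = call$chrom2,
                     pos2 = call$pos2, orient2 = flip(call$orient2))
    rbind(j1, j2)
  } else j1
}

exon_range_label <- function(from, to) {
  if (from == to) sprintf("ex%d", from) else sprintf("ex%d-%d", from, to)
}

#' Predict fusion transcripts for a structural-variant call
#'
#' Reconstructs the derived-strand adjacency at every junction of the call
#' and emits a fusion product when, and only when, transcription can run in
#' one direction through the junction: one disrupted gene must contribute
#' its 5' portion transcribing *towards* the junction and the other its 3'
#' portion transcribing *away* from it. A gene whose retained flank is the
#' reference bases before the breakpoint (`"tail"`) transcribes towards
#' the junction iff it lies on the plus strand; with the `"head"` flank
#' retained, iff it lies on the minus strand. Reciprocal translocations
#' and inversions carry two junctions and can so yield up to two
#' (reciprocal) products; genes oriented head-to-head or tail-to-tail
#' across a junction yield none.
#'
#' Retained exons are reported at exon granularity in transcript order —
#' always a prefix of the 5' gene and a suffix of the 3' gene. Reading
#' frame is not assessed.
#'
#' @param calls one or more call rows from [type_svs()] (ideally with
#'   validated breakpoints via [apply_breakpoint_overrides()]).
#' @param genes a `gene_set`.
#' @return data.frame with one row per predicted fusion: `call_id`, `jct`,
#'   `five_gene`, `five_exons`, `three_gene`, `three_exons`, `label`,
#'   `orientation_compatible` (always `TRUE` for emitted rows); zero rows
#'   when no junction is orientation-compatible.
#' @export
predict_fusions <- function(calls, genes) {
  stopifnot(inherits(genes, "gene_set"))
  rows <- list()
  for (r in seq_len(nrow(calls))) {
    call <- calls[r, ]
    jx <- call_junctions(call)
    for (k in seq_len(nrow(jx))) {
      annA <- locate_breakpoint(genes, jx$chrom1[k], jx$pos1[k])
      annB <- locate_breakpoint(genes, jx$chrom2[k], jx$pos2[k])
      if (annA$region == "intergenic" || annB$region == "intergenic") next
      role <- function(ann, orient) {
        towards <- (orient == "tail" & ann$strand == "+") |
                   (orient == "head" & ann$strand == "-")
        if (towards) "donor" else "acceptor"
      }
      roleA <- role(annA, jx$orient1[k])
      roleB <- role(annB, jx$orient2[k])
      if (roleA == roleB) next   # head-to-head or tail-to-tail: no mRNA
      don <- if (roleA == "donor") annA else annB
      acc <- if (roleA == "donor") annB else annA
      # donor keeps its transcript prefix up to the breakpoint
      don_last <- don$number          # intron k -> exons 1..k; exon k partial
      acc_first <- if (acc$region == "intron") acc$number + 1L else acc$number
      if (don_last < 1L || acc_first > acc$n_exons) next
      five_lab <- exon_range_label(1L, don_last)
      three_lab <- exon_range_label(acc_first, acc$n_exons)
      rows[[length(rows) + 1L]] <- data.frame(
        call_id = call$call_id %||% NA_character_, jct = jx$jct[k],
        five_gene = don$gene_name, five_exons = five_lab,
        three_gene = acc$gene_name, three_exons = three_lab,
        label = paste0(don$gene_name, five_lab, "_", acc$gene_name, three_lab),
        orientation_compatible = TRUE)
    }
  }
  if (!length(rows))
    return(data.frame(call_id = character(0), jct = integer(0),
                      five_gene = character(0), five_exons = character(0),
                      three_gene = character(0), three_exons = character(0),
                      label = character(0), orientation_compatible = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
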