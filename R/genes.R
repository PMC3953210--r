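# Gene models: one (longest) transcript per gene, with ordered exons.

#' Construct a gene model
#'
#' @param gene_id stable identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based inclusive exon intervals in
#'   ascending genomic order; exons must not overlap. Exon numbering used in
#'   annotation follows transcript (5' to 3') order, i.e. it is reversed on
#'   the minus strand.
#' @param gene_name display name (defaults to `gene_id`).
#' @param biotype `"protein_coding"`, `"non_coding"` or `"pseudogene"`.
#' @return one-row data.frame usable with [gene_set()].
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       gene_name = gene_id,
                       biotype = c("protein_coding", "non_coding",
                                   "pseudogene")) {
  biotype <- match.arg(biotype)
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1)
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (any(exon_ends < exon_starts)) stopf("exon end before start")
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(utils::head(exon_ends, -1) >= utils::tail(exon_starts, -1)))
    stopf("exons must be sorted and non-overlapping")
  out <- data.frame(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                    strand = strand, start = exon_starts[1],
                    end = exon_ends[length(exon_ends)], biotype = biotype,
                    n_exons = length(exon_starts))
  out$exon_starts <- list(exon_starts)
  out$exon_ends <- list(exon_ends)
  class(out) <- c("gene_set", "data.frame")
  out
}

#' Combine gene models into a gene set
#'
#' @param ... [gene_model()] rows (or an existing gene set).
#' @return data.frame of class `gene_set`.
#' @export
gene_set <- function(...) {
  out <- do.call(rbind, list(...))
  if (anyDuplicated(out$gene_id)) stopf("duplicated gene_id")
  rownames(out) <- NULL
  class(out) <- c("gene_set", "data.frame")
  out
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand)
}

#' Read gene models from GFF3 or BED12
#'
#' Uses rtracklayer for parsing. For GFF3, exons are grouped by transcript
#' (`Parent`) and the longest transcript per gene is kept, matching a
#' one-transcript-per-gene annotation report; features without transcript
#' parents fall back to exons grouped directly under the gene. For BED12,
#' each record is a transcript whose blocks are its exons; the longest
#' record per `name` is kept.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return a `gene_set` data.frame.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12"
              else "gff3"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$blocks)) stopf("BED file lacks block (exon) structure")
    width_of <- GenomicRanges::width(gr)
    keep <- !duplicated(gr$name) | TRUE  # resolved below per name
    df <- data.frame(name = gr$name, width = width_of, idx = seq_along(gr))
    best <- do.call(rbind, lapply(split(df, df$name), function(d)
      d[which.max(d$width), , drop = FALSE]))
    rows <- lapply(best$idx, function(i) {
      blocks <- gr$blocks[[i]]  # relative to the record start
      abs_start <- GenomicRanges::start(gr)[i] + IRanges::start(blocks) - 1L
      abs_end <- GenomicRanges::start(gr)[i] + IRanges::end(blocks) - 1L
      gene_model(gr$name[i], as.character(GenomicRanges::seqnames(gr))[i],
                 as.character(GenomicRanges::strand(gr))[i],
                 abs_start, abs_end)
    })
    return(do.call(gene_set, rows))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- GenomicRanges::mcols(gr)
  type <- as.character(md$type)
  first_chr <- function(x) if (length(x)) as.character(x)[1] else NA_character_
  exons <- gr[type == "exon"]
  if (!length(exons)) stopf("GFF3 contains no exon features")
  parent <- vapply(GenomicRanges::mcols(exons)$Parent, first_chr, character(1))
  genes <- gr[type == "gene"]
  gene_ids <- if (length(genes)) {
    ids <- GenomicRanges::mcols(genes)$ID
    if (is.null(ids)) GenomicRanges::mcols(genes)$gene_id else ids
  } else character(0)
  tx <- gr[type %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA",
                       "pseudogenic_transcript")]
  rows <- list()
  if (length(tx)) {
    tx_id <- as.character(GenomicRanges::mcols(tx)$ID)
    tx_parent <- vapply(GenomicRanges::mcols(tx)$Parent, first_chr, character(1))
    for (g in unique(tx_parent)) {
      cand <- which(tx_parent == g)
      best <- cand[which.max(GenomicRanges::width(tx)[cand])]
      ex <- exons[parent == tx_id[best]]
      ex <- sort(ex)
      gi <- which(gene_ids == g)
      bt <- if (length(gi)) first_chr(GenomicRanges::mcols(genes)$biotype[gi]) else NA
      nm <- if (length(gi)) first_chr(GenomicRanges::mcols(genes)$Name[gi]) else NA
      rows[[length(rows) + 1L]] <- gene_model(
        g, as.character(GenomicRanges::seqnames(ex))[1],
        as.character(GenomicRanges::strand(ex))[1],
        GenomicRanges::start(ex), GenomicRanges::end(ex),
        gene_name = if (is.na(nm)) g else nm,
        biotype = if (is.na(bt) || !bt %in% c("protein_coding", "non_coding",
                                              "pseudogene"))
          "protein_coding" else bt)
    }
  } else {
    for (g in unique(parent)) {
      ex <- sort(exons[parent == g])
      rows[[length(rows) + 1L]] <- gene_model(
        g, as.character(GenomicRanges::seqnames(ex))[1],
        as.character(GenomicRanges::strand(ex))[1],
        GenomicRanges::start(ex), GenomicRanges::end(ex))
    }
  }
  do.call(gene_set, rows)
}

#' Locate a breakpoint relative to gene models
#'
#' Deterministic exon/intron annotation in transcript order: for a gene
#' whose genomic exons (ascending) are `e1..eN`, a breakpoint in genomic
#' exon `i` is `exon i` on the plus strand and `exon N - i + 1` on the
#' minus strand; a breakpoint between genomic exons `i` and `i + 1` is
#' `intron i` (plus) or `intron N - i` (minus). Breakpoints overlapping
#' several genes report all of them, with the longest transcript as the
#' primary annotation. Intergenic breakpoints report the nearest gene, the
#' distance to it, and whether the breakpoint lies upstream or downstream
#' of it relative to its strand.
#'
#' @param genes a `gene_set`.
#' @param chrom,pos breakpoint coordinate (1-based).
#' @return list of class `breakpoint_annotation` with fields `chrom`,
#'   `pos`, `gene_id`, `gene_name`, `strand`, `region` (`"exon"`,
#'   `"intron"` or `"intergenic"`), `number` (transcript-order index),
#'   `label` (e.g. `"intron7"`), `n_exons`, `hits` (all overlapping gene
#'   ids), and for intergenic sites `nearest_gene`, `distance`,
#'   `relative` (`"upstream"`/`"downstream"`).
#' @export
locate_breakpoint <- function(genes, chrom, pos) {
  stopifnot(inherits(genes, "gene_set"))
  pos <- as.integer(pos)
  gr <- gene_granges(genes)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  hit_idx <- S4Vectors::subjectHits(ov)
  out <- list(chrom = chrom, pos = pos, hits = genes$gene_id[hit_idx])
  if (!length(hit_idx)) {
    on_chrom <- which(genes$chrom == chrom)
    if (!length(on_chrom)) {
      out <- c(out, list(gene_id = NA_character_, gene_name = NA_character_,
                         strand = NA_character_, region = "intergenic",
                         number = NA_integer_, label = "intergenic",
                         n_exons = NA_integer_, nearest_gene = NA_character_,
                         distance = NA_integer_, relative = NA_character_))
      class(out) <- "breakpoint_annotation"
      return(out)
    }
    d <- pmax(genes$start[on_chrom] - pos, pos - genes$end[on_chrom], 0L)
    k <- on_chrom[which.min(d)]
    before <- pos < genes$start[k]
    relative <- if (genes$strand[k] == "+") {
      if (before) "upstream" else "downstream"
    } else {
      if (before) "downstream" else "upstream"
    }
    out <- c(out, list(gene_id = NA_character_, gene_name = NA_character_,
                       strand = NA_character_, region = "intergenic",
                       number = NA_integer_, label = "intergenic",
                       n_exons = NA_integer_,
                       nearest_gene = genes$gene_id[k],
                       distance = as.integer(min(d)), relative = relative))
    class(out) <- "breakpoint_annotation"
    return(out)
  }
  primary <- hit_idx[which.max(genes$end[hit_idx] - genes$start[hit_idx])]
  g <- genes[primary, ]
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  N <- length(es)
  in_exon <- which(pos >= es & pos <= ee)
  if (length(in_exon)) {
    i <- in_exon[1]
    k <- if (g$strand == "+") i else N - i + 1L
    region <- "exon"
  } else {
    i <- max(which(ee < pos))  # genomic intron i: between exons i and i+1
    k <- if (g$strand == "+") i else N - i
    region <- "intron"
  }
  out <- c(out, list(gene_id = g$gene_id, gene_name = g$gene_name,
                     strand = g$strand, region = region,
                     number = as.integer(k),
                     label = paste0(region, k), n_exons = as.integer(N),
                     nearest_gene = g$gene_id, distance = 0L,
                     relative = NA_character_))
  class(out) <- "breakpoint_annotation"
  out
}

#' @export
print.breakpoint_annotation <- function(x, ...) {
  cat(sprintf("%s:%s -> %s%s\n", x$chrom, format(x$pos, big.mark = ","),
              if (x$region == "intergenic")
                sprintf("intergenic (nearest %s, %s bp %s)",
                        x$nearest_gene, format(x$distance, big.mark = ","),
                        x$relative)
              else sprintf("%s of %s", x$label, x$gene_name), ""))
  invisible(x)
}
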