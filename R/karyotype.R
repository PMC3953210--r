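# Cytoband lookup and ISCN-style karyotype assembly.

#' Read a UCSC cytoBand file
#'
#' Five tab-separated columns (chrom, chromStart, chromEnd, band, stain) in
#' 0-based half-open coordinates, converted internally to 1-based closed
#' intervals so each chromosome is partitioned with ties at a boundary
#' going to the earlier band.
#'
#' @param path cytoBand.txt-format file (no header).
#' @return data.frame of class `cytoband_map` with columns `chrom`,
#'   `start`, `end`, `band`, `stain`.
#' @export
read_cytobands <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "band",
                                        "stain"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"))
  tb$start <- tb$start + 1L
  tb <- tb[chrom_order(tb$chrom, tb$start), , drop = FALSE]
  rownames(tb) <- NULL
  class(tb) <- c("cytoband_map", "data.frame")
  tb
}

#' Cytoband map from a data.frame
#'
#' Convenience constructor for tests and toy maps; intervals are 1-based
#' closed and must partition each chromosome.
#' @param df data.frame with columns `chrom`, `start`, `end`, `band` (and
#'   optionally `stain`).
#' @return a `cytoband_map`.
#' @export
cytoband_map <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "band") %in% names(df)))
  if (is.null(df$stain)) df$stain <- "gneg"
  df <- df[chrom_order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] != d$end[-nrow(d)] + 1L))
      stopf("bands do not partition chromosome %s", ch)
  }
  rownames(df) <- NULL
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Band name at a genomic position
#'
#' @param cytobands a `cytoband_map`.
#' @param chrom,pos position(s); vectors are recycled to equal length.
#' @return character vector of band names; error if the chromosome is not
#'   covered by the map, `NA` (with a warning) if the position falls
#'   outside the banded extent.
#' @export
band_for_position <- function(cytobands, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(as.integer(pos), n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    d <- cytobands[cytobands$chrom == ch, , drop = FALSE]
    if (!nrow(d)) stopf("cytoband map does not cover chromosome '%s'", ch)
    sel <- which(chrom == ch)
    i <- findInterval(pos[sel], d$start)
    ok <- i >= 1 & pos[sel] <= d$end[pmax(i, 1)]
    out[sel[ok]] <- d$band[i[ok]]
  }
  if (anyNA(out)) warnf("position outside the banded extent of its chromosome")
  out
}

chrom_label <- function(chrom) sub("^chr", "", chrom)

#' Assemble an ISCN-style revised karyotype
#'
#' One token per call — `t(a;b)(bandA;bandB)` for translocations (lower
#' chromosome first), `inv(c)(band1band2)` for inversions and
#' `del(c)(band1band2)` (collapsed to one band when both breakpoints share
#' it) for deletions — joined after the supplied base karyotype, sorted by
#' chromosome then position. A failed band lookup degrades that token to
#' coordinate form with a warning.
#'
#' @param calls call data.frame from [type_svs()].
#' @param cytobands a `cytoband_map`.
#' @param base_karyotype prefix such as `"46,XY"`.
#' @return list of class `karyotype_report`: `tokens` (data.frame
#'   `call_id`, `token`) and `karyotype` (the assembled string).
#' @export
karyotype_string <- function(calls, cytobands, base_karyotype = "46,XY") {
  if (!nrow(calls))
    return(structure(list(tokens = data.frame(call_id = character(0),
                                              token = character(0)),
                          karyotype = base_karyotype),
                     class = "karyotype_report"))
  band_or_na <- function(chrom, pos) {
    tryCatch(band_for_position(cytobands, chrom, pos),
             error = function(e) NA_character_,
             warning = function(w) NA_character_)
  }
  tokens <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    c1 <- calls$chrom1[i]; c2 <- calls$chrom2[i]
    p1 <- calls$pos1[i]; p2 <- calls$pos2[i]
    b1 <- band_or_na(c1, p1); b2 <- band_or_na(c2, p2)
    type <- calls$sv_type[i]
    if (is.na(b1) || is.na(b2)) {
      warnf("band lookup failed for %s; using coordinate form", calls$call_id[i])
      tokens[i] <- sprintf("%s(%s:%d;%s:%d)", switch(type,
        reciprocal_translocation = , translocation_junction = "t",
        inversion = "inv", deletion = "del"), c1, p1, c2, p2)
      next
    }
    if (type %in% c("reciprocal_translocation", "translocation_junction")) {
      if (chrom_before(c2, c1)) { tmp <- c1; c1 <- c2; c2 <- tmp
                                  tmp <- b1; b1 <- b2; b2 <- tmp }
      tokens[i] <- sprintf("t(%s;%s)(%s;%s)", chrom_label(c1), chrom_label(c2),
                           b1, b2)
    } else if (type == "inversion") {
      if (p2 < p1) { tmp <- b1; b1 <- b2; b2 <- tmp }
      tokens[i] <- sprintf("inv(%s)(%s%s)", chrom_label(c1), b1, b2)
    } else {
      if (p2 < p1) { tmp <- b1; b1 <- b2; b2 <- tmp }
      tokens[i] <- if (b1 == b2) sprintf("del(%s)(%s)", chrom_label(c1), b1)
                   else sprintf("del(%s)(%s%s)", chrom_label(c1), b1, b2)
    }
  }
  ord <- chrom_order(calls$chrom1, calls$pos1)
  structure(list(tokens = data.frame(call_id = calls$call_id, token = tokens),
                 karyotype = paste(c(base_karyotype, tokens[ord]),
                                   collapse = ",")),
            class = "karyotype_report")
}

#' @export
print.karyotype_report <- function(x, ...) {
  cat(x$karyotype, "\n")
  invisible(x)
}

#' Disrupted-gene report for a call set
#'
#' One row per breakpoint of every call: the revised karyotype token, the
#' breakpoint coordinate, the disrupted gene (or nearest-gene note), its
#' transcript interval and exon count, the intron/exon localisation, and
#' any fusion product predicted at that call.
#'
#' @param calls call data.frame from [type_svs()].
#' @param genes a `gene_set`.
#' @param cytobands optional `cytoband_map` for karyotype tokens.
#' @return data.frame report.
#' @export
disruption_report <- function(calls, genes, cytobands = NULL) {
  tokens <- if (!is.null(cytobands))
    karyotype_string(calls, cytobands)$tokens else NULL
  fus <- predict_fusions(calls, genes)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    tok <- if (!is.null(tokens)) tokens$token[i] else NA_character_
    fl <- fus$label[fus$call_id == calls$call_id[i]]
    fusion <- if (length(fl)) paste(fl, collapse = ";") else ""
    for (side in 1:2) {
      ch <- calls[[paste0("chrom", side)]][i]
      po <- calls[[paste0("pos", side)]][i]
      ann <- locate_breakpoint(genes, ch, po)
      tx <- if (ann$region == "intergenic") NA_character_ else {
        g <- genes[genes$gene_id == ann$gene_id, ]
        sprintf("%s:%d-%d", g$chrom, g$start, g$end)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sv_no = i, call_id = calls$call_id[i],
        revised_karyotype = tok,
        breakpoint = sprintf("%s:%d", ch, po),
        disrupted_gene = if (ann$region == "intergenic")
          sprintf("(intergenic; nearest %s)", ann$nearest_gene)
          else ann$gene_name,
        transcript_position = tx,
        exon_count = ann$n_exons,
        region = ann$label,
        fusion_mRNA = if (side == 1) fusion else "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
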