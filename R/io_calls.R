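# Call-set writers/readers: BEDPE, VCF (breakend notation), TSV report,
# curation log, and ground-truth exports for simulated plans.
# Internal coordinates are 1-based closed; BED-family output is 0-based
# half-open, VCF is 1-based.

bedpe_call_columns <- c("chrom1", "start1", "end1", "chrom2", "start2",
                        "end2", "name", "score", "strand1", "strand2",
                        "sv_type", "support", "span", "inversion_class",
                        "pos1", "pos2", "orient1", "orient2", "n_junctions")

fmt_num <- function(x) {
  out <- ifelse(is.na(x), ".",
                format(x, scientific = FALSE, trim = TRUE, justify = "none"))
  out
}

#' Write structural-variant calls
#'
#' Formats: `"bedpe"` (0-based half-open breakpoint intervals plus call
#' annotations, lossless for [read_calls_bedpe()]), `"vcf"` (VCF 4.2;
#' deletions and inversions as `SVTYPE=DEL/INV` records with `END` and
#' confidence intervals, translocation junctions as breakend (`BND`) mate
#' pairs with reciprocal `MATEID` links — a reciprocal translocation
#' yields four BND records), or `"report"` (the disrupted-gene TSV from
#' [disruption_report()]; requires `genes`).
#'
#' Output is deterministic: calls are written in (chrom1, pos1) order as
#' produced by [type_svs()].
#'
#' @param calls call data.frame from [type_svs()].
#' @param path output file.
#' @param format `"bedpe"`, `"vcf"` or `"report"`.
#' @param genes,cytobands passed to [disruption_report()] for
#'   `format = "report"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("bedpe", "vcf", "report"),
                        genes = NULL, cytobands = NULL) {
  format <- match.arg(format)
  if (format == "bedpe") return(write_calls_bedpe(calls, path))
  if (format == "vcf") return(write_calls_vcf(calls, path))
  if (is.null(genes)) stopf("format = 'report' requires gene models")
  rep <- disruption_report(calls, genes, cytobands)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_calls_bedpe <- function(calls, path) {
  mat <- data.frame(chrom1 = calls$chrom1, start1 = calls$ci1_lo - 1L,
                    end1 = calls$ci1_hi,
                    chrom2 = calls$chrom2, start2 = calls$ci2_lo - 1L,
                    end2 = calls$ci2_hi,
                    name = calls$call_id, score = calls$support,
                    strand1 = calls$strand1, strand2 = calls$strand2,
                    sv_type = calls$sv_type, support = calls$support,
                    span = fmt_num(calls$span),
                    inversion_class = ifelse(is.na(calls$inversion_class),
                                             ".", calls$inversion_class),
                    pos1 = calls$pos1, pos2 = calls$pos2,
                    orient1 = calls$orient1, orient2 = calls$orient2,
                    n_junctions = calls$n_junctions)
  lines <- c(paste0("#", paste(bedpe_call_columns, collapse = "\t")),
             if (nrow(mat))
               do.call(paste, c(unname(as.list(mat)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a call set from BEDPE
#'
#' Reads the BEDPE written by [write_calls()] back into the internal call
#' representation (1-based closed intervals); `write -> read -> write`
#' round-trips byte-identically.
#'
#' @param path BEDPE file.
#' @return call data.frame.
#' @export
read_calls_bedpe <- function(path) {
  lines <- readLines(path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t")[[1]]
  if (!identical(cols, bedpe_call_columns))
    stopf("unrecognised BEDPE header in %s", path)
  if (length(lines) < 2) return(empty_calls())
  tb <- utils::read.table(text = lines[-1], sep = "\t",
                          col.names = cols, colClasses = "character")
  data.frame(call_id = tb$name, sv_type = tb$sv_type,
             chrom1 = tb$chrom1, pos1 = as.integer(tb$pos1),
             ci1_lo = as.integer(tb$start1) + 1L,
             ci1_hi = as.integer(tb$end1),
             orient1 = tb$orient1, strand1 = tb$strand1,
             chrom2 = tb$chrom2, pos2 = as.integer(tb$pos2),
             ci2_lo = as.integer(tb$start2) + 1L,
             ci2_hi = as.integer(tb$end2),
             orient2 = tb$orient2, strand2 = tb$strand2,
             support = as.integer(tb$support),
             span = ifelse(tb$span == ".", NA_real_, suppressWarnings(
               as.numeric(tb$span))),
             inversion_class = ifelse(tb$inversion_class == ".",
                                      NA_character_, tb$inversion_class),
             n_junctions = as.integer(tb$n_junctions),
             cluster_ids = NA_character_)
}

bnd_alt <- function(orient_here, mate_chrom, mate_pos, mate_orient) {
  br <- if (mate_orient == "head") sprintf("[%s:%d[", mate_chrom, mate_pos)
        else sprintf("]%s:%d]", mate_chrom, mate_pos)
  if (orient_here == "tail") paste0("N", br) else paste0(br, "N")
}

write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svpairs",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
           "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
           "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
           sprintf("##contig=<ID=%s>",
                   unique(c(calls$chrom1, calls$chrom2))[
                     chrom_order(unique(c(calls$chrom1, calls$chrom2)))]),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  rec <- function(chrom, pos, id, alt, info)
    sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s", chrom, pos, id, alt, info)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    ci1 <- sprintf("CIPOS=%d,%d", cl$ci1_lo - cl$pos1, cl$ci1_hi - cl$pos1)
    if (cl$sv_type %in% c("deletion", "inversion")) {
      svt <- if (cl$sv_type == "deletion") "DEL" else "INV"
      info <- sprintf("SVTYPE=%s;END=%d;SUPPORT=%d;%s;CIEND=%d,%d",
                      svt, max(cl$pos1, cl$pos2), cl$support, ci1,
                      cl$ci2_lo - cl$pos2, cl$ci2_hi - cl$pos2)
      recs <- c(recs, rec(cl$chrom1, min(cl$pos1, cl$pos2), cl$call_id,
                          sprintf("<%s>", svt), info))
    } else {
      jx <- call_junctions(cl)
      for (k in seq_len(nrow(jx))) {
        idA <- sprintf("%s_J%d_A", cl$call_id, jx$jct[k])
        idB <- sprintf("%s_J%d_B", cl$call_id, jx$jct[k])
        infoA <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d", idB, cl$support)
        infoB <- sprintf("SVTYPE=BND;MATEID=%s;SUPPORT=%d", idA, cl$support)
        recs <- c(recs,
                  rec(jx$chrom1[k], jx$pos1[k], idA,
                      bnd_alt(jx$orient1[k], jx$chrom2[k], jx$pos2[k],
                              jx$orient2[k]), infoA),
                  rec(jx$chrom2[k], jx$pos2[k], idB,
                      bnd_alt(jx$orient2[k], jx$chrom1[k], jx$pos1[k],
                              jx$orient1[k]), infoB))
      }
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the curation log
#'
#' Machine-readable record of every cluster discarded by the pipeline and
#' why (sub-threshold support, everted orientation) — the package's
#' replacement for interactive curation of candidate clusters.
#'
#' @param curation the `curation` element of a [call_svs()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_curation_log <- function(curation, path) {
  jsonlite::write_json(curation, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export simulator ground truth
#'
#' Writes the planted junction table as BEDPE (one row per junction,
#' 0-based half-open single-base intervals at the per-side departure
#' coordinates) and the full plan (planted SVs, liftover segments,
#' junction table) as JSON.
#'
#' @param plan a [apply_sv_plan()] result.
#' @param bedpe_path,json_path output files (either may be `NULL`).
#' @return invisibly, a list with the paths written.
#' @export
write_truth <- function(plan, bedpe_path = NULL, json_path = NULL) {
  stopifnot(inherits(plan, "rearrangement_plan"))
  if (!is.null(bedpe_path)) {
    jx <- plan$junctions
    lines <- c("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore\torient1\torient2\tder_chrom",
               if (nrow(jx))
                 sprintf("%s\t%d\t%d\t%s\t%d\t%d\tjct%d\t0\t%s\t%s\t%s",
                         jx$chrom1, jx$departure1 - 1L, jx$departure1,
                         jx$chrom2, jx$departure2 - 1L, jx$departure2,
                         seq_len(nrow(jx)), jx$orient1, jx$orient2,
                         jx$der_chrom))
    writeLines(lines, bedpe_path)
  }
  if (!is.null(json_path)) {
    planted <- lapply(plan$planted, unclass)
    jsonlite::write_json(list(planted = planted,
                              der_lengths = as.list(plan$der_lengths),
                              segments = plan$segments,
                              junctions = plan$junctions),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(bedpe = bedpe_path, json = json_path))
}
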