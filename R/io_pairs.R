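# Read-pair table input/output: native 10-column TSV and SAM/BAM.

pair_columns <- c("pair_id", "chromA", "posA", "strandA", "mapqA",
                  "chromB", "posB", "strandB", "mapqB", "source_tag")

#' Write read pairs
#'
#' `"tsv"` writes the native 10-column pair table (plus the `duplicate`
#' flag). `"sam"` writes a coordinate-sorted SAM file with proper paired
#' flags (strand, mate strand, first/last of pair, duplicate) and the
#' source tag as `XT:Z:`; use `Rsamtools::asBam()` for BAM.
#'
#' @param pairs pair data.frame (see [simulate_pairs()]).
#' @param path output file.
#' @param format `"tsv"` or `"sam"`.
#' @param seqlengths named chromosome lengths for the SAM header; defaults
#'   to the `seqlengths` attribute of `pairs`.
#' @param read_length read length for CIGAR; defaults to the `read_length`
#'   attribute of `pairs` (else 36).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, format = c("tsv", "sam"),
                        seqlengths = NULL, read_length = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- pairs[, c(pair_columns,
                     intersect("duplicate", names(pairs))), drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  seqlengths <- seqlengths %||% attr(pairs, "seqlengths")
  if (is.null(seqlengths)) stopf("seqlengths required to write SAM")
  read_length <- read_length %||% attr(pairs, "read_length") %||% 36L
  dup <- if ("duplicate" %in% names(pairs)) pairs$duplicate else
    rep(FALSE, nrow(pairs))
  flag_of <- function(strand, mate_strand, first, dupf) {
    0x1 + ifelse(strand == "-", 0x10, 0) + ifelse(mate_strand == "-", 0x20, 0) +
      ifelse(first, 0x40, 0x80) + ifelse(dupf, 0x400, 0)
  }
  mk <- function(first) {
    me <- if (first) "A" else "B"; mt <- if (first) "B" else "A"
    data.frame(
      qname = pairs$pair_id,
      flag = flag_of(pairs[[paste0("strand", me)]],
                     pairs[[paste0("strand", mt)]], first, dup),
      rname = pairs[[paste0("chrom", me)]],
      pos = pairs[[paste0("pos", me)]],
      mapq = pairs[[paste0("mapq", me)]],
      cigar = sprintf("%dM", read_length),
      rnext = ifelse(pairs[[paste0("chrom", mt)]] ==
                       pairs[[paste0("chrom", me)]], "=",
                     pairs[[paste0("chrom", mt)]]),
      pnext = pairs[[paste0("pos", mt)]],
      tlen = 0L, seq = "*", qual = "*",
      xt = sprintf("XT:Z:%s", pairs$source_tag))
  }
  aln <- rbind(mk(TRUE), mk(FALSE))
  aln <- aln[order(chrom_key(aln$rname), aln$rname, aln$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  body <- do.call(sprintf,
                  c(list("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\t%s"),
                    aln))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read aligned read pairs
#'
#' Accepts the native tab-separated pair table or SAM/BAM (SAM is converted
#' with `Rsamtools::asBam()` and both are parsed with
#' `Rsamtools::scanBam()`). Records are normalised to 1-based leftmost
#' coordinates with ends ordered so endA <= endB by (chromosome,
#' position); duplicate and quality flags are carried through.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"sam"` or `"bam"`.
#' @return canonicalised pair data.frame.
#' @export
read_pairs <- function(path, format = c("auto", "tsv", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") return(read_pairs_tsv(path))
  bam <- if (format == "sam")
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  else path
  read_pairs_bam(bam)
}

read_pairs_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(pair_columns, names(tb))
  if (length(missing))
    stopf("pair table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.integer(tb[[col]]))
    bad <- which(is.na(v) & !is.na(tb[[col]]))
    if (length(bad))
      stopf("malformed %s at line %d of %s", col, bad[1] + 1L, path)
    v
  }
  pairs <- data.frame(pair_id = tb$pair_id,
                      chromA = tb$chromA, posA = num("posA"),
                      strandA = tb$strandA, mapqA = num("mapqA"),
                      chromB = tb$chromB, posB = num("posB"),
                      strandB = tb$strandB, mapqB = num("mapqB"),
                      source_tag = tb$source_tag,
                      duplicate = if ("duplicate" %in% names(tb))
                        as.logical(tb$duplicate) else FALSE)
  bad_pos <- which(pairs$posA < 1 | pairs$posB < 1)
  if (length(bad_pos))
    stopf("coordinate < 1 in 1-based pair table at line %d of %s",
          bad_pos[1] + 1L, path)
  bad_strand <- which(!(pairs$strandA %in% c("+", "-") &
                        pairs$strandB %in% c("+", "-")))
  if (length(bad_strand))
    stopf("malformed strand at line %d of %s", bad_strand[1] + 1L, path)
  canonicalize_pairs(pairs)
}

read_pairs_bam <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "XT")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  first <- bitwAnd(flag, 0x40) > 0
  rec <- data.frame(qname = res$qname,
                    chrom = as.character(res$rname), pos = res$pos,
                    strand = ifelse(bitwAnd(flag, 0x10) > 0, "-", "+"),
                    mapq = res$mapq,
                    dup = bitwAnd(flag, 0x400) > 0,
                    first = first,
                    tag = if (is.null(res$tag$XT)) NA_character_
                          else res$tag$XT)
  a <- rec[rec$first, ]; b <- rec[!rec$first, ]
  idx <- match(a$qname, b$qname)
  if (anyNA(idx)) stopf("unpaired records in %s", bam)
  b <- b[idx, ]
  pairs <- data.frame(pair_id = a$qname,
                      chromA = a$chrom, posA = a$pos, strandA = a$strand,
                      mapqA = a$mapq,
                      chromB = b$chrom, posB = b$pos, strandB = b$strand,
                      mapqB = b$mapq,
                      source_tag = ifelse(is.na(a$tag), "unknown", a$tag),
                      duplicate = a$dup | b$dup)
  rownames(pairs) <- NULL
  canonicalize_pairs(pairs)
}
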