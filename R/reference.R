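#' Build a toy reference genome
#'
#' A minimal multi-chromosome reference used by the rearrangement simulator:
#' chromosome names and lengths, optional centromere intervals (needed to
#' classify inversions as pericentric vs paracentric) and optional base
#' sequences (needed only for junction-sequence reconstruction).
#'
#' Coordinates are 1-based and inclusive throughout the package; BED-family
#' files are converted at the reader/writer boundary only.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive) giving one centromere interval per chromosome.
#' @param sequences optional named character vector of chromosome sequences;
#'   each must have exactly `chrom_lengths[chrom]` bases.
#' @return An object of class `toy_reference`.
#' @examples
#' ref <- toy_reference(c(chr1 = 1e6, chr2 = 8e5),
#'                      centromeres = data.frame(chrom = c("chr1", "chr2"),
#'                                               start = c(4e5, 3e5),
#'                                               end   = c(4.2e5, 3.2e5)))
#' @export
toy_reference <- function(chrom_lengths, centromeres = NULL, sequences = NULL) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    stopf("duplicated chromosome names")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be > 0")
  chrom_lengths <- round(chrom_lengths)
  if (!is.null(centromeres)) {
    need <- c("chrom", "start", "end")
    if (!all(need %in% names(centromeres)))
      stopf("centromeres needs columns chrom, start, end")
    bad <- !(centromeres$chrom %in% names(chrom_lengths))
    if (any(bad)) stopf("centromere on unknown chromosome: %s",
                        paste(centromeres$chrom[bad], collapse = ", "))
    len <- chrom_lengths[centromeres$chrom]
    if (any(centromeres$start < 1 | centromeres$end > len |
            centromeres$start > centromeres$end))
      stopf("centromere interval outside its chromosome")
  }
  if (!is.null(sequences)) {
    if (!all(names(chrom_lengths) %in% names(sequences)))
      stopf("sequences missing for some chromosomes")
    if (any(nchar(sequences[names(chrom_lengths)]) != chrom_lengths))
      stopf("sequence length does not match chromosome length")
  }
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 centromeres = centromeres,
                 sequences = sequences),
            class = "toy_reference")
}

#' @export
print.toy_reference <- function(x, ...) {
  cat(sprintf("toy_reference: %d chromosome(s), %s bp total\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ",")))
  invisible(x)
}

#' Describe one planted structural variant
#'
#' @param sv_type one of `"deletion"`, `"inversion"`,
#'   `"reciprocal_translocation"`.
#' @param chromA,chromB chromosome names; equal (and defaulted) for
#'   intra-chromosomal events.
#' @param posA,posB 1-based breakpoint coordinates on the *reference*. For a
#'   deletion, `[posA, posB]` is the deleted segment; for an inversion, the
#'   inverted segment; for a reciprocal translocation, the exchange joins
#'   `chromA[1..posA]` to `chromB[(posB+1)..]` and vice versa.
#' @param junction_indel signed bp applied on the derived strand at each
#'   junction's left side: negative = bases lost, positive = bases duplicated.
#'   Scalar (recycled) or one value per junction (deletion has one junction,
#'   inversion and reciprocal translocation have two). `|junction_indel| <= 10`.
#' @return An object of class `planted_sv`.
#' @export
planted_sv <- function(sv_type = c("deletion", "inversion",
                                   "reciprocal_translocation"),
                       chromA, posA, posB, chromB = chromA,
                       junction_indel = 0L) {
  sv_type <- match.arg(sv_type)
  n_jct <- if (sv_type == "deletion") 1L else 2L
  if (length(junction_indel) == 1L) junction_indel <- rep(junction_indel, n_jct)
  if (length(junction_indel) != n_jct)
    stopf("%s has %d junction(s); got %d junction_indel values",
          sv_type, n_jct, length(junction_indel))
  if (any(abs(junction_indel) > 10))
    stopf("|junction_indel| must be <= 10 bp")
  if (sv_type %in% c("deletion", "inversion")) {
    if (!identical(chromA, chromB))
      stopf("%s requires chromA == chromB", sv_type)
    if (!(posA < posB)) stopf("%s requires posA < posB", sv_type)
  }
  structure(list(sv_type = sv_type, chromA = chromA, chromB = chromB,
                 posA = round(posA), posB = round(posB),
                 junction_indel = as.integer(junction_indel)),
            class = "planted_sv")
}

#' @export
print.planted_sv <- function(x, ...) {
  cat(sprintf("%s %s:%s | %s:%s (junction indel %s)\n", x$sv_type,
              x$chromA, format(x$posA, big.mark = ","),
              x$chromB, format(x$posB, big.mark = ","),
              paste(x$junction_indel, collapse = "/")))
  invisible(x)
}

#' Mate-pair library model
#'
#' Statistical description of the simulated sequencing library: a ~5 kb
#' median-insert mate-pair preparation read as 2 x 36 bp, with an optional
#' fraction of contaminating short-insert paired-end fragments that survive
#' mate-pair enrichment.
#'
#' Insert lengths are drawn from a log-normal distribution parameterised by
#' `median_insert` and `insert_sd` and truncated to
#' `[2 * read_length, 4 * median_insert]`.
#'
#' @param median_insert median insert (outer fragment) length in bp.
#' @param insert_sd standard deviation of the insert length in bp.
#' @param read_length read length in bp.
#' @param n_pairs number of read pairs to emit.
#' @param contamination_fraction proportion in `[0, 1]` of contaminating
#'   short-insert pairs; these carry the opposite read orientation
#'   (paired-end chemistry) and a short insert.
#' @param contaminant_insert mean insert of contaminant pairs in bp.
#' @param orientation concordant mate-pair orientation convention: `"RF"`
#'   (reads face outward after circularisation, the default) or `"FR"`.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return An object of class `library_model`.
#' @export
library_model <- function(median_insert = 5012, insert_sd = 500,
                          read_length = 36L, n_pairs = 10000L,
                          contamination_fraction = 0,
                          contaminant_insert = 300,
                          orientation = c("RF", "FR"), seed = 1L) {
  orientation <- match.arg(orientation)
  if (median_insert <= 2 * read_length)
    stopf("median_insert must exceed 2 x read_length")
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stopf("contamination_fraction must lie in [0, 1]")
  if (insert_sd <= 0) stopf("insert_sd must be > 0")
  if (n_pairs < 0) stopf("n_pairs must be >= 0")
  structure(list(median_insert = median_insert, insert_sd = insert_sd,
                 read_length = as.integer(read_length),
                 n_pairs = as.integer(n_pairs),
                 contamination_fraction = contamination_fraction,
                 contaminant_insert = contaminant_insert,
                 orientation = orientation, seed = as.integer(seed)),
            class = "library_model")
}
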