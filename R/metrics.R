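# Quality-control and validation metrics.

#' Theoretical genome-wide spanning coverage
#'
#' The expected number of mate-pair inserts covering a genomic position:
#' `n_pairs * median_insert / genome_size`. The plain formula with no
#' hidden filtering.
#'
#' @param n_pairs number of read pairs.
#' @param median_insert median insert length in bp.
#' @param genome_size genome size in bp.
#' @return list of class `coverage_stats` with the inputs and
#'   `spanning_depth` (fold).
#' @examples
#' spanning_coverage(1e6, 5000, 1e9)$spanning_depth  # 5
#' @export
spanning_coverage <- function(n_pairs, median_insert, genome_size) {
  if (n_pairs <= 0 || median_insert <= 0 || genome_size <= 0)
    stopf("all inputs must be > 0")
  structure(list(n_pairs = n_pairs, median_insert = median_insert,
                 genome_size = genome_size,
                 spanning_depth = n_pairs * median_insert / genome_size),
            class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("spanning depth %.1f-fold (%s pairs x %s bp / %s bp)\n",
              x$spanning_depth, format(x$n_pairs, big.mark = ","),
              format(x$median_insert, big.mark = ","),
              format(x$genome_size, big.mark = ",")))
  invisible(x)
}

#' Per-chromosome sequencing enrichment
#'
#' Length-normalised enrichment of a target chromosome in a read set, as
#' used to check flow-sorted chromosome fractions:
#' `fold = (count_target / total_count) / (length_target / total_length)`.
#' Because the matching criterion between raw and length-normalised
#' reporting is convention-dependent, the per-chromosome table also carries
#' `fold_vs_rest`, the target's read density relative to the density over
#' all other chromosomes pooled.
#'
#' @param counts named vector of read counts per chromosome.
#' @param lengths named vector of chromosome lengths (same names).
#' @param target target chromosome name.
#' @return list of class `enrichment_result`: `target`,
#'   `observed_fraction`, `expected_fraction`, `fold`, `fold_vs_rest` and
#'   the full per-chromosome `table`.
#' @export
chromosome_enrichment <- function(counts, lengths, target) {
  if (!setequal(names(counts), names(lengths)))
    stopf("counts and lengths must cover the same chromosome set")
  if (!target %in% names(counts)) stopf("unknown target chromosome '%s'", target)
  lengths <- lengths[names(counts)]
  total <- sum(counts)
  if (total <= 0) stopf("total read count must be > 0")
  tl <- sum(lengths)
  obs <- counts / total
  exp_frac <- lengths / tl
  fold <- obs / exp_frac
  fold_vs_rest <- vapply(names(counts), function(ch) {
    dens <- counts[[ch]] / lengths[[ch]]
    rest <- (total - counts[[ch]]) / (tl - lengths[[ch]])
    unname(dens / rest)
  }, numeric(1))
  tb <- data.frame(chrom = names(counts), count = as.numeric(counts),
                   length = as.numeric(lengths),
                   observed_fraction = as.numeric(obs),
                   expected_fraction = as.numeric(exp_frac),
                   fold = as.numeric(fold), fold_vs_rest = fold_vs_rest)
  rownames(tb) <- NULL
  structure(list(target = target,
                 observed_fraction = unname(obs[target]),
                 expected_fraction = unname(exp_frac[target]),
                 fold = unname(fold[target]),
                 fold_vs_rest = unname(fold_vs_rest[target]),
                 table = tb),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s enriched %.2f-fold (%.2f-fold vs pooled others)\n",
              x$target, x$fold, x$fold_vs_rest))
  invisible(x)
}

#' Validate a predicted call set against a confirmed one
#'
#' A predicted call is confirmed when some confirmed call has the same SV
#' type and chromosome(s) and either a reciprocal overlap of at least
#' `min_reciprocal_overlap` between the two breakpoint-to-breakpoint
#' intervals (intra-chromosomal calls) or both breakpoints within
#' `breakpoint_tolerance` (translocations). The validation rate is
#' `100 * n_confirmed / n_predicted`; the exact fraction is retained and
#' the display value rounded to the nearest integer percent.
#'
#' @param predicted,confirmed call data.frames (columns `sv_type`,
#'   `chrom1`, `pos1`, `chrom2`, `pos2`; e.g. from [type_svs()] or
#'   [read_calls_bedpe()]).
#' @param min_reciprocal_overlap reciprocal-overlap threshold (default 0.5).
#' @param breakpoint_tolerance translocation breakpoint distance bound in
#'   bp (default 10000, ~ the library cutoff).
#' @return list of class `validation_result`: `n_predicted`, `n_confirmed`,
#'   `rate` (exact percent), `rate_rounded`, and a per-call `matches` table
#'   with overlap fractions.
#' @examples
#' # 10 of 11 predictions confirmed -> 90.909...%, reported as 91%
#' @export
validate_callsets <- function(predicted, confirmed,
                              min_reciprocal_overlap = 0.5,
                              breakpoint_tolerance = 10000) {
  if (!nrow(predicted)) stopf("empty predicted set: validation rate undefined")
  trans_types <- c("reciprocal_translocation", "translocation_junction")
  match_one <- function(p) {
    for (j in seq_len(nrow(confirmed))) {
      q <- confirmed[j, ]
      if (p$sv_type != q$sv_type) next
      if (p$sv_type %in% trans_types) {
        same <- (p$chrom1 == q$chrom1 && p$chrom2 == q$chrom2 &&
                 abs(p$pos1 - q$pos1) <= breakpoint_tolerance &&
                 abs(p$pos2 - q$pos2) <= breakpoint_tolerance) ||
                (p$chrom1 == q$chrom2 && p$chrom2 == q$chrom1 &&
                 abs(p$pos1 - q$pos2) <= breakpoint_tolerance &&
                 abs(p$pos2 - q$pos1) <= breakpoint_tolerance)
        if (same) return(list(j = j, ov1 = NA_real_, ov2 = NA_real_))
      } else {
        if (p$chrom1 != q$chrom1) next
        a <- sort(c(p$pos1, p$pos2)); b <- sort(c(q$pos1, q$pos2))
        ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
        ovp <- ov / (a[2] - a[1] + 1); ovq <- ov / (b[2] - b[1] + 1)
        if (ovp >= min_reciprocal_overlap && ovq >= min_reciprocal_overlap)
          return(list(j = j, ov1 = ovp, ov2 = ovq))
      }
    }
    NULL
  }
  matches <- do.call(rbind, lapply(seq_len(nrow(predicted)), function(i) {
    m <- match_one(predicted[i, ])
    data.frame(predicted_id = predicted$call_id[i] %||% i,
               confirmed_id = if (is.null(m)) NA_character_
                 else as.character(confirmed$call_id[m$j] %||% m$j),
               confirmed = !is.null(m),
               overlap_predicted = if (is.null(m)) NA_real_ else m$ov1,
               overlap_confirmed = if (is.null(m)) NA_real_ else m$ov2)
  }))
  n_conf <- sum(matches$confirmed)
  rate <- 100 * n_conf / nrow(predicted)
  structure(list(n_predicted = nrow(predicted), n_confirmed = n_conf,
                 rate = rate, rate_rounded = round(rate), matches = matches),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation: %d of %d predicted calls confirmed (%d%%; exact %.3f%%)\n",
              x$n_confirmed, x$n_predicted, x$rate_rounded, x$rate))
  invisible(x)
}
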