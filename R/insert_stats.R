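#' Estimate library insert-size statistics
#'
#' The median outer span of concordantly oriented same-chromosome pairs
#' (spans above 10 x the kit-nominal insert are excluded as already
#' discordant) sets the library's distance cutoff at twice the median —
#' e.g. a 5,012 bp median gives a 10,024 bp cutoff, the "10 kb (2x library
#' insert size)" rule. The span of a pair is
#' `posB - posA + read_length` (outer fragment length).
#'
#' @param pairs read-pair data.frame (see [simulate_pairs()] / [read_pairs()]).
#' @param config a [pipeline_config()]. If fewer than 100 usable pairs are
#'   available the function fails unless `config$median_insert` supplies the
#'   median directly.
#' @return An object of class `insert_stats` with fields `median_insert`,
#'   `mad`, `n_used` and `cutoff` (always `2 * median_insert`).
#' @export
estimate_insert_stats <- function(pairs, config = pipeline_config()) {
  conv <- conv_strands(config$orientation)
  same <- pairs$chromA == pairs$chromB
  span <- pairs$posB - pairs$posA + config$read_length
  usable <- same & pairs$strandA == conv[["left"]] &
    pairs$strandB == conv[["right"]] & span < 10 * config$nominal_insert
  n_used <- sum(usable)
  if (n_used < 100) {
    if (is.null(config$median_insert))
      stopf(paste0("only %d usable concordant pairs (need >= 100) and no ",
                   "median_insert override in the configuration"), n_used)
    med <- config$median_insert
    mad_bp <- if (n_used > 0) stats::mad(span[usable], constant = 1) else 0
  } else {
    med <- stats::median(span[usable])
    mad_bp <- stats::mad(span[usable], constant = 1)
  }
  cutoff <- if (!is.null(config$cutoff)) config$cutoff else 2 * med
  structure(list(median_insert = med, mad = mad_bp, n_used = n_used,
                 cutoff = cutoff),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf("insert_stats: median %s bp (MAD %s, n = %d), cutoff %s bp\n",
              format(x$median_insert, big.mark = ","),
              format(round(x$mad), big.mark = ","), x$n_used,
              format(x$cutoff, big.mark = ",")))
  invisible(x)
}

#' Classify read pairs against the library model
#'
#' Total, deterministic classification with fixed precedence
#' `duplicate > low_quality > interchromosomal > long_span >
#' orientation_aberrant > concordant`:
#' marked duplicates first; then pairs with a read below the mapping-quality
#' threshold; then pairs whose reads align to different chromosomes; then
#' same-chromosome pairs whose span exceeds the cutoff (2 x median insert);
#' then pairs whose strands violate the concordant orientation convention;
#' everything else is concordant.
#'
#' @param pairs canonicalised read-pair data.frame.
#' @param stats an [estimate_insert_stats()] result (sets the cutoff).
#' @param config a [pipeline_config()].
#' @return character vector of classes, one per pair.
#' @export
classify_pairs <- function(pairs, stats, config = pipeline_config()) {
  stopifnot(inherits(stats, "insert_stats"))
  n <- nrow(pairs)
  if (!n) return(character(0))
  conv <- conv_strands(config$orientation)
  dup <- if ("duplicate" %in% names(pairs)) pairs$duplicate else rep(FALSE, n)
  lowq <- pmin(pairs$mapqA, pairs$mapqB) < config$mapq_threshold
  inter <- pairs$chromA != pairs$chromB
  span <- pairs$posB - pairs$posA + config$read_length
  long <- !inter & span > stats$cutoff
  aberrant <- !inter &
    !(pairs$strandA == conv[["left"]] & pairs$strandB == conv[["right"]])
  out <- rep("concordant", n)
  out[aberrant] <- "orientation_aberrant"
  out[long] <- "long_span"
  out[inter] <- "interchromosomal"
  out[lowq] <- "low_quality"
  out[dup] <- "duplicate"
  out
}
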