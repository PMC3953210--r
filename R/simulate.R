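# Mate-pair library simulation over a rearranged genome.

# Log-normal insert lengths parameterised by median m and standard deviation
# s: meanlog = log(m); sdlog solved in closed form from
# s^2 = m^2 * t * (t - 1) with t = exp(sdlog^2). Truncated by rejection.
draw_insert_lengths <- function(n, median_insert, insert_sd, lo, hi) {
  if (n == 0L) return(integer(0))
  t <- (1 + sqrt(1 + 4 * (insert_sd / median_insert)^2)) / 2
  sdlog <- sqrt(log(t))
  meanlog <- log(median_insert)
  out <- round(stats::rlnorm(n, meanlog, sdlog))
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- round(stats::rlnorm(length(bad), meanlog, sdlog))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  as.integer(out)
}

# Concordant (left-read, right-read) strands for an orientation convention:
# RF mate-pairs read outward (left "-", right "+"); FR paired-end reads
# inward (left "+", right "-").
conv_strands <- function(orientation) {
  switch(orientation,
         RF = c(left = "-", right = "+"),
         FR = c(left = "+", right = "-"),
         stopf("unknown orientation convention '%s'", orientation))
}

empty_pairs <- function() {
  data.frame(pair_id = character(0),
             chromA = character(0), posA = integer(0), strandA = character(0),
             mapqA = integer(0),
             chromB = character(0), posB = integer(0), strandB = character(0),
             mapqB = integer(0), source_tag = character(0),
             duplicate = logical(0))
}

# Reorder each pair's ends so endA <= endB by (chromosome, position).
canonicalize_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  swap <- chrom_before(pairs$chromB, pairs$chromA) |
    (pairs$chromA == pairs$chromB & pairs$posB < pairs$posA)
  if (any(swap)) {
    a <- pairs[swap, c("chromA", "posA", "strandA", "mapqA")]
    pairs[swap, c("chromA", "posA", "strandA", "mapqA")] <-
      pairs[swap, c("chromB", "posB", "strandB", "mapqB")]
    pairs[swap, c("chromB", "posB", "strandB", "mapqB")] <- a
  }
  pairs
}

#' Simulate mate-pair alignment records over a rearranged genome
#'
#' Draws fragments uniformly over the derived chromosomes of a
#' [apply_sv_plan()] plan, with insert lengths from the library model's
#' truncated log-normal, and maps both 36-bp (by default) read ends through
#' the liftover back to *reference* coordinates — the simulator plays the
#' role of the aligner. With probability `contamination_fraction` a pair is
#' replaced by a short-insert contaminant with the opposite (paired-end)
#' orientation. Pairs in which a read straddles a derived-segment boundary
#' are dropped, emulating junction-spanning short reads that fail to align.
#'
#' Deterministic given `lib$seed`; the caller's RNG state is untouched.
#'
#' @param plan a [apply_sv_plan()] result.
#' @param lib a [library_model()].
#' @return data.frame of aligned pairs with columns `pair_id`, `chromA`,
#'   `posA`, `strandA`, `mapqA`, `chromB`, `posB`, `strandB`, `mapqB`,
#'   `source_tag` (`"mate_pair"` or `"contaminant"`), `duplicate`; ends are
#'   ordered so that endA <= endB by (chromosome, position). Attributes
#'   `read_length` and `seqlengths` are attached for the writers.
#' @export
simulate_pairs <- function(plan, lib) {
  stopifnot(inherits(plan, "rearrangement_plan"), inherits(lib, "library_model"))
  rl <- lib$read_length
  lens <- plan$der_lengths
  if (any(lens <= 3 * lib$median_insert))
    stopf("derived chromosomes must be longer than 3 x median_insert")
  res <- if (lib$n_pairs == 0L) empty_pairs() else with_private_seed(lib$seed, {
    n <- lib$n_pairs
    contam <- stats::runif(n) < lib$contamination_fraction
    insert <- integer(n)
    insert[!contam] <- draw_insert_lengths(sum(!contam), lib$median_insert,
                                           lib$insert_sd, 2L * rl,
                                           as.integer(4 * lib$median_insert))
    if (any(contam)) {
      ci <- round(stats::rnorm(sum(contam), lib$contaminant_insert,
                               0.1 * lib$contaminant_insert))
      insert[contam] <- pmax(as.integer(ci), 2L * rl)
    }
    der <- sample(names(lens), n, replace = TRUE, prob = lens)
    span_room <- lens[der] - insert + 1
    frag <- 1L + as.integer(floor(stats::runif(n) * pmax(span_room, 1)))

    conv <- conv_strands(lib$orientation)
    opp <- conv_strands(if (lib$orientation == "RF") "FR" else "RF")
    left_strand <- ifelse(contam, opp[["left"]], conv[["left"]])
    right_strand <- ifelse(contam, opp[["right"]], conv[["right"]])

    l1 <- frag; r1 <- frag + rl - 1L
    l2 <- frag + insert - rl; r2 <- frag + insert - 1L

    m1 <- lift_read(plan, der, l1, r1)
    m2 <- lift_read(plan, der, l2, r2)
    ok <- m1$ok & m2$ok
    flip <- function(s, inverted) ifelse(inverted, ifelse(s == "+", "-", "+"), s)
    pairs <- data.frame(
      pair_id = sprintf("p%07d", seq_len(n)),
      chromA = m1$ref_chrom, posA = m1$ref_pos,
      strandA = flip(left_strand, m1$inverted), mapqA = 37L,
      chromB = m2$ref_chrom, posB = m2$ref_pos,
      strandB = flip(right_strand, m2$inverted), mapqB = 37L,
      source_tag = ifelse(contam, "contaminant", "mate_pair"),
      duplicate = FALSE)[ok, , drop = FALSE]
    rownames(pairs) <- NULL
    canonicalize_pairs(pairs)
  })
  attr(res, "read_length") <- rl
  attr(res, "seqlengths") <- plan$reference$chrom_lengths
  attr(res, "library") <- lib
  res
}

# Vectorised alignment of reads [l, r] on derived chromosomes: a read maps
# iff it lies inside a single non-junction segment. Returns the reference
# coordinate of the read's leftmost reference base and whether the segment
# is inverted (strand must then be flipped).
lift_read <- function(plan, der, l, r) {
  n <- length(der)
  out <- list(ok = logical(n), ref_chrom = rep(NA_character_, n),
              ref_pos = rep(NA_integer_, n), inverted = rep(FALSE, n))
  segs <- plan$segments
  for (d in unique(der)) {
    s <- segs[segs$der_chrom == d, , drop = FALSE]
    sel <- which(der == d)
    i1 <- findInterval(l[sel], s$der_start)
    i2 <- findInterval(r[sel], s$der_start)
    ok <- i1 == i2 & !s$junction[i1]
    fwd <- s$orient[i1] == "+"
    rp <- ifelse(fwd, s$ref_start[i1] + (l[sel] - s$der_start[i1]),
                 s$ref_end[i1] - (r[sel] - s$der_start[i1]))
    out$ok[sel] <- ok
    out$ref_chrom[sel] <- s$ref_chrom[i1]
    out$ref_pos[sel] <- as.integer(rp)
    out$inverted[sel] <- !fwd
  }
  out
}
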