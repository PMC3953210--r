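#' Reconcile a sequenced junction against its reference flanks
#'
#' Measures the micro-indel at a rearrangement junction by maximal exact
#' extension: the junction sequence is aligned from its start against the
#' left reference flank and from its end against the right reference flank,
#' and the signed length difference `nchar(junction) - nchar(left) -
#' nchar(right)` gives the bases lost (negative) or gained (positive) at
#' the fusion point. A gained base is reported as a duplication when the
#' extra sequence copies the flank adjacent to the junction (the typical
#' "both derivatives carry the same base" outcome of capillary validation),
#' otherwise as a novel insertion.
#'
#' @param ref_left reference sequence ending at the nominal breakpoint
#'   (last retained base); at least 20 bp.
#' @param ref_right reference sequence starting at the nominal first
#'   retained base of the other flank; at least 20 bp.
#' @param junction observed derived sequence spanning from the start of
#'   `ref_left` to the end of `ref_right`.
#' @param min_flank_match minimum exact prefix/suffix match required to
#'   accept that the junction belongs to these flanks (default 10 bp).
#' @return list with `delta` (signed bp; 0 = perfectly balanced),
#'   `description`, and the matched prefix/suffix lengths.
#' @examples
#' left <- "ACGTACGTACGTACGTACGTG"; right <- "CATGCATGCATGCATGCATGA"
#' junction_delta(left, right, paste0(left, right))$delta          # 0
#' junction_delta(left, right, paste0(left, substring(right, 2)))  # -1
#' @export
junction_delta <- function(ref_left, ref_right, junction,
                           min_flank_match = 10L) {
  ref_left <- toupper(ref_left); ref_right <- toupper(ref_right)
  junction <- toupper(junction)
  L <- nchar(ref_left); R <- nchar(ref_right); n <- nchar(junction)
  if (L < 20 || R < 20) stopf("reference flanks must be at least 20 bp")
  shared_prefix <- function(a, b) {
    av <- strsplit(a, NULL)[[1]]; bv <- strsplit(b, NULL)[[1]]
    k <- min(length(av), length(bv))
    if (k == 0) return(0L)
    eq <- av[seq_len(k)] == bv[seq_len(k)]
    if (all(eq)) k else which.min(eq) - 1L
  }
  rev_chars <- function(x) paste(rev(strsplit(x, NULL)[[1]]), collapse = "")
  a <- shared_prefix(junction, ref_left)
  b <- shared_prefix(rev_chars(junction), rev_chars(ref_right))
  if (a < min_flank_match || b < min_flank_match)
    stopf("not a junction of these references (prefix match %d bp, suffix match %d bp)",
          a, b)
  delta <- n - L - R
  description <-
    if (delta == 0) "balanced"
    else if (delta < 0) sprintf("%d bp lost", -delta)
    else {
      mid <- substr(junction, a + 1L, n - b)
      dup <- nchar(mid) == delta &&
        (mid == substr(ref_right, 1L, delta) ||
         mid == substr(ref_left, L - delta + 1L, L))
      if (dup) sprintf("%d bp duplicated", delta)
      else sprintf("%d bp inserted (novel)", delta)
    }
  list(delta = as.integer(delta), description = description,
       matched_left = a, matched_right = b)
}
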