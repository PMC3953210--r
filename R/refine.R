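#' Refine a cluster's breakpoint intervals
#'
#' For each side of a discordant cluster, intersects the geometric
#' constraints every member places on the junction: reads must lie entirely
#' on the retained flank, and each member's fragment must still fit within
#' the library bound (the cutoff, 2 x median insert). The direction a read
#' constrains is set by its strand under the library orientation
#' convention — under RF, a "-" read is the fragment's left end so the
#' junction lies to its right, and vice versa.
#'
#' The reported interval brackets the *departure base*: the first reference
#' position, approached along the supporting reads, no longer shared with
#' the derived chromosome. With reads starting at positions `p` and read
#' length `L`, a junction-to-the-right side gives
#' `[max(p) + L, min(p) + cutoff]` and a junction-to-the-left side
#' `[max(p) + L - 1 - cutoff, min(p) - 1]`. Width is therefore at most the
#' cutoff and never increases as members are added.
#'
#' @param cluster a `discordant_cluster` from [cluster_discordant()].
#' @param stats an [estimate_insert_stats()] result.
#' @param config a [pipeline_config()] (orientation and read length).
#' @return the cluster with `intervalA`, `intervalB` (c(lo, hi)), per-side
#'   flank orientation `orientA`/`orientB` (`"tail"` = reference bases
#'   before the junction retained, `"head"` = after) and midpoint estimates
#'   `bpA`/`bpB` filled in.
#' @export
refine_intervals <- function(cluster, stats, config = pipeline_config()) {
  stopifnot(inherits(cluster, "discordant_cluster"),
            inherits(stats, "insert_stats"))
  m <- cluster$members
  if (!nrow(m)) stopf("cannot refine an empty cluster")
  if (any(m$strandA != cluster$strandA) || any(m$strandB != cluster$strandB) ||
      any(m$chromA != cluster$chromA) || any(m$chromB != cluster$chromB))
    stopf("cluster members do not share the cluster signature")
  conv <- conv_strands(config$orientation)
  rl <- config$read_length
  cutoff <- stats$cutoff

  chained <- FALSE
  side <- function(p, strand) {
    towards_right <- strand == conv[["left"]]   # read is the fragment's left end
    if (towards_right) {
      lo <- max(p) + rl
      hi <- min(p) + cutoff
    } else {
      lo <- max(p + rl - 1) - cutoff
      hi <- min(p) - 1
    }
    if (lo > hi) {
      # single-linkage chain wider than the cutoff: the per-member bounds
      # have an empty intersection, so fall back to the innermost member's
      # own bound and mark the cluster as chained
      chained <<- TRUE
      if (towards_right) { lo <- max(p) + rl; hi <- max(p) + cutoff }
      else { lo <- min(p + rl - 1) - cutoff; hi <- min(p) - 1 }
    }
    c(max(lo, 1), hi)
  }
  cluster$intervalA <- side(m$posA, cluster$strandA)
  cluster$intervalB <- side(m$posB, cluster$strandB)
  cluster$chained <- chained
  cluster$orientA <- if (cluster$strandA == conv[["left"]]) "tail" else "head"
  cluster$orientB <- if (cluster$strandB == conv[["left"]]) "tail" else "head"
  cluster$bpA <- floor(mean(cluster$intervalA))
  cluster$bpB <- floor(mean(cluster$intervalB))
  cluster
}
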