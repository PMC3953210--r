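# Single-linkage clustering of discordant read pairs.

# Union-find with path halving; small integer universes only.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

signature_of <- function(pairs) {
  paste(pairs$chromA, pairs$chromB, pairs$strandA, pairs$strandB, sep = "|")
}

#' Cluster discordant read pairs
#'
#' Single-linkage clustering within each signature (chromosome pair and
#' strand pair): two pairs link iff both their endA positions and their
#' endB positions lie within `stats$cutoff` of each other. Read pairs with
#' identical end coordinates and strands are collapsed to one before
#' support counting. Clusters with support below `min_support` (default 6,
#' the "at least six overlapping read pairs" rule) are discarded; they are
#' recorded, with a reason, in the `"discarded"` attribute of the result so
#' that no filtering step is silent.
#'
#' @param pairs data.frame of pairs already classified as
#'   `interchromosomal`, `long_span` or `orientation_aberrant`.
#' @param stats an [estimate_insert_stats()] result.
#' @param min_support minimum member count for a retained cluster.
#' @return list of `discordant_cluster` objects sorted by
#'   (chromA, intervalA start); attribute `"discarded"` holds the curation
#'   log rows for sub-threshold clusters.
#' @export
cluster_discordant <- function(pairs, stats, min_support = 6L) {
  stopifnot(inherits(stats, "insert_stats"))
  discarded <- data.frame(chromA = character(0), chromB = character(0),
                          strandA = character(0), strandB = character(0),
                          support = integer(0), posA = integer(0),
                          posB = integer(0), reason = character(0))
  if (!nrow(pairs)) {
    out <- list()
    attr(out, "discarded") <- discarded
    return(out)
  }
  key <- paste(pairs$chromA, pairs$posA, pairs$strandA,
               pairs$chromB, pairs$posB, pairs$strandB)
  pairs <- pairs[!duplicated(key), , drop = FALSE]

  cutoff <- stats$cutoff
  clusters <- list()
  for (sig in unique(signature_of(pairs))) {
    sub <- pairs[signature_of(pairs) == sig, , drop = FALSE]
    sub <- sub[order(sub$posA, sub$posB), , drop = FALSE]
    n <- nrow(sub)
    parent <- uf_new(n)
    if (n > 1) {
      for (i in 1:(n - 1)) {
        j <- i + 1L
        while (j <= n && sub$posA[j] - sub$posA[i] <= cutoff) {
          if (abs(sub$posB[j] - sub$posB[i]) <= cutoff)
            parent <- uf_union(parent, i, j)
          j <- j + 1L
        }
      }
    }
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    for (cc in unique(comp)) {
      members <- sub[comp == cc, , drop = FALSE]
      rownames(members) <- NULL
      cl <- structure(list(chromA = members$chromA[1],
                           chromB = members$chromB[1],
                           strandA = members$strandA[1],
                           strandB = members$strandB[1],
                           members = members,
                           support = nrow(members),
                           intervalA = NULL, intervalB = NULL),
                      class = "discordant_cluster")
      if (cl$support >= min_support) {
        clusters[[length(clusters) + 1L]] <- cl
      } else {
        discarded <- rbind(discarded, data.frame(
          chromA = cl$chromA, chromB = cl$chromB,
          strandA = cl$strandA, strandB = cl$strandB,
          support = cl$support,
          posA = min(members$posA), posB = min(members$posB),
          reason = "below_min_support"))
      }
    }
  }
  if (length(clusters)) {
    ord <- order(chrom_key(vapply(clusters, `[[`, character(1), "chromA")),
                 vapply(clusters, `[[`, character(1), "chromA"),
                 vapply(clusters, function(c) min(c$members$posA), numeric(1)))
    clusters <- clusters[ord]
  }
  attr(clusters, "discarded") <- discarded
  clusters
}

#' @export
print.discordant_cluster <- function(x, ...) {
  cat(sprintf("discordant_cluster %s(%s)/%s(%s), support %d\n",
              x$chromA, x$strandA, x$chromB, x$strandB, x$support))
  if (!is.null(x$intervalA))
    cat(sprintf("  intervals %s:[%s-%s]  %s:[%s-%s]\n",
                x$chromA, format(x$intervalA[1], big.mark = ","),
                format(x$intervalA[2], big.mark = ","),
                x$chromB, format(x$intervalB[1], big.mark = ","),
                format(x$intervalB[2], big.mark = ",")))
  invisible(x)
}
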