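# Typing and merging of refined discordant clusters into SV calls.

empty_calls <- function() {
  data.frame(call_id = character(0), sv_type = character(0),
             chrom1 = character(0), pos1 = integer(0),
             ci1_lo = integer(0), ci1_hi = integer(0),
             orient1 = character(0), strand1 = character(0),
             chrom2 = character(0), pos2 = integer(0),
             ci2_lo = integer(0), ci2_hi = integer(0),
             orient2 = character(0), strand2 = character(0),
             support = integer(0), span = numeric(0),
             inversion_class = character(0), n_junctions = integer(0),
             cluster_ids = character(0))
}

cluster_summary <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(id = i, chromA = cl$chromA, chromB = cl$chromB,
               strandA = cl$strandA, strandB = cl$strandB,
               loA = cl$intervalA[1], hiA = cl$intervalA[2],
               loB = cl$intervalB[1], hiB = cl$intervalB[2],
               orientA = cl$orientA, orientB = cl$orientB,
               bpA = cl$bpA, bpB = cl$bpB, support = cl$support)
  }))
}

# Greedy complementary-signature pairing by smallest combined interval
# distance; both per-side midpoint distances must be within the cutoff.
pair_complementary <- function(sm, idx1, idx2, cutoff) {
  cand <- expand.grid(i = idx1, j = idx2)
  if (!nrow(cand)) return(cand[0, ])
  dA <- abs(sm$bpA[cand$i] - sm$bpA[cand$j])
  dB <- abs(sm$bpB[cand$i] - sm$bpB[cand$j])
  cand <- cand[dA <= cutoff & dB <= cutoff, , drop = FALSE]
  cand$score <- abs(sm$bpA[cand$i] - sm$bpA[cand$j]) +
    abs(sm$bpB[cand$i] - sm$bpB[cand$j])
  cand <- cand[order(cand$score), , drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$i[k] %in% used) && !(cand$j[k] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, cand$i[k], cand$j[k])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Type refined clusters into structural-variant calls
#'
#' Applies the signature logic of the discovery procedure:
#' \itemize{
#'   \item same-chromosome clusters in concordant strand order whose spans
#'     exceeded the cutoff become \emph{deletions};
#'   \item same-strand (`++` / `--`) clusters are inversion junctions; a
#'     `++` and a `--` cluster whose breakpoint intervals match within the
#'     cutoff merge into one \emph{inversion} call with two junctions;
#'   \item inter-chromosomal clusters on the same chromosome pair with
#'     complementary strand signatures and intervals within the cutoff
#'     merge into a \emph{reciprocal_translocation}; unpaired ones remain
#'     \emph{translocation_junction} calls;
#'   \item everted same-chromosome clusters (strand order opposite to the
#'     concordant convention, the signature of contaminating short-insert
#'     paired-end reads) are discarded with reason `"everted_orientation"`
#'     in the curation log.
#' }
#' Inversions are classed \emph{pericentric} when the centromere interval
#' lies between the two breakpoints, \emph{paracentric} otherwise. For
#' intra-chromosomal calls `span = |pos2 - pos1|` over the breakpoint point
#' estimates (interval midpoints, or validated overrides applied with
#' [apply_breakpoint_overrides()]).
#'
#' @param clusters list of refined `discordant_cluster` objects (see
#'   [refine_intervals()]; unrefined clusters are refined on the fly).
#' @param centromeres optional data.frame (`chrom`, `start`, `end`); without
#'   it inversion calls get `inversion_class = NA` with a warning.
#' @param stats an [estimate_insert_stats()] result.
#' @param config a [pipeline_config()].
#' @return data.frame of calls, one row per call, sorted by (chrom1, pos1);
#'   attribute `"curation"` logs every discarded cluster with its reason.
#' @export
type_svs <- function(clusters, centromeres = NULL, stats,
                     config = pipeline_config()) {
  stopifnot(inherits(stats, "insert_stats"))
  clusters <- lapply(clusters, function(cl) {
    if (is.null(cl$intervalA)) refine_intervals(cl, stats, config) else cl
  })
  curation <- data.frame(chromA = character(0), chromB = character(0),
                         strandA = character(0), strandB = character(0),
                         support = integer(0), posA = integer(0),
                         posB = integer(0), reason = character(0))
  if (!length(clusters)) {
    out <- empty_calls()
    attr(out, "curation") <- curation
    return(out)
  }
  sm <- cluster_summary(clusters)
  conv <- conv_strands(config$orientation)
  cutoff <- stats$cutoff

  inter <- sm$chromA != sm$chromB
  same_strand <- !inter & sm$strandA == sm$strandB
  del_sig <- !inter & sm$strandA == conv[["left"]] & sm$strandB == conv[["right"]]
  everted <- !inter & !same_strand & !del_sig

  for (i in which(everted)) {
    curation <- rbind(curation, data.frame(
      chromA = sm$chromA[i], chromB = sm$chromB[i],
      strandA = sm$strandA[i], strandB = sm$strandB[i],
      support = sm$support[i], posA = sm$bpA[i], posB = sm$bpB[i],
      reason = "everted_orientation"))
  }

  rows <- list()
  add_call <- function(sv_type, i, j = NULL) {
    if (is.null(j)) {
      ci1 <- c(sm$loA[i], sm$hiA[i]); ci2 <- c(sm$loB[i], sm$hiB[i])
      support <- sm$support[i]
      o1 <- sm$orientA[i]; o2 <- sm$orientB[i]
      s1 <- sm$strandA[i]; s2 <- sm$strandB[i]
      ids <- as.character(sm$id[i])
    } else {
      # canonical junction 1 = the cluster whose side-A flank is "tail"
      first <- if (sm$orientA[i] == "tail") i else j
      ci1 <- c(min(sm$loA[c(i, j)]), max(sm$hiA[c(i, j)]))
      ci2 <- c(min(sm$loB[c(i, j)]), max(sm$hiB[c(i, j)]))
      support <- sm$support[i] + sm$support[j]
      o1 <- sm$orientA[first]; o2 <- sm$orientB[first]
      s1 <- sm$strandA[first]; s2 <- sm$strandB[first]
      ids <- paste(sm$id[c(i, j)], collapse = ",")
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      sv_type = sv_type,
      chrom1 = sm$chromA[i], pos1 = as.integer(floor(mean(ci1))),
      ci1_lo = ci1[1], ci1_hi = ci1[2], orient1 = o1, strand1 = s1,
      chrom2 = sm$chromB[i], pos2 = as.integer(floor(mean(ci2))),
      ci2_lo = ci2[1], ci2_hi = ci2[2], orient2 = o2, strand2 = s2,
      support = support, span = NA_real_,
      inversion_class = NA_character_,
      n_junctions = if (is.null(j)) 1L else 2L,
      cluster_ids = ids)
  }

  # inter-chromosomal: reciprocal pairing within each chromosome pair
  for (cp in unique(paste(sm$chromA[inter], sm$chromB[inter]))) {
    sel <- which(inter & paste(sm$chromA, sm$chromB) == cp)
    paired <- integer(0)
    flip <- function(s) ifelse(s == "+", "-", "+")
    sig <- paste(sm$strandA[sel], sm$strandB[sel])
    for (s in unique(sig)) {
      comp <- paste(flip(substr(s, 1, 1)), flip(substr(s, 3, 3)))
      i1 <- sel[sig == s & !(sel %in% paired)]
      i2 <- sel[sig == comp & !(sel %in% paired)]
      pp <- pair_complementary(sm, i1, i2, cutoff)
      for (k in seq_len(nrow(pp))) {
        add_call("reciprocal_translocation", pp$i[k], pp$j[k])
        paired <- c(paired, pp$i[k], pp$j[k])
      }
    }
    for (i in setdiff(sel, paired)) add_call("translocation_junction", i)
  }

  # intra-chromosomal inversions: pair ++ with -- on the same chromosome
  for (ch in unique(sm$chromA[same_strand])) {
    sel <- which(same_strand & sm$chromA == ch)
    plus <- sel[sm$strandA[sel] == "+"]
    minus <- sel[sm$strandA[sel] == "-"]
    pp <- pair_complementary(sm, plus, minus, cutoff)
    paired <- integer(0)
    for (k in seq_len(nrow(pp))) {
      add_call("inversion", pp$i[k], pp$j[k])
      paired <- c(paired, pp$i[k], pp$j[k])
    }
    for (i in setdiff(sel, paired)) add_call("inversion", i)
  }

  for (i in which(del_sig)) add_call("deletion", i)

  if (!length(rows)) {
    out <- empty_calls()
    attr(out, "curation") <- curation
    return(out)
  }
  calls <- do.call(rbind, rows)
  calls <- finalize_calls(calls, centromeres)
  attr(calls, "curation") <- curation
  calls
}

# Recompute span and inversion class from the point estimates, sort, and
# (re)assign call ids.
finalize_calls <- function(calls, centromeres = NULL) {
  intra <- calls$chrom1 == calls$chrom2
  calls$span <- ifelse(intra, abs(calls$pos2 - calls$pos1), NA_real_)
  inv <- calls$sv_type == "inversion"
  if (any(inv)) {
    for (i in which(inv)) {
      cen <- if (!is.null(centromeres))
        centromeres[centromeres$chrom == calls$chrom1[i], , drop = FALSE]
      else NULL
      if (is.null(cen) || !nrow(cen)) {
        warnf("no centromere interval for %s; inversion_class set to NA",
              calls$chrom1[i])
        calls$inversion_class[i] <- NA_character_
      } else {
        lo <- min(calls$pos1[i], calls$pos2[i])
        hi <- max(calls$pos1[i], calls$pos2[i])
        peri <- cen$start[1] >= lo & cen$end[1] <= hi
        calls$inversion_class[i] <- if (peri) "pericentric" else "paracentric"
      }
    }
  }
  ord <- chrom_order(calls$chrom1, calls$pos1)
  calls <- calls[ord, , drop = FALSE]
  calls$call_id <- sprintf("sv%02d", seq_len(nrow(calls)))
  rownames(calls) <- NULL
  calls[, c("call_id", setdiff(names(calls), "call_id"))]
}

#' Apply validated breakpoint overrides to calls
#'
#' Replaces interval-midpoint breakpoint estimates with validated base-pair
#' positions (e.g. from capillary sequencing of junction amplicons),
#' collapsing the confidence intervals to points and recomputing span and
#' inversion class.
#'
#' @param calls a call set from [type_svs()].
#' @param overrides data.frame with columns `call_id`, `pos1`, `pos2`.
#' @param centromeres optional centromere intervals, as in [type_svs()].
#' @return the updated call data.frame.
#' @export
apply_breakpoint_overrides <- function(calls, overrides, centromeres = NULL) {
  stopifnot(all(c("call_id", "pos1", "pos2") %in% names(overrides)))
  idx <- match(overrides$call_id, calls$call_id)
  if (anyNA(idx)) stopf("unknown call_id in overrides: %s",
                        paste(overrides$call_id[is.na(idx)], collapse = ", "))
  calls$pos1[idx] <- as.integer(overrides$pos1)
  calls$pos2[idx] <- as.integer(overrides$pos2)
  calls$ci1_lo[idx] <- calls$ci1_hi[idx] <- as.integer(overrides$pos1)
  calls$ci2_lo[idx] <- calls$ci2_hi[idx] <- as.integer(overrides$pos2)
  cur <- attr(calls, "curation")
  calls <- finalize_calls(calls, centromeres)
  attr(calls, "curation") <- cur
  calls
}

#' Run the full discovery pipeline on a pair table
#'
#' Marks duplicates, estimates insert statistics, classifies pairs,
#' clusters the discordant classes, refines breakpoint intervals and types
#' the clusters into calls.
#'
#' @param pairs read-pair data.frame ([simulate_pairs()] or [read_pairs()]).
#' @param config a [pipeline_config()].
#' @param centromeres optional centromere intervals (`chrom`, `start`, `end`).
#' @return An object of class `sv_callset`: list with `stats`,
#'   `class_counts`, `clusters` (refined, retained), `calls` and
#'   `curation` (every discarded cluster with its reason).
#' @export
call_svs <- function(pairs, config = pipeline_config(), centromeres = NULL) {
  key <- paste(pairs$chromA, pairs$posA, pairs$strandA,
               pairs$chromB, pairs$posB, pairs$strandB)
  pairs$duplicate <- (if ("duplicate" %in% names(pairs)) pairs$duplicate
                      else FALSE) | duplicated(key)
  stats <- estimate_insert_stats(pairs, config)
  classes <- classify_pairs(pairs, stats, config)
  disc <- pairs[classes %in% c("interchromosomal", "long_span",
                               "orientation_aberrant"), , drop = FALSE]
  clusters <- cluster_discordant(disc, stats, config$min_support)
  refined <- lapply(clusters, refine_intervals, stats = stats, config = config)
  calls <- type_svs(refined, centromeres, stats, config)
  curation <- rbind(attr(clusters, "discarded"), attr(calls, "curation"))
  structure(list(stats = stats,
                 class_counts = table(classes),
                 clusters = refined,
                 calls = calls,
                 curation = curation,
                 config = config),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset: %d call(s) from %d retained cluster(s); %d cluster(s) discarded\n",
              nrow(x$calls), length(x$clusters), nrow(x$curation)))
  print(x$stats)
  if (nrow(x$calls))
    print(x$calls[, c("call_id", "sv_type", "chrom1", "pos1", "chrom2",
                      "pos2", "support", "span", "inversion_class")])
  invisible(x)
}
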