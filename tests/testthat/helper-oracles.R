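# Independent oracles and fixture builders used across the suite.

# ---- per-base walk oracle for derivative-genome construction -------------
# Each chromosome is a character vector of base addresses "chrom:pos:orient"
# (":J" appended for junction-duplicated bases); SVs are applied by direct
# vector surgery, independently of the segment machinery under test.

walk_identity <- function(chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(ch)
    paste0(ch, ":", seq_len(chrom_lengths[[ch]]), ":+"))
  names(out) <- names(chrom_lengths)
  out
}

walk_flip <- function(x) {
  flipped <- sub(":\\+$", ":FLIP", x)
  flipped <- sub(":-$", ":+", flipped)
  sub(":FLIP$", ":-", flipped)
}

walk_locate <- function(state, chrom, pos) {
  target <- paste0(chrom, ":", pos, ":+")
  for (ch in names(state)) {
    i <- match(target, state[[ch]])
    if (!is.na(i)) return(list(der = ch, idx = i))
  }
  stop("oracle: breakpoint not found in forward orientation")
}

walk_indel <- function(v, j, d) {
  if (d == 0) return(v)
  if (d < 0) return(v[-((j + d + 1):j)])
  dup <- paste0(v[(j - d + 1):j], ":J")
  append(v, dup, after = j)
}

walk_apply <- function(ref, planted) {
  state <- walk_identity(ref$chrom_lengths)
  for (sv in planted) {
    la <- walk_locate(state, sv$chromA, sv$posA)
    lb <- walk_locate(state, sv$chromB, sv$posB)
    if (sv$sv_type == "deletion") {
      stopifnot(la$der == lb$der)
      v <- state[[la$der]]
      v <- v[-(la$idx:lb$idx)]
      v <- walk_indel(v, la$idx - 1L, sv$junction_indel[1])
      state[[la$der]] <- v
    } else if (sv$sv_type == "inversion") {
      stopifnot(la$der == lb$der)
      v <- state[[la$der]]
      v[la$idx:lb$idx] <- walk_flip(rev(v[la$idx:lb$idx]))
      v <- walk_indel(v, lb$idx, sv$junction_indel[2])
      v <- walk_indel(v, la$idx - 1L, sv$junction_indel[1])
      state[[la$der]] <- v
    } else {
      stopifnot(la$der != lb$der)
      va <- state[[la$der]]; vb <- state[[lb$der]]
      newA <- c(va[1:la$idx], vb[(lb$idx + 1):length(vb)])
      newB <- c(vb[1:lb$idx], va[(la$idx + 1):length(va)])
      state[[la$der]] <- walk_indel(newA, la$idx, sv$junction_indel[1])
      state[[lb$der]] <- walk_indel(newB, lb$idx, sv$junction_indel[2])
    }
  }
  state
}

walk_parse <- function(addr) {
  parts <- strsplit(addr, ":", fixed = TRUE)
  data.frame(ref_chrom = vapply(parts, `[`, "", 1),
             ref_pos = as.integer(vapply(parts, `[`, "", 2)),
             orientation = vapply(parts, `[`, "", 3),
             junction = vapply(parts, function(p) length(p) == 4, TRUE))
}

# ---- brute-force single-linkage clustering oracle ------------------------
# Quadratic adjacency + BFS connected components; returns a canonical
# partition signature for comparison.

brute_cluster_partition <- function(pairs, cutoff) {
  n <- nrow(pairs)
  sig <- paste(pairs$chromA, pairs$chromB, pairs$strandA, pairs$strandB)
  adj <- outer(sig, sig, "==") &
    abs(outer(pairs$posA, pairs$posA, "-")) <= cutoff &
    abs(outer(pairs$posB, pairs$posB, "-")) <= cutoff
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1L
    queue <- s
    comp[s] <- cc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cc
      queue <- c(queue, nb)
    }
  }
  parts <- split(pairs$pair_id, comp)
  sort(vapply(parts, function(m) paste(sort(m), collapse = ","), ""))
}

cluster_partition_signature <- function(clusters) {
  sort(vapply(clusters, function(cl)
    paste(sort(cl$members$pair_id), collapse = ","), ""))
}

# Random discordant pair tables mixing signatures.
random_discordant_pairs <- function(n, chroms = c("chr1", "chr2", "chr3"),
                                    span = 2e6) {
  svpairs:::canonicalize_pairs(data.frame(pair_id = sprintf("r%04d", seq_len(n)),
             chromA = sample(chroms, n, replace = TRUE),
             posA = sample.int(span, n, replace = TRUE),
             strandA = sample(c("+", "-"), n, replace = TRUE),
             mapqA = rep(37L, n),
             chromB = sample(chroms, n, replace = TRUE),
             posB = sample.int(span, n, replace = TRUE),
             strandB = sample(c("+", "-"), n, replace = TRUE),
             mapqB = rep(37L, n), source_tag = rep("mate_pair", n),
             duplicate = rep(FALSE, n)))
}

# ---- junction-delta oracle ----------------------------------------------
# Exhaustive explanation of a junction string against its flanks: try every
# pure loss (dL bases off the left flank end, dR off the right flank start)
# and every flank-copy duplication up to 10 bp; return the feasible signed
# delta of smallest magnitude, or NA when nothing fits.

junction_delta_oracle <- function(left, right, junction) {
  L <- nchar(left); R <- nchar(right)
  feasible <- integer(0)
  for (dL in 0:10) for (dR in 0:10) {
    cand <- paste0(substr(left, 1, L - dL), substr(right, 1 + dR, R))
    if (cand == junction) feasible <- c(feasible, -(dL + dR))
  }
  for (d in 0:10) {
    cand1 <- paste0(left, substr(left, L - d + 1, L), right)
    cand2 <- paste0(left, substr(right, 1, d), right)
    if (cand1 == junction || cand2 == junction) feasible <- c(feasible, d)
  }
  if (!length(feasible)) return(NA_integer_)
  feasible[which.min(abs(feasible))]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# ---- shared fixtures -----------------------------------------------------

study_reference <- function() {
  toy_reference(c(chr1 = 10e6, chr2 = 10e6),
                centromeres = data.frame(chrom = c("chr1", "chr2"),
                                         start = c(4.5e6, 4.8e6),
                                         end = c(5.0e6, 5.2e6)))
}

study_planted <- function() {
  list(planted_sv("deletion", "chr1", 1000000, 1015000),
       planted_sv("inversion", "chr1", 6000000, 7500000),
       planted_sv("inversion", "chr2", 3000000, 8000000),
       planted_sv("reciprocal_translocation", "chr1", 2500000,
                  posB = 9200000, chromB = "chr2",
                  junction_indel = c(1L, -1L)))
}

# Synthetic discordant pairs supporting one junction: `support` members on
# each side approaching the breakpoints, signature chosen by strands.
synthetic_cluster_pairs <- function(chromA, posA, strandA, chromB, posB,
                                    strandB, support, spread = 2000,
                                    read_length = 36, prefix = "m") {
  offs <- round(seq(40, spread, length.out = support))
  pA <- if (strandA == "-") posA - offs - read_length + 1 else posA + offs
  pB <- if (strandB == "-") posB - offs - read_length + 1 else posB + offs
  data.frame(pair_id = sprintf("%s%03d", prefix, seq_len(support)),
             chromA = chromA, posA = as.integer(pA), strandA = strandA,
             mapqA = 37L,
             chromB = chromB, posB = as.integer(pB), strandB = strandB,
             mapqB = 37L, source_tag = "mate_pair", duplicate = FALSE)
}

fixed_stats <- function(median_insert = 5012) {
  structure(list(median_insert = median_insert, mad = 300,
                 n_used = 1000L, cutoff = 2 * median_insert),
            class = "insert_stats")
}
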