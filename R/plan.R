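# Derivative-chromosome construction and liftover.
#
# A derived chromosome is an ordered list of segments, each a contiguous run
# of reference bases copied either forward ("+") or reverse-complemented
# ("-"). Junction micro-duplications are carried as short segments flagged
# `junction = TRUE`. All coordinates are 1-based inclusive.

seg_widths <- function(segs) segs$ref_end - segs$ref_start + 1L

# Ensure a segment boundary exists immediately after derived position k.
split_segs <- function(segs, k) {
  cum <- cumsum(seg_widths(segs))
  total <- if (nrow(segs)) cum[nrow(segs)] else 0L
  if (k <= 0 || k >= total || k %in% cum) return(segs)
  i <- findInterval(k, c(0L, cum), left.open = TRUE)
  prev <- if (i == 1L) 0L else cum[i - 1L]
  o <- k - prev                       # bases of segment i staying left
  s <- segs[i, ]
  if (s$orient == "+") {
    left  <- transform(s, ref_end = s$ref_start + o - 1L)
    right <- transform(s, ref_start = s$ref_start + o)
  } else {
    left  <- transform(s, ref_start = s$ref_end - o + 1L)
    right <- transform(s, ref_end = s$ref_end - o)
  }
  out <- rbind(segs[seq_len(i - 1L), ], left, right,
               segs[seq_len(nrow(segs)) > i, ])
  rownames(out) <- NULL
  out
}

# Split so derived range [a, b] is a whole number of segments; return the
# pieces before, inside, and after the range.
extract_segs <- function(segs, a, b) {
  segs <- split_segs(segs, a - 1L)
  segs <- split_segs(segs, b)
  cum <- cumsum(seg_widths(segs))
  start <- cum - seg_widths(segs) + 1L
  inside <- start >= a & cum <= b
  list(before = segs[cum < a, , drop = FALSE],
       mid = segs[inside, , drop = FALSE],
       after = segs[start > b, , drop = FALSE])
}

rev_segs <- function(segs) {
  if (!nrow(segs)) return(segs)
  out <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  rownames(out) <- NULL
  out
}

cat_segs <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# Apply a signed junction indel on the left side of the junction sitting
# after derived position j: d < 0 removes |d| bases from the left flank,
# d > 0 duplicates the left flank's last d bases as junction-flagged bases.
apply_junction_indel <- function(segs, j, d) {
  d <- as.integer(d)
  if (d == 0L) return(segs)
  if (d < 0L) {
    ex <- extract_segs(segs, j + d + 1L, j)
    return(cat_segs(ex$before, ex$after))
  }
  ex <- extract_segs(segs, j - d + 1L, j)
  dup <- ex$mid
  dup$junction <- TRUE
  cat_segs(ex$before, ex$mid, dup, ex$after)
}

identity_segs <- function(chrom, len) {
  data.frame(ref_chrom = chrom, ref_start = 1L, ref_end = as.integer(len),
             orient = "+", junction = FALSE)
}

# Find the derived location of a reference base in the current state.
locate_ref_in_state <- function(state, chrom, pos) {
  for (der in names(state)) {
    segs <- state[[der]]
    cum <- cumsum(seg_widths(segs))
    start <- cum - seg_widths(segs) + 1L
    hit <- which(!segs$junction & segs$ref_chrom == chrom &
                 segs$ref_start <= pos & segs$ref_end >= pos)
    if (length(hit)) {
      i <- hit[1L]
      dpos <- if (segs$orient[i] == "+") start[i] + (pos - segs$ref_start[i])
              else start[i] + (segs$ref_end[i] - pos)
      return(list(der = der, pos = dpos, orient = segs$orient[i]))
    }
  }
  NULL
}

merge_segs <- function(segs) {
  if (nrow(segs) < 2L) return(segs)
  keep <- rep(TRUE, nrow(segs))
  for (i in 2:nrow(segs)) {
    a <- max(which(keep[1:(i - 1L)]))
    contiguous <- !segs$junction[a] && !segs$junction[i] &&
      segs$ref_chrom[a] == segs$ref_chrom[i] &&
      segs$orient[a] == segs$orient[i] &&
      ((segs$orient[i] == "+" && segs$ref_start[i] == segs$ref_end[a] + 1L) ||
       (segs$orient[i] == "-" && segs$ref_end[i] == segs$ref_start[a] - 1L))
    if (contiguous) {
      if (segs$orient[i] == "+") segs$ref_end[a] <- segs$ref_end[i]
      else segs$ref_start[a] <- segs$ref_start[i]
      keep[i] <- FALSE
    }
  }
  out <- segs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply planted structural variants to a toy reference
#'
#' Builds the derivative chromosomes produced by a list of planted SVs
#' (applied in list order, coordinates always given on the reference) and
#' returns the derived-to-reference liftover map together with a
#' ground-truth junction table used by recovery tests.
#'
#' Each junction side is recorded with its retained-flank orientation
#' (`"tail"` = reference bases up to the breakpoint retained, `"head"` =
#' bases from the breakpoint on retained) and its *departure* coordinate:
#' the first reference base, approached along the retained flank, that is no
#' longer shared with the derived chromosome. Breakpoint intervals reported
#' by [refine_intervals()] bracket exactly this coordinate.
#'
#' @param reference a [toy_reference()].
#' @param planted a [planted_sv()] or list of them; breakpoints of distinct
#'   SVs must be at least 1 kb apart.
#' @return An object of class `rearrangement_plan` with elements
#'   `segments` (derived-to-reference map), `junctions` (ground truth),
#'   `der_lengths`, `planted` and `reference`.
#' @examples
#' ref <- toy_reference(c(chrA = 10000L))
#' plan <- apply_sv_plan(ref, planted_sv("deletion", "chrA", 1001, 2000))
#' plan$der_lengths  # 9000
#' @export
apply_sv_plan <- function(reference, planted = list()) {
  stopifnot(inherits(reference, "toy_reference"))
  if (inherits(planted, "planted_sv")) planted <- list(planted)
  if (!all(vapply(planted, inherits, logical(1), "planted_sv")))
    stopf("planted must be planted_sv objects")

  lens <- reference$chrom_lengths
  bps <- do.call(rbind, lapply(seq_along(planted), function(i) {
    sv <- planted[[i]]
    data.frame(sv = i, chrom = c(sv$chromA, sv$chromB), pos = c(sv$posA, sv$posB))
  }))
  if (!is.null(bps)) {
    unknown <- !(bps$chrom %in% names(lens))
    if (any(unknown)) stopf("breakpoint on unknown chromosome: %s",
                            paste(unique(bps$chrom[unknown]), collapse = ", "))
    out <- bps$pos < 1 | bps$pos > lens[bps$chrom]
    if (any(out)) stopf("breakpoint outside chromosome: %s:%d",
                        bps$chrom[out][1], bps$pos[out][1])
    if (nrow(bps) > 1) {
      conflicts <- character(0)
      for (i in 1:(nrow(bps) - 1)) for (j in (i + 1):nrow(bps)) {
        if (bps$sv[i] != bps$sv[j] && bps$chrom[i] == bps$chrom[j] &&
            abs(bps$pos[i] - bps$pos[j]) < 1000)
          conflicts <- c(conflicts,
            sprintf("SV %d %s:%d vs SV %d %s:%d", bps$sv[i], bps$chrom[i],
                    bps$pos[i], bps$sv[j], bps$chrom[j], bps$pos[j]))
      }
      if (length(conflicts))
        stopf("planted SV breakpoints conflict (within 1 kb):\n  %s",
              paste(conflicts, collapse = "\n  "))
    }
  }

  state <- lapply(names(lens), function(ch) identity_segs(ch, lens[[ch]]))
  names(state) <- names(lens)

  for (sv in planted) {
    locA <- locate_ref_in_state(state, sv$chromA, sv$posA)
    locB <- locate_ref_in_state(state, sv$chromB, sv$posB)
    if (is.null(locA) || is.null(locB))
      stopf("%s breakpoint falls in previously deleted sequence", sv$sv_type)
    if (locA$orient != "+" || locB$orient != "+")
      stopf("%s breakpoint falls inside a previously inverted segment; reorder the planted list",
            sv$sv_type)
    if (sv$sv_type %in% c("deletion", "inversion")) {
      if (locA$der != locB$der)
        stopf("%s breakpoints no longer on one derived chromosome", sv$sv_type)
      if (locA$pos >= locB$pos)
        stopf("%s breakpoints out of order after earlier events", sv$sv_type)
      segs <- state[[locA$der]]
      if (sv$sv_type == "deletion") {
        ex <- extract_segs(segs, locA$pos, locB$pos)
        segs <- cat_segs(ex$before, ex$after)
        segs <- apply_junction_indel(segs, locA$pos - 1L, sv$junction_indel[1])
      } else {
        ex <- extract_segs(segs, locA$pos, locB$pos)
        segs <- cat_segs(ex$before, rev_segs(ex$mid), ex$after)
        # indel 2 first: it sits right of indel 1 and must not be shifted by it
        segs <- apply_junction_indel(segs, locB$pos, sv$junction_indel[2])
        segs <- apply_junction_indel(segs, locA$pos - 1L, sv$junction_indel[1])
      }
      state[[locA$der]] <- segs
    } else {
      if (locA$der == locB$der)
        stopf("reciprocal translocation breakpoints on one derived chromosome")
      exA <- extract_segs(state[[locA$der]], 1L, locA$pos)
      exB <- extract_segs(state[[locB$der]], 1L, locB$pos)
      headA <- cat_segs(exA$before, exA$mid); tailA <- exA$after
      headB <- cat_segs(exB$before, exB$mid); tailB <- exB$after
      newA <- apply_junction_indel(cat_segs(headA, tailB), locA$pos,
                                   sv$junction_indel[1])
      newB <- apply_junction_indel(cat_segs(headB, tailA), locB$pos,
                                   sv$junction_indel[2])
      state[[locA$der]] <- newA
      state[[locB$der]] <- newB
    }
  }

  state <- lapply(state, merge_segs)

  segments <- do.call(rbind, lapply(names(state), function(der) {
    segs <- state[[der]]
    w <- seg_widths(segs)
    cum <- cumsum(w)
    cbind(data.frame(der_chrom = der, der_start = cum - w + 1L, der_end = cum),
          segs)
  }))
  rownames(segments) <- NULL

  junctions <- plan_junction_table(state)
  structure(list(reference = reference, planted = planted,
                 segments = segments,
                 junctions = junctions,
                 der_lengths = vapply(state, function(s) sum(seg_widths(s)),
                                      numeric(1))),
            class = "rearrangement_plan")
}

# Ground-truth junction table: one row per non-contiguous adjacency in the
# derived genome, with per-side retained-flank orientation and departure base.
plan_junction_table <- function(state) {
  rows <- list()
  for (der in names(state)) {
    segs <- state[[der]]
    cum <- cumsum(seg_widths(segs))
    core <- which(!segs$junction)
    if (length(core) < 2L) next
    for (k in seq_len(length(core) - 1L)) {
      i <- core[k]; j <- core[k + 1L]
      dup_len <- if (j > i + 1L) sum(seg_widths(segs[(i + 1L):(j - 1L), ])) else 0L
      contiguous <- dup_len == 0L &&
        segs$ref_chrom[i] == segs$ref_chrom[j] &&
        segs$orient[i] == segs$orient[j] &&
        ((segs$orient[i] == "+" && segs$ref_start[j] == segs$ref_end[i] + 1L) ||
         (segs$orient[i] == "-" && segs$ref_end[j] == segs$ref_start[i] - 1L))
      if (contiguous) next
      if (segs$orient[i] == "+") {
        o1 <- "tail"; d1 <- segs$ref_end[i] + 1L
      } else {
        o1 <- "head"; d1 <- segs$ref_start[i] - 1L
      }
      if (segs$orient[j] == "+") {
        o2 <- "head"; d2 <- segs$ref_start[j] - 1L
      } else {
        o2 <- "tail"; d2 <- segs$ref_end[j] + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        der_chrom = der, der_pos = cum[i],
        chrom1 = segs$ref_chrom[i], departure1 = d1, orient1 = o1,
        chrom2 = segs$ref_chrom[j], departure2 = d2, orient2 = o2,
        dup_len = dup_len)
    }
  }
  if (!length(rows))
    return(data.frame(der_chrom = character(0), der_pos = integer(0),
                      chrom1 = character(0), departure1 = integer(0),
                      orient1 = character(0), chrom2 = character(0),
                      departure2 = integer(0), orient2 = character(0),
                      dup_len = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rearrangement_plan <- function(x, ...) {
  cat(sprintf("rearrangement_plan: %d planted SV(s), %d junction(s), %d derived chromosome(s)\n",
              length(x$planted), nrow(x$junctions), length(x$der_lengths)))
  invisible(x)
}

#' Lift derived coordinates back to the reference
#'
#' Maps positions on a derived chromosome to the unique underlying reference
#' base; orientation is `"-"` inside inverted segments. Bases created by a
#' junction micro-duplication are flagged `junction = TRUE` (the reference
#' coordinate returned is that of the copied base).
#'
#' @param plan a [apply_sv_plan()] result.
#' @param der_chrom derived chromosome name(s), recycled against `der_pos`.
#' @param der_pos 1-based derived position(s).
#' @return data.frame with columns `ref_chrom`, `ref_pos`, `orientation`,
#'   `junction`.
#' @export
lift_to_reference <- function(plan, der_chrom, der_pos) {
  stopifnot(inherits(plan, "rearrangement_plan"))
  n <- max(length(der_chrom), length(der_pos))
  der_chrom <- rep_len(as.character(der_chrom), n)
  der_pos <- rep_len(as.integer(der_pos), n)
  out <- data.frame(ref_chrom = character(n), ref_pos = NA_integer_,
                    orientation = character(n), junction = NA)
  segs <- plan$segments
  for (der in unique(der_chrom)) {
    s <- segs[segs$der_chrom == der, , drop = FALSE]
    if (!nrow(s)) stopf("unknown derived chromosome '%s'", der)
    sel <- which(der_chrom == der)
    p <- der_pos[sel]
    if (any(p < 1L | p > s$der_end[nrow(s)]))
      stopf("derived position outside chromosome %s", der)
    i <- findInterval(p, s$der_start)
    fwd <- s$orient[i] == "+"
    rp <- ifelse(fwd, s$ref_start[i] + (p - s$der_start[i]),
                 s$ref_end[i] - (p - s$der_start[i]))
    out$ref_chrom[sel] <- s$ref_chrom[i]
    out$ref_pos[sel] <- rp
    out$orientation[sel] <- ifelse(fwd, "+", "-")
    out$junction[sel] <- s$junction[i]
  }
  out
}

#' Locate reference bases in the derived genome
#'
#' Inverse of [lift_to_reference()] over non-junction bases. Deleted
#' reference bases return `NA` coordinates with `deleted = TRUE`.
#'
#' @inheritParams lift_to_reference
#' @param ref_chrom,ref_pos reference coordinates, recycled to equal length.
#' @return data.frame with columns `der_chrom`, `der_pos`, `orientation`,
#'   `deleted`.
#' @export
locate_in_derived <- function(plan, ref_chrom, ref_pos) {
  stopifnot(inherits(plan, "rearrangement_plan"))
  n <- max(length(ref_chrom), length(ref_pos))
  ref_chrom <- rep_len(as.character(ref_chrom), n)
  ref_pos <- rep_len(as.integer(ref_pos), n)
  out <- data.frame(der_chrom = NA_character_, der_pos = NA_integer_,
                    orientation = NA_character_, deleted = TRUE)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  segs <- plan$segments[!plan$segments$junction, , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    sel <- which(ref_chrom == s$ref_chrom & ref_pos >= s$ref_start &
                 ref_pos <= s$ref_end & out$deleted)
    if (!length(sel)) next
    p <- ref_pos[sel]
    dp <- if (s$orient == "+") s$der_start + (p - s$ref_start)
          else s$der_start + (s$ref_end - p)
    out$der_chrom[sel] <- s$der_chrom
    out$der_pos[sel] <- dp
    out$orientation[sel] <- s$orient
    out$deleted[sel] <- FALSE
  }
  out
}
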