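# Internal helpers shared across modules.

# Deterministic ordering key for chromosome names: numeric chromosomes first
# in natural order, then X, Y, M/MT, then anything else alphabetically.
chrom_key <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.numeric(x))
  key <- ifelse(!is.na(n), n,
         ifelse(x == "X", 1e6,
         ifelse(x == "Y", 1e6 + 1,
         ifelse(x %in% c("M", "MT"), 1e6 + 2, 2e6))))
  key
}

# TRUE where chromosome a sorts strictly before chromosome b.
chrom_before <- function(a, b) {
  ka <- chrom_key(a); kb <- chrom_key(b)
  ka < kb | (ka == kb & as.character(a) < as.character(b))
}

chrom_order <- function(chrom, pos = NULL) {
  if (is.null(pos)) order(chrom_key(chrom), as.character(chrom))
  else order(chrom_key(chrom), as.character(chrom), pos)
}

# Run an expression with a private RNG stream seeded from `seed`, restoring
# the caller's RNG state afterwards so simulation calls are side-effect free.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Reverse complement for plain character DNA (A/C/G/T/N, case-insensitive).
revcomp <- function(x) {
  chartr("ACGTacgtNn", "TGCAtgcaNn",
         vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}
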