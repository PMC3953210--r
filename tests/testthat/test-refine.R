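# Breakpoint-interval refinement geometry.

one_member_cluster <- function(posA, strandA, posB = 5e6, strandB = "+",
                               chromA = "chr1", chromB = "chr9") {
  m <- data.frame(pair_id = "m1", chromA = chromA, posA = as.integer(posA),
                  strandA = strandA, mapqA = 37L, chromB = chromB,
                  posB = as.integer(posB), strandB = strandB, mapqB = 37L,
                  source_tag = "mate_pair", duplicate = FALSE)
  structure(list(chromA = chromA, chromB = chromB, strandA = strandA,
                 strandB = strandB, members = m, support = 1L,
                 intervalA = NULL, intervalB = NULL),
            class = "discordant_cluster")
}

test_that("a single forward-facing read bounds the junction ahead of its end", {
  # + read starting at 1,000 under FR: fragment extends right, junction right
  stats <- structure(list(median_insert = 5000, mad = 0, n_used = 100L,
                          cutoff = 10000), class = "insert_stats")
  cfg <- pipeline_config(orientation = "FR", read_length = 36L)
  cl <- refine_intervals(one_member_cluster(1000, "+", strandB = "-"),
                         stats, cfg)
  expect_equal(cl$intervalA[1], 1036)
  expect_lte(cl$intervalA[2] - cl$intervalA[1] + 1, stats$cutoff)
  expect_equal(cl$orientA, "tail")
})

test_that("interval width shrinks monotonically as members stack up", {
  stats <- fixed_stats(5000)
  cfg <- pipeline_config()
  full <- synthetic_cluster_pairs("chr3", 4e6, "-", "chr5", 6e6, "+",
                                  support = 30, spread = 4000)
  widths <- vapply(2:30, function(k) {
    cl <- cluster_discordant(full[1:k, ], stats, min_support = 1)[[1]]
    cl <- refine_intervals(cl, stats, cfg)
    (cl$intervalA[2] - cl$intervalA[1] + 1) +
      (cl$intervalB[2] - cl$intervalB[1] + 1)
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  # a 30-member stack is strictly tighter than any single member's bound
  single <- refine_intervals(
    cluster_discordant(full[1, , drop = FALSE], stats, min_support = 1)[[1]],
    stats, cfg)
  expect_lt(widths[length(widths)],
            single$intervalA[2] - single$intervalA[1] + 1 +
              single$intervalB[2] - single$intervalB[1] + 1)
})

test_that("interval widths never exceed the cutoff on random clusters", {
  stats <- fixed_stats(5000)
  cfg <- pipeline_config()
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    pos <- 2e6 + sample.int(3000, 1)
    cl <- cluster_discordant(
      synthetic_cluster_pairs("chr1", pos, "-", "chr2", 3e6, "+", n,
                              spread = sample(500:4000, 1)),
      stats, min_support = 1)[[1]]
    cl <- refine_intervals(cl, stats, cfg)
    expect_lte(cl$intervalA[2] - cl$intervalA[1] + 1, stats$cutoff)
    expect_lte(cl$intervalB[2] - cl$intervalB[1] + 1, stats$cutoff)
  }
})

test_that("planted translocation junctions land inside refined intervals", {
  ref <- toy_reference(c(chr1 = 2e6, chr2 = 2e6))
  plan <- apply_sv_plan(ref,
    planted_sv("reciprocal_translocation", "chr1", 987654, posB = 1234567,
               chromB = "chr2"))
  cfg <- pipeline_config()
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    lib <- library_model(median_insert = 5000, n_pairs = 30000L, seed = seed)
    pairs <- simulate_pairs(plan, lib)
    stats <- estimate_insert_stats(pairs, cfg)
    inter <- pairs[classify_pairs(pairs, stats, cfg) == "interchromosomal", ]
    clusters <- cluster_discordant(inter, stats, min_support = 6)
    expect_gte(length(clusters), 2)
    for (cl in clusters) {
      cl <- refine_intervals(cl, stats, cfg)
      jx <- plan$junctions
      side_hit <- function(interval, chrom_side, dep_side, strand_chrom)
        any(jx[[chrom_side]] == strand_chrom &
            jx[[dep_side]] >= interval[1] & jx[[dep_side]] <= interval[2])
      okA <- side_hit(cl$intervalA, "chrom1", "departure1", cl$chromA) ||
             side_hit(cl$intervalA, "chrom2", "departure2", cl$chromA)
      okB <- side_hit(cl$intervalB, "chrom1", "departure1", cl$chromB) ||
             side_hit(cl$intervalB, "chrom2", "departure2", cl$chromB)
      hits <- hits + okA + okB
      total <- total + 2L
    }
  }
  expect_equal(hits, total)  # every refined interval brackets its junction
})

test_that("members violating the cluster signature are rejected", {
  stats <- fixed_stats(5000)
  cl <- one_member_cluster(1000, "-")
  cl$members$strandA <- "+"
  expect_error(refine_intervals(cl, stats, pipeline_config()),
               "signature")
})
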