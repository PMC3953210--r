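# Coverage, enrichment and validation metrics.

test_that("spanning coverage is the plain pairs x insert / genome formula", {
  expect_equal(spanning_coverage(1e6, 5000, 1e9)$spanning_depth, 5)
  expect_equal(spanning_coverage(2e5, 5000, 1e9)$spanning_depth, 1)
  # linear in every argument
  base <- spanning_coverage(28.2e6, 5012, 3.0957e9)$spanning_depth
  expect_equal(spanning_coverage(2 * 28.2e6, 5012, 3.0957e9)$spanning_depth,
               2 * base)
  expect_equal(spanning_coverage(28.2e6, 5012, 2 * 3.0957e9)$spanning_depth,
               base / 2)
  expect_error(spanning_coverage(0, 5000, 1e9), "> 0")
})

test_that("uniform coverage means fold 1 everywhere; all-on-target is the limit case", {
  lens <- c(chr1 = 2e6, chr2 = 1e6, chr3 = 1e6)
  uniform <- round(lens / 100)
  for (ch in names(lens))
    expect_equal(chromosome_enrichment(uniform, lens, ch)$fold, 1)
  all_t <- c(chr1 = 1000, chr2 = 0, chr3 = 0)
  expect_equal(chromosome_enrichment(all_t, lens, "chr1")$fold,
               sum(lens) / lens[["chr1"]])
})

test_that("length-weighted folds conserve to exactly 1", {
  set.seed(9)
  lens <- c(chr1 = 3e6, chr2 = 2e6, chr3 = 5e5)
  counts <- c(chr1 = rpois(1, 5000), chr2 = rpois(1, 1000),
              chr3 = rpois(1, 9000))
  res <- chromosome_enrichment(counts, lens, "chr3")
  w <- res$table$expected_fraction
  expect_equal(sum(res$table$fold * w), 1)
})

test_that("oversampled simulated reads show the planted enrichment", {
  ref <- toy_reference(c(chr1 = 2e6, chr2 = 2e6))
  plan <- apply_sv_plan(ref, list())
  # emulate flow-sorting by resampling chr1 pairs 5x
  pairs <- simulate_pairs(plan, library_model(median_insert = 5000,
                                              n_pairs = 12000L, seed = 13L))
  keep <- pairs$chromA == "chr1"
  enriched <- rbind(pairs, pairs[rep(which(keep), 4), ])
  counts <- table(enriched$chromA)
  res <- chromosome_enrichment(c(chr1 = counts[["chr1"]],
                                 chr2 = counts[["chr2"]]),
                               c(chr1 = 2e6, chr2 = 2e6), "chr1")
  # raw density of chr1 vs chr2 should sit near 5
  expect_lt(abs(res$fold_vs_rest - 5), 0.35)
})

val_call <- function(id, sv_type, chrom, p1, p2, chrom2 = chrom) {
  data.frame(call_id = id, sv_type = sv_type, chrom1 = chrom,
             pos1 = as.integer(p1), chrom2 = chrom2, pos2 = as.integer(p2))
}

test_that("ten confirmed out of eleven predicted reports 91%", {
  predicted <- do.call(rbind, lapply(1:11, function(i)
    val_call(sprintf("p%02d", i), "deletion", "chr2",
             i * 1e6, i * 1e6 + 20000)))
  confirmed <- do.call(rbind, lapply(1:10, function(i)
    val_call(sprintf("c%02d", i), "deletion", "chr2",
             i * 1e6 + 3000, i * 1e6 + 23000)))  # ~0.74 reciprocal overlap
  res <- validate_callsets(predicted, confirmed)
  expect_equal(res$n_predicted, 11L)
  expect_equal(res$n_confirmed, 10L)
  expect_equal(res$rate, 1000 / 11)
  expect_equal(res$rate_rounded, 91)
})

test_that("identical sets validate fully and disjoint sets not at all", {
  a <- rbind(val_call("a1", "deletion", "chr1", 1e6, 1.05e6),
             val_call("a2", "inversion", "chr2", 2e6, 3e6))
  expect_equal(validate_callsets(a, a)$rate, 100)
  b <- rbind(val_call("b1", "deletion", "chr9", 1e6, 1.05e6))
  expect_equal(validate_callsets(a, b)$rate, 0)
  expect_error(validate_callsets(a[0, ], a), "empty predicted")
})

test_that("translocations match on both breakpoints within the tolerance", {
  p <- val_call("p1", "reciprocal_translocation", "chr2", 8181790,
                135245984, chrom2 = "chr7")
  hit <- val_call("c1", "reciprocal_translocation", "chr2", 8185000,
                  135240000, chrom2 = "chr7")
  far <- val_call("c2", "reciprocal_translocation", "chr2", 8300000,
                  135240000, chrom2 = "chr7")
  expect_equal(validate_callsets(p, hit)$rate, 100)
  expect_equal(validate_callsets(p, far)$rate, 0)
  # swapped chromosome order still matches
  swapped <- val_call("c3", "reciprocal_translocation", "chr7", 135240000,
                      8185000, chrom2 = "chr2")
  expect_equal(validate_callsets(p, swapped)$rate, 100)
})

test_that("the validation rate is monotone in both call sets", {
  set.seed(41)
  predicted <- do.call(rbind, lapply(1:8, function(i)
    val_call(sprintf("p%02d", i), "deletion", "chr1",
             i * 2e6, i * 2e6 + 30000)))
  confirmed <- predicted[sample(8, 5), ]
  base <- validate_callsets(predicted, confirmed)$rate
  # adding a confirmed call never decreases the rate
  more_conf <- rbind(confirmed, predicted[1, ])
  expect_gte(validate_callsets(predicted, more_conf)$rate, base)
  # adding an unmatched prediction never increases it
  more_pred <- rbind(predicted,
                     val_call("px", "deletion", "chr5", 1e6, 1.2e6))
  expect_lte(validate_callsets(more_pred, confirmed)$rate, base)
})
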