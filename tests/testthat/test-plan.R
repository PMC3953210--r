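# Derivative-chromosome construction and liftover.

test_that("empty plan is the identity map", {
  ref <- toy_reference(c(chrA = 5000L, chrB = 3000L))
  plan <- apply_sv_plan(ref, list())
  expect_equal(unname(plan$der_lengths), c(5000, 3000))
  expect_equal(nrow(plan$junctions), 0L)
  lifted <- lift_to_reference(plan, "chrA", c(1L, 500L, 5000L))
  expect_equal(lifted$ref_pos, c(1L, 500L, 5000L))
  expect_equal(lifted$ref_chrom, rep("chrA", 3))
  expect_equal(lifted$orientation, rep("+", 3))
})

test_that("a deletion shifts downstream coordinates by its width", {
  ref <- toy_reference(c(chrA = 10000L))
  plan <- apply_sv_plan(ref, planted_sv("deletion", "chrA", 1001, 2000))
  expect_equal(unname(plan$der_lengths), 9000)
  expect_equal(lift_to_reference(plan, "chrA", 1001)$ref_pos, 2001L)
  expect_equal(lift_to_reference(plan, "chrA", 1000)$ref_pos, 1000L)
  loc <- locate_in_derived(plan, "chrA", c(1000L, 1500L, 2001L))
  expect_equal(loc$der_pos, c(1000L, NA, 1001L))
  expect_equal(loc$deleted, c(FALSE, TRUE, FALSE))
})

test_that("reciprocal translocation derivative lengths honour the junction indel", {
  lenA <- 20000L; lenB <- 30000L
  ref <- toy_reference(c(chrA = lenA, chrB = lenB))
  plan <- apply_sv_plan(ref,
    planted_sv("reciprocal_translocation", "chrA", 5000, posB = 7000,
               chromB = "chrB", junction_indel = c(0L, -1L)))
  expect_equal(unname(plan$der_lengths["chrA"]), 5000 + (lenB - 7000))
  expect_equal(unname(plan$der_lengths["chrB"]), 7000 + (lenA - 5000) - 1)
  # first base after the derA junction is chrB:7001
  j <- lift_to_reference(plan, "chrA", 5001)
  expect_equal(j$ref_chrom, "chrB")
  expect_equal(j$ref_pos, 7001L)
})

test_that("inverted segments lift with mirrored coordinates and flipped orientation", {
  ref <- toy_reference(c(chrA = 10000L))
  plan <- apply_sv_plan(ref, planted_sv("inversion", "chrA", 2000, 8000))
  for (k in c(0L, 1L, 137L, 6000L)) {
    l <- lift_to_reference(plan, "chrA", 2000L + k)
    expect_equal(l$ref_pos, 8000L - k)
    expect_equal(l$orientation, "-")
  }
  expect_equal(lift_to_reference(plan, "chrA", 1999)$orientation, "+")
})

test_that("segment map agrees with a per-base walk oracle, junction flags included", {
  ref <- toy_reference(c(chrA = 12000L, chrB = 15000L))
  planted <- list(
    planted_sv("deletion", "chrA", 2001, 2500, junction_indel = -2L),
    planted_sv("inversion", "chrB", 4000, 9000, junction_indel = c(1L, 0L)),
    planted_sv("reciprocal_translocation", "chrA", 8000, posB = 12000,
               chromB = "chrB", junction_indel = c(2L, -1L)))
  plan <- apply_sv_plan(ref, planted)
  oracle <- walk_apply(ref, planted)
  expect_equal(plan$der_lengths,
               vapply(oracle, length, numeric(1))[names(plan$der_lengths)])
  for (der in names(oracle)) {
    want <- walk_parse(oracle[[der]])
    got <- lift_to_reference(plan, der, seq_along(oracle[[der]]))
    expect_equal(got$ref_chrom, want$ref_chrom)
    expect_equal(got$ref_pos, want$ref_pos)
    expect_equal(got$junction, want$junction)
    # orientation comparison is meaningful for non-junction bases
    expect_equal(got$orientation[!want$junction],
                 want$orientation[!want$junction])
  }
})

test_that("liftover round-trips and conserves non-deleted bases", {
  ref <- toy_reference(c(chrA = 12000L, chrB = 15000L))
  planted <- list(
    planted_sv("deletion", "chrA", 2001, 2500),
    planted_sv("inversion", "chrB", 4000, 9000),
    planted_sv("reciprocal_translocation", "chrA", 8000, posB = 12000,
               chromB = "chrB"))
  plan <- apply_sv_plan(ref, planted)
  non_junction <- sum(plan$der_lengths) -
    sum(plan$segments$junction *
          (plan$segments$der_end - plan$segments$der_start + 1))
  expect_equal(non_junction, 12000 + 15000 - 500)
  for (der in names(plan$der_lengths)) {
    pos <- seq_len(plan$der_lengths[[der]])
    fwd <- lift_to_reference(plan, der, pos)
    keep <- !fwd$junction
    back <- locate_in_derived(plan, fwd$ref_chrom[keep], fwd$ref_pos[keep])
    expect_false(any(back$deleted))
    expect_equal(back$der_chrom, rep(der, sum(keep)))
    expect_equal(back$der_pos, pos[keep])
  }
})

test_that("conflicting or out-of-range planted SVs are rejected", {
  ref <- toy_reference(c(chrA = 10000L, chrB = 10000L))
  expect_error(apply_sv_plan(ref, planted_sv("deletion", "chrA", 500, 20000)),
               "outside chromosome")
  expect_error(
    apply_sv_plan(ref, list(planted_sv("deletion", "chrA", 2000, 3000),
                            planted_sv("inversion", "chrA", 3500, 6000))),
    "conflict")
  expect_error(planted_sv("deletion", "chrA", 3000, 2000), "posA < posB")
  expect_error(planted_sv("deletion", "chrA", 1000, 2000,
                          junction_indel = -11L), "<= 10")
})
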