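# Cytoband lookup and karyotype assembly.

toy_bands <- cytoband_map(data.frame(
  chrom = c("chrT", "chrT"), start = c(1, 5001), end = c(5000, 10000),
  band = c("p1", "q1")))

test_that("band lookup is total and boundary ties go to the earlier band", {
  expect_equal(band_for_position(toy_bands, "chrT", 4000), "p1")
  expect_equal(band_for_position(toy_bands, "chrT", 5000), "p1")
  expect_equal(band_for_position(toy_bands, "chrT", 5001), "q1")
  expect_error(band_for_position(toy_bands, "chrZ", 10), "does not cover")
  # every covered position maps to exactly one band
  got <- band_for_position(toy_bands, "chrT", 1:10000)
  expect_equal(as.vector(table(got)[c("p1", "q1")]), c(5000L, 5000L))
})

test_that("a UCSC-format cytoband file reads into 1-based closed bands", {
  path <- system.file("extdata", "toy_cytoBand.txt", package = "svpairs")
  cb <- read_cytobands(path)
  expect_s3_class(cb, "cytoband_map")
  expect_equal(band_for_position(cb, "chr2", 8181790), "p25.1")
  expect_equal(band_for_position(cb, "chr7", 135245984), "q33")
  expect_equal(band_for_position(cb, "chr2", 10000000), "p25.1")  # boundary
  expect_equal(band_for_position(cb, "chr2", 10000001), "p24.1")
})

mk_call <- function(sv_type, chrom1, pos1, chrom2, pos2, id = "sv01") {
  data.frame(call_id = id, sv_type = sv_type, chrom1 = chrom1,
             pos1 = as.integer(pos1), ci1_lo = as.integer(pos1),
             ci1_hi = as.integer(pos1), orient1 = "tail", strand1 = "-",
             chrom2 = chrom2, pos2 = as.integer(pos2),
             ci2_lo = as.integer(pos2), ci2_hi = as.integer(pos2),
             orient2 = "head", strand2 = "+", support = 10L,
             span = NA_real_, inversion_class = NA_character_,
             n_junctions = 1L, cluster_ids = "1")
}

test_that("karyotype tokens follow ISCN-like syntax", {
  cb <- read_cytobands(system.file("extdata", "toy_cytoBand.txt",
                                   package = "svpairs"))
  calls <- rbind(
    mk_call("reciprocal_translocation", "chr2", 8181790, "chr7", 135245984,
            "sv01"),
    mk_call("inversion", "chr2", 22350265, "chr2", 162196595, "sv02"),
    mk_call("inversion", "chr2", 185679985, "chr2", 188161779, "sv03"),
    mk_call("deletion", "chr19", 54800252, "chr19", 54809071, "sv04"))
  rep <- karyotype_string(calls, cb, base_karyotype = "46,XY")
  expect_equal(rep$tokens$token,
               c("t(2;7)(p25.1;q33)", "inv(2)(p24.1q24.2)",
                 "inv(2)(q32.1q32.1)", "del(19)(q13.4)"))
  expect_equal(rep$karyotype,
               "46,XY,t(2;7)(p25.1;q33),inv(2)(p24.1q24.2),inv(2)(q32.1q32.1),del(19)(q13.4)")
})

test_that("translocation tokens order chromosomes numerically", {
  cb <- read_cytobands(system.file("extdata", "toy_cytoBand.txt",
                                   package = "svpairs"))
  call <- mk_call("reciprocal_translocation", "chr7", 135245984,
                  "chr2", 8181790)
  expect_equal(karyotype_string(call, cb)$tokens$token, "t(2;7)(p25.1;q33)")
})

test_that("an empty call set leaves the base karyotype unchanged", {
  cb <- toy_bands
  rep <- karyotype_string(svpairs:::empty_calls(), cb, "46,XY")
  expect_equal(rep$karyotype, "46,XY")
})

test_that("a failed band lookup degrades to coordinate form with a warning", {
  call <- mk_call("deletion", "chrT", 11000, "chrT", 12000)  # beyond q1
  expect_warning(rep <- karyotype_string(call, toy_bands), "coordinate form")
  expect_match(rep$tokens$token, "^del\\(chrT:11000")
})

test_that("the disrupted-gene report mirrors the per-breakpoint table layout", {
  genes <- gene_set(
    gene_model("GENEA", "chr2", "+", seq(8e6, by = 1e5, length.out = 8),
               seq(8e6, by = 1e5, length.out = 8) + 2e4),
    gene_model("GENEB", "chr7", "+",
               seq(135.2e6, by = 1e5, length.out = 5),
               seq(135.2e6, by = 1e5, length.out = 5) + 2e4))
  cb <- read_cytobands(system.file("extdata", "toy_cytoBand.txt",
                                   package = "svpairs"))
  call <- mk_call("reciprocal_translocation", "chr2", 8150000,
                  "chr7", 135250000)
  call$n_junctions <- 2L
  rep <- disruption_report(call, genes, cb)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$disrupted_gene, c("GENEA", "GENEB"))
  expect_equal(rep$revised_karyotype, rep("t(2;7)(p25.1;q33)", 2))
  expect_true(all(rep$exon_count == c(8, 5)))
})
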