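# Breakpoint localisation and fusion prediction.

toy_gene <- function(strand = "+", chrom = "chrT", id = "G1") {
  gene_model(id, chrom, strand, exon_starts = c(100, 300),
             exon_ends = c(200, 400))
}

test_that("intron/exon numbering follows transcript order on both strands", {
  plus <- toy_gene("+")
  minus <- toy_gene("-")
  expect_equal(locate_breakpoint(plus, "chrT", 250)$label, "intron1")
  expect_equal(locate_breakpoint(plus, "chrT", 150)$label, "exon1")
  expect_equal(locate_breakpoint(plus, "chrT", 350)$label, "exon2")
  # minus strand: genomic gap 201..299 is still between transcript exons 1|2
  expect_equal(locate_breakpoint(minus, "chrT", 250)$label, "intron1")
  expect_equal(locate_breakpoint(minus, "chrT", 150)$label, "exon2")
  expect_equal(locate_breakpoint(minus, "chrT", 350)$label, "exon1")
})

test_that("intergenic breakpoints report nearest gene, distance and side", {
  g <- toy_gene("+")
  ann <- locate_breakpoint(g, "chrT", 500)
  expect_equal(ann$region, "intergenic")
  expect_equal(ann$nearest_gene, "G1")
  expect_equal(ann$distance, 100L)
  expect_equal(ann$relative, "downstream")
  expect_equal(locate_breakpoint(g, "chrT", 50)$relative, "upstream")
  expect_equal(locate_breakpoint(toy_gene("-"), "chrT", 50)$relative,
               "downstream")
})

test_that("annotation is invariant under genome reflection with strand flip", {
  # reflecting all coordinates about the chromosome midpoint and flipping
  # the strand must preserve every transcript-order label
  set.seed(52)
  L <- 100000L
  for (rep in 1:10) {
    n_ex <- sample(2:8, 1)
    starts <- sort(sample.int(L - 200, n_ex))
    starts <- starts + cumsum(rep(150, n_ex))       # enforce gaps
    ends <- starts + sample(30:120, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    g <- gene_model("G", "chrT", strand, starts, ends)
    gr <- gene_model("G", "chrT", if (strand == "+") "-" else "+",
                     rev(2L * L - ends), rev(2L * L - starts))
    for (pos in sample(seq(min(starts), max(ends)), 20)) {
      a <- locate_breakpoint(g, "chrT", pos)
      b <- locate_breakpoint(gr, "chrT", 2L * L - pos)
      expect_equal(a$label, b$label)
    }
  }
})

test_that("overlapping genes are all reported with the longest as primary", {
  genes <- gene_set(
    gene_model("short", "chrT", "+", 1000, 1500),
    gene_model("long", "chrT", "+", c(900, 1800), c(1100, 2500)))
  ann <- locate_breakpoint(genes, "chrT", 1050)
  expect_setequal(ann$hits, c("short", "long"))
  expect_equal(ann$gene_id, "long")
})

fusion_genes <- function(strandA = "+", strandB = "+") {
  # gene A: 43 exons on chrA; breakpoint intron 1. gene B: 8 exons on chrB;
  # breakpoint intron 7.
  ea <- seq(10000, by = 2000, length.out = 43)
  eb <- seq(50000, by = 2000, length.out = 8)
  gene_set(
    gene_model("A", "chrA", strandA, ea, ea + 500),
    gene_model("B", "chrB", strandB, eb, eb + 500))
}

reciprocal_call <- function(posA, posB, orient1 = "tail", orient2 = "head") {
  data.frame(call_id = "sv01", sv_type = "reciprocal_translocation",
             chrom1 = "chrA", pos1 = as.integer(posA),
             ci1_lo = as.integer(posA), ci1_hi = as.integer(posA),
             orient1 = orient1, strand1 = "-",
             chrom2 = "chrB", pos2 = as.integer(posB),
             ci2_lo = as.integer(posB), ci2_hi = as.integer(posB),
             orient2 = orient2, strand2 = "+",
             support = 30L, span = NA_real_,
             inversion_class = NA_character_, n_junctions = 2L,
             cluster_ids = "1,2")
}

test_that("a compatible reciprocal translocation yields exactly the two reciprocal products", {
  genes <- fusion_genes("+", "+")
  # intron1 of A is between exons 1 and 2; intron7 of B between 7 and 8
  call <- reciprocal_call(posA = 11000, posB = 63000)
  fus <- predict_fusions(call, genes)
  expect_equal(nrow(fus), 2L)
  expect_setequal(fus$label, c("Aex1_Bex8", "Bex1-7_Aex2-43"))
  expect_true(all(fus$orientation_compatible))
})

test_that("genes transcribing towards each other across an inversion junction fuse nothing", {
  genes <- gene_set(
    gene_model("P", "chrA", "+", c(10000, 14000), c(10500, 14500)),
    gene_model("Q", "chrA", "+", c(60000, 64000), c(60500, 64500)))
  call <- data.frame(call_id = "sv01", sv_type = "inversion",
                     chrom1 = "chrA", pos1 = 12000L, ci1_lo = 12000L,
                     ci1_hi = 12000L, orient1 = "tail", strand1 = "-",
                     chrom2 = "chrA", pos2 = 62000L, ci2_lo = 62000L,
                     ci2_hi = 62000L, orient2 = "tail", strand2 = "-",
                     support = 24L, span = 50000, inversion_class = "paracentric",
                     n_junctions = 2L, cluster_ids = "1,2")
  fus <- predict_fusions(call, genes)
  expect_equal(nrow(fus), 0L)
  # opposite-strand partners across the same junction do fuse
  genes2 <- gene_set(
    gene_model("P", "chrA", "+", c(10000, 14000), c(10500, 14500)),
    gene_model("Q", "chrA", "-", c(60000, 64000), c(60500, 64500)))
  expect_equal(nrow(predict_fusions(call, genes2)), 2L)
})

test_that("an intergenic side never produces a fusion", {
  genes <- fusion_genes()
  call <- reciprocal_call(posA = 11000, posB = 5000)  # chrB side intergenic
  expect_equal(nrow(predict_fusions(call, genes)), 0L)
})

test_that("fusion direction logic matches a hand-written adjacency oracle", {
  # for every flank/strand combination at a two-gene junction, transcription
  # runs through the junction iff exactly one side is a 5' donor
  oracle_compatible <- function(orientA, strandA, orientB, strandB) {
    donorA <- (orientA == "tail" && strandA == "+") ||
              (orientA == "head" && strandA == "-")
    donorB <- (orientB == "tail" && strandB == "+") ||
              (orientB == "head" && strandB == "-")
    xor(donorA, donorB)
  }
  for (oA in c("tail", "head")) for (sA in c("+", "-"))
    for (oB in c("tail", "head")) for (sB in c("+", "-")) {
      genes <- fusion_genes(sA, sB)
      call <- reciprocal_call(11000, 63000, orient1 = oA, orient2 = oB)
      call$n_junctions <- 1L   # inspect a single junction at a time
      fus <- predict_fusions(call, genes)
      expect_equal(nrow(fus) == 1L,
                   oracle_compatible(oA, sA, oB, sB),
                   info = paste(oA, sA, oB, sB))
      if (nrow(fus)) {
        # retained lists are a transcript-order prefix (5') and suffix (3')
        expect_match(fus$five_exons, "^ex1($|-)")
        expect_match(fus$three_exons, "(^ex|-)(43|8)$")
      }
    }
})
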