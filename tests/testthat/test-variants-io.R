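test_that("variant kinds follow VCF allele conventions", {
  df <- data.frame(chrom = "chr1", pos = c(100, 100, 100, 100),
                   ref = c("C", "C", "CAG", "CA"),
                   alt = c("T", "CAG", "C", "GT"),
                   sample = "s")
  v <- variant_set(df)
  expect_setequal(v$kind, c("SBS", "INS", "DEL", "OTHER"))
})

test_that("variant sets are sorted and deduplicated", {
  df <- data.frame(chrom = c("chr2", "chr1", "chr1", "chr1"),
                   pos = c(5L, 9L, 2L, 9L),
                   ref = "C", alt = "T", sample = "s")
  v <- variant_set(df)
  expect_equal(nrow(v), 3)                   # exact duplicate dropped
  expect_equal(v$pos, c(2L, 9L, 5L))
  expect_equal(v$chrom, c("chr1", "chr1", "chr2"))
})

test_that("minimal VCF parses with kind assignment and multiallelic split", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tC\tT\t.\t.\tSAMPLE=tumor1",
    "chr1\t200\t.\tCAG\tC\t.\t.\tSAMPLE=tumor1",
    "chr1\t300\t.\tA\tG,T\t.\t.\tSAMPLE=tumor1",
    "chr1\t400\t.\tT\t<DEL>\t.\t.\tSAMPLE=tumor1"), f)
  v <- read_variants(f)
  expect_equal(nrow(v), 4)                   # multiallelic split, symbolic skipped
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(v$kind[v$pos == 100], "SBS")
  expect_equal(v$kind[v$pos == 200], "DEL")
  expect_equal(sort(v$alt[v$pos == 300]), c("G", "T"))
  expect_true(all(v$sample == "tumor1"))
})

test_that("empty VCF with a valid header gives an empty set", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), f)
  expect_equal(nrow(read_variants(f)), 0)
})

test_that("malformed VCF records name the offending line", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tC\tT\t.\t.\t.",
               "chr1\t100\tbroken"), f)
  expect_error(read_variants(f), "line 4")
})

test_that("variants round-trip through VCF and TSV preserving the core fields", {
  df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   pos = c(10L, 50L, 7L),
                   ref = c("C", "CAT", "G"),
                   alt = c("A", "C", "GTT"),
                   sample = c("a", "a", "b"))
  v <- variant_set(df)
  for (fmt in c("VCF", "TSV")) {
    f <- tempfile(fileext = paste0(".", tolower(fmt)))
    write_variants(v, f, fmt)
    back <- read_variants(f, fmt)
    expect_equal(as.data.frame(back)[c("chrom", "pos", "ref", "alt", "sample")],
                 as.data.frame(v)[c("chrom", "pos", "ref", "alt", "sample")],
                 info = fmt)
  }
})

test_that("consensus intersection keeps set-a records overlapping set b", {
  a <- variant_set(data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                              sample = "s"))
  b_same <- variant_set(data.frame(chrom = "chr1", pos = 100L, ref = "C",
                                   alt = "T", sample = "s"))
  b_off <- variant_set(data.frame(chrom = "chr1", pos = 101L, ref = "C",
                                  alt = "T", sample = "s"))
  expect_equal(nrow(consensus_intersect(a, b_same)), 1)
  expect_equal(nrow(consensus_intersect(a, b_off)), 0)
})

test_that("indel consensus matches on reference footprints, once per record", {
  # footprint of CAAA at 100 is [100,103]; partner deletion at 102 overlaps
  a <- variant_set(data.frame(chrom = "chr1", pos = 100L, ref = "CAAA",
                              alt = "C", sample = "s"))
  b <- variant_set(data.frame(chrom = "chr1", pos = c(102L, 103L),
                              ref = c("AAG", "AG"), alt = c("A", "A"),
                              sample = "s"))
  out <- consensus_intersect(a, b)
  expect_equal(nrow(out), 1)                 # -u: emitted at most once
  # exact mode requires identical alleles
  expect_equal(nrow(consensus_intersect(a, b, mode = "exact")), 0)
})

test_that("consensus intersection is idempotent and bounded", {
  set.seed(8)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                   pos = sample(1000L, 40), ref = "C", alt = "T",
                   sample = sample(c("x", "y"), 40, TRUE))
  a <- variant_set(df)
  self <- consensus_intersect(a, a)
  expect_equal(as.data.frame(self), as.data.frame(a))
  b <- variant_set(df[1:10, ])
  expect_lte(nrow(consensus_intersect(a, b)), nrow(a))
})

test_that("mappability annotation assigns interval scores with sentinel", {
  v <- variant_set(data.frame(chrom = "chr1", pos = c(150L, 250L, 500L),
                              ref = "C", alt = "T", sample = "s"))
  track <- data.frame(chrom = "chr1", start = c(100L, 200L),
                      end = c(199L, 299L), score = c(1.0, 0.5))
  out <- annotate_mappability(v, track)
  expect_equal(out$mappability, c(1.0, 0.5, NA))
  expect_equal(attr(out, "n_uncovered"), 1L)
  bad <- data.frame(chrom = "chr1", start = c(100L, 150L), end = c(199L, 260L),
                    score = c(1.0, 0.3))
  expect_error(annotate_mappability(v, bad), "conflicting")
})

test_that("planted mappability distribution is recovered", {
  n <- 1000L
  pos <- seq(10L, by = 10L, length.out = n)
  v <- variant_set(data.frame(chrom = "chr1", pos = pos, ref = "C", alt = "T",
                              sample = paste0("s", seq_len(n))))
  half <- pos <= pos[n / 2]
  track <- data.frame(chrom = "chr1",
                      start = c(1L, pos[n / 2] + 1L),
                      end = c(pos[n / 2], max(pos) + 10L),
                      score = c(1.0, 0.2))
  out <- annotate_mappability(v, track)
  expect_equal(mean(out$mappability == 1.0), 0.5)
})

test_that("bedGraph coordinates convert to 1-based inclusive", {
  bg <- data.frame(chrom = "chr1", start = 0L, end = 100L, score = 0.7)
  tr <- bedgraph_to_track(bg)
  expect_equal(tr$start, 1L)
  expect_equal(tr$end, 100L)
})

test_that("region annotation follows exon > UTR > intron > intergenic", {
  gm <- data.frame(chrom = "chr1",
                   start = c(1000L, 1000L, 1100L),
                   end = c(2000L, 1050L, 1150L),
                   type = c("gene", "exon", "UTR"))
  v <- variant_set(data.frame(chrom = "chr1",
                              pos = c(1020L, 1120L, 1500L, 5000L),
                              ref = "C", alt = "T",
                              sample = paste0("s", 1:4)))
  out <- annotate_region(v, gm)
  expect_equal(out$region_class, c("exon", "UTR", "intron", "intergenic"))
  tab <- region_fraction_table(out)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$n[tab$region_class == "exon"], 1L)
})

test_that("GFF3 gene models load into the interval-table form", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1",
               "chr1\tsrc\texon\t1000\t1050\t.\t+\t.\tParent=g1",
               "chr1\tsrc\tfive_prime_UTR\t1000\t1010\t.\t+\t.\tParent=g1"), f)
  gm <- read_gene_model(f)
  expect_setequal(gm$type, c("gene", "exon", "UTR"))
  expect_equal(gm$start[gm$type == "gene"], 1000)
})
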