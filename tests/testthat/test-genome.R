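test_that("genome container records N-gaps and computes contig N50", {
  g <- genome(c(s1 = "ACGTACGTNNNNACGTACGTACGT", s2 = "ACGT"))
  expect_equal(g$gaps$s1, data.frame(start = 8L, end = 12L))
  expect_equal(nrow(g$gaps$s2), 0L)
  expect_equal(total_length(g), 28L)
  # contigs: 8, 12, 4 -> N50 is 12 (cumulative 12 >= 24/2)
  expect_equal(contig_n50(g), 12L)
  dg <- degap_genome(g)
  expect_equal(dg$seq[["s1"]], "ACGTACGTACGTACGTACGT")
})

test_that("FASTA writer and reader are inverses at the object level", {
  withr::local_seed(1)
  g <- genome(c(chrA = pansynt:::random_dna(257),
                chrB = pansynt:::random_dna(61)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, path)
  g2 <- read_fasta(path)
  expect_identical(g2$seq, g$seq)
  # and writing what was read reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("degap_coord converts gapped to ungapped coordinates", {
  g <- genome(c(s = "ACGTNNNNACGT"))
  expect_equal(pansynt:::degap_coord(g, "s", c(0L, 4L, 8L, 12L)),
               c(0L, 4L, 4L, 8L))
})
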