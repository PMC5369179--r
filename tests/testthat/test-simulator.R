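test_that("simulate_reference obeys the configured size and determinism", {
  cfg <- sim_config(seed = 1, ref_length = 1e5, n_accessions = 1,
                    gene_model = list(counts = c(other = 10L, TE = 0L),
                                      mean_cds = 600,
                                      cluster_frac = 0, cluster_size = 3))
  r1 <- simulate_reference(cfg)
  expect_equal(total_length(r1$genome), 100000L)
  expect_equal(nrow(r1$genome$gaps$chr1), 0L)
  expect_equal(sum(!r1$genes$genes$is_te), 10L)
  # gene models do not overlap
  g <- r1$genes$genes[order(r1$genes$genes$start), ]
  expect_true(all(head(g$end, -1) <= g$start[-1]))
  # same config, same seed: byte-identical output
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(r1$genes, r2$genes)
})

test_that("clustered family members land in one compact window", {
  cfg <- sim_config(seed = 3, ref_length = 2e5, n_accessions = 1,
                    gene_model = list(counts = c(NBSLRR = 5L, TE = 0L),
                                      mean_cds = 600, cluster_frac = 1,
                                      cluster_size = 5L))
  r <- simulate_reference(cfg)
  g <- r$genes$genes[r$genes$genes$family == "NBSLRR", ]
  expect_equal(nrow(g), 5L)
  span <- max(g$end) - min(g$start)
  gene_len <- mean(g$end - g$start)
  expect_lt(span, 5 * (gene_len + 800))
})

test_that("infeasible gene configurations raise a placement error", {
  expect_error(
    sim_config(seed = 1, ref_length = 1e4,
               gene_model = list(counts = c(other = 50L, TE = 0L),
                                 mean_cds = 900, cluster_frac = 0,
                                 cluster_size = 3)),
    "infeasible")
})

test_that("mutate_genome round-trips through apply_truth byte-identically", {
  co <- small_cohort()
  for (a in names(co$accessions)) {
    rebuilt <- apply_truth(co$ref, co$accessions[[a]]$truth)
    expect_identical(rebuilt$seq, co$accessions[[a]]$genome$seq)
  }
})

test_that("all-zero rates reproduce the reference with an empty truth set", {
  cfg <- sim_config(seed = 2, ref_length = 5e4, snp_rate = 0,
                    short_indel_rate = 0,
                    sv_counts = list(large_del = 0, large_ins = 0,
                                     tandem_dup = 0, translocation = 0,
                                     novel_ins = 0),
                    gene_model = list(counts = c(other = 3L, TE = 0L),
                                      mean_cds = 300, cluster_frac = 0,
                                      cluster_size = 2))
  ref <- simulate_reference(cfg)
  mu <- mutate_genome(ref$genome, cfg, "a1")
  expect_identical(mu$genome$seq, ref$genome$seq)
  expect_equal(nrow(mu$truth), 0L)
})

test_that("a single planted deletion shortens the genome by its length", {
  cfg <- sim_config(seed = 4, ref_length = 5e4, snp_rate = 0,
                    short_indel_rate = 0,
                    sv_counts = list(large_del = 1, large_ins = 0,
                                     tandem_dup = 0, translocation = 0,
                                     novel_ins = 0),
                    sv_lengths = list(large_del = c(60, 60),
                                      large_ins = c(50, 100),
                                      tandem_dup = c(500, 1000),
                                      translocation = c(300, 1000),
                                      novel_ins = c(2000, 3000)),
                    gene_model = list(counts = c(other = 2L, TE = 0L),
                                      mean_cds = 300, cluster_frac = 0,
                                      cluster_size = 2))
  ref <- simulate_reference(cfg)
  mu <- mutate_genome(ref$genome, cfg, "a1")
  expect_equal(nrow(mu$truth), 1L)
  expect_equal(total_length(mu$genome), total_length(ref$genome) - 60L)
})

test_that("overlapping truth records are rejected", {
  ref <- genome(c(chr1 = strrep("ACGT", 2500)))
  truth <- data.frame(
    id = c("v1", "v2"), class = "large_del",
    t_start = c(100L, 130L), t_end = c(160L, 190L),
    seq_del = c(strrep("A", 60), strrep("A", 60)), seq_ins = "",
    src_start = NA_integer_, src_end = NA_integer_, dest = NA_integer_,
    copies = NA_integer_, t_seq = "chr1")
  expect_error(apply_truth(ref, truth), "overlapping")
})

test_that("planted SNP counts follow the binomial expectation", {
  # across 20 seeds the planted count stays within 3 sigma of
  # Binomial(L, rate); sigma(count) for the mixture of draws is below
  # the binomial sigma because each draw is itself binomial
  L <- 5e4; rate <- 0.01
  counts <- vapply(1:20, function(sd) {
    cfg <- sim_config(seed = sd, ref_length = L, snp_rate = rate,
                      short_indel_rate = 0,
                      sv_counts = list(large_del = 0, large_ins = 0,
                                       tandem_dup = 0, translocation = 0,
                                       novel_ins = 0),
                      gene_model = list(counts = c(other = 2L, TE = 0L),
                                        mean_cds = 300, cluster_frac = 0,
                                        cluster_size = 2))
    ref <- simulate_reference(cfg)
    mu <- mutate_genome(ref$genome, cfg, "a1")
    sum(mu$truth$class == "SNP")
  }, 0L)
  sigma <- sqrt(L * rate * (1 - rate))
  expect_true(all(abs(counts - L * rate) <= 3 * sigma))
  expect_lt(abs(mean(counts) - L * rate), 3 * sigma / sqrt(20))
})

test_that("fragmentation hits the target contig N50 and conserves sequence", {
  withr::local_seed(9)
  g <- genome(c(chr1 = pansynt:::random_dna(1e6)))
  cfg <- sim_config(seed = 9, ref_length = 1e6,
                    gene_model = list(counts = c(other = 2L, TE = 0L),
                                      mean_cds = 300, cluster_frac = 0,
                                      cluster_size = 2),
                    fragmentation = list(n50 = 2e4, gap_range = c(50L, 300L),
                                         scaffold_len = 2.5e5,
                                         te_gap_frac = 0))
  fr <- fragment_assembly(g, cfg)
  expect_gte(contig_n50(fr), 16000)
  expect_lte(contig_n50(fr), 24000)
  dg <- degap_genome(fr)
  expect_identical(dg$seq[["chr1"]], g$seq[["chr1"]])
})

test_that("fragmentation with target N50 at sequence length is a no-op", {
  g <- genome(c(chr1 = strrep("ACGT", 5000)))
  cfg <- sim_config(seed = 1, ref_length = 2e4,
                    gene_model = list(counts = c(other = 2L, TE = 0L),
                                      mean_cds = 300, cluster_frac = 0,
                                      cluster_size = 2),
                    fragmentation = list(n50 = 2e4, gap_range = c(50L, 300L),
                                         scaffold_len = 5e5,
                                         te_gap_frac = 0))
  fr <- fragment_assembly(g, cfg)
  expect_identical(fr$seq[["chr1"]], g$seq[["chr1"]])
  expect_equal(nrow(fr$gaps$chr1), 0L)
})

test_that("simulated reads reach the requested depth and are exact at rate 0", {
  withr::local_seed(11)
  g <- genome(c(chr1 = pansynt:::random_dna(1e5)))
  cfg <- sim_config(seed = 11, ref_length = 1e5,
                    gene_model = list(counts = c(other = 2L, TE = 0L),
                                      mean_cds = 300, cluster_frac = 0,
                                      cluster_size = 2),
                    read_sim = list(depth = 10, mean_len = 3000,
                                    sdlog = 0.25, min_len = 500,
                                    error_rate = 0))
  reads <- simulate_long_reads(g, cfg)
  total <- sum(reads$end - reads$start)
  expect_gte(total, 0.9e6)
  expect_lte(total, 1.1e6)
  # every read is an exact substring at its truth placement
  for (i in sample(nrow(reads), 25)) {
    r <- reads[i, ]
    sub <- pansynt:::subseq0(g$seq[["chr1"]], r$start, r$end)
    seq <- if (r$strand == "-") pansynt:::revcomp(r$sequence) else r$sequence
    expect_identical(seq, sub)
  }
  # determinism
  reads2 <- simulate_long_reads(g, cfg)
  expect_identical(reads, reads2)
})

test_that("feature lifting tracks indels, duplications and novel genes", {
  co <- small_cohort()
  a <- names(co$accessions)[1]
  acc <- co$accessions[[a]]
  # every lifted (non-novel, non-dup) gene matches the reference protein
  # unless a SNP hit it; spot-check coordinates by re-translating
  prot <- translate_genes(acc$genome, acc$genes)
  expect_true(all(nchar(prot) > 0))
  expect_false(any(grepl("^\\*", prot)))
  # duplicated copies exist when a tandem dup covered a gene, and novel
  # genes appear for large novel insertions
  dup_rows <- grepl("_dup", acc$genes$genes$gene_id)
  nov_rows <- grepl("novel_g", acc$genes$genes$gene_id)
  truth <- acc$truth
  if (any(truth$class == "novel_ins" &
            nchar(truth$seq_ins) >= 3000))
    expect_true(any(nov_rows))
  expect_true(all(acc$genes$genes$end <= total_length(acc$genome)))
})
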