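test_that("truth placements copy the simulator and naive mapping agrees", {
  co <- small_cohort()
  a <- names(co$accessions)[1]
  acc <- co$accessions[[a]]
  gn <- acc$genome
  reads <- acc$reads[1:200, ]
  pl_truth <- place_reads(reads, gn, "truth")
  expect_equal(nrow(pl_truth), 200L)
  pl_naive <- place_reads(reads, gn, "naive")
  m <- match(pl_naive$read_id, pl_truth$read_id)
  agree <- pl_naive$seq_name == pl_truth$seq_name[m] &
    abs(pl_naive$start - pl_truth$start[m]) <= 25 &
    pl_naive$strand == pl_truth$strand[m]
  expect_gte(mean(agree), 0.99)
  expect_gte(nrow(pl_naive) / nrow(reads), 0.95)
})

test_that("place_reads truth mode errors without simulator placements", {
  bad <- data.frame(read_id = "r1", sequence = "ACGT")
  expect_error(place_reads(bad, genome(c(s = "ACGTACGT")), "truth"),
               "truth placements")
  empty <- place_reads(data.frame(), genome(c(s = "ACGTACGT")), "naive")
  expect_equal(nrow(empty), 0L)
})

test_that("validity flips exactly at five spanning reads per breakpoint", {
  sv <- data.frame(v_class = "large_del", t_seq = "chr1", t_start = 100L,
                   t_end = 300L, q_seq = "chr1", q_start = 5000L,
                   q_end = 5000L, ref_allele = "", alt_allele = "",
                   length = 200L, flank_ok = TRUE, gap_free = TRUE,
                   id = "sv1")
  mk_pl <- function(n) data.frame(
    read_id = sprintf("r%02d", seq_len(n)), seq_name = "chr1",
    start = 4400L, end = 5600L, strand = "+", source = "truth")
  expect_false(validate_svs(sv, mk_pl(4))$valid)
  expect_true(validate_svs(sv, mk_pl(5))$valid)
  # a second breakpoint with fewer reads invalidates the whole SV
  sv2 <- within(sv, { v_class <- "large_ins"; q_end <- 9000L })
  pl <- rbind(mk_pl(100),
              data.frame(read_id = sprintf("x%02d", 1:4),
                         seq_name = "chr1", start = 8400L, end = 9600L,
                         strand = "+", source = "truth"))
  expect_false(validate_svs(sv2, pl)$valid)
})

test_that("a read must span the full +/-500 bp window to count", {
  sv <- data.frame(v_class = "large_del", t_seq = "chr1", t_start = 0L,
                   t_end = 1L, q_seq = "chr1", q_start = 5000L,
                   q_end = 5000L, ref_allele = "", alt_allele = "",
                   length = 1L, flank_ok = TRUE, gap_free = TRUE,
                   id = "sv1")
  near_miss <- data.frame(read_id = paste0("r", 1:5), seq_name = "chr1",
                          start = 4501L, end = 5600L, strand = "+",
                          source = "truth")
  expect_false(validate_svs(sv, near_miss)$valid)
  exact <- within(near_miss, start <- 4500L)
  expect_true(validate_svs(sv, exact)$valid)
})

test_that("error-free 20x reads validate true SVs at a high rate", {
  co <- small_cohort()
  res <- small_results()
  a <- names(co$accessions)[1]
  sv <- res$calls[[a]][res$calls[[a]]$v_class %in%
                         c("large_del", "large_ins", "copy_gain",
                           "copy_loss", "translocation"), ]
  svd <- degap_variants(sv, co$accessions[[a]]$assembly)
  pl <- place_reads(co$accessions[[a]]$reads, co$accessions[[a]]$genome,
                    "truth")
  val <- validate_svs(svd, pl)
  rep <- validation_report(val, svd, co$genes)
  expect_gte(rep$overall, 0.95)
  expect_equal(rep$n, nrow(svd))
  # weighted class rates reproduce the overall rate
  expect_equal(sum(rep$by_class$rate * rep$by_class$n) / rep$n,
               rep$overall)
})

test_that("increasing depth never decreases validation support", {
  co <- small_cohort()
  res <- small_results()
  a <- names(co$accessions)[1]
  sv <- res$calls[[a]][res$calls[[a]]$v_class == "large_del", ]
  svd <- degap_variants(sv, co$accessions[[a]]$assembly)
  pl <- place_reads(co$accessions[[a]]$reads, co$accessions[[a]]$genome,
                    "truth")
  half <- pl[seq_len(nrow(pl) %/% 2), ]
  v_half <- validate_svs(svd, half)
  v_full <- validate_svs(svd, pl)
  expect_true(all(v_full$min_support >= v_half$min_support))
})

test_that("reads from the unmutated haplotype reject planted false SVs", {
  co <- small_cohort()
  res <- small_results()
  a <- names(co$accessions)[1]
  sv <- res$calls[[a]][res$calls[[a]]$v_class %in%
                         c("large_del", "large_ins", "copy_gain"), ]
  svd <- degap_variants(sv, co$accessions[[a]]$assembly)
  # simulate reads from the REFERENCE (no variants) and map them onto the
  # accession genome: junction windows cannot be spanned contiguously
  cfg <- co$config
  ref_reads <- simulate_long_reads(co$ref, cfg)
  pl <- place_reads(ref_reads, co$accessions[[a]]$genome, "naive")
  val <- validate_svs(svd, pl)
  expect_lte(mean(val$valid), 0.05)
})
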