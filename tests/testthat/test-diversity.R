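test_that("theta-pi matches hand-computed values", {
  # 2 accessions, 1 difference over L = 100
  geno <- matrix(c("alt", "ref"), 1, 2,
                 dimnames = list(NULL, c("a1", "a2")))
  gm <- fake_genotypes(geno, 10L)
  mask <- full_mask(c("a1", "a2"), 100L)
  expect_equal(theta_pi(gm, mask)$theta_pi, 0.01)
  # 4 accessions with allele counts 2/2 at one site, L = 1
  geno2 <- matrix(c("alt", "alt", "ref", "ref"), 1, 4,
                  dimnames = list(NULL, paste0("a", 1:4)))
  gm2 <- fake_genotypes(geno2, 0L)
  mask2 <- full_mask(paste0("a", 1:4), 1L)
  expect_equal(theta_pi(gm2, mask2)$theta_pi, 4 / 6)
})

test_that("theta-pi equals the all-pairs brute force on random matrices", {
  withr::local_seed(71)
  for (trial in 1:100) {
    n_acc <- sample(3:8, 1)
    n_site <- sample(1:30, 1)
    L <- sample(50:500, 1)
    geno <- matrix(sample(c("ref", "alt", "missing"), n_acc * n_site,
                          replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                   n_site, n_acc,
                   dimnames = list(NULL, paste0("a", seq_len(n_acc))))
    gm <- fake_genotypes(geno, sort(sample.int(L, n_site)) - 1L)
    mask <- full_mask(paste0("a", seq_len(n_acc)), L)
    expect_equal(theta_pi(gm, mask)$theta_pi,
                 brute_force_theta_pi(geno, L))
  }
})

test_that("Watterson's theta matches direct harmonic sums", {
  expect_equal(theta_w(5, 2, 100)$theta_w, 0.05)  # a_2 = 1
  expect_equal(theta_w(10, 5, 1000)$theta_w,
               10 / (sum(1 / (1:4)) * 1000))
  expect_equal(theta_w(0, 7, 100)$theta_w, 0)
  for (n in c(3, 10, 50, 100)) {
    expect_equal(theta_w(1, n, 1)$a_n, sum(1 / seq_len(n - 1)))
  }
  expect_error(theta_w(1, 1, 100), "n >= 2")
  expect_error(theta_w(1, 5, 0), "L > 0")
})

test_that("zero-length callable regions report missing statistics", {
  geno <- matrix("alt", 1, 2, dimnames = list(NULL, c("a1", "a2")))
  gm <- fake_genotypes(geno, 10L)
  empty_mask <- structure(list(acc = list(a1 = list(), a2 = list()),
                               seqlens = c(chr1 = 100L)),
                          class = "pg_mask")
  st <- theta_pi(gm, empty_mask)
  expect_true(is.na(st$theta_pi))
  expect_equal(st$L, 0)
})

test_that("the window track conserves gene counts and flags uncovered windows", {
  co <- small_cohort()
  res <- small_results()
  wt <- window_track(res$genotypes, co$genes, res$mask, co$ref,
                     window = 5e4)
  expect_equal(sum(wt$n_genes) + sum(wt$n_te), nrow(co$genes$genes))
  expect_true(all(wt$coverage >= 0 & wt$coverage <= 1))
  expect_true(all(is.na(wt$pi_snp[wt$coverage < 0.5])))
})

test_that("SNP effects match the genetic code, including strand handling", {
  # gene: ATG | GCT TGG GAA TAT | TAA on the plus strand at offset 100
  cds_seq <- "ATGGCTTGGGAATATTAA"
  refseq <- paste0(strrep("C", 100), cds_seq, strrep("C", 100))
  gene <- data.frame(gene_id = "g1", seq_name = "chr1", strand = "+",
                     start = 100L, end = 118L, family = "other",
                     is_te = FALSE)
  cds <- data.frame(gene_id = "g1", start = 100L, end = 118L)
  cls <- function(pos, ref, alt)
    classify_snp_effect(list(t_start = pos, ref_allele = ref,
                             alt_allele = alt), gene, cds, refseq)
  expect_equal(cls(107L, "G", "A")$effect, "stop_gained")   # TGG -> TGA
  expect_true(cls(107L, "G", "A")$large_effect)
  expect_equal(cls(101L, "T", "C")$effect, "start_lost")    # ATG -> ACG
  expect_equal(cls(105L, "T", "C")$effect, "synonymous")    # GCT -> GCC
  expect_equal(cls(115L, "T", "C")$effect, "stop_lost")     # TAA -> CAA
  expect_equal(cls(104L, "C", "A")$effect, "missense")      # GCT -> GAT? A->D
  expect_equal(cls(50L, "C", "A")$effect, "intergenic")

  # same gene on the minus strand
  refseq_m <- paste0(strrep("C", 100), pansynt:::revcomp(cds_seq),
                     strrep("C", 100))
  gene_m <- within(gene, strand <- "-")
  cls_m <- function(pos, ref, alt)
    classify_snp_effect(list(t_start = pos, ref_allele = ref,
                             alt_allele = alt), gene_m, cds, refseq_m)
  # plus-strand position of the TGG codon on minus: bases 110..112
  # (revcomp CCA); mutating the C at 110 to T gives TGG -> TGA
  expect_equal(cls_m(110L, "C", "T")$effect, "stop_gained")
})

test_that("splice-site changes are recognised within 2 bp of intron ends", {
  # two-exon gene: exon1 [100,109), intron [109,209), exon2 [209,217)
  exon1 <- "ATGGCTTGG"; exon2 <- "GAATATTA"  # total 17 bp -> pad to 18
  exon2 <- "GAATATTAA"
  intron <- paste0("GT", strrep("A", 96), "AG")
  refseq <- paste0(strrep("C", 100), exon1, intron, exon2,
                   strrep("C", 100))
  gene <- data.frame(gene_id = "g1", seq_name = "chr1", strand = "+",
                     start = 100L, end = 218L, family = "other",
                     is_te = FALSE)
  cds <- data.frame(gene_id = "g1", start = c(100L, 209L),
                    end = c(109L, 218L))
  cls <- function(pos, ref, alt)
    classify_snp_effect(list(t_start = pos, ref_allele = ref,
                             alt_allele = alt), gene, cds, refseq)
  expect_equal(cls(109L, "G", "C")$effect, "splice_site")   # donor +1
  expect_equal(cls(110L, "T", "C")$effect, "splice_site")   # donor +2
  expect_equal(cls(111L, "A", "C")$effect, "intronic")
  expect_equal(cls(208L, "G", "C")$effect, "splice_site")   # acceptor -1
  expect_equal(cls(207L, "A", "C")$effect, "splice_site")   # acceptor -2
  expect_equal(cls(206L, "A", "C")$effect, "intronic")
})

test_that("gene coverage filter applies the >=80% in >=10 accessions rule", {
  genes <- structure(list(
    genes = data.frame(gene_id = "g1", seq_name = "chr1", strand = "+",
                       start = 0L, end = 1000L, family = "other",
                       is_te = FALSE),
    cds = data.frame(gene_id = "g1", start = 0L, end = 1000L)),
    class = "pg_genes")
  accs <- paste0("a", 1:13)
  # covered 79% in all accessions: dropped
  acc <- setNames(lapply(accs, function(a)
    list(chr1 = IRanges::IRanges(1L, 790L))), accs)
  m79 <- structure(list(acc = acc, seqlens = c(chr1 = 1000L)),
                   class = "pg_mask")
  expect_length(gene_coverage_filter(genes, m79), 0L)
  # fully covered in 9 accessions only (deletion in 4): dropped
  acc2 <- acc
  for (a in accs[1:9]) acc2[[a]] <- list(chr1 = IRanges::IRanges(1L, 1000L))
  for (a in accs[10:13]) acc2[[a]] <- list(chr1 = IRanges::IRanges(1L, 100L))
  m9 <- structure(list(acc = acc2, seqlens = c(chr1 = 1000L)),
                  class = "pg_mask")
  expect_length(gene_coverage_filter(genes, m9), 0L)
  # fully covered in 10: kept
  acc3 <- acc2
  acc3[[accs[10]]] <- list(chr1 = IRanges::IRanges(1L, 1000L))
  m10 <- structure(list(acc = acc3, seqlens = c(chr1 = 1000L)),
                   class = "pg_mask")
  expect_equal(gene_coverage_filter(genes, m10), "g1")
})

test_that("MPPD is zero for identical proteins and counts differing columns", {
  expect_equal(mppd(c("MKLV", "MKLV"))$mppd, 0)
  a <- strrep("M", 100)
  b <- paste0(strrep("M", 95), strrep("W", 5))
  expect_equal(mppd(c(a, b))$mppd, 0.05)
  expect_error(mppd("MKLV"), "at least two")
  # oracle equivalence: mean over per-pair distances computed directly
  withr::local_seed(72)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  prots <- vapply(1:4, function(i)
    paste(sample(aas, 60, replace = TRUE), collapse = ""), "")
  got <- mppd(prots)
  manual <- combn(4, 2, function(ij)
    pansynt:::protein_distance(prots[ij[1]], prots[ij[2]]))
  expect_equal(got$mppd, mean(manual))
})

test_that("copy-number CV uses the population standard deviation", {
  expect_equal(copy_number_cv(rep(1, 13))$cv, 0)
  got <- copy_number_cv(c(2, 0, 0))
  expect_equal(got$mean, 2 / 3)
  expect_equal(got$sd, sqrt(8 / 9), tolerance = 1e-12)
  expect_equal(got$cv, sqrt(2), tolerance = 1e-12)
  # scale invariance
  expect_equal(copy_number_cv(c(4, 0, 0))$cv, got$cv)
})

test_that("similarity clustering groups orthologs and isolates private genes", {
  withr::local_seed(73)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")
  base <- paste(sample(aas, 120, replace = TRUE), collapse = "")
  mutate_prot <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(aas, k, replace = TRUE)
    paste(ch, collapse = "")
  }
  prots <- data.frame(
    accession = c("a1", "a2", "a3", "a1"),
    gene_id = c("g1", "g2", "g3", "g4"),
    family = c("NBSLRR", "NBSLRR", "NBSLRR", "other"),
    sequence = c(base, mutate_prot(base, 6), mutate_prot(base, 10),
                 paste(sample(aas, 100, replace = TRUE), collapse = "")))
  groups <- cluster_ortholog_groups(prots, c("a1", "a2", "a3"))
  expect_length(groups, 2L)
  bins <- vapply(groups, `[[`, 0L, "sharing_bin")
  expect_setequal(bins, c(3L, 1L))
  big <- groups[[which(bins == 3)]]
  expect_equal(unname(big$copy_counts), c(1L, 1L, 1L))
  expect_equal(big$family, "NBSLRR")
})

test_that("family summary reports one row per family with sane shares", {
  groups <- list(
    list(family = "NBSLRR", sharing_bin = 1L),
    list(family = "NBSLRR", sharing_bin = 3L),
    list(family = "other", sharing_bin = 3L),
    list(family = "other", sharing_bin = 3L))
  fs <- family_summary(groups, n_accessions = 3L)
  expect_equal(nrow(fs), 2L)
  expect_equal(fs$frac_specific[fs$family == "NBSLRR"], 0.5)
  expect_equal(fs$frac_core[fs$family == "other"], 1)
  expect_equal(sum(fs$share_of_core), 1)
})
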