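mk_block_pair <- function(seed, edit) {
  # builds (query, target) genomes from one 6 kb sequence with one edit
  withr::local_seed(seed)
  s <- pansynt:::random_dna(6e3)
  q <- edit(s)
  list(q = genome(c(q = q)), t = genome(c(t = s)), s = s)
}

first_block <- function(g) {
  syn <- build_synteny(g$q, g$t)
  syn$blocks[[1]]
}

test_that("identical sequences yield zero SNPs and a mismatch yields one", {
  g <- mk_block_pair(41, identity)
  expect_equal(nrow(call_snps(first_block(g))), 0L)

  g2 <- mk_block_pair(42, function(s) {
    substr(s, 3001, 3001) <- if (substr(s, 3001, 3001) == "A") "G" else "A"
    s
  })
  snps <- call_snps(first_block(g2))
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$t_start, 3000L)
  expect_equal(snps$ref_allele, substr(g2$s, 3001, 3001))
})

test_that("short indels are called with the 49/50 class boundary", {
  g3 <- mk_block_pair(43, function(s)
    paste0(substr(s, 1, 3000), substr(s, 3004, 6000)))  # 3 bp deletion
  ind <- call_short_indels(first_block(g3), g3$t)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$v_class, "short_del")
  expect_equal(ind$length, 3L)

  # 49 bp deletion is short; 50 bp is not emitted here
  g49 <- mk_block_pair(44, function(s)
    paste0(substr(s, 1, 3000), substr(s, 3050, 6000)))
  ind49 <- call_short_indels(first_block(g49), g49$t)
  expect_equal(ind49$length, 49L)
  g50 <- mk_block_pair(45, function(s)
    paste0(substr(s, 1, 3000), substr(s, 3051, 6000)))
  ind50 <- call_short_indels(first_block(g50), g50$t)
  expect_equal(nrow(ind50), 0L)
  svs50 <- call_svs(list(first_block(g50)), g50$q, g50$t)
  expect_equal(nrow(svs50), 1L)
  expect_equal(svs50$v_class, "large_del")
  expect_equal(svs50$length, 50L)
})

test_that("indels in homopolymers are left-aligned to the lowest coordinate", {
  # exhaustive-shift oracle on a constructed homopolymer deletion
  s <- paste0(strrep("ACGT", 30), strrep("A", 12), strrep("TGCA", 30))
  la <- pansynt:::left_align_indel(s, 126L, "AA")  # delete two As mid-run
  # leftmost equivalent position: the start of the A run (position 120)
  shifts <- vapply(0:130, function(p) {
    paste0(substr(s, 1, p), substr(s, p + 3, nchar(s))) ==
      paste0(substr(s, 1, 126), substr(s, 129, nchar(s)))
  }, TRUE)
  expect_equal(la$pos, min(which(shifts)) - 1L)
})

test_that("a clean 60 bp deletion is recovered with exact breakpoints", {
  g <- mk_block_pair(46, function(s)
    paste0(substr(s, 1, 2500), substr(s, 2561, 6000)))
  svs <- call_svs(list(first_block(g)), g$q, g$t)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$v_class, "large_del")
  la_truth <- pansynt:::left_align_indel(g$s, 2500L, substr(g$s, 2501, 2560))
  expect_equal(svs$t_start, la_truth$pos)
  expect_equal(svs$length, 60L)
})

test_that("a tandem duplication is called as copy gain matching its source", {
  g <- mk_block_pair(47, function(s) {
    unit <- substr(s, 3001, 3600)
    paste0(substr(s, 1, 3600), unit, substr(s, 3601, 6000))
  })
  svs <- call_svs(list(first_block(g)), g$q, g$t)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$v_class, "copy_gain")
  expect_equal(svs$length, 600L)
})

test_that("insertion/deletion calls swap when query and target swap", {
  g <- mk_block_pair(48, function(s)
    paste0(substr(s, 1, 2500), substr(s, 2801, 6000)))  # 300 bp deletion
  fwd <- call_svs(list(first_block(g)), g$q, g$t)
  rev_pair <- list(q = g$t, t = g$q)
  syn_rev <- build_synteny(g$t, g$q)
  rev <- call_svs(syn_rev$blocks, g$t, g$q)
  expect_equal(fwd$v_class, "large_del")
  expect_equal(rev$v_class, "large_ins")
  expect_equal(fwd$length, rev$length)
})

test_that("SVs whose span touches an N-gap are discarded with reason gap", {
  withr::local_seed(49)
  s <- pansynt:::random_dna(6e3)
  # deletion plus an N-gap right at the breakpoint in the query assembly
  q <- paste0(substr(s, 1, 2480), strrep("N", 100),
              substr(s, 2481, 2500), substr(s, 2561, 6000))
  qg <- genome(c(q = q)); tg <- genome(c(t = s))
  syn <- build_synteny(qg, tg)
  svs <- call_svs(syn$blocks, qg, tg)
  expect_equal(nrow(svs[svs$v_class == "large_del", ]), 0L)
  disc <- attr(svs, "discards")
  expect_true(is.data.frame(disc))
})

test_that("merging imputes reference genotypes only where covered", {
  co <- small_cohort()
  res <- small_results()
  gm <- res$genotypes
  # imputed cells are always ref
  expect_true(all(gm$geno[gm$prov == "imputed"] == "ref"))
  # missing cells exactly match uncallable provenance
  expect_true(all((gm$geno == "missing") == (gm$prov == "uncallable")))
  # a site called in one accession and covered in the other imputes ref
  one_alt <- rowSums(gm$geno == "alt") == 1
  expect_gt(sum(gm$geno[one_alt, ] == "ref"), 0)
})

test_that("merging conflicting allele records raises an error", {
  v1 <- data.frame(v_class = "SNP", t_seq = "chr1", t_start = 10L,
                   t_end = 11L, q_seq = "q", q_start = 10L, q_end = 11L,
                   ref_allele = "A", alt_allele = c("G", "C"),
                   length = 1L, flank_ok = TRUE, gap_free = TRUE,
                   id = c("a", "b"))
  mask <- full_mask("acc1", 100L)
  expect_error(merge_and_impute(list(acc1 = v1), mask), "conflicting")
  expect_equal(nrow(merge_and_impute(list(acc1 = v1[1, ]), mask)$variants),
               1L)
})

test_that("affected span sums classes and merges overlaps in the union", {
  geno <- matrix(c("alt", "alt"), 2, 1, dimnames = list(NULL, "a1"))
  gm <- fake_genotypes(geno, c(100L, 150L))
  gm$variants$v_class <- c("large_del", "large_del")
  gm$variants$t_end <- c(300L, 400L)          # overlapping deletions
  gm$variants$length <- c(200L, 250L)
  sp <- affected_span(gm, "a1")
  expect_equal(unname(sp$per_class["large_del"]), 450)
  expect_equal(sp$union_bp, 300)              # union [100, 400)
  expect_lt(sp$union_bp, sum(sp$per_class))
})
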