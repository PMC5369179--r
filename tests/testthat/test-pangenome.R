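test_that("novel extraction returns nothing for a fully aligned accession", {
  withr::local_seed(61)
  s <- pansynt:::random_dna(5e4)
  g <- genome(c(chr1 = s))
  syn <- build_synteny(g, g)
  expect_equal(nrow(extract_novel(g, syn$blocks, "self", ref = g)), 0L)
})

test_that("planted novel insertions are recovered as segments; islets are dropped", {
  withr::local_seed(62)
  s <- pansynt:::random_dna(5e4)
  ins <- pansynt:::random_dna(5e3)
  q <- paste0(substr(s, 1, 25000), ins, substr(s, 25001, 50000))
  qg <- genome(c(q = q)); tg <- genome(c(t = s))
  syn <- build_synteny(qg, tg)
  segs <- extract_novel(qg, syn$blocks, "a1", ref = tg)
  expect_equal(nrow(segs), 1L)
  recovered <- sum(segs$end - segs$start)
  expect_gte(recovered / 5000, 0.95)
  # a 49 bp unaligned islet is below the reporting threshold
  q2 <- paste0(substr(s, 1, 25000), pansynt:::random_dna(49),
               substr(s, 25001, 50000))
  qg2 <- genome(c(q = q2))
  syn2 <- build_synteny(qg2, tg)
  expect_equal(nrow(extract_novel(qg2, syn2$blocks, "a1", ref = tg)), 0L)
})

test_that("complexity filter removes poly-A and dinucleotide arrays, keeps random", {
  segs <- data.frame(
    accession = "a1", seq_name = "s", start = 0L,
    end = c(200L, 500L, 200L),
    sequence = c(strrep("A", 200),
                 {withr::local_seed(63); pansynt:::random_dna(500)},
                 strrep("AT", 100)))
  filt <- complexity_filter(segs)
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$end - filt$start, 500L)
  expect_identical(filt$sequence, segs$sequence[2])
})

test_that("the DUST score of a random segment stays under threshold", {
  # independent triplet-count computation on one window
  withr::local_seed(64)
  s <- pansynt:::random_dna(64)
  trip <- substring(s, 1:62, 3:64)
  cnt <- table(trip)
  score <- sum(cnt * (cnt - 1) / 2) / (length(trip) - 1)
  expect_lt(score, 2)
  expect_false(any(pansynt:::dust_mask(s)))
  expect_true(all(pansynt:::dust_mask(strrep("A", 64))))
})

test_that("shared segments cluster together; private ones stay singletons", {
  withr::local_seed(65)
  shared <- pansynt:::random_dna(2000)
  segs <- data.frame(
    accession = c("a1", "a2", "a3", "a1"),
    seq_name = "s", start = 0L,
    end = c(2000L, 2000L, 2000L, 1500L),
    sequence = c(shared, shared, shared, pansynt:::random_dna(1500)))
  cl <- collapse_redundancy(segs, c("a1", "a2", "a3"))
  expect_equal(nrow(cl$clusters), 2L)
  big <- cl$clusters[cl$clusters$n_members == 3, ]
  expect_equal(big$n_accessions, 3L)
  # non-redundant bp never exceeds pooled bp
  expect_lte(sum(cl$clusters$length), sum(segs$end - segs$start))
})

test_that("size curves are monotone and recover planted core + private structure", {
  co <- small_cohort()
  res <- small_results()
  segs <- do.call(rbind, lapply(names(co$accessions), function(a)
    extract_novel(co$accessions[[a]]$assembly, res$synteny[[a]]$blocks, a,
                  ref = co$ref)))
  filt <- complexity_filter(segs)
  cl <- collapse_redundancy(filt, names(co$accessions))
  cur <- size_curves(res$mask, cl, seed = 3)
  expect_true(all(diff(cur$pan_mean) >= -1e-9))
  expect_true(all(diff(cur$core_mean) <= 1e-9))
  expect_equal(cur$core_mean[1], cur$pan_mean[1])
  # every permutation individually is monotone
  for (p in seq_len(nrow(cur$pan))) {
    expect_true(all(diff(cur$pan[p, ]) >= -1e-9))
    expect_true(all(diff(cur$core[p, ]) <= 1e-9))
  }
})

test_that("identical accessions give flat pan and core curves", {
  withr::local_seed(66)
  s <- pansynt:::random_dna(3e4)
  g <- genome(c(chr1 = s))
  syn <- build_synteny(g, g)
  mask <- coverage_mask(list(a1 = syn$blocks, a2 = syn$blocks), g)
  cl <- collapse_redundancy(
    data.frame(accession = character(0), seq_name = character(0),
               start = integer(0), end = integer(0),
               sequence = character(0)), c("a1", "a2"))
  cur <- size_curves(mask, cl, seed = 1)
  expect_equal(cur$pan_mean, cur$core_mean)
  expect_equal(diff(cur$pan_mean), 0)
})

test_that("the asymptotic fit recovers noise-free parameters to 1e-4", {
  x <- 1:13
  y <- 256 + 175 * (1 - exp(-exp(-0.6) * x))
  fit <- fit_asymptotic(x, y)
  expect_lt(abs(fit$b0 - 256) / 256, 1e-4)
  expect_lt(abs(fit$b1 - 175) / 175, 1e-4)
  expect_lt(abs(fit$lrc - (-0.6)) / 0.6, 1e-4)
  # fit idempotence: fitting the fitted curve returns the same parameters
  fit2 <- fit_asymptotic(x, fit$fitted)
  expect_equal(fit2$asymptote, fit$asymptote, tolerance = 1e-6)
  # asymptote dominates every observed value for an increasing curve
  expect_gte(fit$asymptote + 1e-9, max(y))
})

test_that("a constant curve degenerates to b1 = 0 with asymptote c", {
  fit <- fit_asymptotic(1:8, rep(420, 8))
  expect_equal(fit$b1, 0)
  expect_equal(fit$asymptote, 420)
})

test_that("accession-specific genes require > 50% CDS inside private segments", {
  genes <- structure(list(
    genes = data.frame(gene_id = c("g1", "g2"), seq_name = "s",
                       strand = "+", start = c(100L, 1000L),
                       end = c(400L, 1300L), family = "other",
                       is_te = FALSE),
    cds = data.frame(gene_id = c("g1", "g2"), start = c(100L, 1000L),
                     end = c(400L, 1300L))), class = "pg_genes")
  segs <- data.frame(seq_name = "s", start = c(50L, 1180L),
                     end = c(450L, 1300L))
  # g1 fully inside; g2 overlaps 120/300 = 40% -> excluded
  expect_equal(accession_specific_genes(genes, segs), "g1")
})
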