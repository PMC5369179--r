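# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small but complete cohort: 300 kb reference, 2 accessions, all variant
# classes, fragmentation and (error-free) long reads
small_cohort <- function() {
  fixture("small_cohort", function() {
    cfg <- sim_config(
      seed = 5, ref_length = 3e5, n_accessions = 2,
      snp_rate = 0.005, short_indel_rate = 5e-4,
      sv_counts = list(large_del = 4, large_ins = 4, tandem_dup = 2,
                       translocation = 1, novel_ins = 2),
      sv_lengths = list(large_del = c(50, 2000), large_ins = c(50, 2000),
                        tandem_dup = c(500, 1500),
                        translocation = c(300, 3000),
                        novel_ins = c(3000, 8000)),
      gene_model = list(counts = c(NBSLRR = 6, NCR = 4, TE = 10,
                                   other = 12),
                        mean_cds = 600, cluster_frac = 0.5,
                        cluster_size = 3),
      read_sim = list(depth = 20, mean_len = 3000, sdlog = 0.25,
                      min_len = 500, error_rate = 0))
    simulate_cohort(cfg, reads = TRUE)
  })
}

small_results <- function() {
  fixture("small_results", function() run_pipeline(small_cohort()))
}

# anchors data.frame usable by chain_anchors() without a genome
fake_anchors <- function(q_start, t_start, length, q_len = 10000L) {
  a <- data.frame(q_seq = "q", t_seq = "t", strand = "+",
                  q_start = as.integer(q_start),
                  t_start = as.integer(t_start),
                  length = as.integer(length))
  attr(a, "q_lens") <- c(q = q_len)
  attr(a, "t_lens") <- c(t = 10000L)
  class(a) <- c("pg_anchors", "data.frame")
  a
}

# exhaustive best chain score over all collinear anchor subsets, under
# the same overlap-clipping model as the DP (overlaps up to ov_max bases
# clip the later anchor and are charged against the score)
brute_force_chain_score <- function(a, params, ov_max = 100L) {
  n <- nrow(a)
  best <- -Inf
  score_of <- function(idx) {
    sub <- a[idx, , drop = FALSE]
    sub <- sub[order(sub$t_start, sub$q_start), , drop = FALSE]
    s <- sub$length[1]
    if (nrow(sub) > 1) {
      pt <- sub$t_start[1] + sub$length[1]
      pq <- sub$q_start[1] + sub$length[1]
      for (i in 2:nrow(sub)) {
        o <- max(pt - sub$t_start[i], pq - sub$q_start[i], 0L)
        if (o > ov_max || o >= sub$length[i]) return(NA_real_)
        if (sub$t_start[i] + sub$length[i] <= pt ||
              sub$q_start[i] + sub$length[i] <= pq) return(NA_real_)
        dt <- sub$t_start[i] + o - pt
        dq <- sub$q_start[i] + o - pq
        s <- s + (sub$length[i] - o) -
          (params$open + params$extend * abs(dq - dt) +
             params$diag * min(dq, dt))
        pt <- sub$t_start[i] + sub$length[i]
        pq <- sub$q_start[i] + sub$length[i]
      }
    }
    s
  }
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0)
    s <- score_of(idx)
    if (!is.na(s) && s > best) best <- s
  }
  best
}

# hand-rolled mask over one reference sequence fully covered per accession
full_mask <- function(accessions, seqlen, seqname = "chr1") {
  acc <- setNames(lapply(accessions, function(a)
    setNames(list(IRanges::IRanges(1L, seqlen)), seqname)), accessions)
  structure(list(acc = acc, seqlens = setNames(seqlen, seqname)),
            class = "pg_mask")
}

# genotype matrix object from a plain character matrix and positions
fake_genotypes <- function(geno, positions, v_class = "SNP",
                           seqname = "chr1") {
  n <- nrow(geno)
  variants <- data.frame(
    v_class = v_class, t_seq = seqname, t_start = positions,
    t_end = positions + 1L, q_seq = "q", q_start = positions,
    q_end = positions + 1L, ref_allele = "A", alt_allele = "G",
    length = 1L, flank_ok = TRUE, gap_free = TRUE,
    id = as.character(seq_len(n)))
  prov <- ifelse(geno == "missing", "uncallable",
                 ifelse(geno == "alt", "called", "imputed"))
  structure(list(variants = variants, geno = geno, prov = prov),
            class = "pg_genotypes")
}

# all-pairs brute force for theta-pi on a genotype matrix
brute_force_theta_pi <- function(geno, L) {
  total <- 0
  for (s in seq_len(nrow(geno))) {
    called <- which(geno[s, ] != "missing")
    if (length(called) < 2) next
    diff <- 0; pairs <- 0
    for (i in seq_along(called)[-length(called)]) {
      for (j in (i + 1):length(called)) {
        pairs <- pairs + 1
        if (geno[s, called[i]] != geno[s, called[j]]) diff <- diff + 1
      }
    }
    total <- total + diff / pairs
  }
  total / L
}
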