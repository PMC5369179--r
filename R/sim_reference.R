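#' Simulate a reference genome with gene families and TE-like repeats
#'
#' Generates a gap-free single-chromosome reference: random background
#' sequence carrying non-overlapping gene models for each configured family
#' (a configurable fraction of family members in tandem clusters, emulating
#' the clustered organisation of resistance-gene and peptide families) and
#' transposon-like repeat copies at 85--99% identity to a small set of
#' family consensus elements.
#'
#' Gene models are returned as a `pg_genes` object: a `genes` table
#' (`gene_id, seq_name, strand, start, end, family, is_te`) plus a `cds`
#' table (`gene_id, start, end`), 0-based half-open.  CDS sequences are
#' proper ORFs (ATG ... stop, no internal stop) so functional-effect
#' classification is meaningful; introns carry canonical GT..AG ends.
#'
#' @param config A [sim_config()].
#' @return `list(genome = pg_genome, genes = pg_genes)`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(derive_seed(config$seed, "reference"))
  L <- config$ref_length
  gm <- config$gene_model

  background <- random_dna(L, gc = 0.4)
  occupied <- IRanges::IRanges()
  margin <- 100L

  reserve <- function(len, what) {
    for (i in 1:2000) {
      s <- sample.int(L - len, 1L) - 1L
      cand <- IRanges::IRanges(s + 1L, s + len)
      if (length(occupied) == 0 ||
          !IRanges::overlapsAny(cand + margin, occupied)) {
        occupied <<- c(occupied, cand)
        return(s)
      }
    }
    stop("placement failure: could not place ", what,
         " (reference too crowded)")
  }

  genes <- list(); cds <- list(); patches <- list()
  gid <- 0L

  add_gene <- function(start, family, is_te, local) {
    gid <<- gid + 1L
    id <- sprintf("g%04d", gid)
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, seq_name = "chr1", strand = local$strand,
      start = start, end = start + local$len, family = family,
      is_te = is_te)
    cds[[length(cds) + 1L]] <<- data.frame(
      gene_id = id, start = start + local$cds$start,
      end = start + local$cds$end)
    patches[[length(patches) + 1L]] <<- list(start = start, seq = local$seq)
  }

  fams <- names(gm$counts)
  for (fam in fams[fams != "TE"]) {
    n <- gm$counts[[fam]]
    if (n == 0) next
    n_clustered <- round(gm$cluster_frac * n)
    n_clusters <- if (n_clustered > 0) ceiling(n_clustered / gm$cluster_size) else 0
    left <- n
    for (cl in seq_len(n_clusters)) {
      size <- min(gm$cluster_size, n_clustered - (cl - 1L) * gm$cluster_size,
                  left)
      if (size <= 0) break
      locals <- replicate(size, make_gene_local(gm$mean_cds), simplify = FALSE)
      spacers <- sample(200:800, size)
      span <- sum(vapply(locals, `[[`, 0L, "len")) + sum(spacers)
      s0 <- reserve(span, paste0(fam, " cluster"))
      pos <- s0
      for (i in seq_len(size)) {
        add_gene(pos, fam, FALSE, locals[[i]])
        pos <- pos + locals[[i]]$len + spacers[i]
        left <- left - 1L
      }
    }
    for (i in seq_len(left)) {
      local <- make_gene_local(gm$mean_cds)
      s <- reserve(local$len, fam)
      add_gene(s, fam, FALSE, local)
    }
  }

  # TE-like repeats: a few consensus elements copied at sampled identity
  n_te <- gm$counts[["TE"]] %||% 0L
  if (n_te > 0) {
    n_fam <- min(3L, n_te)
    consensi <- replicate(n_fam, random_dna(3L * sample(200:500, 1L), 0.42))
    for (i in seq_len(n_te)) {
      cons <- consensi[[(i - 1L) %% n_fam + 1L]]
      ident <- runif(1, config$te_identity[1], config$te_identity[2])
      seq <- mutate_string(cons, 1 - ident)
      len <- nchar(seq)
      s <- reserve(len, "TE copy")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") seq <- revcomp(seq)
      add_gene(s, "TE", TRUE,
               list(len = len, seq = seq, strand = strand,
                    cds = data.frame(start = 0L, end = len)))
    }
  }

  for (p in patches)
    substr(background, p$start + 1L, p$start + nchar(p$seq)) <- p$seq

  gn <- genome(c(chr1 = background))
  gs <- as_pg_genes(do.call(rbind, genes), do.call(rbind, cds))
  list(genome = gn, genes = gs)
}

# random ORF + intron structure in gene-local coordinates (plus strand of
# the genome; minus-strand genes carry the reverse-complemented layout)
make_gene_local <- function(mean_cds) {
  n_cod <- max(30L, round(runif(1, 0.6, 1.4) * mean_cds / 3))
  orf <- make_orf(n_cod)
  n_ex <- sample(1:3, 1L)
  cuts <- if (n_ex > 1) sort(sample(seq(3, (n_cod - 1L) * 3, by = 1L), n_ex - 1L)) else integer(0)
  ex_len <- diff(c(0L, cuts, n_cod * 3L))
  introns <- if (n_ex > 1) sample(100:300, n_ex - 1L, replace = TRUE) else integer(0)
  pieces <- character(0); cds_local <- list(); pos <- 0L
  off <- cumsum(c(0L, ex_len[-n_ex] + introns))
  for (i in seq_len(n_ex)) {
    es <- substr(orf, sum(ex_len[seq_len(i - 1L)]) + 1L,
                 sum(ex_len[seq_len(i)]))
    cds_local[[i]] <- data.frame(start = pos, end = pos + ex_len[i])
    pieces <- c(pieces, es)
    pos <- pos + ex_len[i]
    if (i < n_ex) {
      ilen <- introns[i]
      intron <- paste0("GT", random_dna(ilen - 4L, 0.35), "AG")
      pieces <- c(pieces, intron)
      pos <- pos + ilen
    }
  }
  seq <- paste(pieces, collapse = "")
  len <- nchar(seq)
  strand <- sample(c("+", "-"), 1L)
  cds <- do.call(rbind, cds_local)
  if (strand == "-") {
    seq <- revcomp(seq)
    cds <- data.frame(start = len - rev(cds$end), end = len - rev(cds$start))
  }
  list(len = len, seq = seq, strand = strand, cds = cds)
}

# ATG + random non-stop codons + stop; length = 3 * n_codons
make_orf <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

# substitution-only divergence at the given per-base rate
mutate_string <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}
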