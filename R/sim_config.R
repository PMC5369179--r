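#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-genome module: reference size and
#' gene/repeat content, per-accession variant rates and SV counts, assembly
#' fragmentation and long-read simulation.  The seed fully determines all
#' outputs; each operation derives its own stream from
#' `(seed, accession, operation)` so stages are individually reproducible.
#'
#' Default variant rates follow the divergence observed between wild
#' accessions and a conspecific reference (SNP densities of roughly
#' 0.6--2.4% per bp; the default 1% sits inside that range).  The boundary
#' between short indels and large SVs is 50 bp everywhere: short classes
#' have length < 50, large classes >= 50.
#'
#' @param seed Integer master seed.
#' @param ref_length Reference length in bp (single chromosome), >= 10 kb.
#' @param n_accessions Number of accession genomes to derive.
#' @param snp_rate Per-bp substitution probability in `[0, 1]`.
#' @param short_indel_rate Per-bp probability of a short indel (lengths
#'   1--49, geometric with `indel_geom_p`).
#' @param indel_geom_p Geometric parameter for short-indel lengths.  The
#'   source data do not pin this distribution down; it is an explicit,
#'   configurable stand-in.
#' @param sv_counts Named list of per-accession SV event counts:
#'   `large_del`, `large_ins`, `tandem_dup`, `translocation`, `novel_ins`,
#'   `copy_loss`.
#' @param sv_lengths Named list of `c(min, max)` length ranges (bp) per SV
#'   class; lengths are drawn log-uniformly.  Minima must respect the 50 bp
#'   large-SV boundary.
#' @param dup_copies Range of total tandem copy number `c(2, 4)`.
#' @param gene_model List with `counts` (named integer vector of gene
#'   counts per family label; the `TE` label marks transposon-like
#'   repeats), `mean_cds` (mean CDS length, bp), `cluster_frac` (fraction
#'   of family members placed in tandem clusters) and `cluster_size`.
#' @param te_identity Range of sequence identity of TE copies to their
#'   family consensus.
#' @param fragmentation List with `n50` (target contig N50, bp),
#'   `gap_range` (`c(min, max)` N-run length), `scaffold_len` (approximate
#'   scaffold size, bp) and `te_gap_frac` (fraction of gaps placed
#'   preferentially inside TE intervals).
#' @param read_sim List with `depth` (fold coverage), `mean_len` / `sdlog`
#'   (log-normal read lengths, bp), `min_len` and `error_rate` (per-base
#'   substitution probability).
#' @param novel_gc GC content of novel-insertion sequence.
#' @param novel_genes_per_ins Number of gene models embedded in each novel
#'   insertion long enough to hold them.
#' @param dispensable List describing a pool of novel segments shared by
#'   subsets of accessions (the dispensable genome): `n_segments`,
#'   `length` range (bp) and `presence_prob` (per-accession carriage
#'   probability).  Each pool segment has one fixed reference insertion
#'   point and sequence, so carriers share it identically and the
#'   pan-genome curve saturates; the default pool is empty.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ref_length = 2e6,
                       n_accessions = 3L,
                       snp_rate = 0.01,
                       short_indel_rate = 1e-3,
                       indel_geom_p = 0.3,
                       sv_counts = list(large_del = 20L, large_ins = 20L,
                                        tandem_dup = 5L, translocation = 5L,
                                        novel_ins = 3L, copy_loss = 0L),
                       sv_lengths = list(large_del = c(50, 5000),
                                         large_ins = c(50, 5000),
                                         tandem_dup = c(500, 2000),
                                         translocation = c(300, 10000),
                                         novel_ins = c(2000, 10000)),
                       dup_copies = c(2L, 4L),
                       gene_model = list(
                         counts = c(NBSLRR = 20L, NCR = 15L, RLK = 15L,
                                    LRR = 10L, HSP = 5L, Fbox = 10L,
                                    kinase = 15L, TE = 30L, other = 60L),
                         mean_cds = 900L,
                         cluster_frac = 0.5,
                         cluster_size = 4L),
                       te_identity = c(0.85, 0.99),
                       fragmentation = list(n50 = 5e4,
                                            gap_range = c(50L, 500L),
                                            scaffold_len = 5e5,
                                            te_gap_frac = 0.3),
                       read_sim = list(depth = 20, mean_len = 3000,
                                       sdlog = 0.25, min_len = 500,
                                       error_rate = 0.01),
                       novel_gc = 0.4,
                       novel_genes_per_ins = 1L,
                       dispensable = list(n_segments = 0L,
                                          length = c(5000, 15000),
                                          presence_prob = 0.5)) {
  cfg <- list(seed = as.integer(seed), ref_length = as.integer(ref_length),
              n_accessions = as.integer(n_accessions), snp_rate = snp_rate,
              short_indel_rate = short_indel_rate,
              indel_geom_p = indel_geom_p, sv_counts = sv_counts,
              sv_lengths = sv_lengths, dup_copies = dup_copies,
              gene_model = gene_model, te_identity = te_identity,
              fragmentation = fragmentation, read_sim = read_sim,
              novel_gc = novel_gc,
              novel_genes_per_ins = as.integer(novel_genes_per_ins),
              dispensable = dispensable)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$ref_length >= 1e4,
            cfg$snp_rate >= 0, cfg$snp_rate <= 1,
            cfg$short_indel_rate >= 0, cfg$short_indel_rate <= 1,
            cfg$indel_geom_p > 0, cfg$indel_geom_p <= 1,
            cfg$read_sim$error_rate >= 0, cfg$read_sim$error_rate <= 1,
            cfg$te_identity[1] >= 0.5, cfg$te_identity[2] <= 1)
  for (cl in names(cfg$sv_lengths)) {
    rng <- cfg$sv_lengths[[cl]]
    if (rng[1] < 50)
      stop("sv_lengths$", cl, ": large-SV lengths must be >= 50 bp")
    if (rng[1] > rng[2]) stop("sv_lengths$", cl, ": empty length range")
  }
  gm <- cfg$gene_model
  if (sum(gm$counts) * gm$mean_cds > 0.5 * cfg$ref_length)
    stop("gene model infeasible: families occupy more than 50% of the reference")
  invisible(cfg)
}

#' Read / write a simulation configuration as JSON
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to serialise configurations")
  x <- unclass(cfg)
  # named count vectors must serialise as JSON objects, not arrays
  x$gene_model$counts <- as.list(x$gene_model$counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to serialise configurations")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$gene_model$counts <- unlist(raw$gene_model$counts)
  raw$sv_lengths <- lapply(raw$sv_lengths, unlist)
  raw$dup_copies <- unlist(raw$dup_copies)
  raw$te_identity <- unlist(raw$te_identity)
  raw$fragmentation$gap_range <- unlist(raw$fragmentation$gap_range)
  raw$dispensable$length <- unlist(raw$dispensable$length)
  do.call(sim_config, raw)
}
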