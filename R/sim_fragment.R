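#' Fragment a genome into gapped scaffolds
#'
#' Emulates a short-read draft assembly: each sequence is cut into
#' scaffolds of roughly `scaffold_len`, and within each scaffold contigs
#' are joined by runs of N whose lengths are drawn from `gap_range`.
#' Contig lengths are drawn uniformly in `[0.4, 1.4] *` target N50, which
#' puts the realised contig N50 within about 20% of the target.  A
#' configurable fraction of gap positions is relocated into TE intervals,
#' mirroring the tendency of assembly breaks to fall in repeats.  Gaps are
#' insertions of N only: removing all N-runs and concatenating sibling
#' scaffolds restores the input sequence exactly.
#'
#' @param gn A `pg_genome` (typically an accession genome).
#' @param config A [sim_config()] (uses `$fragmentation`).
#' @param te_intervals Optional `data.frame(seq_name, start, end)` of
#'   repeat intervals used for preferential gap placement.
#' @return A `pg_genome` of gapped scaffolds with `scaffolds` provenance.
#' @export
fragment_assembly <- function(gn, config, te_intervals = NULL) {
  fr <- config$fragmentation
  withr::local_seed(derive_seed(config$seed, "fragment",
                                paste(names(gn$seq), collapse = ",")))
  target <- fr$n50
  out_seq <- character(0); out_gap <- list(); prov <- list()
  for (nm in names(gn$seq)) {
    s <- gn$seq[[nm]]
    L <- nchar(s)
    if (target >= L) {
      out_seq[nm] <- s
      out_gap[[nm]] <- data.frame(start = integer(0), end = integer(0))
      prov[[length(prov) + 1L]] <- data.frame(name = nm, source = nm,
                                              offset = 0L)
      next
    }
    n_scaf <- max(1L, round(L / fr$scaffold_len))
    scaf_bounds <- unique(c(0L, sort(sample.int(L - 1L, n_scaf - 1L)), L))
    te_here <- if (!is.null(te_intervals))
      te_intervals[te_intervals$seq_name == nm, , drop = FALSE] else NULL
    for (si in seq_len(length(scaf_bounds) - 1L)) {
      s0 <- scaf_bounds[si]; s1 <- scaf_bounds[si + 1L]
      seg <- subseq0(s, s0, s1)
      slen <- s1 - s0
      sname <- if (length(scaf_bounds) > 2L) sprintf("%s.%d", nm, si) else nm
      # contig breakpoints within the scaffold
      breaks <- integer(0); pos <- 0L
      repeat {
        pos <- pos + round(runif(1, 0.4, 1.4) * target)
        if (pos >= slen) break
        breaks <- c(breaks, pos)
      }
      # relocate a fraction of breaks into TE intervals
      if (length(breaks) > 0 && !is.null(te_here) && nrow(te_here) > 0 &&
          fr$te_gap_frac > 0) {
        n_move <- rbinom(1L, length(breaks), fr$te_gap_frac)
        if (n_move > 0) {
          idx <- sample(seq_along(breaks), n_move)
          mid <- (te_here$start + te_here$end) / 2
          for (ii in idx) {
            b_abs <- breaks[ii] + s0
            r <- te_here[which.min(abs(mid - b_abs)), ]
            p <- sample(r$start:max(r$start, r$end - 1L), 1L) - s0
            # only relocate to a nearby repeat, so contig sizes stay on target
            if (p > 0 && p < slen && abs(p - breaks[ii]) < target)
              breaks[ii] <- p
          }
          breaks <- sort(unique(breaks))
        }
      }
      if (length(breaks) == 0) {
        out_seq[sname] <- seg
        out_gap[[sname]] <- data.frame(start = integer(0), end = integer(0))
      } else {
        glens <- sample(fr$gap_range[1]:fr$gap_range[2], length(breaks),
                        replace = TRUE)
        pieces <- character(2L * length(breaks) + 1L)
        prev <- 0L
        gstart <- integer(length(breaks))
        acc_gap <- 0L
        for (bi in seq_along(breaks)) {
          pieces[2L * bi - 1L] <- subseq0(seg, prev, breaks[bi])
          pieces[2L * bi] <- strrep("N", glens[bi])
          gstart[bi] <- breaks[bi] + acc_gap
          acc_gap <- acc_gap + glens[bi]
          prev <- breaks[bi]
        }
        pieces[2L * length(breaks) + 1L] <- subseq0(seg, prev, slen)
        out_seq[sname] <- paste(pieces, collapse = "")
        out_gap[[sname]] <- data.frame(start = gstart, end = gstart + glens)
      }
      prov[[length(prov) + 1L]] <- data.frame(name = sname, source = nm,
                                              offset = s0)
    }
  }
  genome(out_seq, gaps = out_gap, scaffolds = do.call(rbind, prov))
}

#' Simulate long reads from a genome
#'
#' Draws reads with log-normal lengths and uniform placements until the
#' target depth is reached, applying substitution errors at the configured
#' per-base rate (indel errors are not modelled; the mapper and the
#' breakpoint-validation logic only require the diagonal structure that
#' substitutions preserve).  With error rate 0 every read is an exact
#' substring of the genome at its truth placement.
#'
#' @param gn A `pg_genome`; sequences shorter than the minimum read length
#'   are skipped with a warning.
#' @param config A [sim_config()] (uses `$read_sim`).
#' @return data.frame with `read_id, seq_name, start, end, strand, n_err,
#'   sequence` (truth placements, 0-based half-open, forward coordinates).
#' @export
simulate_long_reads <- function(gn, config) {
  rs <- config$read_sim
  stopifnot(rs$depth > 0)
  withr::local_seed(derive_seed(config$seed, "reads",
                                paste(names(gn$seq), collapse = ",")))
  out <- list()
  rid <- 0L
  for (nm in names(gn$seq)) {
    s <- gn$seq[[nm]]
    L <- nchar(s)
    if (L < rs$min_len) {
      warning("sequence ", nm, " shorter than minimum read length; skipped")
      next
    }
    goal <- rs$depth * L
    got <- 0
    meanlog <- log(rs$mean_len) - rs$sdlog^2 / 2
    while (got < goal) {
      rl <- min(L, max(rs$min_len, round(rlnorm(1, meanlog, rs$sdlog))))
      st <- sample.int(L - rl + 1L, 1L) - 1L
      seq <- subseq0(s, st, st + rl)
      n_err <- rbinom(1L, rl, rs$error_rate)
      if (n_err > 0) seq <- substitute_bases(seq, n_err)
      strand <- sample(c("+", "-"), 1L)
      rseq <- if (strand == "-") revcomp(seq) else seq
      rid <- rid + 1L
      out[[rid]] <- data.frame(read_id = sprintf("read%06d", rid),
                               seq_name = nm, start = st, end = st + rl,
                               strand = strand, n_err = n_err,
                               sequence = rseq)
      got <- got + rl
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(read_id = character(0), seq_name = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               n_err = integer(0), sequence = character(0))
  rownames(res) <- NULL
  res
}
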