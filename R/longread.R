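# Long-read breakpoint validation: read placement, the +/-500 bp
# spanning-read rule, and the validation report.

#' Place long reads on an assembly
#'
#' `truth` mode copies the simulator's placements (error for reads
#' without them).  `naive` mode seeds unique 21-mers against the
#' assembly, votes per diagonal and reports the best contiguous
#' placement per read; reads without a confident placement are omitted
#' (count in attribute `n_unplaced`).
#'
#' @param reads Read data.frame from [simulate_long_reads()].
#' @param assembly `pg_genome` to place on (the gap-removed accession
#'   assembly; placements are in its forward coordinates).
#' @param mode `"truth"` or `"naive"`.
#' @param k Seed k-mer size for naive mode.
#' @param min_votes Minimum k-mer votes for a confident placement.
#' @return data.frame `read_id, seq_name, start, end, strand, source`.
#' @export
place_reads <- function(reads, assembly, mode = c("truth", "naive"),
                        k = 21L, min_votes = 5L) {
  mode <- match.arg(mode)
  if (nrow(reads) == 0) {
    out <- data.frame(read_id = character(0), seq_name = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), source = character(0))
    attr(out, "n_unplaced") <- 0L
    return(out)
  }
  if (mode == "truth") {
    if (!all(c("seq_name", "start", "end") %in% names(reads)) ||
        anyNA(reads$start))
      stop("truth placements are unavailable for these reads")
    out <- data.frame(read_id = reads$read_id, seq_name = reads$seq_name,
                      start = reads$start, end = reads$end,
                      strand = reads$strand, source = "truth")
    attr(out, "n_unplaced") <- 0L
    return(out)
  }
  hit <- cpp_map_sequences(reads$sequence, unname(assembly$seq), k, 4L)
  ok <- !is.na(hit$t_seq_i) & hit$votes >= min_votes &
    hit$votes >= 2L * pmax(1L, hit$votes2)
  out <- data.frame(read_id = reads$read_id[ok],
                    seq_name = names(assembly$seq)[hit$t_seq_i[ok]],
                    start = hit$t_start[ok], end = hit$t_end[ok],
                    strand = ifelse(hit$plus[ok], "+", "-"),
                    source = "mapped")
  attr(out, "n_unplaced") <- sum(!ok)
  rownames(out) <- NULL
  out
}

#' Validate SV breakpoints with spanning long reads
#'
#' A read supports a breakpoint when its placement covers the closed
#' window `[bp - window, bp + window]` in one contiguous piece.  An SV is
#' valid only when every one of its breakpoints has at least `min_reads`
#' supporting reads.  Breakpoints are taken in accession (assembly)
#' coordinates: the fused junction for deletions (one breakpoint) and
#' the two insertion junctions for insertion-like calls; translocations
#' use both ends of the inserted segment.
#'
#' @param svs Variant data.frame (large classes; `q_seq/q_start/q_end`
#'   must be in the same coordinates as the placements).
#' @param placements data.frame from [place_reads()].
#' @param window Half-window in bp (500 in the standard rule).
#' @param min_reads Support threshold per breakpoint (5 in the standard
#'   rule).
#' @return data.frame: `id, v_class, n_breakpoints, min_support, valid`
#'   plus a `support` list-column of per-breakpoint counts.
#' @export
validate_svs <- function(svs, placements, window = 500L, min_reads = 5L) {
  out <- list()
  for (i in seq_len(nrow(svs))) {
    v <- svs[i, ]
    bps <- switch(
      v$v_class,
      large_del = , copy_loss = v$q_start,
      large_ins = , copy_gain = , translocation = ,
      novel_ins = c(v$q_start, v$q_end),
      c(v$q_start, v$q_end))
    bps <- unique(bps)
    pl <- placements[placements$seq_name == v$q_seq, , drop = FALSE]
    support <- vapply(bps, function(bp) {
      sum(pl$start <= bp - window & pl$end >= bp + window)
    }, 0L)
    out[[i]] <- data.frame(id = v$id %||% NA_character_,
                           v_class = v$v_class,
                           n_breakpoints = length(bps),
                           min_support = if (length(support)) min(support)
                           else 0L,
                           valid = all(support >= min_reads))
    out[[i]]$support <- I(list(support))
  }
  res <- do.call(rbind, out) %||%
    data.frame(id = character(0), v_class = character(0),
               n_breakpoints = integer(0), min_support = integer(0),
               valid = logical(0))
  rownames(res) <- NULL
  res
}

#' Validation-rate report
#'
#' Overall validation rate, per SV class, and per genomic context
#' (genic / TE / intergenic, from reference gene models).
#'
#' @param validations Output of [validate_svs()].
#' @param svs The corresponding variant data.frame (reference
#'   coordinates used for context assignment).
#' @param genes Reference `pg_genes` (optional; contexts `NA` without
#'   it).
#' @return List of class `sv_validation_report`: `overall`, `by_class`
#'   (data.frame), `by_context` (data.frame), `n`.
#' @export
validation_report <- function(validations, svs, genes = NULL) {
  stopifnot(nrow(validations) == nrow(svs))
  ctx <- rep(NA_character_, nrow(svs))
  if (!is.null(genes)) {
    g <- genes$genes
    for (i in seq_len(nrow(svs))) {
      s0 <- svs$t_start[i]; s1 <- max(svs$t_end[i], svs$t_start[i] + 1L)
      hit <- g$seq_name == svs$t_seq[i] & g$start < s1 & g$end > s0
      ctx[i] <- if (any(hit & !g$is_te)) "genic"
      else if (any(hit & g$is_te)) "TE" else "intergenic"
    }
  }
  by_class <- do.call(rbind, lapply(split(seq_len(nrow(svs)),
                                          svs$v_class), function(idx)
    data.frame(v_class = svs$v_class[idx[1]], n = length(idx),
               rate = mean(validations$valid[idx]))))
  by_context <- if (!all(is.na(ctx)))
    do.call(rbind, lapply(split(seq_len(nrow(svs)), ctx), function(idx)
      data.frame(context = ctx[idx[1]], n = length(idx),
                 rate = mean(validations$valid[idx])))) else NULL
  structure(list(overall = mean(validations$valid),
                 by_class = by_class, by_context = by_context,
                 n = nrow(svs)),
            class = "sv_validation_report")
}

#' @export
print.sv_validation_report <- function(x, ...) {
  cat(sprintf("<sv_validation_report> %d SVs, overall rate %.3f\n",
              x$n, x$overall))
  print(x$by_class)
  invisible(x)
}

#' Convert variant query coordinates to ungapped accession coordinates
#'
#' Variant calls carry query coordinates on the gapped assembly
#' scaffolds; long-read truth placements live on the ungapped accession
#' genome.  This maps `q_start`/`q_end` (and `q_seq`) onto the ungapped
#' source sequences using the assembly's gap registry and scaffold
#' provenance.
#'
#' @param variants Variant data.frame.
#' @param assembly Fragmented `pg_genome` with `scaffolds` provenance.
#' @return The variant data.frame in accession coordinates.
#' @export
degap_variants <- function(variants, assembly) {
  sc <- assembly$scaffolds
  for (i in seq_len(nrow(variants))) {
    nm <- variants$q_seq[i]
    off <- if (!is.null(sc)) sc$offset[match(nm, sc$name)] else 0L
    src <- if (!is.null(sc)) sc$source[match(nm, sc$name)] else nm
    variants$q_start[i] <- off + degap_coord(assembly, nm,
                                             variants$q_start[i])
    variants$q_end[i] <- off + degap_coord(assembly, nm, variants$q_end[i])
    variants$q_seq[i] <- src
  }
  variants
}
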