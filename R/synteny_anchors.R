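#' Synteny-alignment parameters
#'
#' Tunables of the anchoring/chaining/netting pipeline.  Chaining maximises
#' `sum(anchor length) - sum(join penalty)` with
#' `penalty = open + extend * |dq - dt| + diag * min(dq, dt)` for a join
#' with query gap `dq` and target gap `dt`.
#'
#' @param k Anchor k-mer size of the first pass (unique in both genomes).
#' @param k2 k-mer size of the rescue pass restricted to query regions the
#'   first pass left uncovered.
#' @param open,extend,diag Join-penalty coefficients (bp units).
#' @param min_score Minimum chain score retained.
#' @param min_block Minimum chain span (bp) surviving netting.
#' @param fill_limit Largest inter-anchor gap (bp) that is base-level
#'   aligned; larger gaps are kept as unaligned SV-candidate segments.
#' @param slop Coordinate tolerance (bp) of the reciprocal-best agreement.
#' @param max_sv_len Largest between-block discontinuity (bp) accepted as
#'   an SV candidate; larger jumps are treated as non-syntenic junctions
#'   and discarded.
#' @param flank_min Minimum aligned flank (bp) required on both sides of an
#'   SV call.
#' @param gap_margin N-gap exclusion margin (bp) around SV spans.
#' @return A list of class `synteny_params`.
#' @export
synteny_params <- function(k = 15L, k2 = 13L, open = 50, extend = 0.5,
                           diag = 0.01, min_score = 200, min_block = 100L,
                           fill_limit = 5000L, slop = 100L,
                           flank_min = 100L, gap_margin = 100L,
                           max_sv_len = 20000L) {
  structure(list(k = k, k2 = k2, open = open, extend = extend, diag = diag,
                 min_score = min_score, min_block = min_block,
                 fill_limit = fill_limit, slop = slop,
                 flank_min = flank_min, gap_margin = gap_margin,
                 max_sv_len = max_sv_len),
            class = "synteny_params")
}

#' Find unique k-mer anchors between two genomes
#'
#' Anchors are maximal merged runs of k-mers that occur exactly once in
#' each genome (counting both strands), reported on both strands and
#' sorted by `(t_seq, t_start)`.  Minus-strand anchors are stored in
#' plus-of-target orientation with the query coordinate flipped onto the
#' reverse-complemented query ("effective" query frame), so query and
#' target positions increase together in every anchor.
#'
#' @param query,target `pg_genome` objects.
#' @param k k-mer size (>= 11 for genome-scale use; >= 2 accepted for
#'   constructed examples).
#' @param restrict Optional `data.frame(seq_name, start, end)`: only index
#'   query k-mers inside these intervals (used by the rescue pass).
#' @return data.frame of class `pg_anchors` with columns
#'   `q_seq, t_seq, q_start, t_start, length, strand`; query/target
#'   sequence lengths are carried in attributes `q_lens` / `t_lens`.
#' @export
find_anchors <- function(query, target, k = 15L, restrict = NULL) {
  qseqs <- query$seq
  if (!is.null(restrict) && nrow(restrict) > 0) {
    qseqs <- vapply(names(qseqs), function(nm) {
      iv <- restrict[restrict$seq_name == nm, , drop = FALSE]
      s <- qseqs[[nm]]
      if (nrow(iv) == 0) return(strrep("N", nchar(s)))
      keep <- IRanges::reduce(iv_to_ir(iv$start, iv$end))
      masked <- strrep("N", nchar(s))
      for (j in seq_along(keep)) {
        a <- IRanges::start(keep)[j]; b <- IRanges::end(keep)[j]
        substr(masked, a, b) <- substr(s, a, b)
      }
      masked
    }, "")
  }
  raw <- cpp_find_anchors(unname(qseqs), unname(target$seq), as.integer(k))
  out <- data.frame(
    q_seq = names(query$seq)[raw$q_seq_i],
    t_seq = names(target$seq)[raw$t_seq_i],
    q_start = raw$q_start, t_start = raw$t_start, length = raw$length,
    strand = ifelse(raw$plus, "+", "-"))
  out <- out[order(out$t_seq, out$t_start, out$q_seq, out$q_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q_lens") <- vapply(query$seq, nchar, 0L)
  attr(out, "t_lens") <- vapply(target$seq, nchar, 0L)
  class(out) <- c("pg_anchors", "data.frame")
  out
}
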