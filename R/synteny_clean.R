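# Gap-aware cleaning: excise alignment overlapping assembly N-gaps and
# split blocks at the excisions.

flip_iv <- function(iv, len) {
  if (nrow(iv) == 0) return(iv)
  data.frame(start = len - iv$end, end = len - iv$start)
}

#' Clean synteny blocks against assembly gaps
#'
#' Alignment columns overlapping an N-gap interval of either genome are
#' excised and the block is split at every excision; the resulting
#' sub-blocks carry `clean = TRUE`.  Unaligned (double-gap) segments are
#' not excised but are flagged `gap_free = FALSE` when an N-gap falls
#' inside or within `gap_margin` of their span, which later disqualifies
#' them as SV candidates.  Blocks entirely inside a gap are removed.
#'
#' @param blocks List of `pg_block`.
#' @param query_gaps,target_gaps Named lists of `data.frame(start, end)`
#'   N-run registries per sequence (as stored in `pg_genome$gaps`).
#' @param params A [synteny_params()].
#' @return List of clean `pg_block`.
#' @export
clean_blocks <- function(blocks, query_gaps, target_gaps,
                         params = synteny_params()) {
  out <- list()
  for (b in blocks) {
    qg <- query_gaps[[b$q_seq]] %||% data.frame(start = integer(0),
                                                end = integer(0))
    tg <- target_gaps[[b$t_seq]] %||% data.frame(start = integer(0),
                                                 end = integer(0))
    if (b$strand == "-") qg <- flip_iv(qg, b$q_len)
    pieces <- split_block_at_gaps(b, qg, tg, params)
    out <- c(out, pieces)
  }
  out
}

split_block_at_gaps <- function(b, qg, tg, params) {
  seg <- b$segments
  n <- nrow(seg)
  m <- params$gap_margin
  meta <- list(q_seq = b$q_seq, t_seq = b$t_seq, strand = b$strand,
               q_len = b$q_len, id = b$chain_id)
  una <- seg$type == "unaligned"
  tbad <- qbad <- rep(FALSE, n)
  if (nrow(tg) > 0)
    tbad <- seg$t_end > seg$t_start &
      iv_overlaps_any(seg$t_start, seg$t_end, tg)
  if (nrow(qg) > 0)
    qbad <- seg$q_end > seg$q_start &
      iv_overlaps_any(seg$q_start, seg$q_end, qg)
  seg$gap_free <- TRUE
  if (any(una))
    seg$gap_free[una] <-
      !(iv_overlaps_any(seg$t_start[una] - m, seg$t_end[una] + m, tg) |
          iv_overlaps_any(seg$q_start[una] - m, seg$q_end[una] + m, qg))
  bad <- (tbad | qbad) & !una
  mk <- function(rows) {
    if (nrow(rows) == 0) return(NULL)
    if (!any(rows$t_end > rows$t_start | rows$q_end > rows$q_start))
      return(NULL)
    new_block(meta, rows, clean = TRUE)
  }
  if (!any(bad)) {
    blk <- mk(seg)
    return(if (is.null(blk)) list() else list(blk))
  }
  # runs of good segments become sub-blocks; surviving pieces of excised
  # segments become their own sub-blocks
  res <- list()
  grp <- cumsum(bad | c(FALSE, head(bad, -1L)))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1 && bad[idx]) {
      pieces <- excise_segment(seg[idx, ], qg, tg)
      for (p in pieces) {
        p$gap_free <- TRUE
        blk <- mk(as.data.frame(p))
        if (!is.null(blk)) res[[length(res) + 1L]] <- blk
      }
    } else {
      blk <- mk(seg[idx[!bad[idx]], , drop = FALSE])
      if (!is.null(blk)) res[[length(res) + 1L]] <- blk
    }
  }
  res
}

# cut one columnar/gap segment against gap intervals; returns surviving
# pieces in order (possibly the untouched segment itself)
excise_segment <- function(s, qg, tg) {
  w <- max(s$t_end - s$t_start, s$q_end - s$q_start)
  bad <- IRanges::IRanges()
  if (s$t_end > s$t_start && nrow(tg) > 0) {
    os <- pmax(tg$start, s$t_start); oe <- pmin(tg$end, s$t_end)
    ok <- os < oe
    if (any(ok))
      bad <- c(bad, IRanges::shift(iv_to_ir(os[ok], oe[ok]), -s$t_start))
  }
  if (s$q_end > s$q_start && nrow(qg) > 0) {
    os <- pmax(qg$start, s$q_start); oe <- pmin(qg$end, s$q_end)
    ok <- os < oe
    if (any(ok))
      bad <- c(bad, IRanges::shift(iv_to_ir(os[ok], oe[ok]), -s$q_start))
  }
  if (length(bad) == 0) return(list(s))
  keep <- IRanges::setdiff(IRanges::IRanges(1L, w), IRanges::reduce(bad))
  lapply(seq_along(keep), function(j) {
    o0 <- IRanges::start(keep)[j] - 1L; o1 <- IRanges::end(keep)[j]
    p <- s
    if (s$t_end > s$t_start) { p$t_start <- s$t_start + o0; p$t_end <- s$t_start + o1 }
    if (s$q_end > s$q_start) { p$q_start <- s$q_start + o0; p$q_end <- s$q_start + o1 }
    if (!is.na(s$ref_seq) && nzchar(s$ref_seq))
      p$ref_seq <- substr(s$ref_seq, o0 + 1L, o1)
    if (!is.na(s$alt_seq) && nzchar(s$alt_seq))
      p$alt_seq <- substr(s$alt_seq, o0 + 1L, o1)
    p
  })
}
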