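# Per-accession reference coverage masks derived from clean synteny blocks.

#' Build a coverage mask from clean synteny blocks
#'
#' A reference position counts as covered for an accession when a clean
#' synteny block aligns accession sequence across it (match or mismatch
#' columns).  Positions deleted in the accession or inside unaligned
#' double-gap segments are not covered: the mask marks exactly the places
#' where the alignment supports the non-variant state, which is what
#' reference-genotype imputation requires.
#'
#' @param blocks_by_acc Named list: accession -> list of clean `pg_block`.
#' @param target Reference `pg_genome` (for sequence lengths).
#' @return A `pg_mask`: per accession, per reference sequence, an
#'   `IRanges` of covered intervals, plus sequence lengths.
#' @export
coverage_mask <- function(blocks_by_acc, target) {
  seqlens <- vapply(target$seq, nchar, 0L)
  acc <- lapply(blocks_by_acc, function(blocks) {
    per_seq <- list()
    for (b in blocks) {
      if (!isTRUE(b$clean)) next
      s <- b$segments
      keep <- s$type %in% c("match", "mismatch")
      if (!any(keep)) next
      ir <- iv_to_ir(s$t_start[keep], s$t_end[keep])
      per_seq[[b$t_seq]] <- c(per_seq[[b$t_seq]] %||% IRanges::IRanges(), ir)
    }
    lapply(per_seq, IRanges::reduce)
  })
  structure(list(acc = acc, seqlens = seqlens), class = "pg_mask")
}

#' @export
print.pg_mask <- function(x, ...) {
  for (a in names(x$acc)) {
    bp <- mask_bp(x, a)
    cat(sprintf("  %s: %s bp covered (%.1f%%)\n", a,
                format(bp, big.mark = ","), 100 * bp / sum(x$seqlens)))
  }
  invisible(x)
}

#' Covered base pairs of one accession (or of an intersection/union)
#'
#' @param mask A `pg_mask`.
#' @param accessions Accession name(s).
#' @param op `"single"` (first accession), `"intersect"` (bases covered in
#'   all) or `"union"` (bases covered in any).
#' @return Total bp.
#' @export
mask_bp <- function(mask, accessions, op = c("single", "intersect", "union")) {
  op <- match.arg(op)
  if (op == "single") accessions <- accessions[1]
  ir <- mask_combine(mask, accessions, if (op == "intersect") "intersect"
                     else "union")
  sum(vapply(ir, function(x) sum(IRanges::width(x)), 0))
}

# combine per-sequence interval lists across accessions
mask_combine <- function(mask, accessions, op) {
  seqs <- unique(unlist(lapply(mask$acc[accessions], names)))
  out <- list()
  for (sq in seqs) {
    irs <- lapply(accessions, function(a)
      mask$acc[[a]][[sq]] %||% IRanges::IRanges())
    cur <- irs[[1]]
    for (j in seq_along(irs)[-1]) {
      cur <- if (op == "intersect") IRanges::intersect(cur, irs[[j]])
      else IRanges::union(cur, irs[[j]])
    }
    out[[sq]] <- cur
  }
  out
}

# does the mask of `accession` fully cover [start, end) on seq_name?
mask_covers <- function(mask, accession, seq_name, start, end) {
  ir <- mask$acc[[accession]][[seq_name]]
  if (is.null(ir) || length(ir) == 0) return(rep(FALSE, length(start)))
  end <- pmax(end, start + 1L)
  q <- iv_to_ir(start, end)
  hits <- IRanges::findOverlaps(q, ir)
  ok <- rep(FALSE, length(q))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  full <- IRanges::start(ir)[sh] <= IRanges::start(q)[qh] &
    IRanges::end(ir)[sh] >= IRanges::end(q)[qh]
  ok[unique(qh[full])] <- TRUE
  ok
}

#' Track of bases covered in at least m accessions
#'
#' @param mask A `pg_mask`.
#' @param m Minimum number of accessions.
#' @return Named list per reference sequence of `IRanges` covered in
#'   `>= m` accessions.
#' @export
min_cover_track <- function(mask, m) {
  seqs <- names(mask$seqlens)
  out <- list()
  for (sq in seqs) {
    irs <- lapply(mask$acc, function(a) a[[sq]] %||% IRanges::IRanges())
    cov <- Reduce(`+`, lapply(irs, function(x)
      IRanges::coverage(x, width = mask$seqlens[[sq]])))
    out[[sq]] <- IRanges::reduce(IRanges::IRanges(S4Vectors::Rle(cov >= m)))
  }
  out
}
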