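# Netting: single-coverage selection of chains, and reciprocal-best
# filtering between the two netting directions.

# clip a chain's anchors to the allowed (free) intervals in one space
clip_chain <- function(ch, free_ir, space, min_piece = 10L) {
  a <- ch$anchors
  pos <- if (space == "target") a$t_start else a$q_start
  air <- iv_to_ir(pos, pos + a$length)
  hits <- IRanges::findOverlaps(air, free_ir)
  if (length(hits) == 0) return(NULL)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ps <- pmax(IRanges::start(air)[qh], IRanges::start(free_ir)[sh])
  pe <- pmin(IRanges::end(air)[qh], IRanges::end(free_ir)[sh])
  off <- ps - IRanges::start(air)[qh]
  len <- pe - ps + 1L
  keep <- len >= pmin(min_piece, a$length[qh])
  if (!any(keep)) return(NULL)
  na <- data.frame(q_start = a$q_start[qh] + off,
                   t_start = a$t_start[qh] + off,
                   length = len)[keep, , drop = FALSE]
  na <- na[order(na$t_start, na$q_start), , drop = FALSE]
  rownames(na) <- NULL
  na
}

#' Net chains to single coverage
#'
#' Accepts chains in descending score order; the portion of each chain's
#' anchors overlapping already-accepted anchors (in the chosen space) is
#' trimmed away, and chains whose remaining span falls below `min_block`
#' are dropped.  Occupancy is tracked at anchor granularity, so a chain
#' that fits entirely inside a large unaligned gap of a better chain (for
#' example a translocated segment) survives as its own block.  Accepted
#' anchors never overlap pairwise in the netting space.
#'
#' @param chains List of `pg_chain` (any order; sorted internally).
#' @param params A [synteny_params()].
#' @param space `"target"` (single coverage in the reference) or
#'   `"query"`.
#' @return List of netted `pg_chain` (original ids preserved).
#' @export
net_chains <- function(chains, params = synteny_params(),
                       space = c("target", "query")) {
  space <- match.arg(space)
  if (length(chains) == 0) return(list())
  chains <- sort_chains(chains)
  occupied <- list()
  out <- list()
  for (ch in chains) {
    seqnm <- if (space == "target") ch$t_seq else ch$q_seq
    # minus-strand query coordinates live in the effective (flipped) frame;
    # occupancy in query space must be tracked in the forward frame
    a <- ch$anchors
    if (space == "query" && ch$strand == "-") {
      fstart <- ch$q_len - (a$q_start + a$length)
      air <- iv_to_ir(fstart, fstart + a$length)
    } else {
      pos <- if (space == "target") a$t_start else a$q_start
      air <- iv_to_ir(pos, pos + a$length)
    }
    occ <- occupied[[seqnm]] %||% IRanges::IRanges()
    lo <- min(IRanges::start(air)); hi <- max(IRanges::end(air))
    # a chain whose span threads through already-accepted alignment is a
    # parallel (interleaved) duplicate, not a nested rescue: drop it.  A
    # chain nested inside a large gap of an accepted chain has zero
    # overlap with accepted anchors and passes untouched.
    span_occ <- sum(IRanges::width(
      IRanges::intersect(IRanges::IRanges(lo, hi), occ)))
    if (span_occ > 0.3 * (hi - lo + 1)) next
    free <- IRanges::setdiff(IRanges::IRanges(lo, hi), occ)
    if (space == "query" && ch$strand == "-") {
      # clip in the effective frame: flip free intervals back
      fs <- ch$q_len - (IRanges::end(free))     # 0-based start
      fe <- ch$q_len - (IRanges::start(free) - 1L)
      free_eff <- iv_to_ir(fs, fe)
      na <- clip_chain(ch, free_eff, "query")
    } else {
      na <- clip_chain(ch, free, space)
    }
    if (is.null(na)) next
    span <- if (space == "target")
      na$t_start[nrow(na)] + na$length[nrow(na)] - na$t_start[1]
    else na$q_start[nrow(na)] + na$length[nrow(na)] - na$q_start[1]
    if (span < params$min_block) next
    nc <- new_chain(ch$q_seq, ch$t_seq, ch$strand, na,
                    score_chain(na, params), ch$q_len, ch$id)
    out[[length(out) + 1L]] <- nc
    if (space == "query" && ch$strand == "-") {
      fstart <- ch$q_len - (na$q_start + na$length)
      claimed <- iv_to_ir(fstart, fstart + na$length)
    } else {
      pos <- if (space == "target") na$t_start else na$q_start
      claimed <- iv_to_ir(pos, pos + na$length)
    }
    occupied[[seqnm]] <- IRanges::reduce(c(occ, claimed))
  }
  out
}

#' Reciprocal-best filtering of two netting directions
#'
#' Keeps, for each chain of the target-space net, the anchor regions whose
#' query<->target mapping also survives the query-space net of the same
#' chain set (agreement within `slop` bp).  Chains absent from either net
#' are dropped.
#'
#' @param net_t Chains netted with `space = "target"`.
#' @param net_q The same chain set netted with `space = "query"`.
#' @param params A [synteny_params()].
#' @return List of reciprocal-best `pg_chain`.
#' @export
reciprocal_best <- function(net_t, net_q, params = synteny_params()) {
  if (length(net_t) == 0 || length(net_q) == 0) return(list())
  qids <- vapply(net_q, `[[`, 0L, "id")
  out <- list()
  for (ch in net_t) {
    j <- match(ch$id, qids)
    if (is.na(j)) next
    cq <- net_q[[j]]$anchors
    allowed <- IRanges::reduce(
      iv_to_ir(cq$q_start, cq$q_start + cq$length) + params$slop)
    na <- clip_chain(ch, allowed, "query")
    if (is.null(na)) next
    span <- na$t_start[nrow(na)] + na$length[nrow(na)] - na$t_start[1]
    if (span < params$min_block) next
    out[[length(out) + 1L]] <-
      new_chain(ch$q_seq, ch$t_seq, ch$strand, na,
                score_chain(na, params), ch$q_len, ch$id)
  }
  out
}
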