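# Base-level fill of inter-anchor gaps, producing synteny blocks.

new_block <- function(chain, segments, clean = FALSE) {
  seg <- segments[segments$t_end > segments$t_start |
                    segments$q_end > segments$q_start, , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(q_seq = chain$q_seq, t_seq = chain$t_seq,
                 strand = chain$strand, q_len = chain$q_len,
                 t_start = min(seg$t_start), t_end = max(seg$t_end),
                 q_start = min(seg$q_start), q_end = max(seg$q_end),
                 segments = seg, clean = clean, chain_id = chain$id),
            class = "pg_block")
}

#' @export
print.pg_block <- function(x, ...) {
  cat(sprintf(
    "<block> %s:%d-%d %s %s:%d-%d (%d segments%s)\n",
    x$q_seq, x$q_start, x$q_end, x$strand, x$t_seq, x$t_start, x$t_end,
    nrow(x$segments), if (isTRUE(x$clean)) ", clean" else ""))
  invisible(x)
}

#' Fill inter-anchor gaps of a chain to base level
#'
#' Anchors become match segments.  Gaps with `max(dq, dt) <= fill_limit`
#' are resolved to columns: single-sided gaps become one insertion/deletion
#' run, equal-length gaps are compared column-wise (mismatch columns are
#' SNP sites), and unequal two-sided gaps are globally aligned (match +1,
#' mismatch -2, gap open -10, extend -0.5; the stiff mismatch and open
#' costs keep unrelated sequence gapped out rather than chopped into
#' pseudo-matches).  Larger gaps are recorded as
#' unaligned double-gap segments -- the large-SV candidates.  The segments
#' tile the chain spans exactly.
#'
#' Segment types: `match`, `mismatch` (run of mismatch columns), `gap_q`
#' (query missing target bases: deletion in the accession), `gap_t`
#' (target missing query bases: insertion), `unaligned`.  `ref_seq` /
#' `alt_seq` hold the literal alleles for mismatch and gap segments.
#' Query coordinates are in the effective frame of the chain's strand.
#'
#' @param chain A `pg_chain`.
#' @param query,target `pg_genome` objects.
#' @param params A [synteny_params()].
#' @return A `pg_block`.
#' @export
fill_alignment <- function(chain, query, target, params = synteny_params()) {
  qs_full <- query$seq[[chain$q_seq]]
  qs <- if (chain$strand == "-") revcomp(qs_full) else qs_full
  ts <- target$seq[[chain$t_seq]]
  a <- chain$anchors
  n <- nrow(a)

  segs <- vector("list", 2L * n)
  cnt <- 0L
  emit <- function(type, t0, t1, q0, q1, ref = NA_character_,
                   alt = NA_character_) {
    cnt <<- cnt + 1L
    if (cnt > length(segs)) length(segs) <<- 2L * cnt
    segs[[cnt]] <<- list(type = type, t_start = t0, t_end = t1,
                         q_start = q0, q_end = q1, ref_seq = ref,
                         alt_seq = alt)
  }

  for (i in seq_len(n)) {
    if (i > 1) {
      t0 <- a$t_start[i - 1] + a$length[i - 1]; t1 <- a$t_start[i]
      q0 <- a$q_start[i - 1] + a$length[i - 1]; q1 <- a$q_start[i]
      dt <- t1 - t0; dq <- q1 - q0
      if (dt > 0 || dq > 0) {
        if (max(dt, dq) > params$fill_limit) {
          emit("unaligned", t0, t1, q0, q1)
        } else if (dq == 0) {
          emit("gap_q", t0, t1, q0, q0, ref = subseq0(ts, t0, t1), alt = "")
        } else if (dt == 0) {
          emit("gap_t", t0, t0, q0, q1, ref = "", alt = subseq0(qs, q0, q1))
        } else if (dq == dt) {
          emit_columns(emit, subseq0(ts, t0, t1), subseq0(qs, q0, q1),
                       t0, q0)
        } else {
          emit_aligned(emit, subseq0(ts, t0, t1), subseq0(qs, q0, q1),
                       t0, q0)
        }
      }
    }
    emit("match", a$t_start[i], a$t_start[i] + a$length[i],
         a$q_start[i], a$q_start[i] + a$length[i])
  }

  seg <- data.frame(
    type = vapply(segs[seq_len(cnt)], `[[`, "", "type"),
    t_start = vapply(segs[seq_len(cnt)], `[[`, 0L, "t_start"),
    t_end = vapply(segs[seq_len(cnt)], `[[`, 0L, "t_end"),
    q_start = vapply(segs[seq_len(cnt)], `[[`, 0L, "q_start"),
    q_end = vapply(segs[seq_len(cnt)], `[[`, 0L, "q_end"),
    ref_seq = vapply(segs[seq_len(cnt)], `[[`, "", "ref_seq"),
    alt_seq = vapply(segs[seq_len(cnt)], `[[`, "", "alt_seq"))
  new_block(chain, seg)
}

# equal-length gap: column-wise comparison into match/mismatch runs;
# offsetting indels inside the gap make direct columns look noisy, in
# which case the gap is re-aligned properly
emit_columns <- function(emit, rseq, aseq, t0, q0) {
  rc <- strsplit(rseq, "")[[1]]
  ac <- strsplit(aseq, "")[[1]]
  eq <- rc == ac
  if (length(eq) > 8L && mean(eq) < 0.7) {
    emit_aligned(emit, rseq, aseq, t0, q0)
    return(invisible(NULL))
  }
  r <- rle(eq)
  pos <- 0L
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    if (r$values[j]) {
      emit("match", t0 + pos, t0 + pos + len, q0 + pos, q0 + pos + len)
    } else {
      emit("mismatch", t0 + pos, t0 + pos + len, q0 + pos, q0 + pos + len,
           ref = substr(rseq, pos + 1L, pos + len),
           alt = substr(aseq, pos + 1L, pos + len))
    }
    pos <- pos + len
  }
}

# unequal two-sided gap: global alignment, parsed into runs
emit_aligned <- function(emit, rseq, aseq, t0, q0) {
  if (as.double(nchar(rseq)) * nchar(aseq) > 2.6e7) {
    # too divergent to resolve to columns; keep as SV-candidate segment
    emit("unaligned", t0, t0 + nchar(rseq), q0, q0 + nchar(aseq))
    return(invisible(NULL))
  }
  aln <- cpp_nw_align(rseq, aseq, 1, -2, 10, 0.5)
  p <- strsplit(aln[1], "")[[1]]
  s <- strsplit(aln[2], "")[[1]]
  aligned <- p != "-" & s != "-"
  if (min(nchar(rseq), nchar(aseq)) >= 50L &&
      (sum(aligned) < 10L || mean(p[aligned] == s[aligned]) < 0.75)) {
    # the two sides do not correspond base-by-base: keep the double gap
    # as an SV-candidate segment instead of a fragmented alignment
    emit("unaligned", t0, t0 + nchar(rseq), q0, q0 + nchar(aseq))
    return(invisible(NULL))
  }
  cat_col <- ifelse(p == "-", "gap_t", ifelse(s == "-", "gap_q",
                                              ifelse(p == s, "match",
                                                     "mismatch")))
  r <- rle(cat_col)
  tp <- t0; qp <- q0; pos <- 0L
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    idx <- (pos + 1L):(pos + len)
    type <- r$values[j]
    dtt <- if (type == "gap_t") 0L else len
    dqq <- if (type == "gap_q") 0L else len
    ref <- paste(p[idx][p[idx] != "-"], collapse = "")
    alt <- paste(s[idx][s[idx] != "-"], collapse = "")
    if (type == "match")
      emit("match", tp, tp + dtt, qp, qp + dqq)
    else
      emit(type, tp, tp + dtt, qp, qp + dqq, ref = ref, alt = alt)
    tp <- tp + dtt; qp <- qp + dqq; pos <- pos + len
  }
}
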