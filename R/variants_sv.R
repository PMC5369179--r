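# Large-SV calling: classify >= 50 bp discontinuities from within-block
# gap runs, unaligned double-gap segments and between-block structure.

#' Call large structural variants for one accession
#'
#' Candidates come from three sources: (a) gap runs and unaligned
#' double-gap segments inside blocks with `max(dq, dt) >= 50`; (b)
#' discontinuities between consecutive netted blocks on the same scaffold;
#' (c) blocks whose reference placement breaks the monotone order of their
#' scaffold neighbourhood (translocations; strand-discordant blocks are
#' folded in here).  Classification: `dt >= 50 & dq < 50` is a deletion,
#' `dq >= 50 & dt < 50` an insertion, both `>= 50` a complex substitution
#' emitted as a del+ins pair sharing an id -- unless the reference-side
#' sequence is still contained in the query side at >= 90% identity, in
#' which case the event is a pure insertion of the surplus (tandem
#' duplications land here).  A deletion whose sequence still matches
#' elsewhere in the accession becomes a `copy_loss`; an insertion whose
#' sequence matches the reference (or adjacent query) becomes a
#' `copy_gain`.  Every SV needs `flank_min` aligned bases on both sides
#' within one scaffold and no N-gap within `gap_margin` of its span;
#' discarded candidates are logged with reason codes in the `"discards"`
#' attribute.
#'
#' @param blocks Clean `pg_block` list of one accession (from
#'   [build_synteny()]).
#' @param query Accession assembly `pg_genome`.
#' @param target Reference `pg_genome`.
#' @param params A [synteny_params()].
#' @return Variant data.frame with attribute `discards`.
#' @export
call_svs <- function(blocks, query, target, params = synteny_params()) {
  if (length(blocks) == 0) return(empty_variants())
  qidx <- cpp_kmer_index(unname(query$seq), 13L, 32L)
  tidx <- cpp_kmer_index(unname(target$seq), 13L, 32L)
  cand <- list(); disc <- list()
  push_cand <- function(block, t0, t1, q0, q1, flank_ok, gap_free) {
    cand[[length(cand) + 1L]] <<- list(block = block, t0 = t0, t1 = t1,
                                       q0 = q0, q1 = q1,
                                       flank_ok = flank_ok,
                                       gap_free = gap_free)
  }

  # (a) within-block gap runs / unaligned segments
  for (b in blocks) {
    s <- b$segments
    dt <- s$t_end - s$t_start
    dq <- s$q_end - s$q_start
    idx <- which((s$type %in% c("gap_q", "gap_t", "unaligned")) &
                   pmax(dt, dq) >= 50L)
    for (i in idx) {
      flank_ok <- aligned_flank(s, i) >= params$flank_min
      push_cand(b, s$t_start[i], s$t_end[i], s$q_start[i], s$q_end[i],
                flank_ok, isTRUE(s$gap_free[i]))
    }
  }

  # aligned coverage of reference and scaffolds across all blocks, used to
  # recognise junction gaps whose content is in fact aligned elsewhere
  tcov <- list(); qcov <- list()
  for (b in blocks) {
    s <- b$segments
    keep <- s$type %in% c("match", "mismatch")
    if (!any(keep)) next
    tcov[[b$t_seq]] <- c(tcov[[b$t_seq]] %||% IRanges::IRanges(),
                         iv_to_ir(s$t_start[keep], s$t_end[keep]))
    qf <- q_to_fwd(b, s$q_start[keep], s$q_end[keep])
    qcov[[b$q_seq]] <- c(qcov[[b$q_seq]] %||% IRanges::IRanges(),
                         iv_to_ir(qf[, 1], qf[, 2]))
  }
  tcov <- lapply(tcov, IRanges::reduce)
  qcov <- lapply(qcov, IRanges::reduce)
  cov_frac <- function(cov, seqnm, start, end) {
    if (end <= start) return(0)
    ir <- cov[[seqnm]]
    if (is.null(ir)) return(0)
    hit <- IRanges::intersect(ir, iv_to_ir(start, end))
    sum(IRanges::width(hit)) / (end - start)
  }

  # order blocks per scaffold in forward query coordinates
  binfo <- data.frame(
    i = seq_along(blocks),
    q_seq = vapply(blocks, `[[`, "", "q_seq"),
    t_seq = vapply(blocks, `[[`, "", "t_seq"),
    strand = vapply(blocks, `[[`, "", "strand"),
    t_start = vapply(blocks, `[[`, 0L, "t_start"),
    t_end = vapply(blocks, `[[`, 0L, "t_end"))
  qiv <- t(vapply(blocks, function(b) q_fwd_interval(b), c(0, 0)))
  binfo$qf_start <- qiv[, 1]; binfo$qf_end <- qiv[, 2]
  binfo$span <- pmax(binfo$t_end - binfo$t_start,
                     binfo$qf_end - binfo$qf_start)

  # (c) translocated blocks: reference placement inconsistent with the
  # dominant neighbourhood of the scaffold
  tra_rows <- list()
  tra_t <- list(); tra_q <- list()
  for (sc in unique(binfo$q_seq)) {
    sub <- binfo[binfo$q_seq == sc, , drop = FALSE]
    sub <- sub[order(sub$qf_start), , drop = FALSE]
    if (nrow(sub) < 2) next
    main_t <- sub$t_seq[which.max(sub$span)]
    main_strand <- sub$strand[which.max(sub$span)]
    for (j in seq_len(nrow(sub))) {
      others <- sub[-j, , drop = FALSE]
      big <- others[others$span >= 5L * sub$span[j], , drop = FALSE]
      if (nrow(big) == 0) next
      # flanking context: a bigger block on each side in query order
      has_left <- any(big$qf_start < sub$qf_start[j])
      has_right <- any(big$qf_end > sub$qf_end[j])
      if (!has_left || !has_right) next
      discordant <- sub$t_seq[j] != main_t || sub$strand[j] != main_strand
      if (!discordant) {
        # expected reference neighbourhood from query-adjacent big blocks
        lo <- max(c(big$t_start[big$qf_start < sub$qf_start[j]],
                    -Inf))
        hi <- min(c(big$t_end[big$qf_end > sub$qf_end[j]], Inf))
        near <- sub$t_start[j] < hi + 50000 && sub$t_end[j] > lo - 50000
        discordant <- !near
      }
      if (discordant && sub$span[j] >= 50L) {
        b <- blocks[[sub$i[j]]]
        tra_rows[[length(tra_rows) + 1L]] <- data.frame(
          v_class = "translocation", t_seq = b$t_seq, t_start = b$t_start,
          t_end = b$t_end, q_seq = b$q_seq, q_start = sub$qf_start[j],
          q_end = sub$qf_end[j], ref_allele = "<TRA>",
          alt_allele = "<TRA>", length = b$t_end - b$t_start,
          flank_ok = TRUE, gap_free = TRUE, id = NA_character_)
      }
    }
  }
  # a translocated region split over several blocks reports once: pieces
  # within 500 bp of each other (in both genomes) merge into one call
  if (length(tra_rows) > 0) {
    tdf <- do.call(rbind, tra_rows)
    tdf <- tdf[order(tdf$t_seq, tdf$t_start), , drop = FALSE]
    grp <- integer(nrow(tdf)); g <- 1L; grp[1] <- 1L
    hi <- tdf$t_end[1]
    for (j in seq_len(nrow(tdf))[-1]) {
      same <- tdf$t_seq[j] == tdf$t_seq[j - 1L] &&
        tdf$q_seq[j] == tdf$q_seq[j - 1L] &&
        tdf$t_start[j] - hi <= 500L
      if (!same) { g <- g + 1L; hi <- tdf$t_end[j] }
      else hi <- max(hi, tdf$t_end[j])
      grp[j] <- g
    }
    merged <- lapply(split(seq_len(nrow(tdf)), grp), function(idx) {
      m <- tdf[idx[1], , drop = FALSE]
      m$t_start <- min(tdf$t_start[idx]); m$t_end <- max(tdf$t_end[idx])
      m$q_start <- min(tdf$q_start[idx]); m$q_end <- max(tdf$q_end[idx])
      m$length <- m$t_end - m$t_start
      m
    })
    tdf <- do.call(rbind, merged)
    tra_rows <- lapply(seq_len(nrow(tdf)), function(j) tdf[j, , drop = FALSE])
    for (j in seq_len(nrow(tdf))) {
      tra_t[[j]] <- data.frame(seq = tdf$t_seq[j], start = tdf$t_start[j],
                               end = tdf$t_end[j])
      tra_q[[j]] <- data.frame(seq = tdf$q_seq[j], start = tdf$q_start[j],
                               end = tdf$q_end[j])
    }
  }

  # (b) between-block discontinuities on one scaffold, concordant order
  for (sc in unique(binfo$q_seq)) {
    sub <- binfo[binfo$q_seq == sc, , drop = FALSE]
    sub <- sub[order(sub$qf_start), , drop = FALSE]
    if (nrow(sub) < 2) next
    for (j in seq_len(nrow(sub) - 1L)) {
      a <- sub[j, ]; b2 <- sub[j + 1L, ]
      if (a$t_seq != b2$t_seq || a$strand != b2$strand) next
      if (a$strand == "+") {
        dtv <- b2$t_start - a$t_end
      } else {
        dtv <- a$t_start - b2$t_end
      }
      dqv <- b2$qf_start - a$qf_end
      if (is.na(dtv) || dtv < 0 || dqv < 0) next
      if (max(dtv, dqv) < 50L) next
      if (max(dtv, dqv) > params$max_sv_len) next  # non-syntenic junction
      t0 <- if (a$strand == "+") a$t_end else b2$t_end
      blkA <- blocks[[a$i]]
      # effective-frame query start of the gap
      q0e <- if (a$strand == "+") a$qf_end else blkA$q_len - a$qf_end
      flank_ok <- (a$qf_end - a$qf_start) >= params$flank_min &&
        (b2$qf_end - b2$qf_start) >= params$flank_min
      if (cov_frac(tcov, a$t_seq, t0, t0 + dtv) <= 0.2) {
        push_cand(blkA, t0, t0 + dtv, q0e, q0e + dqv, flank_ok, TRUE)
      } else {
        # most of the skipped reference is aligned by other blocks: only
        # its uncovered islands are deletion candidates, and the query
        # side is an insertion candidate only if unaligned itself
        free <- IRanges::setdiff(iv_to_ir(t0, t0 + dtv),
                                 tcov[[a$t_seq]] %||% IRanges::IRanges())
        for (fi in seq_along(free)) {
          f0 <- IRanges::start(free)[fi] - 1L; f1 <- IRanges::end(free)[fi]
          if (f1 - f0 >= 50L)
            push_cand(blkA, f0, f1, q0e, q0e, flank_ok, TRUE)
        }
        if (dqv >= 50L &&
            cov_frac(qcov, a$q_seq, a$qf_end, a$qf_end + dqv) <= 0.5)
          push_cand(blkA, t0, t0, q0e, q0e + dqv, flank_ok, TRUE)
      }
    }
  }

  tra_t <- do.call(rbind, tra_t)
  tra_q <- do.call(rbind, tra_q)

  out <- list()
  drop_log <- function(b, t0, t1, reason) {
    disc[[length(disc) + 1L]] <<- data.frame(t_seq = b$t_seq, t_start = t0,
                                             t_end = t1, reason = reason)
  }
  sv_id <- 0L
  for (cd in cand) {
    b <- cd$block
    dt <- cd$t1 - cd$t0; dq <- cd$q1 - cd$q0
    qf <- q_to_fwd(b, cd$q0, cd$q1)
    # suppressed when explained by a translocated block
    if (!is.null(tra_t) && dt >= 50L &&
        any(tra_t$seq == b$t_seq &
              pmin(tra_t$end, cd$t1) - pmax(tra_t$start, cd$t0) >= -100L &
              dt <= 2L * (tra_t$end - tra_t$start) + 500L)) next
    if (!is.null(tra_q) && dq >= 50L &&
        any(tra_q$seq == b$q_seq & pmin(tra_q$end, qf[1, 2]) -
              pmax(tra_q$start, qf[1, 1]) >= 0.5 * dq)) next
    if (!cd$flank_ok) { drop_log(b, cd$t0, cd$t1, "flank"); next }
    if (!cd$gap_free) { drop_log(b, cd$t0, cd$t1, "gap"); next }
    # N-gap proximity re-check in forward frames
    if (near_gap(query$gaps[[b$q_seq]], qf[1, 1], qf[1, 2], params$gap_margin) ||
        near_gap(target$gaps[[b$t_seq]], cd$t0, cd$t1, params$gap_margin)) {
      drop_log(b, cd$t0, cd$t1, "gap")
      next
    }
    qseq_eff <- if (b$strand == "-") revcomp(query$seq[[b$q_seq]]) else
      query$seq[[b$q_seq]]
    tseq <- target$seq[[b$t_seq]]
    ref_part <- subseq0(tseq, cd$t0, cd$t1)
    alt_part <- subseq0(qseq_eff, cd$q0, cd$q1)
    sv_id <- sv_id + 1L
    id <- sprintf("sv%04d", sv_id)
    if (dt >= 50L && dq >= 50L) {
      dec <- NULL
      if (as.double(dt) * dq <= 1.2e8) {
        # resolve the double gap by alignment and classify each gap run;
        # a decomposition whose aligned columns disagree is rejected
        dec <- decompose_gap(b, cd, ref_part, alt_part, tseq, id,
                             query, target, qidx, tidx, tra_t)
      }
      if (!is.null(dec)) {
        out <- c(out, dec)
      } else if (cov_frac(tcov, b$t_seq, cd$t0, cd$t1) > 0.2) {
        # most of the reference side is aligned by other (nested/rescue)
        # blocks: only its uncovered islands are deletion candidates, and
        # the query side is an insertion only if unaligned itself
        free <- IRanges::setdiff(iv_to_ir(cd$t0, cd$t1),
                                 tcov[[b$t_seq]] %||% IRanges::IRanges())
        for (fi in seq_along(free)) {
          f0 <- IRanges::start(free)[fi] - 1L; f1 <- IRanges::end(free)[fi]
          if (f1 - f0 < 50L) next
          la <- left_align_indel(tseq, f0, subseq0(tseq, f0, f1))
          out[[length(out) + 1L]] <- sv_row(b, "del", la$pos, la$seq, id,
                                            qf, query, target, qidx, tidx,
                                            t_end = la$pos + nchar(la$seq))
        }
        if (cov_frac(qcov, b$q_seq, qf[1, 1], qf[1, 2]) <= 0.2) {
          la <- left_align_indel(tseq, cd$t0, alt_part)
          out[[length(out) + 1L]] <- sv_row(b, "ins", la$pos, la$seq, id,
                                            qf, query, target, qidx, tidx,
                                            tra_t = tra_t)
        }
      } else if (seq_similar(ref_part, alt_part) >=
                   (if (as.double(dt) * dq <= 1.2e8) 0.5 else 0.15)) {
        # same locus, merely divergent / unanchorable (e.g. repeat copies):
        # not a structural variant
        drop_log(b, cd$t0, cd$t1, "divergent_fill")
      } else {
        out[[length(out) + 1L]] <- sv_row(b, "del", cd$t0, ref_part, id,
                                          qf, query, target, qidx, tidx,
                                          t_end = cd$t1)
        out[[length(out) + 1L]] <- sv_row(b, "ins", cd$t0, alt_part,
                                          id, qf, query, target, qidx, tidx,
                                          tra_t = tra_t)
      }
    } else if (dt >= 50L) {
      la <- left_align_indel(tseq, cd$t0, ref_part)
      out[[length(out) + 1L]] <- sv_row(b, "del", la$pos, la$seq, id, qf,
                                        query, target, qidx, tidx,
                                        t_end = la$pos + nchar(la$seq))
    } else if (dq >= 50L) {
      la <- left_align_indel(tseq, cd$t0, alt_part)
      out[[length(out) + 1L]] <- sv_row(b, "ins", la$pos, la$seq, id, qf,
                                        query, target, qidx, tidx,
                                        tra_t = tra_t)
    }
  }

  out <- Filter(Negate(is.null), out)
  res <- do.call(rbind, c(out, tra_rows)) %||% empty_variants()
  rownames(res) <- NULL
  # near-duplicate large calls (same event reached through two block
  # paths, left-aligned a base or two apart) collapse to the first
  if (nrow(res) > 1) {
    res <- res[order(res$v_class, res$t_seq, res$t_start), , drop = FALSE]
    drop <- rep(FALSE, nrow(res))
    for (j in seq_len(nrow(res))[-1]) {
      p <- j - 1L
      if (!drop[p] &&
          res$v_class[j] == res$v_class[p] &&
          res$t_seq[j] == res$t_seq[p] &&
          abs(res$t_start[j] - res$t_start[p]) <= 10L &&
          abs(res$length[j] - res$length[p]) <= 10L)
        drop[j] <- TRUE
    }
    res <- res[!drop, , drop = FALSE]
    rownames(res) <- NULL
  }
  # large deletions at the very edge of a called translocation are
  # breakpoint residue of the translocated block, not separate events
  if (!is.null(tra_t) && nrow(res) > 0) {
    is_del <- res$v_class %in% c("large_del", "copy_loss")
    near_tra <- vapply(seq_len(nrow(res)), function(j) {
      if (!is_del[j]) return(FALSE)
      any(tra_t$seq == res$t_seq[j] &
            pmin(tra_t$end, res$t_end[j]) -
            pmax(tra_t$start, res$t_start[j]) >= -100L &
            res$length[j] <= 0.5 * (tra_t$end - tra_t$start) + 200L)
    }, TRUE)
    res <- res[!near_tra, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "discards") <- do.call(rbind, disc) %||%
    data.frame(t_seq = character(0), t_start = integer(0),
               t_end = integer(0), reason = character(0))
  res
}

# align a double-sided gap and turn its gap runs into indel calls
decompose_gap <- function(b, cd, ref_part, alt_part, tseq, id,
                          query, target, qidx, tidx, tra_t = NULL) {
  aln <- cpp_nw_align(ref_part, alt_part, 1, -2, 10, 0.5)
  p <- strsplit(aln[1], "")[[1]]
  s <- strsplit(aln[2], "")[[1]]
  cat_col <- ifelse(p == "-", "gap_t", ifelse(s == "-", "gap_q", "aln"))
  aligned <- cat_col == "aln"
  if (sum(aligned) < 10L || mean(p[aligned] == s[aligned]) < 0.75)
    return(NULL)
  r <- rle(cat_col)
  rows <- list()
  tp <- cd$t0; qp <- cd$q0; pos <- 0L
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]
    type <- r$values[j]
    dtt <- if (type == "gap_t") 0L else len
    dqq <- if (type == "gap_q") 0L else len
    if (type == "gap_q" && len >= 1L) {
      seqd <- paste(p[(pos + 1L):(pos + len)], collapse = "")
      la <- left_align_indel(tseq, tp, seqd)
      qfr <- q_to_fwd(b, qp, qp)
      if (len >= 50L) {
        rows[[length(rows) + 1L]] <- sv_row(b, "del", la$pos, la$seq, id,
                                            qfr, query, target, qidx, tidx,
                                            t_end = la$pos + len)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          v_class = "short_del", t_seq = b$t_seq, t_start = la$pos,
          t_end = la$pos + len, q_seq = b$q_seq, q_start = qfr[1, 1],
          q_end = qfr[1, 2], ref_allele = la$seq, alt_allele = "",
          length = len, flank_ok = TRUE, gap_free = TRUE,
          id = NA_character_)
      }
    } else if (type == "gap_t" && len >= 1L) {
      seqi <- paste(s[(pos + 1L):(pos + len)], collapse = "")
      la <- left_align_indel(tseq, tp, seqi)
      qfr <- q_to_fwd(b, qp, qp + len)
      if (len >= 50L) {
        rows[[length(rows) + 1L]] <- sv_row(b, "ins", la$pos, la$seq, id,
                                            qfr, query, target, qidx, tidx,
                                            tra_t = tra_t)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          v_class = "short_ins", t_seq = b$t_seq, t_start = la$pos,
          t_end = la$pos, q_seq = b$q_seq, q_start = qfr[1, 1],
          q_end = qfr[1, 2], ref_allele = "", alt_allele = la$seq,
          length = len, flank_ok = TRUE, gap_free = TRUE,
          id = NA_character_)
      }
    }
    tp <- tp + dtt; qp <- qp + dqq; pos <- pos + len
  }
  rows
}

# aligned bp immediately flanking segment i within its block
aligned_flank <- function(s, i) {
  w <- ifelse(s$type %in% c("match", "mismatch"),
              s$t_end - s$t_start, 0L)
  left <- sum(w[seq_len(i - 1L)])
  right <- sum(w[seq(i + 1L, length.out = nrow(s) - i)])
  min(left, right)
}

near_gap <- function(gaps, start, end, margin) {
  if (is.null(gaps) || nrow(gaps) == 0) return(FALSE)
  any(gaps$start < end + margin & gaps$end > start - margin)
}

# shared-k-mer fraction of the shorter of two sequences: a cheap estimate
# of whether they are the same (possibly divergent) locus
seq_similar <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (nchar(a) < 20L) return(0)
  hit <- cpp_map_sequences(a, b, 13L, 64L)
  hit$votes[1] / max(1L, nchar(a) - 12L)
}

# containment of `needle` in `haystack` at high identity; returns the
# identity and the (0-based) offset of the match in the haystack
seq_contained <- function(needle, haystack) {
  none <- list(ident = 0, offset = NA_integer_)
  nl <- nchar(needle)
  if (nl > nchar(haystack)) return(none)
  # fast path: exact-ish prefix (tandem-duplication geometry)
  pref <- substr(haystack, 1L, nl)
  eq <- sum(strsplit(pref, "")[[1]] == strsplit(needle, "")[[1]]) / nl
  if (eq >= 0.95) return(list(ident = eq, offset = 0L))
  hit <- cpp_map_sequences(needle, haystack, 13L, 16L)
  if (is.na(hit$t_seq_i[1]) || hit$votes[1] < 3 || !isTRUE(hit$plus[1]))
    return(none)
  ident <- verify_identity(needle, haystack, hit)
  list(ident = ident, offset = max(0L, hit$t_start[1] - hit$q_start[1]))
}

# verify a seed hit by global alignment of the matched windows
verify_identity <- function(qseq, tseq, hit) {
  t0 <- max(0L, hit$t_start[1] - hit$q_start[1] - 50L)
  t1 <- min(nchar(tseq), hit$t_end[1] + (nchar(qseq) - hit$q_end[1]) + 50L)
  win <- subseq0(tseq, t0, t1)
  if (nchar(win) == 0) return(0)
  if (as.double(nchar(win)) * nchar(qseq) > 2.5e7) {
    # too large to verify by DP; fall back to the k-mer vote fraction
    return(hit$votes[1] / max(1L, nchar(qseq) - 13L + 1L))
  }
  aln <- cpp_nw_align(qseq, win, 1, -1, 4, 1)
  p <- strsplit(aln[1], "")[[1]]; s <- strsplit(aln[2], "")[[1]]
  core <- p != "-"
  sum(p[core] == s[core]) / sum(core)
}

sv_row <- function(b, kind, t_pos, seq, id, qf, query, target,
                   qidx, tidx, t_end = NULL, tra_t = NULL) {
  len <- nchar(seq)
  if (kind == "del") {
    hit <- copy_hit(seq, query, qidx)
    cls <- if (!is.null(hit)) "copy_loss" else "large_del"
    data.frame(v_class = cls, t_seq = b$t_seq, t_start = t_pos,
               t_end = t_end %||% (t_pos + len), q_seq = b$q_seq,
               q_start = qf[1, 1], q_end = qf[1, 1], ref_allele = seq,
               alt_allele = "", length = len, flank_ok = TRUE,
               gap_free = TRUE, id = id)
  } else {
    hit <- copy_hit(seq, target, tidx)
    if (!is.null(hit) && !is.null(tra_t) &&
        any(tra_t$seq == names(target$seq)[hit$seq_i] &
              pmin(tra_t$end, hit$t1) - pmax(tra_t$start, hit$t0) >= -500L))
      return(NULL)  # the insertion is a translocation destination
    cls <- if (!is.null(hit)) "copy_gain" else "large_ins"
    data.frame(v_class = cls, t_seq = b$t_seq, t_start = t_pos,
               t_end = t_pos, q_seq = b$q_seq, q_start = qf[1, 1],
               q_end = qf[1, 2], ref_allele = "", alt_allele = seq,
               length = len, flank_ok = TRUE, gap_free = TRUE, id = id)
  }
}

# best >= 90%-identity match of `seq` elsewhere in `gn` (NULL if none).
# Probed with up to three 150 bp windows so tandem arrays (whose full
# length exceeds any single genomic copy) are still recognised.
copy_hit <- function(seq, gn, idx) {
  len <- nchar(seq)
  if (len < 50L) return(NULL)
  w <- min(150L, len)
  starts <- unique(pmax(0L, c(0L, (len - w) %/% 2L, len - w)))
  probes <- vapply(starts, function(s) subseq0(seq, s, s + w), "")
  locs <- lapply(seq_along(probes), function(i) {
    p <- probes[i]
    hit <- cpp_map_indexed(p, idx)
    if (is.na(hit$t_seq_i[1])) return(NULL)
    if (hit$votes[1] < max(3L, 0.05 * (nchar(p) - 12L))) return(NULL)
    tseq <- gn$seq[[hit$t_seq_i[1]]]
    qs <- if (isTRUE(hit$plus[1])) p else revcomp(p)
    if (verify_identity(qs, tseq, hit) < 0.9) return(NULL)
    data.frame(seq_i = hit$t_seq_i[1],
               t0 = max(0L, hit$t_start[1] - starts[i]),
               t1 = hit$t_end[1] + (len - starts[i] - w))
  })
  locs <- locs[!vapply(locs, is.null, TRUE)]
  if (length(locs) * 2L <= length(probes)) return(NULL)
  loc <- do.call(rbind, locs)
  list(seq_i = loc$seq_i[1], t0 = min(loc$t0), t1 = max(loc$t1))
}
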