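# Variant calling from clean synteny blocks: SNPs, short indels, anchored
# large SVs.  Variants are reported on the target (reference) plus strand;
# query coordinates are converted from the block's effective frame to
# forward scaffold coordinates.

variant_cols <- c("v_class", "t_seq", "t_start", "t_end", "q_seq",
                  "q_start", "q_end", "ref_allele", "alt_allele", "length",
                  "flank_ok", "gap_free", "id")

empty_variants <- function() {
  data.frame(v_class = character(0), t_seq = character(0),
             t_start = integer(0), t_end = integer(0),
             q_seq = character(0), q_start = integer(0),
             q_end = integer(0), ref_allele = character(0),
             alt_allele = character(0), length = integer(0),
             flank_ok = logical(0), gap_free = logical(0),
             id = character(0))
}

# forward-frame query coordinates of an effective-frame interval
q_to_fwd <- function(block, q0, q1) {
  if (block$strand == "+") cbind(q0, q1)
  else cbind(block$q_len - q1, block$q_len - q0)
}

#' Call SNPs from a clean synteny block
#'
#' One SNP per mismatch column, alleles on the target plus strand.
#'
#' @param block A clean `pg_block`.
#' @return Variant data.frame (one row per SNP).
#' @export
call_snps <- function(block) {
  s <- block$segments
  mm <- s[s$type == "mismatch", , drop = FALSE]
  if (nrow(mm) == 0) return(empty_variants())
  w <- mm$t_end - mm$t_start
  t0 <- rep(mm$t_start, w) + sequence(w) - 1L
  q0 <- rep(mm$q_start, w) + sequence(w) - 1L
  refb <- unlist(strsplit(mm$ref_seq, ""), use.names = FALSE)
  altb <- unlist(strsplit(mm$alt_seq, ""), use.names = FALSE)
  qf <- q_to_fwd(block, q0, q0 + 1L)
  ok <- refb %in% c("A", "C", "G", "T") & altb %in% c("A", "C", "G", "T")
  data.frame(v_class = "SNP", t_seq = block$t_seq, t_start = t0,
             t_end = t0 + 1L, q_seq = block$q_seq, q_start = qf[, 1],
             q_end = qf[, 2], ref_allele = refb, alt_allele = altb,
             length = 1L, flank_ok = TRUE, gap_free = TRUE,
             id = NA_character_)[ok, , drop = FALSE]
}

# shift an indel to its leftmost equivalent position on the target
# (VCF-style normalisation).  type "del": seq removed from target at pos;
# type "ins": seq inserted into target at pos.
left_align_indel <- function(tseq, pos, seq, lo = 0L) {
  len <- nchar(seq)
  if (len == 0) return(list(pos = pos, seq = seq))
  while (pos > lo) {
    prev <- subseq0(tseq, pos - 1L, pos)
    last <- substr(seq, len, len)
    if (prev != last) break
    seq <- paste0(prev, substr(seq, 1L, len - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

#' Call short indels from a clean synteny block
#'
#' Each gap run of length 1--49 becomes one indel, left-aligned against
#' the target.  Gap runs of 50 bp or more are left to [call_svs()].
#'
#' @param block A clean `pg_block`.
#' @param target Reference `pg_genome` (context for left alignment).
#' @return Variant data.frame.
#' @export
call_short_indels <- function(block, target) {
  s <- block$segments
  g <- s[s$type %in% c("gap_q", "gap_t"), , drop = FALSE]
  if (nrow(g) == 0) return(empty_variants())
  glen <- pmax(g$t_end - g$t_start, g$q_end - g$q_start)
  g <- g[glen >= 1L & glen <= 49L, , drop = FALSE]
  if (nrow(g) == 0) return(empty_variants())
  tseq <- target$seq[[block$t_seq]]
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    if (r$type == "gap_q") {           # deletion in the accession
      la <- left_align_indel(tseq, r$t_start, r$ref_seq)
      len <- nchar(la$seq)
      qf <- q_to_fwd(block, r$q_start, r$q_start)
      rows[[i]] <- data.frame(v_class = "short_del", t_seq = block$t_seq,
                              t_start = la$pos, t_end = la$pos + len,
                              q_seq = block$q_seq, q_start = qf[1, 1],
                              q_end = qf[1, 2], ref_allele = la$seq,
                              alt_allele = "", length = len,
                              flank_ok = TRUE, gap_free = TRUE,
                              id = NA_character_)
    } else {                           # insertion in the accession
      la <- left_align_indel(tseq, r$t_start, r$alt_seq)
      len <- nchar(la$seq)
      qf <- q_to_fwd(block, r$q_start, r$q_end)
      rows[[i]] <- data.frame(v_class = "short_ins", t_seq = block$t_seq,
                              t_start = la$pos, t_end = la$pos,
                              q_seq = block$q_seq, q_start = qf[1, 1],
                              q_end = qf[1, 2], ref_allele = "",
                              alt_allele = la$seq, length = len,
                              flank_ok = TRUE, gap_free = TRUE,
                              id = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
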