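#' Lift reference gene models onto an accession genome
#'
#' Projects gene models through a truth set: genes untouched by
#' length-changing variants shift by the cumulative indel offset, genes
#' hit by a deletion, translocation or overlapping indel are dropped,
#' genes fully inside a tandem-duplication source gain one extra copy per
#' planted copy, and gene models embedded in novel insertions are added at
#' their accession position.  SNPs inside genes leave the model in place
#' (the protein sequence changes, the coordinates do not).
#'
#' @param genes Reference `pg_genes`.
#' @param truth Truth set from [mutate_genome()] (after application, i.e.
#'   with `q_start`/`q_end` filled).
#' @return A `pg_genes` in accession coordinates.
#' @export
lift_features <- function(genes, truth) {
  gtab <- genes$genes
  ctab <- genes$cds
  if (nrow(truth) == 0) return(genes)

  # length-changing edits on the reference, in reference order
  ed <- list()
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    if (r$class == "SNP") next
    if (r$class == "translocation") {
      ed[[length(ed) + 1L]] <- data.frame(start = r$t_start, end = r$t_end,
                                          ins = 0L)
      ed[[length(ed) + 1L]] <- data.frame(start = r$dest, end = r$dest,
                                          ins = nchar(r$seq_ins))
    } else if (r$class == "tandem_dup") {
      ed[[length(ed) + 1L]] <- data.frame(start = r$t_end, end = r$t_end,
                                          ins = nchar(r$seq_ins))
    } else {
      ed[[length(ed) + 1L]] <- data.frame(start = r$t_start, end = r$t_end,
                                          ins = nchar(r$seq_ins))
    }
  }
  ed <- if (length(ed)) do.call(rbind, ed) else
    data.frame(start = integer(0), end = integer(0), ins = integer(0))
  ed <- ed[order(ed$start), , drop = FALSE]
  delta <- cumsum(ed$ins - (ed$end - ed$start))
  shift_at <- function(p) {
    i <- findInterval(p, ed$end)
    ifelse(i == 0, 0L, delta[pmax(i, 1L)])
  }

  changed <- ed[ed$end > ed$start | ed$ins > 0, , drop = FALSE]
  hit <- iv_overlaps_any(gtab$start, gtab$end, changed)
  keep <- gtab[!hit, , drop = FALSE]
  off <- shift_at(keep$start)
  out_g <- keep
  out_g$start <- keep$start + off
  out_g$end <- keep$end + off
  out_c <- ctab[ctab$gene_id %in% keep$gene_id, , drop = FALSE]
  coff <- off[match(out_c$gene_id, keep$gene_id)]
  out_c$start <- out_c$start + coff
  out_c$end <- out_c$end + coff

  glist <- list(out_g); clist <- list(out_c)

  # extra copies of genes inside tandem-duplication sources
  dups <- truth[truth$class == "tandem_dup", , drop = FALSE]
  for (i in seq_len(nrow(dups))) {
    d <- dups[i, ]
    inside <- gtab$start >= d$src_start & gtab$end <= d$src_end
    if (!any(inside)) next
    len <- d$src_end - d$src_start
    base_q <- d$q_start  # accession position where extra copies begin
    for (cp in seq_len(d$copies - 1L)) {
      g2 <- gtab[inside, , drop = FALSE]
      rel <- g2$start - d$src_start
      g2$gene_id <- paste0(g2$gene_id, "_dup", cp)
      g2$start <- base_q + (cp - 1L) * len + rel
      g2$end <- g2$start + (gtab$end - gtab$start)[inside]
      c2 <- ctab[ctab$gene_id %in% gtab$gene_id[inside], , drop = FALSE]
      src_off <- (base_q + (cp - 1L) * len) - d$src_start
      c2$start <- c2$start + src_off
      c2$end <- c2$end + src_off
      c2$gene_id <- paste0(c2$gene_id, "_dup", cp)
      glist[[length(glist) + 1L]] <- g2
      clist[[length(clist) + 1L]] <- c2
    }
  }

  # genes embedded in novel insertions
  ng <- attr(truth, "novel_genes")
  if (!is.null(ng)) {
    for (item in ng) {
      r <- truth[truth$id == item$id, ]
      if (nrow(r) != 1L || nrow(item$genes$genes) == 0) next
      g2 <- item$genes$genes
      c2 <- item$genes$cds
      g2$seq_name <- r$t_seq
      g2$gene_id <- paste0(r$id, "_", g2$gene_id)
      c2$gene_id <- paste0(r$id, "_", c2$gene_id)
      g2$start <- g2$start + r$q_start; g2$end <- g2$end + r$q_start
      c2$start <- c2$start + r$q_start; c2$end <- c2$end + r$q_start
      glist[[length(glist) + 1L]] <- g2
      clist[[length(clist) + 1L]] <- c2
    }
  }

  g <- do.call(rbind, glist); cc <- do.call(rbind, clist)
  g <- g[order(g$start), , drop = FALSE]
  cc <- cc[order(cc$start), , drop = FALSE]
  as_pg_genes(g, cc)
}

#' Translate gene models to protein sequences
#'
#' Extracts and splices CDS intervals (strand-aware), translates with the
#' standard genetic code and strips the terminal stop.
#'
#' @param gn A `pg_genome`.
#' @param genes A `pg_genes` on that genome.
#' @return Named character vector of amino-acid sequences.
#' @export
translate_genes <- function(gn, genes) {
  gtab <- genes$genes
  out <- character(nrow(gtab))
  for (i in seq_len(nrow(gtab))) {
    g <- gtab[i, ]
    cds <- genes$cds[genes$cds$gene_id == g$gene_id, , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    seq <- paste(vapply(seq_len(nrow(cds)), function(j)
      subseq0(gn$seq[[g$seq_name]], cds$start[j], cds$end[j]), ""),
      collapse = "")
    if (g$strand == "-") seq <- revcomp(seq)
    n <- nchar(seq) - nchar(seq) %% 3L
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(seq, 1L, n)), no.init.codon = TRUE))
    out[i] <- sub("\\*$", "", aa)
  }
  setNames(out, gtab$gene_id)
}
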