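#' Derive an accession genome by planting variants
#'
#' Plants SNPs, short indels (1--49 bp) and large SVs (deletions,
#' insertions, tandem duplications, translocations, novel insertions and
#' optional copy losses over repeat copies) at loci sampled uniformly
#' outside already-used intervals.  Planted variants never overlap one
#' another on the reference, so the truth set is an exact oracle:
#' [apply_truth()] reproduces the accession genome byte-identically.
#'
#' The truth set is a data.frame with one row per planted variant:
#' `id, class, t_start, t_end` (reference interval; insertions have
#' `t_start == t_end`), `seq_del`/`seq_ins` (literal alleles), `src_start,
#' src_end` (source locus of duplications/translocations/copy losses),
#' `dest` (translocation destination point), `copies` and, after
#' application, `q_start, q_end` in accession coordinates.
#'
#' @param ref Gap-free reference `pg_genome` (single sequence).
#' @param config A [sim_config()].
#' @param accession_id Label of the accession (also seeds its RNG stream).
#' @param genes Optional reference `pg_genes`; required for `copy_loss`
#'   planting (which deletes one TE copy).
#' @return `list(genome = pg_genome, truth = data.frame)`.
#' @export
mutate_genome <- function(ref, config, accession_id, genes = NULL) {
  stopifnot(inherits(ref, "pg_genome"), length(ref$seq) == 1L)
  if (any(vapply(ref$gaps, nrow, 0L) > 0))
    stop("mutate_genome requires a gap-free reference")
  withr::local_seed(derive_seed(config$seed, accession_id, "mutate"))
  seqname <- names(ref$seq)[1]
  refseq <- ref$seq[[1]]
  L <- nchar(refseq)

  occupied <- IRanges::IRanges()
  margin <- 10L
  take <- function(start, end) {
    cand <- iv_to_ir(start, pmax(end, start + 1L))
    if (length(occupied) > 0 && any(IRanges::overlapsAny(cand + margin, occupied)))
      return(FALSE)
    occupied <<- c(occupied, cand)
    TRUE
  }
  pick_interval <- function(len, class) {
    for (i in 1:2000) {
      s <- sample.int(L - len - 1L, 1L)
      if (take(s, s + len)) return(s)
    }
    stop("unplaceable SV class: ", class)
  }
  draw_len <- function(class) {
    rng <- config$sv_lengths[[class]]
    round(exp(runif(1, log(rng[1]), log(rng[2]))))
  }

  rec <- list()
  novel_genes <- list()
  push <- function(class, t_start, t_end, seq_del = "", seq_ins = "",
                   src_start = NA_integer_, src_end = NA_integer_,
                   dest = NA_integer_, copies = NA_integer_) {
    rec[[length(rec) + 1L]] <<- data.frame(
      id = NA_character_, class = class, t_start = t_start, t_end = t_end,
      seq_del = seq_del, seq_ins = seq_ins, src_start = src_start,
      src_end = src_end, dest = dest, copies = copies)
  }

  # shared dispensable pool: fixed insertion points and sequences drawn
  # from one common stream, per-accession carriage from the accession's
  # own stream -- carriers of a segment share it identically
  disp <- config$dispensable %||% list(n_segments = 0L)
  if ((disp$n_segments %||% 0L) > 0L) {
    pool <- withr::with_seed(
      derive_seed(config$seed, "dispensable_pool"), {
        n <- disp$n_segments
        lens <- round(exp(runif(n, log(disp$length[1]),
                                log(disp$length[2]))))
        pos <- sort(sample.int(L - 2L, n))
        keep <- c(TRUE, diff(pos) > 100L)
        list(pos = pos[keep], seqs = vapply(lens[keep], random_dna,
                                            "", gc = config$novel_gc))
      })
    carry <- withr::with_seed(
      derive_seed(config$seed, "dispensable", accession_id),
      runif(length(pool$pos)) < disp$presence_prob)
    for (j in which(carry)) {
      if (take(pool$pos[j], pool$pos[j] + 1L))
        push("novel_ins", pool$pos[j], pool$pos[j],
             seq_ins = pool$seqs[j])
    }
  }

  sv <- config$sv_counts
  for (i in seq_len(sv$large_del %||% 0L)) {
    len <- draw_len("large_del"); s <- pick_interval(len, "large_del")
    push("large_del", s, s + len, seq_del = subseq0(refseq, s, s + len))
  }
  for (i in seq_len(sv$large_ins %||% 0L)) {
    len <- draw_len("large_ins"); s <- pick_interval(1L, "large_ins")
    push("large_ins", s, s, seq_ins = random_dna(len, config$novel_gc))
  }
  for (i in seq_len(sv$novel_ins %||% 0L)) {
    len <- draw_len("novel_ins"); s <- pick_interval(1L, "novel_ins")
    ins <- random_dna(len, config$novel_gc)
    ng <- NULL
    if (config$novel_genes_per_ins > 0 && len >= 3000) {
      ng <- embed_genes(ins, config$novel_genes_per_ins, config$gene_model)
      ins <- ng$seq
    }
    push("novel_ins", s, s, seq_ins = ins)
    if (!is.null(ng) && nrow(ng$genes$genes) > 0)
      novel_genes[[length(novel_genes) + 1L]] <-
        list(idx = length(rec), genes = ng$genes)
  }
  for (i in seq_len(sv$tandem_dup %||% 0L)) {
    len <- draw_len("tandem_dup"); s <- pick_interval(len, "tandem_dup")
    copies <- sample(config$dup_copies[1]:config$dup_copies[2], 1L)
    seg <- subseq0(refseq, s, s + len)
    push("tandem_dup", s, s + len,
         seq_ins = strrep(seg, copies - 1L),
         src_start = s, src_end = s + len, copies = copies)
  }
  for (i in seq_len(sv$translocation %||% 0L)) {
    len <- draw_len("translocation"); s <- pick_interval(len, "translocation")
    seg <- subseq0(refseq, s, s + len)
    d <- NA_integer_
    for (j in 1:2000) {
      cand <- sample.int(L - 2L, 1L)
      if (abs(cand - s) > 5L * len + 20000L && take(cand, cand + 1L)) {
        d <- cand; break
      }
    }
    if (is.na(d)) stop("unplaceable SV class: translocation")
    push("translocation", s, s + len, seq_del = seg, seq_ins = seg,
         src_start = s, src_end = s + len, dest = d)
  }
  n_cl <- sv$copy_loss %||% 0L
  if (n_cl > 0) {
    if (is.null(genes)) stop("copy_loss planting requires reference genes")
    te <- genes$genes[genes$genes$is_te, ]
    te <- te[sample.int(nrow(te)), ]
    placed <- 0L
    for (r in seq_len(nrow(te))) {
      if (placed >= n_cl) break
      s <- te$start[r]; e <- te$end[r]
      if (take(s, e)) {
        push("copy_loss", s, e, seq_del = subseq0(refseq, s, e),
             src_start = s, src_end = e)
        placed <- placed + 1L
      }
    }
    if (placed < n_cl) stop("unplaceable SV class: copy_loss")
  }

  # short indels (batched placement: sample, filter overlaps, then commit)
  n_ind <- rbinom(1L, L, config$short_indel_rate)
  if (n_ind > 0) {
    pos <- sample.int(L - 60L, min(n_ind * 2L, L - 60L))
    len <- pmin(rgeom(length(pos), config$indel_geom_p) + 1L, 49L)
    is_del <- runif(length(pos)) < 0.5
    iend <- ifelse(is_del, pos + len, pos + 1L)
    ok <- !iv_overlaps_any(pos - margin, iend + margin,
                           if (length(occupied)) ir_to_iv(occupied) else NULL)
    pos <- pos[ok]; len <- len[ok]; is_del <- is_del[ok]; iend <- iend[ok]
    o <- order(pos)
    pos <- pos[o]; len <- len[o]; is_del <- is_del[o]; iend <- iend[o]
    keep <- logical(length(pos)); prev_end <- -margin - 1L
    for (i in seq_along(pos)) {
      if (pos[i] > prev_end + margin) { keep[i] <- TRUE; prev_end <- iend[i] }
    }
    sel <- which(keep)[seq_len(min(n_ind, sum(keep)))]
    for (i in sel) {
      if (is_del[i])
        push("short_del", pos[i], pos[i] + len[i],
             seq_del = subseq0(refseq, pos[i], pos[i] + len[i]))
      else
        push("short_ins", pos[i], pos[i],
             seq_ins = random_dna(len[i], config$novel_gc))
    }
    if (length(sel) > 0)
      occupied <- IRanges::reduce(c(occupied, iv_to_ir(pos[sel], iend[sel])))
  }

  # SNPs (vectorised: the dominant class by count)
  snp_df <- NULL
  n_snp <- rbinom(1L, L, config$snp_rate)
  if (n_snp > 0) {
    cand <- sample.int(L, min(L, ceiling(n_snp * 1.5) + 100L)) - 1L
    free <- !iv_overlaps_any(cand, cand + 1L,
                             if (length(occupied)) ir_to_iv(occupied) else NULL)
    cand <- head(cand[free], n_snp)
    bases <- c("A", "C", "G", "T")
    rb <- substring(refseq, cand + 1L, cand + 1L)
    ok <- rb %in% bases
    cand <- cand[ok]; rb <- rb[ok]
    # alt = ref shifted by 1..3 in base order, never equal to ref
    alt <- bases[(match(rb, bases) - 1L +
                    sample.int(3L, length(rb), replace = TRUE)) %% 4L + 1L]
    if (length(cand) > 0)
      snp_df <- data.frame(id = NA_character_, class = "SNP",
                           t_start = cand, t_end = cand + 1L,
                           seq_del = rb, seq_ins = alt,
                           src_start = NA_integer_, src_end = NA_integer_,
                           dest = NA_integer_, copies = NA_integer_)
  }

  truth <- do.call(rbind, c(rec, list(snp_df)))
  if (is.null(truth) || nrow(truth) == 0) {
    truth <- data.frame(id = character(0), class = character(0),
                        t_start = integer(0), t_end = integer(0),
                        seq_del = character(0), seq_ins = character(0),
                        src_start = integer(0), src_end = integer(0),
                        dest = integer(0), copies = integer(0),
                        t_seq = character(0))
    attr(truth, "accession") <- accession_id
    res <- apply_truth_full(ref, truth)
    return(list(genome = res$genome, truth = res$truth))
  }
  ord <- order(truth$t_start, truth$t_end)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  truth$id <- sprintf("%s_v%05d", accession_id, seq_len(nrow(truth)))
  truth$t_seq <- seqname
  attr(truth, "accession") <- accession_id
  if (length(novel_genes) > 0) {
    # re-key embedded-gene records to variant ids after sorting
    idx <- vapply(novel_genes, function(x) x$idx, 0L)
    ord_ids <- truth$id[match(idx, ord)]
    for (i in seq_along(novel_genes)) novel_genes[[i]]$id <- ord_ids[i]
    attr(truth, "novel_genes") <- novel_genes
  }

  res <- apply_truth_full(ref, truth)
  list(genome = res$genome, truth = res$truth)
}

# place small gene models inside a novel-insertion sequence
embed_genes <- function(ins, n, gm) {
  len <- nchar(ins)
  fams <- setdiff(names(gm$counts), "TE")
  genes <- list(); cds <- list(); pos <- 200L
  for (i in seq_len(n)) {
    local <- make_gene_local(min(gm$mean_cds, 600L))
    if (pos + local$len + 200L > len) break
    id <- sprintf("novel_g%02d", i)
    substr(ins, pos + 1L, pos + local$len) <- local$seq
    genes[[i]] <- data.frame(gene_id = id, seq_name = NA_character_,
                             strand = local$strand, start = pos,
                             end = pos + local$len,
                             family = sample(fams, 1L), is_te = FALSE)
    cds[[i]] <- data.frame(gene_id = id, start = pos + local$cds$start,
                           end = pos + local$cds$end)
    pos <- pos + local$len + sample(300:600, 1L)
  }
  list(seq = ins,
       genes = structure(list(genes = do.call(rbind, genes) %||%
                                data.frame(),
                              cds = do.call(rbind, cds) %||% data.frame()),
                         class = "pg_genes"))
}

#' Apply a truth set to the reference
#'
#' Replays planted variants on the reference and returns the accession
#' genome; this is the round-trip oracle for the whole simulator (the
#' genome produced by [mutate_genome()] is byte-identical).  Overlapping
#' truth records are an error.
#'
#' @param ref Reference `pg_genome`.
#' @param truth Truth data.frame from [mutate_genome()].
#' @return A `pg_genome`.
#' @export
apply_truth <- function(ref, truth) {
  apply_truth_full(ref, truth)$genome
}

apply_truth_full <- function(ref, truth) {
  seqname <- names(ref$seq)[1]
  refseq <- ref$seq[[1]]
  acc <- attr(truth, "accession") %||% "accession"

  if (nrow(truth) == 0) {
    g <- genome(setNames(refseq, seqname))
    return(list(genome = g, truth = truth))
  }

  # expand records into edits (remove [start,end), insert string at start)
  is_tra <- truth$class == "translocation"
  is_dup <- truth$class == "tandem_dup"
  main <- which(!is_tra)
  ed <- data.frame(rec = main, part = "main",
                   start = ifelse(is_dup[main], truth$t_end[main],
                                  truth$t_start[main]),
                   end = ifelse(is_dup[main], truth$t_end[main],
                                truth$t_end[main]),
                   ins = truth$seq_ins[main])
  if (any(is_tra)) {
    tr <- which(is_tra)
    ed <- rbind(ed,
                data.frame(rec = tr, part = "src",
                           start = truth$t_start[tr], end = truth$t_end[tr],
                           ins = ""),
                data.frame(rec = tr, part = "dest", start = truth$dest[tr],
                           end = truth$dest[tr], ins = truth$seq_ins[tr]))
  }
  ed <- ed[order(ed$start, ed$end), , drop = FALSE]
  if (any(ed$start[-1] < ed$end[-nrow(ed)]))
    stop("overlapping truth records")

  pieces <- character(2L * nrow(ed) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(ed))) {
    pieces[2L * i - 1L] <- subseq0(refseq, prev, ed$start[i])
    pieces[2L * i] <- ed$ins[i]
    prev <- ed$end[i]
  }
  pieces[2L * nrow(ed) + 1L] <- subseq0(refseq, prev, nchar(refseq))
  out <- paste(pieces, collapse = "")

  # accession coordinates of each edit
  delta <- cumsum(nchar(ed$ins) - (ed$end - ed$start))
  q_at_start <- ed$start + c(0L, head(delta, -1L))
  truth$q_start <- NA_integer_; truth$q_end <- NA_integer_
  for (i in seq_len(nrow(ed))) {
    r <- ed$rec[i]
    qs <- q_at_start[i]
    if (ed$part[i] == "src") next  # translocation source: a pure deletion
    truth$q_start[r] <- qs
    truth$q_end[r] <- qs + nchar(ed$ins[i])
  }
  # q interval of a translocation is the destination insertion (set above)

  g <- genome(setNames(out, seqname))
  attr(truth, "accession") <- acc
  list(genome = g, truth = truth)
}
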