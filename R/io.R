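# Plain-text interchange formats.  Every writer/reader pair here
# round-trips exactly at the object level: read(write(x)) == x.
# Coordinates convert between the package's 0-based half-open convention
# and each format's native convention at this boundary only.

#' Write / read gene models as GFF3
#'
#' One `gene` feature plus `CDS` children per gene model; the family
#' label travels in a `family=` attribute and TE status in `te=`.
#'
#' @param genes A `pg_genes`.
#' @param path File path.
#' @return `read_gff3()` returns a `pg_genes`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    writeLines(sprintf(
      "%s\tpansynt\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%s;te=%d",
      r$seq_name, r$start + 1L, r$end, r$strand, r$gene_id, r$family,
      as.integer(r$is_te)), con)
    cds <- genes$cds[genes$cds$gene_id == r$gene_id, , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    for (j in seq_len(nrow(cds))) {
      writeLines(sprintf(
        "%s\tpansynt\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.cds%d;Parent=%s",
        r$seq_name, cds$start[j] + 1L, cds$end[j], r$strand, r$gene_id,
        j, r$gene_id), con)
    }
  }
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))[[1]]
    if (length(m) == 0) NA_character_ else m[3]
  }
  genes <- list(); cds <- list()
  for (x in f) {
    if (x[3] == "gene") {
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = attr_of(x[9], "ID"), seq_name = x[1], strand = x[7],
        start = as.integer(x[4]) - 1L, end = as.integer(x[5]),
        family = attr_of(x[9], "family"),
        is_te = attr_of(x[9], "te") == "1")
    } else if (x[3] == "CDS") {
      cds[[length(cds) + 1L]] <- data.frame(
        gene_id = attr_of(x[9], "Parent"),
        start = as.integer(x[4]) - 1L, end = as.integer(x[5]))
    }
  }
  g <- do.call(rbind, genes) %||%
    data.frame(gene_id = character(0), seq_name = character(0),
               strand = character(0), start = integer(0),
               end = integer(0), family = character(0),
               is_te = logical(0))
  cc <- do.call(rbind, cds) %||%
    data.frame(gene_id = character(0), start = integer(0),
               end = integer(0))
  rownames(g) <- NULL; rownames(cc) <- NULL
  structure(list(genes = g, cds = cc), class = "pg_genes")
}

#' Write / read a truth set as VCF 4.2
#'
#' SNPs and short indels are written with explicit alleles (indels
#' anchored on the preceding base per VCF convention); large classes use
#' symbolic ALTs (`<DEL>`, `<INS>`, `<DUP>`, `<TRA>`) with `END`,
#' `SVLEN` and `SVTYPE` INFO fields.  The reader reconstructs the truth
#' data.frame (literal SV alleles are carried in a `SEQ` INFO field so
#' the round trip is exact).
#'
#' @param truth Truth data.frame from [mutate_genome()].
#' @param ref Reference `pg_genome` (for anchor bases).
#' @param path File path.
#' @param sample Sample name in the header.
#' @return `read_truth_vcf()` returns the truth data.frame.
#' @export
write_truth_vcf <- function(truth, ref, path, sample = "accession") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$seq),
            nchar(ref$seq)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Planted class\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Literal allele\">",
    "##INFO=<ID=SRC,Number=2,Type=Integer,Description=\"Source interval\">",
    "##INFO=<ID=DEST,Number=1,Type=Integer,Description=\"Destination\">",
    "##INFO=<ID=COPIES,Number=1,Type=Integer,Description=\"Total copies\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample)), con)
  refseq <- ref$seq[[1]]
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    if (r$class == "SNP") {
      line <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=SNP\tGT\t1",
                      r$t_seq, r$t_start + 1L, r$id, r$seq_del, r$seq_ins)
    } else if (r$class %in% c("short_del", "short_ins")) {
      anchor <- subseq0(refseq, r$t_start - 1L, r$t_start)
      if (r$class == "short_del") {
        line <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=%s\tGT\t1",
                        r$t_seq, r$t_start, r$id,
                        paste0(anchor, r$seq_del), anchor, r$class)
      } else {
        line <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tCLASS=%s\tGT\t1",
                        r$t_seq, r$t_start, r$id, anchor,
                        paste0(anchor, r$seq_ins), r$class)
      }
    } else {
      svtype <- switch(r$class, large_del = "DEL", copy_loss = "DEL",
                       large_ins = "INS", novel_ins = "INS",
                       tandem_dup = "DUP", translocation = "TRA")
      info <- sprintf("CLASS=%s;SVTYPE=%s;END=%d;SVLEN=%d", r$class,
                      svtype, r$t_end,
                      nchar(r$seq_ins) - nchar(r$seq_del))
      seqlit <- if (nzchar(r$seq_ins)) r$seq_ins else r$seq_del
      if (nzchar(seqlit)) info <- paste0(info, ";SEQ=", seqlit)
      if (!is.na(r$src_start))
        info <- paste0(info, sprintf(";SRC=%d,%d", r$src_start, r$src_end))
      if (!is.na(r$dest)) info <- paste0(info, sprintf(";DEST=%d", r$dest))
      if (!is.na(r$copies)) info <- paste0(info, sprintf(";COPIES=%d",
                                                         r$copies))
      anchor <- subseq0(refseq, r$t_start, r$t_start + 1L)
      line <- sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\t%s\tGT\t1",
                      r$t_seq, r$t_start + 1L, r$id, anchor, svtype, info)
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_truth_vcf
#' @export
read_truth_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  rows <- list()
  info_of <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]*)"),
                                  info))[[1]]
    if (length(m) == 0) NA_character_ else m[3]
  }
  for (ln in lines) {
    x <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- x[8]
    cls <- info_of(info, "CLASS")
    pos1 <- as.integer(x[2])
    if (cls == "SNP") {
      rows[[length(rows) + 1L]] <- data.frame(
        id = x[3], class = "SNP", t_start = pos1 - 1L, t_end = pos1,
        seq_del = x[4], seq_ins = x[5], src_start = NA_integer_,
        src_end = NA_integer_, dest = NA_integer_, copies = NA_integer_,
        t_seq = x[1])
    } else if (cls %in% c("short_del", "short_ins")) {
      if (cls == "short_del") {
        del <- substr(x[4], 2L, nchar(x[4]))
        rows[[length(rows) + 1L]] <- data.frame(
          id = x[3], class = cls, t_start = pos1, t_end = pos1 +
            nchar(del), seq_del = del, seq_ins = "",
          src_start = NA_integer_, src_end = NA_integer_,
          dest = NA_integer_, copies = NA_integer_, t_seq = x[1])
      } else {
        ins <- substr(x[5], 2L, nchar(x[5]))
        rows[[length(rows) + 1L]] <- data.frame(
          id = x[3], class = cls, t_start = pos1, t_end = pos1,
          seq_del = "", seq_ins = ins, src_start = NA_integer_,
          src_end = NA_integer_, dest = NA_integer_,
          copies = NA_integer_, t_seq = x[1])
      }
    } else {
      seqlit <- info_of(info, "SEQ")
      src <- info_of(info, "SRC")
      src2 <- if (!is.na(src)) as.integer(strsplit(src, ",")[[1]]) else
        c(NA_integer_, NA_integer_)
      svlen <- as.integer(info_of(info, "SVLEN"))
      is_ins <- cls %in% c("large_ins", "novel_ins", "tandem_dup")
      seq_del <- if (cls %in% c("large_del", "copy_loss")) seqlit else
        if (cls == "translocation") seqlit else ""
      seq_ins <- if (is_ins || cls == "translocation") seqlit else ""
      if (is.na(seq_del)) seq_del <- ""
      if (is.na(seq_ins)) seq_ins <- ""
      rows[[length(rows) + 1L]] <- data.frame(
        id = x[3], class = cls, t_start = pos1 - 1L,
        t_end = as.integer(info_of(info, "END")), seq_del = seq_del,
        seq_ins = seq_ins, src_start = src2[1], src_end = src2[2],
        dest = as.integer(info_of(info, "DEST")),
        copies = as.integer(info_of(info, "COPIES")), t_seq = x[1])
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write / read chains in UCSC chain format
#'
#' Standard `chain` header lines followed by `size dt dq` alignment
#' lines.  Minus-strand chains carry `qStrand = "-"` with query
#' coordinates in the flipped frame, matching the UCSC convention.
#'
#' @param chains List of `pg_chain`.
#' @param q_lens,t_lens Named sequence lengths of query and target.
#' @param path File path.
#' @return `read_chain()` returns a list of `pg_chain`.
#' @export
write_chain <- function(chains, q_lens, t_lens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       round(ch$score), ch$t_seq, t_lens[[ch$t_seq]],
                       ch$t_start, ch$t_end, ch$q_seq,
                       q_lens[[ch$q_seq]], ch$strand, ch$q_start,
                       ch$q_end, ch$id), con)
    a <- ch$anchors
    n <- nrow(a)
    if (n > 1) {
      dt <- a$t_start[-1] - (a$t_start[-n] + a$length[-n])
      dq <- a$q_start[-1] - (a$q_start[-n] + a$length[-n])
      writeLines(c(sprintf("%d\t%d\t%d", a$length[-n], dt, dq),
                   sprintf("%d", a$length[n])), con)
    } else {
      writeLines(sprintf("%d", a$length[1]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "chain")) { i <- i + 1L; next }
    h <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    score <- as.numeric(h[2])
    t_seq <- h[3]; t_start <- as.integer(h[6])
    q_seq <- h[8]; q_len <- as.integer(h[9]); strand <- h[10]
    q_start <- as.integer(h[11]); id <- as.integer(h[13])
    rows <- list()
    tp <- t_start; qp <- q_start
    i <- i + 1L
    while (i <= length(lines) && nzchar(lines[i])) {
      parts <- as.integer(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- data.frame(q_start = qp, t_start = tp,
                                              length = parts[1])
      if (length(parts) == 3) {
        tp <- tp + parts[1] + parts[2]
        qp <- qp + parts[1] + parts[3]
      }
      i <- i + 1L
    }
    a <- do.call(rbind, rows)
    chains[[length(chains) + 1L]] <-
      new_chain(q_seq, t_seq, strand, a, score, q_len, id)
    i <- i + 1L
  }
  chains
}

#' Write / read BED intervals
#'
#' Three- or four-column BED (0-based half-open, matching the package's
#' internal convention).
#'
#' @param df data.frame with `seq`, `start`, `end` and optionally
#'   `name`.
#' @param path File path.
#' @return `read_bed()` returns the data.frame.
#' @export
write_bed <- function(df, path) {
  cols <- c("seq", "start", "end", if ("name" %in% names(df)) "name")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("seq", "start", "end", "name")[seq_len(ncol(df))]
  df
}

#' Write a multi-sample VCF of merged genotypes
#'
#' SNPs and short indels carry explicit alleles; large classes use
#' symbolic ALTs with `END/SVLEN/SVTYPE`.  Genotypes are `1` (alt), `0`
#' (ref) or `.` (missing), with an `IM` FORMAT flag marking imputed
#' reference calls.
#'
#' @param gm A `pg_genotypes`.
#' @param ref Reference `pg_genome`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_genotype_vcf <- function(gm, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  accs <- colnames(gm$geno)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$seq), nchar(ref$seq)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=IM,Number=1,Type=Integer,Description=\"Imputed\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(accs, collapse = "\t"))), con)
  refseq <- ref$seq[[1]]
  v <- gm$variants
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    gt <- gm$geno[i, ]
    im <- as.integer(gm$prov[i, ] == "imputed")
    gtf <- ifelse(gt == "alt", "1", ifelse(gt == "ref", "0", "."))
    samp <- paste(paste0(gtf, ":", im), collapse = "\t")
    if (r$v_class == "SNP") {
      line <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:IM\t%s",
                      r$t_seq, r$t_start + 1L, i, r$ref_allele,
                      r$alt_allele, samp)
    } else if (r$v_class %in% c("short_del", "short_ins")) {
      anchor <- subseq0(refseq, max(0L, r$t_start - 1L), r$t_start)
      if (anchor == "") anchor <- "N"
      ra <- paste0(anchor, r$ref_allele)
      aa <- paste0(anchor, r$alt_allele)
      line <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:IM\t%s",
                      r$t_seq, r$t_start, i, ra, aa, samp)
    } else {
      svtype <- switch(r$v_class, large_del = "DEL", copy_loss = "CNV",
                       large_ins = "INS", copy_gain = "DUP",
                       translocation = "TRA")
      anchor <- subseq0(refseq, r$t_start, r$t_start + 1L)
      svlen <- if (svtype %in% c("DEL", "CNV")) -r$length else r$length
      line <- sprintf(
        "%s\t%d\t%s\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d\tGT:IM\t%s",
        r$t_seq, r$t_start + 1L, i, anchor, svtype, svtype,
        max(r$t_end, r$t_start + 1L), svlen, samp)
    }
    writeLines(line, con)
  }
  invisible(path)
}
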