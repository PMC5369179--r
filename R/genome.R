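#' Genome container
#'
#' A genome is a set of named DNA sequences with a registry of assembly-gap
#' (N-run) intervals and optional per-scaffold provenance (used by the
#' assembly fragmentation simulator to map scaffold coordinates back to
#' their source sequence).  All coordinates are 0-based half-open.
#'
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param gaps Optional named list of `data.frame(start, end)` N-run
#'   intervals per sequence; recomputed from the sequences when `NULL`.
#' @param scaffolds Optional `data.frame(name, source, offset)` recording,
#'   for fragmented assemblies, the source sequence and 0-based offset of
#'   each scaffold (offsets are in source, i.e. ungapped, coordinates).
#' @return An object of class `pg_genome`.
#' @export
genome <- function(sequences, gaps = NULL, scaffolds = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  sequences <- toupper(sequences)
  if (is.null(gaps)) gaps <- lapply(sequences, scan_n_gaps)
  stopifnot(all(names(sequences) %in% names(gaps)))
  structure(list(seq = sequences, gaps = gaps[names(sequences)],
                 scaffolds = scaffolds),
            class = "pg_genome")
}

# maximal N-run intervals, 0-based half-open
scan_n_gaps <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' @export
print.pg_genome <- function(x, ...) {
  cat(sprintf("<pg_genome> %d sequence(s), %s bp total, contig N50 %s bp\n",
              length(x$seq), format(total_length(x), big.mark = ","),
              format(contig_n50(x), big.mark = ",")))
  invisible(x)
}

#' Total sequence length of a genome (including gap Ns)
#' @param x A `pg_genome`.
#' @return Total length in bp.
#' @export
total_length <- function(x) sum(nchar(x$seq))

#' Contig N50 of a genome
#'
#' Contigs are the runs of non-N sequence between assembly gaps.
#' @param x A `pg_genome`.
#' @return Contig N50 in bp.
#' @export
contig_n50 <- function(x) {
  lens <- unlist(lapply(names(x$seq), function(nm) {
    g <- x$gaps[[nm]]
    L <- nchar(x$seq[[nm]])
    if (nrow(g) == 0) return(L)
    bounds <- c(0L, as.vector(rbind(g$start, g$end)), L)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    (ends - starts)[ends > starts]
  }), use.names = FALSE)
  n50(lens)
}

#' Remove assembly gaps from a genome
#'
#' Drops every N-run and concatenates the flanking contigs, and (when
#' scaffold provenance is present) restores the original source sequences
#' by concatenating sibling scaffolds in order.
#' @param x A `pg_genome`.
#' @return A gap-free `pg_genome`.
#' @export
degap_genome <- function(x) {
  seqs <- vapply(x$seq, function(s) gsub("N", "", s, fixed = TRUE), "")
  if (!is.null(x$scaffolds)) {
    sc <- x$scaffolds[order(x$scaffolds$source, x$scaffolds$offset), ]
    merged <- vapply(split(sc$name, sc$source),
                     function(nms) paste(seqs[nms], collapse = ""), "")
    seqs <- merged
  }
  genome(seqs)
}

# cumulative gap bp before each position of one scaffold; used to convert
# gapped scaffold coordinates to ungapped source coordinates
degap_coord <- function(gn, seq_name, pos) {
  g <- gn$gaps[[seq_name]]
  if (is.null(g) || nrow(g) == 0) return(as.integer(pos))
  vapply(pos, function(p) {
    as.integer(p - sum(pmax(0L, pmin(g$end, p) - g$start)))
  }, integer(1))
}

#' Read / write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; writer and reader are exact inverses at
#' the object level (sequence names and bases).
#' @param x A `pg_genome` (or named character vector of sequences).
#' @param path File path.
#' @return `read_fasta()` returns a `pg_genome`.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "pg_genome")) x$seq else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  genome(setNames(as.character(ss), names(ss)))
}

# canonical pg_genes constructor: integer coordinates, clean row names
as_pg_genes <- function(genes, cds) {
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  rownames(genes) <- NULL; rownames(cds) <- NULL
  structure(list(genes = genes, cds = cds), class = "pg_genes")
}
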