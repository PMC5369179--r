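# Multi-accession merging with reference-genotype imputation.

#' Merge per-accession variant calls into a genotype matrix
#'
#' Takes the union of variant sites keyed by `(t_seq, t_start, v_class,
#' ref_allele, alt_allele)`.  For an accession with no call at a site the
#' genotype is imputed as `ref` when the coverage mask fully covers the
#' site's reference span (the synteny alignment supports the non-variant
#' state), and `missing` otherwise.  Cell provenance is `called`,
#' `imputed` or `uncallable`.  Two records with the same key but
#' conflicting query annotations within one accession raise an error.
#'
#' @param calls Named list: accession -> variant data.frame.
#' @param mask A `pg_mask` from [coverage_mask()].
#' @return `pg_genotypes`: list with `variants` (site table), `geno`
#'   (site x accession character matrix: `"ref"`, `"alt"`, `"missing"`)
#'   and `prov` (provenance matrix).
#' @export
merge_and_impute <- function(calls, mask) {
  accs <- names(calls)
  stopifnot(length(accs) > 0)
  keyed <- lapply(accs, function(a) {
    v <- calls[[a]]
    if (nrow(v) == 0) return(v)
    key <- paste(v$t_seq, v$t_start, v$v_class, v$ref_allele,
                 v$alt_allele, sep = "\r")
    v <- v[!duplicated(key), , drop = FALSE]   # identical records collapse
    key <- key[!duplicated(key)]
    key2 <- paste(v$t_seq, v$t_start, v$v_class, sep = "\r")
    if (anyDuplicated(key2)) {
      d <- key2[duplicated(key2)][1]
      stop("conflicting allele records in ", a, " at key: ",
           gsub("\r", " / ", d))
    }
    v$key <- key
    v
  })
  names(keyed) <- accs
  all <- do.call(rbind, lapply(keyed, function(v)
    if (nrow(v) == 0) NULL else v))
  if (is.null(all) || nrow(all) == 0) {
    return(structure(list(variants = empty_variants(),
                          geno = matrix(character(0), 0, length(accs),
                                        dimnames = list(NULL, accs)),
                          prov = matrix(character(0), 0, length(accs),
                                        dimnames = list(NULL, accs))),
                     class = "pg_genotypes"))
  }
  sites <- all[!duplicated(all$key), , drop = FALSE]
  sites <- sites[order(sites$t_seq, sites$t_start, sites$v_class,
                       sites$ref_allele, sites$alt_allele), , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  geno <- matrix("missing", n, length(accs), dimnames = list(NULL, accs))
  prov <- matrix("uncallable", n, length(accs), dimnames = list(NULL, accs))
  for (a in accs) {
    v <- keyed[[a]]
    hit <- if (nrow(v) > 0) match(v$key, sites$key) else integer(0)
    geno[hit, a] <- "alt"
    prov[hit, a] <- "called"
    todo <- setdiff(seq_len(n), hit)
    if (length(todo) > 0) {
      per_seq <- split(todo, sites$t_seq[todo])
      for (sq in names(per_seq)) {
        idx <- per_seq[[sq]]
        cov <- mask_covers(mask, a, sq, sites$t_start[idx],
                           pmax(sites$t_end[idx], sites$t_start[idx] + 1L))
        geno[idx[cov], a] <- "ref"
        prov[idx[cov], a] <- "imputed"
      }
    }
  }
  structure(list(variants = sites, geno = geno, prov = prov),
            class = "pg_genotypes")
}

#' @export
print.pg_genotypes <- function(x, ...) {
  cat(sprintf("<pg_genotypes> %d sites x %d accessions\n",
              nrow(x$variants), ncol(x$geno)))
  if (nrow(x$variants) > 0) print(table(x$variants$v_class))
  invisible(x)
}

#' Genome span affected by variation in one accession
#'
#' Per variant class, affected bp is the sum of `max(reference span,
#' alternate length)` over alt-genotyped variants; the union span merges
#' overlapping reference intervals (insertions count one anchor base).
#'
#' @param gm A `pg_genotypes`.
#' @param accession Accession name.
#' @param mask Optional `pg_mask`; when given, the union is also reported
#'   as a fraction of that accession's alignable (covered) bp.
#' @return List with `per_class` (named bp vector), `union_bp` and
#'   `fraction` (NA without a mask).
#' @export
affected_span <- function(gm, accession, mask = NULL) {
  v <- gm$variants
  alt <- gm$geno[, accession] == "alt"
  v <- v[alt, , drop = FALSE]
  spans <- pmax(v$t_end - v$t_start, v$length)
  per_class <- tapply(spans, v$v_class, sum)
  per_class <- setNames(as.numeric(per_class), names(per_class))
  ir <- iv_to_ir(v$t_start, pmax(v$t_end, v$t_start + 1L))
  union_bp <- 0
  if (nrow(v) > 0) {
    by_seq <- split(seq_len(nrow(v)), v$t_seq)
    union_bp <- sum(vapply(by_seq, function(idx)
      sum(IRanges::width(IRanges::reduce(ir[idx]))), 0))
  }
  fraction <- if (!is.null(mask))
    union_bp / mask_bp(mask, accession) else NA_real_
  list(per_class = per_class, union_bp = union_bp, fraction = fraction)
}
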