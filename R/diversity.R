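# Population-genetic statistics over the merged genotype matrix, SNP
# functional-effect classification, ortholog grouping and gene-family
# summaries.

#' Pairwise nucleotide diversity (theta-pi)
#'
#' Per segregating site the contribution is the number of differing
#' called pairs divided by the number of called pairs (pairwise deletion
#' of missing genotypes); theta-pi is the sum of contributions divided by
#' the callable length L (positions covered in at least two accessions).
#' SNP sites count at their position; indel and SV events count as one
#' biallelic unit at their start position.
#'
#' @param gm A `pg_genotypes`.
#' @param mask A `pg_mask` (defines callable length).
#' @param region Optional `list(seq, start, end)` (0-based half-open);
#'   default: the whole reference.
#' @param v_class `"SNP"`, `"indel"` or `"SV"`.
#' @return List of class `pg_divstats`: `theta_pi, theta_w, S, L, n, a_n`
#'   (all `NA` when L is 0).
#' @export
theta_pi <- function(gm, mask, region = NULL, v_class = "SNP") {
  accs <- colnames(gm$geno)
  n <- length(accs)
  stopifnot(n >= 2)
  classes <- switch(v_class,
                    SNP = "SNP",
                    indel = c("short_ins", "short_del"),
                    SV = c("large_ins", "large_del", "copy_gain",
                           "copy_loss", "translocation"),
                    v_class)
  v <- gm$variants
  sel <- v$v_class %in% classes
  if (!is.null(region)) {
    sel <- sel & v$t_seq == region$seq & v$t_start >= region$start &
      v$t_start < region$end
  }
  L <- callable_bp(mask, region, min_acc = 2L)
  if (L == 0) {
    return(structure(list(theta_pi = NA_real_, theta_w = NA_real_,
                          S = NA_integer_, L = 0, n = n,
                          a_n = sum(1 / seq_len(n - 1))),
                     class = "pg_divstats"))
  }
  g <- gm$geno[sel, , drop = FALSE]
  n_alt <- rowSums(g == "alt")
  n_ref <- rowSums(g == "ref")
  m <- n_alt + n_ref
  contrib <- ifelse(m >= 2, n_alt * n_ref / (m * (m - 1) / 2), 0)
  S <- sum(n_alt > 0 & n_ref > 0 & m >= 2)
  tp <- sum(contrib) / L
  tw <- theta_w(S, n, L)$theta_w
  structure(list(theta_pi = tp, theta_w = tw, S = S, L = L, n = n,
                 a_n = sum(1 / seq_len(n - 1))),
            class = "pg_divstats")
}

#' Watterson's estimator (theta-w)
#'
#' `S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param S Number of segregating sites.
#' @param n Number of accessions (>= 2).
#' @param L Callable length in bp (> 0).
#' @return A `pg_divstats` list (theta_pi `NA`).
#' @export
theta_w <- function(S, n, L) {
  if (n < 2) stop("theta_w requires n >= 2")
  if (L <= 0) stop("theta_w requires L > 0")
  a_n <- sum(1 / seq_len(n - 1))
  structure(list(theta_pi = NA_real_, theta_w = S / (a_n * L), S = S,
                 L = L, n = n, a_n = a_n),
            class = "pg_divstats")
}

#' @export
print.pg_divstats <- function(x, ...) {
  cat(sprintf("<pg_divstats> theta_pi = %s, theta_w = %s (S = %s, L = %s, n = %d)\n",
              format(x$theta_pi, digits = 4), format(x$theta_w, digits = 4),
              x$S, x$L, x$n))
  invisible(x)
}

# callable bp: positions covered in >= min_acc accessions within region
callable_bp <- function(mask, region = NULL, min_acc = 2L) {
  track <- min_cover_track(mask, min_acc)
  if (is.null(region)) return(sum(vapply(track, function(x)
    sum(IRanges::width(x)), 0)))
  ir <- track[[region$seq]]
  if (is.null(ir)) return(0)
  sum(IRanges::width(IRanges::intersect(
    ir, iv_to_ir(region$start, region$end))))
}

#' Sliding-window diversity and density track
#'
#' Tiles the reference into fixed windows and reports, per window: gene,
#' TE and per-family gene counts (by gene start), theta-pi for SNPs,
#' short indels and SVs, and synteny coverage (fraction of the window
#' covered in at least `min_acc_cov` accessions).  Windows whose coverage
#' falls below `min_cov` report `NA` diversity (the missing cells of the
#' genome-landscape heatmaps).
#'
#' @param gm A `pg_genotypes`.
#' @param genes Reference `pg_genes`.
#' @param mask A `pg_mask`.
#' @param ref Reference `pg_genome`.
#' @param window Window size in bp (1 Mbp in the full-genome analysis;
#'   scale down for small simulations).
#' @param min_cov Coverage fraction below which diversity is masked.
#' @param min_acc_cov Accession count defining the coverage track.
#' @return data.frame with one row per window.
#' @export
window_track <- function(gm, genes, mask, ref, window = 1e6,
                         min_cov = 0.5, min_acc_cov = 2L) {
  out <- list()
  track <- min_cover_track(mask, min_acc_cov)
  fams <- setdiff(unique(genes$genes$family), "TE")
  for (sq in names(ref$seq)) {
    L <- nchar(ref$seq[[sq]])
    starts <- seq(0L, L - 1L, by = window)
    for (s0 in starts) {
      s1 <- min(L, s0 + window)
      reg <- list(seq = sq, start = s0, end = s1)
      g <- genes$genes[genes$genes$seq_name == sq &
                         genes$genes$start >= s0 &
                         genes$genes$start < s1, , drop = FALSE]
      cov_ir <- track[[sq]] %||% IRanges::IRanges()
      cov_bp <- sum(IRanges::width(IRanges::intersect(
        cov_ir, iv_to_ir(s0, s1))))
      covered <- cov_bp / (s1 - s0)
      row <- data.frame(seq = sq, start = s0, end = s1,
                        n_genes = sum(!g$is_te), n_te = sum(g$is_te),
                        coverage = covered)
      for (fam in fams)
        row[[paste0("n_", fam)]] <- sum(g$family == fam & !g$is_te)
      if (covered >= min_cov) {
        row$pi_snp <- theta_pi(gm, mask, reg, "SNP")$theta_pi
        row$pi_indel <- theta_pi(gm, mask, reg, "indel")$theta_pi
        row$pi_sv <- theta_pi(gm, mask, reg, "SV")$theta_pi
      } else {
        row$pi_snp <- NA_real_; row$pi_indel <- NA_real_
        row$pi_sv <- NA_real_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the functional effect of a SNP on a gene model
#'
#' Codon-level classification under the standard genetic code,
#' strand-aware.  A SNP within 2 bp of an intron boundary (inside the
#' intron) is a splice-site change.  Large-effect classes are premature
#' stop (`stop_gained`), `stop_lost`, `start_lost` and `splice_site`.
#'
#' @param snp List or one-row data.frame with `t_start`, `ref_allele`
#'   (`ref`), `alt_allele` (`alt`).
#' @param gene One row of a `pg_genes$genes` table.
#' @param cds CDS rows (`start`, `end`) of that gene, sorted by start.
#' @param refseq Reference sequence string of the gene's chromosome.
#' @return List of class `snp_effect`: `effect`, `large_effect`,
#'   `ref_aa`, `alt_aa`, `codon_index`.
#' @export
classify_snp_effect <- function(snp, gene, cds, refseq) {
  pos <- snp$t_start %||% snp$pos
  ref <- snp$ref_allele %||% snp$ref
  alt <- snp$alt_allele %||% snp$alt
  cds <- cds[order(cds$start), , drop = FALSE]
  if (sum(cds$end - cds$start) %% 3L != 0L)
    stop("malformed CDS: total length not divisible by 3")
  eff <- function(effect, large = FALSE, ref_aa = NA, alt_aa = NA, ci = NA)
    structure(list(effect = effect, large_effect = large, ref_aa = ref_aa,
                   alt_aa = alt_aa, codon_index = ci),
              class = "snp_effect")
  if (pos < gene$start || pos >= gene$end) return(eff("intergenic"))
  in_cds <- which(pos >= cds$start & pos < cds$end)
  if (length(in_cds) == 0) {
    # intronic; splice site when within 2 bp of an intron boundary
    for (j in seq_len(nrow(cds) - 1L)) {
      i0 <- cds$end[j]; i1 <- cds$start[j + 1L]  # intron [i0, i1)
      if (pos >= i0 && pos < i1) {
        if (pos < i0 + 2L || pos >= i1 - 2L)
          return(eff("splice_site", TRUE))
        return(eff("intronic"))
      }
    }
    return(eff("intronic"))
  }
  # position within the spliced CDS, in transcription order
  plus_off <- sum(pmax(0L, pmin(cds$end, pos) - cds$start)) +
    (pos - cds$start[in_cds]) - (pmin(cds$end[in_cds], pos) - cds$start[in_cds])
  cds_len <- sum(cds$end - cds$start)
  cds_pos <- if (gene$strand == "+") plus_off else cds_len - 1L - plus_off
  codon_i <- cds_pos %/% 3L
  # assemble the codon from the spliced sequence
  spliced <- paste(vapply(seq_len(nrow(cds)), function(j)
    subseq0(refseq, cds$start[j], cds$end[j]), ""), collapse = "")
  if (gene$strand == "-") spliced <- revcomp(spliced)
  codon <- substr(spliced, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- cds_pos %% 3L
  base_ref <- if (gene$strand == "+") ref else revcomp(ref)
  base_alt <- if (gene$strand == "+") alt else revcomp(alt)
  if (substr(codon, within + 1L, within + 1L) != base_ref)
    stop("reference allele does not match the CDS sequence")
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- base_alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon]); alt_aa <- unname(code[alt_codon])
  if (codon_i == 0L && codon == "ATG" && alt_codon != "ATG")
    return(eff("start_lost", TRUE, ref_aa, alt_aa, codon_i))
  if (ref_aa != "*" && alt_aa == "*")
    return(eff("stop_gained", TRUE, ref_aa, alt_aa, codon_i))
  if (ref_aa == "*" && alt_aa != "*")
    return(eff("stop_lost", TRUE, ref_aa, alt_aa, codon_i))
  if (ref_aa == alt_aa)
    return(eff("synonymous", FALSE, ref_aa, alt_aa, codon_i))
  eff("missense", FALSE, ref_aa, alt_aa, codon_i)
}

#' Filter genes by CDS coverage across accessions
#'
#' Keeps genes whose CDS is covered at `>= min_frac` in at least
#' `min_acc` accessions.
#'
#' @param genes Reference `pg_genes`.
#' @param mask A `pg_mask`.
#' @param min_frac Minimum covered CDS fraction per accession.
#' @param min_acc Minimum number of accessions meeting it.
#' @return Character vector of retained gene ids.
#' @export
gene_coverage_filter <- function(genes, mask, min_frac = 0.8,
                                 min_acc = 10L) {
  accs <- names(mask$acc)
  keep <- character(0)
  for (gid in unique(genes$genes$gene_id)) {
    cds <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    sq <- genes$genes$seq_name[genes$genes$gene_id == gid][1]
    tot <- sum(cds$end - cds$start)
    n_ok <- 0L
    for (a in accs) {
      ir <- mask$acc[[a]][[sq]]
      if (is.null(ir)) next
      cov <- sum(IRanges::width(IRanges::intersect(
        ir, iv_to_ir(cds$start, cds$end))))
      if (cov >= min_frac * tot) n_ok <- n_ok + 1L
    }
    if (n_ok >= min_acc) keep <- c(keep, gid)
  }
  keep
}

#' Syntenic one-to-one ortholog groups
#'
#' Pairs each reference gene with at most one gene per accession: the
#' accession gene whose CDS overlaps the synteny-mapped reference CDS
#' interval best, requiring at least `min_frac` of the reference CDS to
#' be covered by reciprocal-best synteny in that accession.  Groups
#' present (reference included) in fewer than `min_acc` accessions are
#' dropped.
#'
#' @param ref_genes Reference `pg_genes`.
#' @param acc_genes Named list: accession -> `pg_genes` in accession
#'   coordinates.
#' @param synteny Named list: accession -> `pg_synteny`.
#' @param mask A `pg_mask`.
#' @param min_frac Minimum mapped CDS fraction.
#' @param min_acc Minimum accessions per retained group (reference
#'   counted).
#' @return List of `ortholog_group` lists: `id`, `members` (data.frame
#'   `accession, gene_id`), `kind = "syntenic_1to1"`, `n_accessions`.
#' @export
syntenic_ortholog_groups <- function(ref_genes, acc_genes, synteny, mask,
                                     min_frac = 0.5, min_acc = 10L) {
  accs <- names(acc_genes)
  groups <- list()
  gtab <- ref_genes$genes[!ref_genes$genes$is_te, , drop = FALSE]
  for (gi in seq_len(nrow(gtab))) {
    g <- gtab[gi, ]
    cds <- ref_genes$cds[ref_genes$cds$gene_id == g$gene_id, , drop = FALSE]
    tot <- sum(cds$end - cds$start)
    members <- data.frame(accession = "reference", gene_id = g$gene_id)
    for (a in accs) {
      cov <- sum(IRanges::width(IRanges::intersect(
        mask$acc[[a]][[g$seq_name]] %||% IRanges::IRanges(),
        iv_to_ir(cds$start, cds$end))))
      if (cov < min_frac * tot) next
      qiv <- lift_to_query(synteny[[a]]$blocks, g$seq_name, g$start, g$end)
      if (is.null(qiv)) next
      ag <- acc_genes[[a]]$genes
      ag <- ag[ag$seq_name == qiv$seq | is.na(ag$seq_name), , drop = FALSE]
      if (nrow(ag) == 0) next
      ov <- pmin(ag$end, qiv$end) - pmax(ag$start, qiv$start)
      besti <- which.max(ov)
      if (length(besti) == 0 || ov[besti] < min_frac * (g$end - g$start))
        next
      members <- rbind(members,
                       data.frame(accession = a,
                                  gene_id = ag$gene_id[besti]))
    }
    if (nrow(members) >= min_acc) {
      groups[[length(groups) + 1L]] <- list(
        id = g$gene_id, members = members, kind = "syntenic_1to1",
        family = g$family, n_accessions = nrow(members))
    }
  }
  groups
}

# map a reference interval into accession (forward scaffold) coordinates
# through the clean blocks; returns NULL when unmapped
lift_to_query <- function(blocks, t_seq, start, end) {
  for (b in blocks) {
    if (b$t_seq != t_seq || b$t_start > start || b$t_end < end) next
    s <- b$segments
    keep <- s$type %in% c("match", "mismatch")
    rows <- which(keep & s$t_end > start & s$t_start < end)
    if (length(rows) == 0) next
    q0 <- s$q_start[rows[1]] + max(0L, start - s$t_start[rows[1]])
    last <- rows[length(rows)]
    q1 <- s$q_end[last] - max(0L, s$t_end[last] - end)
    qf <- q_to_fwd(b, min(q0, q1), max(q0, q1))
    return(list(seq = b$q_seq, start = qf[1, 1], end = qf[1, 2]))
  }
  NULL
}

#' Mean pairwise protein distance of an ortholog group
#'
#' Aligns every pair globally (identity scoring, gap open -10, extend
#' -0.5); the pair distance is 1 minus the fraction of identical aligned
#' columns, and MPPD is the mean over pairs.
#'
#' @param proteins Character vector of at least two amino-acid
#'   sequences.
#' @return List of class `group_stats` with `mppd` and `n_pairs`.
#' @export
mppd <- function(proteins) {
  if (length(proteins) < 2) stop("mppd requires at least two proteins")
  pairs <- combn(length(proteins), 2)
  d <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    d[j] <- protein_distance(proteins[pairs[1, j]], proteins[pairs[2, j]])
  }
  structure(list(mppd = mean(d), n_pairs = ncol(pairs), distances = d),
            class = "group_stats")
}

protein_distance <- function(a, b) {
  aln <- cpp_nw_align(toupper(a), toupper(b), 1, 0, 10, 0.5)
  p <- strsplit(aln[1], "")[[1]]; s <- strsplit(aln[2], "")[[1]]
  1 - sum(p == s & p != "-") / length(p)
}

#' Similarity-clustered ortholog groups
#'
#' Single-linkage clustering of (non-TE) proteins: two proteins join
#' when a local alignment reaches `min_ident` identity over at least
#' `min_cover` of the longer protein.  Candidate pairs are pre-screened
#' by shared 6-mers.
#'
#' @param proteins data.frame with `accession`, `gene_id`, `family`,
#'   `sequence`.
#' @param accessions All accession names (for copy-count vectors).
#' @param min_ident,min_cover Clustering thresholds.
#' @return List of `ortholog_group`: `id`, `members`, `kind =
#'   "similarity_cluster"`, `family` (majority), `copy_counts` (named
#'   integer vector over accessions), `sharing_bin`.
#' @export
cluster_ortholog_groups <- function(proteins, accessions = NULL,
                                    min_ident = 0.7, min_cover = 0.5) {
  n <- nrow(proteins)
  accessions <- accessions %||% unique(proteins$accession)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    km <- lapply(proteins$sequence, function(s) {
      if (nchar(s) < 6L) return(character(0))
      st <- seq(1L, nchar(s) - 5L)
      unique(substring(s, st, st + 5L))
    })
    tab <- new.env(hash = TRUE)
    for (i in seq_len(n)) for (k in km[[i]])
      assign(k, c(get0(k, envir = tab, ifnotfound = integer(0)), i),
             envir = tab)
    cand <- new.env(hash = TRUE)
    for (k in ls(tab)) {
      ids <- unique(get(k, envir = tab))
      if (length(ids) > 1 && length(ids) <= 30)
        for (a in seq_along(ids)[-length(ids)])
          for (b2 in (a + 1):length(ids)) {
            key <- paste(ids[a], ids[b2])
            v <- get0(key, envir = cand, ifnotfound = 0L)
            assign(key, v + 1L, envir = cand)
          }
    }
    for (key in ls(cand)) {
      if (get(key, envir = cand) < 3L) next   # require several shared 6-mers
      ij <- as.integer(strsplit(key, " ")[[1]])
      if (find(ij[1]) == find(ij[2])) next
      if (protein_pair_linked(proteins$sequence[ij[1]],
                              proteins$sequence[ij[2]],
                              min_ident, min_cover)) {
        ri <- find(ij[1]); rj <- find(ij[2])
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, unique(roots))
  groups <- list()
  for (g in unique(ids)) {
    idx <- which(ids == g)
    members <- proteins[idx, c("accession", "gene_id")]
    cc <- table(factor(proteins$accession[idx], levels = accessions))
    fam <- names(sort(table(proteins$family[idx]), decreasing = TRUE))[1]
    groups[[length(groups) + 1L]] <- list(
      id = sprintf("og%05d", g), members = members,
      kind = "similarity_cluster", family = fam,
      copy_counts = setNames(as.integer(cc), names(cc)),
      sharing_bin = sum(cc > 0))
  }
  groups
}

protein_pair_linked <- function(a, b, min_ident = 0.7, min_cover = 0.5) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- cpp_nw_align(toupper(a), toupper(b), 1, 0, 5, 0.2)
  p <- strsplit(aln[1], "")[[1]]; s <- strsplit(aln[2], "")[[1]]
  ident_cols <- sum(p == s & p != "-")
  ident_cols / nchar(b) >= min_cover * min_ident &&
    ident_cols / nchar(a) >= min_ident * min_cover &&
    ident_cols >= min_ident * min_cover * nchar(b)
}

#' Copy-number coefficient of variation of an ortholog group
#'
#' Population standard deviation (divide by n) over mean of the copy
#' counts across all accessions, zeros included for accessions without a
#' member.
#'
#' @param group An `ortholog_group` with `copy_counts`, or a numeric
#'   vector of counts.
#' @return List of class `group_stats` with `cv`, `mean`, `sd`.
#' @export
copy_number_cv <- function(group) {
  counts <- if (is.list(group)) group$copy_counts else group
  stopifnot(length(counts) > 0, sum(counts) > 0)
  m <- mean(counts)
  s <- sqrt(mean((counts - m)^2))
  structure(list(cv = s / m, mean = m, sd = s), class = "group_stats")
}

#' Per-family diversity and sharing summary
#'
#' Aggregates per-gene diversity, large-effect fractions, MPPD and
#' copy-number CV by family label, and reports each family's share of
#' accession-specific (sharing bin 1) versus core (present in all
#' accessions) ortholog groups with the resulting enrichment ratio.
#'
#' @param groups List of `ortholog_group` (similarity clusters).
#' @param gene_stats Optional data.frame `gene_id, family, theta_pi,
#'   large_effect` of per-gene statistics.
#' @param group_stats Optional data.frame `id, family, mppd, cv`.
#' @param n_accessions Number of accessions defining "core".
#' @return data.frame with one row per family label.
#' @export
family_summary <- function(groups, gene_stats = NULL, group_stats = NULL,
                           n_accessions) {
  fam <- vapply(groups, `[[`, "", "family")
  bin <- vapply(groups, `[[`, 0L, "sharing_bin")
  spec_all <- sum(bin == 1); core_all <- sum(bin == n_accessions)
  out <- list()
  for (f in sort(unique(fam))) {
    sel <- fam == f
    row <- data.frame(
      family = f, n_groups = sum(sel),
      frac_specific = mean(bin[sel] == 1),
      frac_core = mean(bin[sel] == n_accessions),
      share_of_specific = if (spec_all > 0)
        sum(sel & bin == 1) / spec_all else NA_real_,
      share_of_core = if (core_all > 0)
        sum(sel & bin == n_accessions) / core_all else NA_real_)
    row$enrichment <- if (!is.na(row$share_of_core) && row$share_of_core > 0)
      row$share_of_specific / row$share_of_core else NA_real_
    if (!is.null(gene_stats)) {
      gs <- gene_stats[gene_stats$family == f, , drop = FALSE]
      row$median_theta_pi <- if (nrow(gs)) median(gs$theta_pi, na.rm = TRUE)
        else NA_real_
      row$frac_large_effect <- if (nrow(gs)) mean(gs$large_effect)
        else NA_real_
    }
    if (!is.null(group_stats)) {
      qs <- group_stats[group_stats$family == f, , drop = FALSE]
      row$mean_mppd <- if (nrow(qs)) mean(qs$mppd, na.rm = TRUE) else NA_real_
      row$mean_cv <- if (nrow(qs)) mean(qs$cv, na.rm = TRUE) else NA_real_
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
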