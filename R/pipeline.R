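# End-to-end convenience wrappers: simulate a cohort, run the full
# synteny + variant-calling pipeline, and score calls against the truth.

#' Simulate a full accession cohort
#'
#' Reference + gene models, then per accession: planted-variant genome,
#' lifted gene models, gapped-scaffold assembly and (optionally) long
#' reads.
#'
#' @param config A [sim_config()].
#' @param reads Simulate long reads per accession?
#' @return List of class `pg_cohort`: `config`, `ref`, `genes`,
#'   `accessions` (named list with `genome`, `truth`, `genes`, `assembly`,
#'   `reads`).
#' @export
simulate_cohort <- function(config, reads = FALSE) {
  refsim <- simulate_reference(config)
  te <- refsim$genes$genes[refsim$genes$genes$is_te,
                           c("seq_name", "start", "end")]
  accs <- list()
  for (i in seq_len(config$n_accessions)) {
    a <- sprintf("acc%02d", i)
    mu <- mutate_genome(refsim$genome, config, a, genes = refsim$genes)
    accs[[a]] <- list(
      genome = mu$genome,
      truth = mu$truth,
      genes = lift_features(refsim$genes, mu$truth),
      assembly = fragment_assembly(mu$genome, config, te_intervals = te),
      reads = if (reads) simulate_long_reads(mu$genome, config) else NULL)
  }
  structure(list(config = config, ref = refsim$genome,
                 genes = refsim$genes, accessions = accs),
            class = "pg_cohort")
}

#' Run synteny + variant calling over a cohort
#'
#' Builds synteny blocks for every accession assembly against the
#' reference, derives the coverage mask, calls SNPs, short indels and
#' large SVs, and merges everything into an imputed genotype matrix.
#'
#' @param cohort A `pg_cohort` from [simulate_cohort()] (or a compatible
#'   list with `ref` and `accessions[[a]]$assembly`).
#' @param params A [synteny_params()].
#' @param quiet Suppress progress messages.
#' @return List of class `pg_results`: `synteny` (per accession), `mask`,
#'   `calls` (per accession), `genotypes`.
#' @export
run_pipeline <- function(cohort, params = synteny_params(), quiet = TRUE) {
  accs <- names(cohort$accessions)
  synteny <- list(); calls <- list()
  for (a in accs) {
    asm <- cohort$accessions[[a]]$assembly
    syn <- build_synteny(asm, cohort$ref, params, quiet = quiet)
    synteny[[a]] <- syn
    v <- rbind(
      do.call(rbind, lapply(syn$blocks, call_snps)),
      do.call(rbind, lapply(syn$blocks, call_short_indels,
                            target = cohort$ref)),
      call_svs(syn$blocks, asm, cohort$ref, params))
    rownames(v) <- NULL
    # overlapping gap fills of sibling blocks can re-call the same site;
    # collapse duplicates and keep the first record on a rare allele clash
    key <- paste(v$t_seq, v$t_start, v$v_class, v$ref_allele, v$alt_allele)
    v <- v[!duplicated(key), , drop = FALSE]
    key2 <- paste(v$t_seq, v$t_start, v$v_class)
    v <- v[!duplicated(key2), , drop = FALSE]
    calls[[a]] <- v
    if (!quiet)
      message(a, ": ", nrow(v), " variant records")
  }
  mask <- coverage_mask(lapply(synteny, `[[`, "blocks"), cohort$ref)
  gm <- merge_and_impute(calls, mask)
  structure(list(synteny = synteny, mask = mask, calls = calls,
                 genotypes = gm),
            class = "pg_results")
}

# assembly N-gap positions expressed in ungapped source-genome coordinates
assembly_gaps_source <- function(assembly) {
  out <- list()
  sc <- assembly$scaffolds
  for (nm in names(assembly$gaps)) {
    g <- assembly$gaps[[nm]]
    if (nrow(g) == 0) next
    off <- if (!is.null(sc)) sc$offset[match(nm, sc$name)] else 0L
    pos <- off + degap_coord(assembly, nm, g$start)
    out[[length(out) + 1L]] <- data.frame(start = pos, end = pos + 1L)
  }
  do.call(rbind, out) %||% data.frame(start = integer(0), end = integer(0))
}

#' Score calls against a planted truth set
#'
#' SNPs match on exact position and alleles.  Large SVs match a truth
#' record when the call class is compatible (deletion-like:
#' `large_del`/`copy_loss` against planted deletions or translocation
#' sources; insertion-like: `large_ins`/`copy_gain` against planted
#' insertions, duplications or translocation destinations; translocation
#' calls match either side) and the reference intervals agree within
#' `tol` bp at both ends or reciprocally overlap by >= 50%.  Breakpoints
#' count as exact when both interval ends agree exactly after left
#' alignment of both call and truth.  With `exclude` intervals (e.g. TE
#' repeats), truth and calls overlapping them are ignored, which
#' restricts scoring to non-repetitive sequence.
#'
#' @param calls Variant data.frame of one accession.
#' @param truth Truth set of the same accession.
#' @param ref Reference `pg_genome` (for left-aligning truth).
#' @param classes `"SNP"` or `"large"`.
#' @param tol Breakpoint tolerance in bp for a (non-exact) match.
#' @param exclude Optional `data.frame(start, end)` intervals to mask out.
#' @param assembly Optional fragmented assembly `pg_genome`; truth records
#'   whose accession-coordinate span lies within `gap_margin` of an
#'   assembly N-gap are removed from the recall denominator, since the
#'   gap-freedom rule discards such calls by design.
#' @param gap_margin Margin (bp) used with `assembly`.
#' @return List: `recall`, `precision`, `exact_frac`, `n_truth`,
#'   `n_calls`.
#' @export
score_calls <- function(calls, truth, ref, classes = c("SNP", "large"),
                        tol = 20L, exclude = NULL, assembly = NULL,
                        gap_margin = 100L) {
  classes <- match.arg(classes)
  refseq <- ref$seq[[1]]
  if (!is.null(assembly) && classes == "large") {
    agaps <- assembly_gaps_source(assembly)
    if (nrow(agaps) > 0) {
      bad <- iv_overlaps_any(truth$q_start - gap_margin,
                             truth$q_end + gap_margin, agaps)
      truth <- truth[!bad, , drop = FALSE]
    }
  }
  mask_out <- function(start, end) {
    if (is.null(exclude) || nrow(exclude) == 0)
      rep(FALSE, length(start))
    else iv_overlaps_any(start - 50L, end + 50L, exclude)
  }
  if (classes == "SNP") {
    tr <- truth[truth$class == "SNP", , drop = FALSE]
    cl <- calls[calls$v_class == "SNP", , drop = FALSE]
    tr <- tr[!mask_out(tr$t_start, tr$t_end), , drop = FALSE]
    cl <- cl[!mask_out(cl$t_start, cl$t_end), , drop = FALSE]
    tk <- paste(tr$t_start, tr$seq_del, tr$seq_ins)
    ck <- paste(cl$t_start, cl$ref_allele, cl$alt_allele)
    list(recall = mean(tk %in% ck), precision = mean(ck %in% tk),
         exact_frac = mean(tk %in% ck), n_truth = nrow(tr),
         n_calls = nrow(cl))
  } else {
    tr <- truth[truth$class %in% c("large_del", "large_ins", "novel_ins",
                                   "tandem_dup", "translocation",
                                   "copy_loss"), , drop = FALSE]
    tr <- tr[!mask_out(tr$t_start, pmax(tr$t_end, tr$t_start + 1L)), ,
             drop = FALSE]
    cl <- calls[calls$v_class %in% c("large_del", "large_ins", "copy_gain",
                                     "copy_loss", "translocation"), ,
                drop = FALSE]
    cl <- cl[!mask_out(cl$t_start, pmax(cl$t_end, cl$t_start + 1L)), ,
             drop = FALSE]
    # expected signatures per truth record (possibly two for
    # translocations: deletion at source, insertion at destination)
    sig <- list()
    for (i in seq_len(nrow(tr))) {
      r <- tr[i, ]
      if (r$class %in% c("large_del", "copy_loss")) {
        la <- left_align_indel(refseq, r$t_start, r$seq_del)
        sig[[length(sig) + 1L]] <- data.frame(
          tri = i, side = "del", start = la$pos,
          end = la$pos + nchar(la$seq))
      } else if (r$class %in% c("large_ins", "novel_ins")) {
        la <- left_align_indel(refseq, r$t_start, r$seq_ins)
        sig[[length(sig) + 1L]] <- data.frame(
          tri = i, side = "ins", start = la$pos, end = la$pos,
          len = nchar(la$seq))
      } else if (r$class == "tandem_dup") {
        la <- left_align_indel(refseq, r$t_end, r$seq_ins)
        sig[[length(sig) + 1L]] <- data.frame(
          tri = i, side = "ins", start = la$pos, end = la$pos,
          len = nchar(la$seq))
      } else if (r$class == "translocation") {
        sig[[length(sig) + 1L]] <- data.frame(
          tri = i, side = "del", start = r$t_start, end = r$t_end)
        la <- left_align_indel(refseq, r$dest, r$seq_ins)
        sig[[length(sig) + 1L]] <- data.frame(
          tri = i, side = "ins", start = la$pos, end = la$pos,
          len = nchar(la$seq))
      }
    }
    sig <- do.call(rbind, lapply(sig, function(s) {
      if (!"len" %in% names(s)) s$len <- s$end - s$start
      s
    })) %||% data.frame(tri = integer(0), side = character(0),
                        start = integer(0), end = integer(0),
                        len = integer(0))
    cl_side <- ifelse(cl$v_class %in% c("large_del", "copy_loss"), "del",
                      ifelse(cl$v_class == "translocation", "any", "ins"))
    truth_hit <- rep(FALSE, nrow(tr))
    call_hit <- rep(FALSE, nrow(cl))
    call_exact <- rep(FALSE, nrow(cl))
    for (j in seq_len(nrow(cl))) {
      for (k in seq_len(nrow(sig))) {
        if (cl_side[j] != "any" && sig$side[k] != cl_side[j]) next
        d0 <- abs(cl$t_start[j] - sig$start[k])
        d1 <- abs(cl$t_end[j] - sig$end[k])
        ov <- min(cl$t_end[j], sig$end[k]) - max(cl$t_start[j], sig$start[k])
        span <- max(cl$t_end[j] - cl$t_start[j], sig$end[k] - sig$start[k],
                    1L)
        if ((d0 <= tol && d1 <= tol) || ov >= 0.5 * span) {
          truth_hit[sig$tri[k]] <- TRUE
          call_hit[j] <- TRUE
          if (d0 == 0L && d1 == 0L) call_exact[j] <- TRUE
        }
      }
    }
    list(recall = mean(truth_hit), precision = mean(call_hit),
         exact_frac = if (any(call_hit)) mean(call_exact[call_hit]) else NA,
         n_truth = nrow(tr), n_calls = nrow(cl))
  }
}
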