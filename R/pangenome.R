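# Pan-genome construction: novel-segment extraction, complexity filtering,
# redundancy collapse, size curves and the asymptotic fit.

#' Extract novel (reference-unaligned) segments of an assembly
#'
#' Complements the aligned query intervals of the clean synteny blocks
#' over the gap-removed assembly, splits at N-gaps and keeps pieces of at
#' least 50 bp.  Insertion gap content counts as unaligned (it has no
#' reference counterpart).  When `ref` is supplied, a rescue check drops
#' segments that still match the reference somewhere (duplicated or
#' translocated content is not novel sequence).
#'
#' @param assembly Accession assembly `pg_genome`.
#' @param blocks Clean `pg_block` list for that accession.
#' @param accession Accession label stored with each segment.
#' @param ref Optional reference `pg_genome` for the rescue check.
#' @return data.frame `pan_segments`: `accession, seq_name, start, end,
#'   sequence` (scaffold coordinates, 0-based half-open).
#' @export
extract_novel <- function(assembly, blocks, accession = "acc",
                          ref = NULL) {
  aligned <- list()
  for (b in blocks) {
    s <- b$segments
    keep <- s$type %in% c("match", "mismatch")
    if (!any(keep)) next
    qf <- q_to_fwd(b, s$q_start[keep], s$q_end[keep])
    ok <- qf[, 2] > qf[, 1]
    if (!any(ok)) next
    aligned[[b$q_seq]] <- c(aligned[[b$q_seq]] %||% IRanges::IRanges(),
                            iv_to_ir(qf[ok, 1], qf[ok, 2]))
  }
  out <- list()
  for (nm in names(assembly$seq)) {
    L <- nchar(assembly$seq[[nm]])
    cov <- IRanges::reduce(aligned[[nm]] %||% IRanges::IRanges())
    g <- assembly$gaps[[nm]]
    if (!is.null(g) && nrow(g) > 0)
      cov <- IRanges::reduce(c(cov, iv_to_ir(g$start, g$end)))
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), cov)
    free <- free[IRanges::width(free) >= 50L]
    for (j in seq_along(free)) {
      s0 <- IRanges::start(free)[j] - 1L; s1 <- IRanges::end(free)[j]
      out[[length(out) + 1L]] <- data.frame(
        accession = accession, seq_name = nm, start = s0, end = s1,
        sequence = subseq0(assembly$seq[[nm]], s0, s1))
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(accession = character(0), seq_name = character(0),
               start = integer(0), end = integer(0),
               sequence = character(0))
  rownames(res) <- NULL
  if (!is.null(ref) && nrow(res) > 0) {
    tidx <- cpp_kmer_index(unname(ref$seq), 13L, 32L)
    hits_ref <- vapply(res$sequence, function(s) {
      hit <- cpp_map_indexed(s, tidx)
      if (is.na(hit$t_seq_i[1])) return(FALSE)
      frac <- hit$votes[1] / max(1L, nchar(s) - 12L)
      span <- (hit$q_end[1] - hit$q_start[1]) / nchar(s)
      frac >= 0.2 && span >= 0.5
    }, TRUE)
    res <- res[!hits_ref, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Filter low-complexity and tandem-repeat content from segments
#'
#' Implements a DUST-style score (triplet frequencies over 64-base
#' windows; windows scoring above `dust_threshold` are masked) and a
#' short-period tandem detector (periods up to 12 with arrays of at least
#' 50 bp).  Segments with more than 80% masked bases are removed; others
#' are trimmed of terminal masked runs and kept when at least 50 bp
#' remain.
#'
#' @param segments Segment data.frame from [extract_novel()].
#' @param dust_threshold DUST score threshold (default 2).
#' @param max_masked_frac Removal threshold on the masked fraction.
#' @return Filtered segment data.frame.
#' @export
complexity_filter <- function(segments, dust_threshold = 2,
                              max_masked_frac = 0.8) {
  if (nrow(segments) == 0) return(segments)
  keep <- list()
  for (i in seq_len(nrow(segments))) {
    seq <- segments$sequence[i]
    m <- dust_mask(seq, dust_threshold) | tandem_mask(seq)
    if (mean(m) > max_masked_frac) next
    # trim terminal masked runs
    r <- rle(m)
    lead <- if (r$values[1]) r$lengths[1] else 0L
    trail <- if (r$values[length(r$values)]) r$lengths[length(r$values)] else 0L
    s0 <- lead; s1 <- nchar(seq) - trail
    if (s1 - s0 < 50L) next
    row <- segments[i, , drop = FALSE]
    row$start <- row$start + s0
    row$end <- row$start + (s1 - s0)
    row$sequence <- substr(seq, s0 + 1L, s1)
    keep[[length(keep) + 1L]] <- row
  }
  res <- do.call(rbind, keep) %||% segments[0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# DUST-style mask: triplet-count score over sliding 64-base windows
dust_mask <- function(seq, threshold = 2, window = 64L, step = 32L) {
  n <- nchar(seq)
  mask <- logical(n)
  if (n < 5L) return(mask)
  ch <- strsplit(chartr("ACGTN", "01233", seq), "")[[1]]
  code <- as.integer(ch)
  trip <- code[1:(n - 2L)] * 16L + code[2:(n - 1L)] * 4L + code[3:n]
  starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step),
                     max(1L, n - window + 1L)))
  for (s in starts) {
    e <- min(n, s + window - 1L)
    t_idx <- s:(max(s, e - 2L))
    cnt <- tabulate(trip[t_idx] + 1L, 64L)
    nt <- length(t_idx)
    if (nt < 2L) next
    score <- sum(cnt * (cnt - 1L) / 2) / (nt - 1L)
    if (score > threshold) mask[s:e] <- TRUE
  }
  mask
}

# short-period tandem mask: runs of s[i] == s[i + p] of length >= minrun
tandem_mask <- function(seq, max_period = 12L, minrun = 50L) {
  n <- nchar(seq)
  mask <- logical(n)
  if (n < minrun) return(mask)
  ch <- strsplit(seq, "")[[1]]
  for (p in 1:max_period) {
    if (n - p < minrun) break
    eq <- ch[1:(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$lengths)) {
      if (r$values[j] && r$lengths[j] >= minrun - p)
        mask[pos[j]:(pos[j + 1L] - 1L + p)] <- TRUE
    }
  }
  mask
}

#' Collapse redundant segments across accessions
#'
#' Greedy single-linkage clustering: two segments join when they share an
#' alignment at >= 90% identity covering >= 80% of the shorter segment.
#' Candidate pairs are pre-screened by shared 16-mers.  Each cluster
#' keeps its longest member as representative and a presence vector over
#' the accessions contributing members.
#'
#' @param segments Filtered segment data.frame.
#' @param accessions Character vector of all accession names (defines the
#'   presence-vector dimension).
#' @param min_ident,min_cover Clustering thresholds.
#' @return List of class `pan_clusters`: `clusters` (data.frame:
#'   `cluster_id, representative row index, length, n_members,
#'   n_accessions`), `membership` (integer vector), `presence` (logical
#'   matrix cluster x accession), `segments`.
#' @export
collapse_redundancy <- function(segments, accessions = NULL,
                                min_ident = 0.9, min_cover = 0.8) {
  n <- nrow(segments)
  accessions <- accessions %||% unique(segments$accession)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1) {
    # shared-16-mer prescreen; k-mers are selected by their own content
    # (suffix "AA", ~1/16 of positions) so the selection is invariant to
    # coordinate shifts between copies of the same sequence
    km <- lapply(segments$sequence, function(s) {
      if (nchar(s) < 16L) return(character(0))
      ks <- substring(s, 1L:(nchar(s) - 15L), 16L:nchar(s))
      unique(ks[endsWith(ks, "AA")])
    })
    tab <- new.env(hash = TRUE)
    for (i in seq_len(n)) for (k in km[[i]]) {
      assign(k, c(get0(k, envir = tab, ifnotfound = integer(0)), i),
             envir = tab)
    }
    pairs <- new.env(hash = TRUE)
    for (k in ls(tab)) {
      ids <- unique(get(k, envir = tab))
      if (length(ids) > 1 && length(ids) <= 20) {
        for (a in seq_along(ids)[-length(ids)])
          for (b in (a + 1):length(ids))
            assign(paste(ids[a], ids[b]), TRUE, envir = pairs)
      }
    }
    for (key in ls(pairs)) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      if (find(ij[1]) == find(ij[2])) next
      if (segment_match(segments$sequence[ij[1]], segments$sequence[ij[2]],
                        min_ident, min_cover))
        union2(ij[1], ij[2])
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, unique(roots))
  cl <- lapply(split(seq_len(n), ids), function(idx) {
    lens <- segments$end[idx] - segments$start[idx]
    rep_i <- idx[which.max(lens)]
    accs <- unique(segments$accession[idx])
    data.frame(rep = rep_i, length = max(lens), n_members = length(idx),
               n_accessions = length(accs))
  })
  cl <- do.call(rbind, cl) %||%
    data.frame(rep = integer(0), length = integer(0),
               n_members = integer(0), n_accessions = integer(0))
  cl$cluster_id <- seq_len(nrow(cl))
  presence <- matrix(FALSE, nrow(cl), length(accessions),
                     dimnames = list(NULL, accessions))
  for (i in seq_len(n))
    presence[ids[i], segments$accession[i]] <- TRUE
  structure(list(clusters = cl, membership = ids, presence = presence,
                 segments = segments),
            class = "pan_clusters")
}

# do two segments align at >= min_ident over >= min_cover of the shorter?
segment_match <- function(a, b, min_ident = 0.9, min_cover = 0.8) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  hit <- cpp_map_sequences(a, b, 13L, 32L)
  if (is.na(hit$t_seq_i[1]) || hit$votes[1] < 3) return(FALSE)
  cover_est <- (hit$q_end[1] - hit$q_start[1]) / nchar(a)
  if (cover_est < min_cover * 0.8) return(FALSE)
  qs <- if (isTRUE(hit$plus[1])) a else revcomp(a)
  ident <- verify_identity(qs, b, hit)
  aligned_cover <- (hit$q_end[1] - hit$q_start[1]) / nchar(a)
  ident >= min_ident && aligned_cover >= min_cover
}

#' Pan- and core-genome size curves
#'
#' For each seeded permutation of the accession order, `core(k)` is the
#' reference bp covered in all of the first `k` accessions plus the novel
#' bp present in all of them, and `pan(k)` is the reference bp covered in
#' any of them plus the novel bp contributed by any of them.  When the
#' number of accessions is at most 6 all orders are enumerated instead of
#' sampling.  Means over permutations are reported per k.
#'
#' @param mask A `pg_mask` over the accessions.
#' @param clusters A `pan_clusters` from [collapse_redundancy()].
#' @param n_perm Number of permutations (ignored when enumerating).
#' @param seed Integer seed for the permutation draw.
#' @return List of class `pan_curve`: `k`, `core_mean`, `pan_mean`,
#'   `core` / `pan` (permutation x k matrices), `orders`.
#' @export
size_curves <- function(mask, clusters, n_perm = 20L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  accs <- names(mask$acc)
  n <- length(accs)
  cl_len <- clusters$clusters$length
  pres <- clusters$presence[, accs, drop = FALSE]
  orders <- NULL
  if (n <= 6) {
    perm_all <- all_permutations(n)
    orders <- perm_all
  } else {
    withr::local_seed(derive_seed(seed, "size_curves"))
    orders <- lapply(seq_len(n_perm), function(i) sample.int(n))
  }
  core <- matrix(NA_real_, length(orders), n)
  pan <- matrix(NA_real_, length(orders), n)
  for (p in seq_along(orders)) {
    ord <- accs[orders[[p]]]
    inter <- NULL; uni <- NULL
    seen <- rep(FALSE, n); names(seen) <- accs
    for (k in seq_len(n)) {
      a <- ord[k]
      m <- mask$acc[[a]]
      inter <- if (is.null(inter)) m else int_list(inter, m)
      uni <- if (is.null(uni)) m else uni_list(uni, m)
      seen[a] <- TRUE
      in_all <- rowSums(pres[, ord[seq_len(k)], drop = FALSE]) == k
      in_any <- rowSums(pres[, ord[seq_len(k)], drop = FALSE]) > 0
      core[p, k] <- bp_list(inter) + sum(cl_len[in_all])
      pan[p, k] <- bp_list(uni) + sum(cl_len[in_any])
    }
  }
  structure(list(k = seq_len(n), core_mean = colMeans(core),
                 pan_mean = colMeans(pan), core = core, pan = pan,
                 orders = orders, accessions = accs),
            class = "pan_curve")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (s in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(s, n, after = pos)
  }
  out
}

int_list <- function(a, b) {
  seqs <- union(names(a), names(b))
  out <- list()
  for (sq in seqs)
    out[[sq]] <- IRanges::intersect(a[[sq]] %||% IRanges::IRanges(),
                                    b[[sq]] %||% IRanges::IRanges())
  out
}

uni_list <- function(a, b) {
  seqs <- union(names(a), names(b))
  out <- list()
  for (sq in seqs)
    out[[sq]] <- IRanges::union(a[[sq]] %||% IRanges::IRanges(),
                                b[[sq]] %||% IRanges::IRanges())
  out
}

bp_list <- function(a) sum(vapply(a, function(x)
  sum(IRanges::width(x)), 0))

#' Fit the asymptotic regression model to a size curve
#'
#' Fits `y = b0 + b1 * (1 - exp(-exp(lrc) * x))` by nonlinear least
#' squares with multiple starts over an `lrc` grid from -3 to 1, and
#' returns the best fit.  A constant curve degenerates to `b1 = 0` with
#' asymptote equal to the constant.
#'
#' @param x,y Curve points (typically `k` and the mean sizes).
#' @return List of class `pan_fit`: `b0`, `b1`, `lrc`, `rss`,
#'   `asymptote = b0 + b1`, `fitted`.
#' @export
fit_asymptotic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (sd(y) == 0) {
    return(structure(list(b0 = y[1], b1 = 0, lrc = NA_real_, rss = 0,
                          asymptote = y[1], fitted = y),
                     class = "pan_fit"))
  }
  best <- NULL
  for (lrc0 in seq(-3, 1, by = 0.5)) {
    b0_0 <- min(y)
    b1_0 <- max(max(y) - min(y), 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b0 + b1 * (1 - exp(-exp(lrc) * x)),
                        start = list(b0 = b0_0, b1 = b1_0, lrc = lrc0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      co <- coef(fit)
      best <- list(b0 = unname(co["b0"]), b1 = unname(co["b1"]),
                   lrc = unname(co["lrc"]), rss = rss,
                   asymptote = unname(co["b0"] + co["b1"]),
                   fitted = as.numeric(predict(fit)))
    }
  }
  if (is.null(best))
    stop("asymptotic fit failed to converge from every start on the lrc grid")
  structure(best, class = "pan_fit")
}

#' @export
print.pan_fit <- function(x, ...) {
  cat(sprintf("<pan_fit> b0 = %.4g, b1 = %.4g, lrc = %.4g; asymptote %.4g (RSS %.3g)\n",
              x$b0, x$b1, x$lrc, x$asymptote, x$rss))
  invisible(x)
}

#' Accession-specific genes
#'
#' Genes with more than half of their CDS length inside accession-private
#' segments.
#'
#' @param genes A `pg_genes` (coordinates in the same frame as
#'   `segments`, i.e. the accession genome).
#' @param segments data.frame of private segments (`seq_name, start,
#'   end`).
#' @param min_frac Minimum CDS fraction inside private segments.
#' @return Character vector of gene ids.
#' @export
accession_specific_genes <- function(genes, segments, min_frac = 0.5) {
  if (nrow(genes$genes) == 0 || nrow(segments) == 0) return(character(0))
  out <- character(0)
  for (gid in unique(genes$cds$gene_id)) {
    cds <- genes$cds[genes$cds$gene_id == gid, , drop = FALSE]
    g <- genes$genes[genes$genes$gene_id == gid, ]
    seg <- segments[segments$seq_name == g$seq_name |
                      is.na(segments$seq_name), , drop = FALSE]
    if (nrow(seg) == 0) next
    tot <- sum(cds$end - cds$start)
    ov <- 0
    for (i in seq_len(nrow(cds))) {
      ov <- ov + sum(pmax(0, pmin(seg$end, cds$end[i]) -
                            pmax(seg$start, cds$start[i])))
    }
    if (ov > min_frac * tot) out <- c(out, gid)
  }
  out
}
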