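#' Build synteny blocks between an assembly and a reference
#'
#' End-to-end pairwise synteny: unique k-mer anchoring (with a second,
#' smaller-k pass restricted to query regions the first pass left
#' uncovered), chaining, single-coverage netting in the reference,
#' reciprocal-best filtering against the query-space net, base-level gap
#' fill and N-gap-aware cleaning.
#'
#' @param query Assembly `pg_genome` (scaffolds may contain N-gaps).
#' @param target Reference `pg_genome`.
#' @param params A [synteny_params()].
#' @param quiet Suppress progress messages.
#' @return List of class `pg_synteny` with elements `blocks` (clean
#'   `pg_block` list), `net` (reciprocal-best chains), `chains` (all
#'   chains) and `counts` (anchor/chain/block tallies).
#' @export
build_synteny <- function(query, target, params = synteny_params(),
                          quiet = TRUE) {
  a1 <- find_anchors(query, target, params$k)
  ch1 <- chain_genome(a1, params)

  # rescue pass: re-anchor uncovered query regions at smaller k
  qlens <- vapply(query$seq, nchar, 0L)
  cov <- list()
  for (ch in ch1) {
    iv <- q_fwd_interval(ch)
    cov[[ch$q_seq]] <- c(cov[[ch$q_seq]] %||% IRanges::IRanges(),
                         iv_to_ir(iv[1], iv[2]))
  }
  unc <- list()
  for (nm in names(query$seq)) {
    free <- IRanges::setdiff(IRanges::IRanges(1L, qlens[[nm]]),
                             IRanges::reduce(cov[[nm]] %||% IRanges::IRanges()))
    free <- free[IRanges::width(free) >= params$k2]
    if (length(free) > 0)
      unc[[length(unc) + 1L]] <- data.frame(seq_name = nm,
                                            start = IRanges::start(free) - 1L,
                                            end = IRanges::end(free))
  }
  anchors <- a1
  if (length(unc) > 0) {
    a2 <- find_anchors(query, target, params$k2, restrict = do.call(rbind, unc))
    if (nrow(a2) > 0) {
      anchors <- rbind(as.data.frame(a1), as.data.frame(a2))
      anchors <- unique(anchors)
      attr(anchors, "q_lens") <- attr(a1, "q_lens")
      attr(anchors, "t_lens") <- attr(a1, "t_lens")
      class(anchors) <- c("pg_anchors", "data.frame")
    }
  }

  chains <- chain_genome(anchors, params)
  net_t <- net_chains(chains, params, "target")
  net_q <- net_chains(chains, params, "query")
  rb <- reciprocal_best(net_t, net_q, params)
  blocks <- lapply(rb, fill_alignment, query = query, target = target,
                   params = params)
  clean <- clean_blocks(blocks, query$gaps, target$gaps, params)
  counts <- c(anchors = nrow(anchors), chains = length(chains),
              netted = length(rb), blocks = length(clean))
  if (!quiet)
    message(sprintf("anchors %d | chains %d | netted %d | clean blocks %d",
                    counts[1], counts[2], counts[3], counts[4]))
  structure(list(blocks = clean, net = rb, chains = chains,
                 counts = counts),
            class = "pg_synteny")
}

#' @export
print.pg_synteny <- function(x, ...) {
  cat(sprintf("<pg_synteny> %d clean blocks from %d netted chains\n",
              length(x$blocks), length(x$net)))
  invisible(x)
}
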