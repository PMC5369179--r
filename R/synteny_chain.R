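# Chain construction: sparse DP over anchors with greedy chain extraction.

# score of an ordered anchor set under the chain scoring function
score_chain <- function(a, params) {
  s <- sum(a$length)
  if (nrow(a) > 1) {
    for (i in 2:nrow(a)) {
      dt <- a$t_start[i] - (a$t_start[i - 1] + a$length[i - 1])
      dq <- a$q_start[i] - (a$q_start[i - 1] + a$length[i - 1])
      s <- s - (params$open + params$extend * abs(dq - dt) +
                  params$diag * min(dq, dt))
    }
  }
  s
}

new_chain <- function(q_seq, t_seq, strand, anchors, score, q_len, id = NA) {
  structure(list(q_seq = q_seq, t_seq = t_seq, strand = strand,
                 anchors = anchors, score = score,
                 q_start = anchors$q_start[1],
                 q_end = anchors$q_start[nrow(anchors)] +
                   anchors$length[nrow(anchors)],
                 t_start = anchors$t_start[1],
                 t_end = anchors$t_start[nrow(anchors)] +
                   anchors$length[nrow(anchors)],
                 q_len = q_len, id = id),
            class = "pg_chain")
}

#' Chain collinear anchors by sparse dynamic programming
#'
#' All anchors must come from one `(q_seq, t_seq, strand)` triple.  The DP
#' maximises total anchor length minus join penalties (see
#' [synteny_params()]); chains are extracted greedily by descending score,
#' each anchor entering at most one chain, and chains scoring below
#' `min_score` are dropped.
#'
#' @param anchors A `pg_anchors` data.frame (one triple).
#' @param params A [synteny_params()].
#' @return List of `pg_chain` objects, best first.
#' @export
chain_anchors <- function(anchors, params = synteny_params()) {
  if (nrow(anchors) == 0) return(list())
  key <- unique(anchors[, c("q_seq", "t_seq", "strand")])
  if (nrow(key) != 1)
    stop("chain_anchors expects anchors from a single (q_seq, t_seq, strand) triple")
  q_len <- attr(anchors, "q_lens")[[key$q_seq]]
  a <- anchors[order(anchors$t_start, anchors$q_start), , drop = FALSE]
  n <- nrow(a)
  used <- rep(FALSE, n)
  chains <- list()
  repeat {
    if (all(used)) break
    dp <- cpp_chain_dp(a$q_start, a$t_start, a$length,
                       params$open, params$extend, params$diag, used)
    sc <- dp$score
    sc[used] <- -Inf
    best <- which.max(sc)
    if (sc[best] < params$min_score) break
    path <- integer(0)
    i <- best
    while (i > 0) {
      path <- c(i, path)
      i <- dp$bp[i] + 1L  # C++ backpointers are 0-based, -1 terminates
    }
    used[path] <- TRUE
    anchors <- a[path, c("q_start", "t_start", "length"), drop = FALSE]
    # clip micro-homology overlaps against the predecessor (the DP scored
    # them as clipped)
    if (nrow(anchors) > 1) {
      for (r in 2:nrow(anchors)) {
        o <- max(anchors$t_start[r - 1] + anchors$length[r - 1] -
                   anchors$t_start[r],
                 anchors$q_start[r - 1] + anchors$length[r - 1] -
                   anchors$q_start[r], 0L)
        if (o > 0) {
          anchors$t_start[r] <- anchors$t_start[r] + o
          anchors$q_start[r] <- anchors$q_start[r] + o
          anchors$length[r] <- anchors$length[r] - o
        }
      }
    }
    chains[[length(chains) + 1L]] <-
      new_chain(key$q_seq, key$t_seq, key$strand, anchors,
                sc[best], q_len)
  }
  chains
}

#' Chain anchors genome-wide
#'
#' Splits anchors by `(q_seq, t_seq, strand)`, chains each group and
#' returns all chains sorted by `(score desc, t_seq, t_start, q_seq,
#' q_start)` with stable ids assigned.
#'
#' @inheritParams chain_anchors
#' @return List of `pg_chain`.
#' @export
chain_genome <- function(anchors, params = synteny_params()) {
  if (nrow(anchors) == 0) return(list())
  grp <- paste(anchors$q_seq, anchors$t_seq, anchors$strand, sep = "\r")
  chains <- list()
  for (g in unique(grp)) {
    sub <- anchors[grp == g, , drop = FALSE]
    attr(sub, "q_lens") <- attr(anchors, "q_lens")
    chains <- c(chains, chain_anchors(sub, params))
  }
  sort_chains(chains)
}

sort_chains <- function(chains) {
  if (length(chains) == 0) return(chains)
  ord <- order(-vapply(chains, `[[`, 0, "score"),
               vapply(chains, `[[`, "", "t_seq"),
               vapply(chains, `[[`, 0L, "t_start"),
               vapply(chains, `[[`, "", "q_seq"),
               vapply(chains, `[[`, 0L, "q_start"))
  chains <- chains[ord]
  for (i in seq_along(chains)) chains[[i]]$id <- i
  chains
}

# query interval of a chain/block in forward scaffold coordinates
q_fwd_interval <- function(x) {
  if (x$strand == "+") c(x$q_start, x$q_end)
  else c(x$q_len - x$q_end, x$q_len - x$q_start)
}

#' @export
print.pg_chain <- function(x, ...) {
  cat(sprintf("<chain %s> %s:%d-%d %s %s:%d-%d score %.1f (%d anchors)\n",
              ifelse(is.na(x$id), "?", x$id), x$q_seq, x$q_start, x$q_end,
              x$strand, x$t_seq, x$t_start, x$t_end, x$score,
              nrow(x$anchors)))
  invisible(x)
}
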