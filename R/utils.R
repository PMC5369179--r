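#' @useDynLib pansynt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom rlnorm runif sd setNames median coef nls
#'   resid predict
#' @importFrom utils head tail combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open substring; start/end follow the package-wide coordinate
# convention (converted to 1-based only at file-format boundaries).
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# One seeded generator per operation invocation: the stream seed is a stable
# hash of (master seed, labels...), so each stage is independently
# reproducible regardless of how many random draws earlier stages made.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# interval helpers: data.frames with 0-based half-open start/end <-> IRanges
iv_to_ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

ir_to_iv <- function(x) {
  data.frame(start = IRanges::start(x) - 1L, end = IRanges::end(x))
}

iv_overlaps_any <- function(start, end, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(start)))
  IRanges::overlapsAny(iv_to_ir(start, pmax(end, start + 1L)),
                       iv_to_ir(iv$start, iv$end))
}

# exactly n substitutions at distinct positions
substitute_bases <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1]])
}
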