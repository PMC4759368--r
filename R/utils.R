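# Internal helpers shared across modules.  All user-facing coordinates in this
# package are 0-based half-open (BED convention); GRanges conversion happens
# only inside these helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
as_granges0 <- function(df, seqlengths = NULL, seqlevels = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$start >= df$end)) {
    stop("invalid interval(s): start must be < end (0-based half-open)")
  }
  seqnames <- if (is.null(seqlevels)) as.character(df$chrom)
              else factor(as.character(df$chrom), levels = seqlevels)
  GenomicRanges::GRanges(
    seqnames = seqnames,
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end)),
    seqlengths = seqlengths
  )
}

# Run `expr` under a fixed seed when one is given, otherwise use the current
# RNG state.  Keeps all randomness flowing through one explicit generator.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Sort a site table into canonical (chrom, start) order.
sort_sites <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)))
  }
  invisible(x)
}

# Interval midpoint (0-based bp) of half-open [start, end).
interval_mid0 <- function(start, end) floor((start + end - 1) / 2)
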