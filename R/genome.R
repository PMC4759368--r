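#' Generate a synthetic genome annotation
#'
#' Builds a small genome (named chromosomes of fixed length) carrying
#' non-overlapping multi-exon gene models on both strands.  The object stands
#' in for a reference genome assembly so that every downstream stage of the
#' accessibility pipeline can be exercised on data with known ground truth.
#'
#' Coordinates are 0-based half-open throughout (BED convention).  The
#' transcription start site (TSS) of a gene is `tx_start` on the plus strand
#' and `tx_end - 1` on the minus strand.
#'
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes to place, spread across chromosomes.
#' @param seed Optional integer seed; a fixed seed yields byte-identical
#'   output.  `NULL` uses the current RNG state.
#' @param gene_length_range Length-2 numeric, min/max gene length in bp.
#' @param exon_range Length-2 integer, min/max number of exons per gene.
#'
#' @return An object of class `dhs_genome`: a list with `chroms` (named
#'   numeric vector of chromosome lengths), `genes` (data.frame with
#'   `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`) and `exons`
#'   (data.frame with `gene_id`, `start`, `end`).
#' @examples
#' g <- make_genome(n_chroms = 1, chrom_length = 1e6, n_genes = 20, seed = 1)
#' head(g$genes)
#' @export
make_genome <- function(n_chroms = 2, chrom_length = 5e6, n_genes = 200,
                        seed = NULL, gene_length_range = c(2000, 15000),
                        exon_range = c(2L, 10L)) {
  check_scalar_number(n_chroms, "n_chroms", lower = 1)
  check_scalar_number(chrom_length, "chrom_length", lower = 1)
  check_scalar_number(n_genes, "n_genes", lower = 0)
  stopifnot(length(gene_length_range) == 2, gene_length_range[1] >= 3,
            gene_length_range[1] <= gene_length_range[2],
            length(exon_range) == 2, exon_range[1] >= 1)
  with_opt_seed(seed, {
    chroms <- stats::setNames(rep(as.numeric(chrom_length), n_chroms),
                              paste0("chr", seq_len(n_chroms)))
    if (n_genes == 0) {
      return(new_dhs_genome(chroms,
                            empty_gene_table(), empty_exon_table()))
    }
    if (n_genes * gene_length_range[1] > sum(chroms)) {
      stop(sprintf(paste0("gene density infeasible: %d genes of >= %d bp do ",
                          "not fit in %g bp of genome without overlap"),
                   n_genes, gene_length_range[1], sum(chroms)))
    }
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]),
                   n_genes, replace = TRUE)
    # Greedy capacity-balanced assignment of genes (longest first) to
    # chromosomes; errors out if any chromosome overflows.
    free <- chroms
    chrom_of <- character(n_genes)
    for (i in order(lens, decreasing = TRUE)) {
      k <- which.max(free)
      if (free[k] < lens[i]) {
        stop("gene density infeasible: cannot place all genes without overlap")
      }
      chrom_of[i] <- names(chroms)[k]
      free[k] <- free[k] - lens[i]
    }
    genes <- data.frame(chrom = chrom_of, len = lens,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    # Positions: per chromosome scatter the unused space as random gaps
    # between consecutive genes (classic stick-breaking placement).
    genes$tx_start <- NA_real_
    for (ch in names(chroms)) {
      idx <- which(genes$chrom == ch)
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]           # random along-chrom order
      slack <- chroms[[ch]] - sum(genes$len[idx])
      cuts <- sort(stats::runif(length(idx)))
      gaps <- floor(c(cuts, 1) * slack) - floor(c(0, cuts) * slack)
      starts <- cumsum(gaps[seq_along(idx)]) +
        cumsum(c(0, genes$len[idx][-length(idx)]))
      genes$tx_start[idx] <- starts
    }
    genes$tx_end <- genes$tx_start + genes$len
    genes <- genes[order(genes$chrom, genes$tx_start), ]
    genes$gene_id <- sprintf("G%04d", seq_len(n_genes))
    rownames(genes) <- NULL
    exons <- make_exons(genes, exon_range)
    genes$len <- NULL
    new_dhs_genome(chroms,
                   genes[, c("gene_id", "chrom", "strand",
                             "tx_start", "tx_end")],
                   exons)
  })
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             tx_start = numeric(), tx_end = numeric(), stringsAsFactors = FALSE)
}

empty_exon_table <- function() {
  data.frame(gene_id = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

# Split each gene into 2*n_ex - 1 alternating exon/intron segments so that the
# transcript starts and ends with an exon.
make_exons <- function(genes, exon_range) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    len <- genes$len[i]
    n_ex <- sample(seq(exon_range[1], exon_range[2]), 1)
    n_seg <- 2L * n_ex - 1L
    bounds <- c(0, sort(sample.int(len - 1L, n_seg - 1L)), len)
    ex_i <- seq(1L, n_seg, by = 2L)
    out[[i]] <- data.frame(
      gene_id = genes$gene_id[i],
      start = genes$tx_start[i] + bounds[ex_i],
      end = genes$tx_start[i] + bounds[ex_i + 1L],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

new_dhs_genome <- function(chroms, genes, exons) {
  obj <- structure(list(chroms = chroms, genes = genes, exons = exons),
                   class = "dhs_genome")
  validate_genome(obj)
  obj
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "dhs_genome"))
  if (any(genome$chroms <= 0)) stop("chromosome lengths must be > 0")
  g <- genome$genes
  if (nrow(g) > 0) {
    if (any(g$tx_start >= g$tx_end)) stop("gene with tx_start >= tx_end")
    if (!all(g$chrom %in% names(genome$chroms))) {
      stop("gene on unknown chromosome")
    }
    lens <- genome$chroms[g$chrom]
    if (any(g$tx_start < 0) || any(g$tx_end > lens)) {
      stop("gene interval outside chromosome bounds")
    }
    if (anyDuplicated(g$gene_id)) stop("duplicate gene_id")
    e <- genome$exons
    if (!all(e$gene_id %in% g$gene_id)) stop("exon for unknown gene")
    if (any(e$start >= e$end)) stop("exon with start >= end")
  }
  invisible(genome)
}

#' Transcription start sites of a genome's genes
#'
#' @param genome A `dhs_genome` (or its `genes` data.frame).
#' @return Numeric vector of 0-based TSS positions, named by `gene_id`
#'   (`tx_start` on `+`, `tx_end - 1` on `-`).
#' @export
gene_tss <- function(genome) {
  genes <- if (inherits(genome, "dhs_genome")) genome$genes else genome
  stats::setNames(ifelse(genes$strand == "+", genes$tx_start,
                         genes$tx_end - 1),
                  genes$gene_id)
}

#' @export
print.dhs_genome <- function(x, ...) {
  cat(sprintf("<dhs_genome> %d chromosome(s), %g bp total, %d gene(s)\n",
              length(x$chroms), sum(x$chroms), nrow(x$genes)))
  invisible(x)
}
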