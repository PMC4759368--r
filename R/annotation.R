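DHS_CATEGORIES <- c("promoter", "exon", "intron", "distal_upstream",
                    "downstream")

#' Priority-based genomic classification of DHS sites
#'
#' Classifies each site into exactly one category with the priority
#' promoter > exon > intron > distal.  A site is a `promoter` if it
#' intersects `[TSS - halfwidth, TSS + halfwidth)` of any gene; failing
#' that, `exon` if it intersects any exon, `intron` if it intersects any
#' gene body, and otherwise `distal_upstream` or `downstream` according to
#' whether its midpoint lies 5' or 3' of the nearest gene's TSS (strand
#' aware; nearest by midpoint-to-TSS distance, ties to the lexicographically
#' smaller `gene_id`).  Within a priority level the site is assigned to the
#' gene with the nearest TSS.
#'
#' @param sites Data.frame of sites (`chrom`, `start`, `end`, 0-based
#'   half-open; other columns are carried through).
#' @param genome A `dhs_genome` with at least one gene.
#' @param promoter_halfwidth Promoter window half-width in bp.
#' @return List of class `annotated_sites` with `sites` (input plus
#'   `category`, `nearest_gene_id`, `distance_to_tss` -- signed bp from the
#'   assigned gene's TSS to the site midpoint, positive downstream),
#'   `counts` and `fractions` per category.
#' @export
annotate_all <- function(sites, genome, promoter_halfwidth = 2500) {
  validate_genome(genome)
  if (nrow(genome$genes) == 0) {
    stop("cannot classify sites against an empty gene annotation")
  }
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  if (n == 0) {
    counts <- stats::setNames(integer(length(DHS_CATEGORIES)), DHS_CATEGORIES)
    sites$category <- character(0)
    sites$nearest_gene_id <- character(0)
    sites$distance_to_tss <- numeric(0)
    return(structure(list(sites = sites, counts = counts,
                          fractions = stats::setNames(
                            numeric(length(DHS_CATEGORIES)), DHS_CATEGORIES)),
                     class = "annotated_sites"))
  }
  genes <- genome$genes
  tss <- gene_tss(genome)
  levs <- union(names(genome$chroms), unique(sites$chrom))
  gr <- as_granges0(sites, seqlevels = levs)
  mid <- interval_mid0(sites$start, sites$end)

  category <- rep(NA_character_, n)
  gene_sel <- rep(NA_character_, n)

  # Assign, among candidate (site, gene) hits, each still-unassigned site to
  # the gene with the nearest TSS (tie: smaller gene_id).
  assign_level <- function(hits_q, hits_gene_idx, label) {
    open <- is.na(category[hits_q])
    q <- hits_q[open]
    gi <- hits_gene_idx[open]
    if (length(q) == 0) return(invisible(NULL))
    d <- abs(mid[q] - tss[genes$gene_id[gi]])
    ord <- order(q, d, genes$gene_id[gi])
    first <- !duplicated(q[ord])
    qs <- q[ord][first]
    gs <- gi[ord][first]
    category[qs] <<- label
    gene_sel[qs] <<- genes$gene_id[gs]
    invisible(NULL)
  }

  prom <- promoter_windows(genome, promoter_halfwidth, seqlevels = levs)
  ph <- GenomicRanges::findOverlaps(gr, prom)
  assign_level(S4Vectors::queryHits(ph), S4Vectors::subjectHits(ph),
               "promoter")

  ex <- genome$exons
  if (nrow(ex) > 0) {
    exon_gr <- GenomicRanges::GRanges(
      factor(genes$chrom[match(ex$gene_id, genes$gene_id)], levels = levs),
      IRanges::IRanges(ex$start + 1, ex$end))
    eh <- GenomicRanges::findOverlaps(gr, exon_gr)
    assign_level(S4Vectors::queryHits(eh),
                 match(ex$gene_id, genes$gene_id)[S4Vectors::subjectHits(eh)],
                 "exon")
  }

  body_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = levs),
                                    IRanges::IRanges(genes$tx_start + 1,
                                                     genes$tx_end))
  bh <- GenomicRanges::findOverlaps(gr, body_gr)
  assign_level(S4Vectors::queryHits(bh), S4Vectors::subjectHits(bh), "intron")

  # Distal sites: nearest gene on the same chromosome.
  open <- which(is.na(category))
  if (length(open) > 0) {
    for (i in open) {
      gi <- which(genes$chrom == sites$chrom[i])
      if (length(gi) == 0) {
        stop(sprintf(paste0("site %s lies on chromosome '%s' which carries ",
                            "no genes; distal classification undefined"),
                     sites$site_id[i] %||% i, sites$chrom[i]))
      }
      d <- abs(mid[i] - tss[genes$gene_id[gi]])
      j <- gi[order(d, genes$gene_id[gi])][1]
      gene_sel[i] <- genes$gene_id[j]
      upstream <- if (genes$strand[j] == "+") mid[i] < tss[[gene_sel[i]]]
                  else mid[i] > tss[[gene_sel[i]]]
      category[i] <- if (upstream) "distal_upstream" else "downstream"
    }
  }

  strand_sel <- genes$strand[match(gene_sel, genes$gene_id)]
  dist_signed <- ifelse(strand_sel == "+", mid - tss[gene_sel],
                        tss[gene_sel] - mid)
  sites$category <- category
  sites$nearest_gene_id <- gene_sel
  sites$distance_to_tss <- unname(dist_signed)
  counts <- table(factor(category, levels = DHS_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), DHS_CATEGORIES)
  structure(list(sites = sites, counts = counts, fractions = counts / n),
            class = "annotated_sites")
}

#' @rdname annotate_all
#' @param site A single-row site data.frame (or list coercible to one).
#' @return `classify_site()`: the single annotated row as a data.frame.
#' @export
classify_site <- function(site, genome, promoter_halfwidth = 2500) {
  ann <- annotate_all(as.data.frame(site), genome,
                      promoter_halfwidth = promoter_halfwidth)
  ann$sites
}

#' @export
print.annotated_sites <- function(x, ...) {
  cat(sprintf("<annotated_sites> %d sites\n", nrow(x$sites)))
  print(x$counts)
  invisible(x)
}

#' Average tag-density profile around transcription start sites
#'
#' For every gene whose `[TSS - flank, TSS + flank)` window lies fully
#' within its chromosome, extracts the strand-oriented per-bp cut counts
#' from a bedGraph-style track, sums them in `bin`-bp bins, normalizes to a
#' depth of 10 million reads, and averages over genes.
#'
#' @param track Data.frame `chrom`, `start`, `end`, `count` (0-based
#'   half-open runs of per-bp counts).
#' @param genome A `dhs_genome` with at least one gene.
#' @param flank Half-width of the profiled window (bp).
#' @param bin Bin size in bp; must divide `2 * flank`.
#' @param total_reads Library size used for depth normalization.
#' @return Data.frame with `offset` (bp of the bin start relative to the
#'   TSS, 5' to 3') and `density` (mean normalized tag count per bin);
#'   attribute `n_tss` gives the number of genes averaged.
#' @export
aggregation_profile <- function(track, genome, flank = 5000, bin = 50,
                                total_reads) {
  validate_genome(genome)
  if (nrow(genome$genes) == 0) stop("no genes to aggregate around")
  check_scalar_number(total_reads, "total_reads", lower = 1)
  if ((2 * flank) %% bin != 0) stop("`bin` must divide 2 * flank")
  track <- as.data.frame(track)
  width <- as.integer(2 * flank)
  cov <- if (nrow(track) > 0) {
    gr <- as_granges0(track, seqlengths = genome$chroms)
    GenomicRanges::coverage(gr, weight = track$count)
  } else {
    NULL
  }
  genes <- genome$genes
  tss <- gene_tss(genome)
  acc <- numeric(width)
  n_used <- 0L
  for (i in seq_len(nrow(genes))) {
    t0 <- tss[[genes$gene_id[i]]]
    i1 <- t0 - flank + 1
    i2 <- t0 + flank
    if (i1 < 1 || i2 > genome$chroms[[genes$chrom[i]]]) next
    v <- if (is.null(cov)) numeric(width)
         else as.numeric(cov[[genes$chrom[i]]][i1:i2])
    if (genes$strand[i] == "-") v <- rev(v)
    acc <- acc + v
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no gene window fits inside the genome")
  bin_sums <- colSums(matrix(acc, nrow = bin))
  out <- data.frame(offset = seq(-flank, flank - bin, by = bin),
                    density = bin_sums * 1e7 / total_reads / n_used)
  attr(out, "n_tss") <- n_used
  out
}

#' Per-category distributions of normalized MaxD
#'
#' @param annotated An `annotated_sites` object (or a data.frame with
#'   `category` and `norm_maxd`).
#' @return Named list, one element per category, each with sorted `values`,
#'   `n`, and a right-continuous `ecdf` (`NULL` when the category is empty);
#'   attribute `empty_categories` flags categories without sites.
#' @export
maxd_distribution <- function(annotated) {
  df <- if (inherits(annotated, "annotated_sites")) annotated$sites
        else as.data.frame(annotated)
  if (!all(c("category", "norm_maxd") %in% names(df))) {
    stop("need `category` and `norm_maxd` columns")
  }
  out <- lapply(DHS_CATEGORIES, function(cat) {
    v <- sort(df$norm_maxd[df$category == cat])
    list(values = v, n = length(v),
         ecdf = if (length(v) > 0) stats::ecdf(v) else NULL)
  })
  names(out) <- DHS_CATEGORIES
  attr(out, "empty_categories") <-
    DHS_CATEGORIES[vapply(out, function(x) x$n == 0, logical(1))]
  out
}
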