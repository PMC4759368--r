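#' Define enhancers by promoter exclusion
#'
#' Enhancers, in the operational sense used throughout this package, are
#' condition-unique DHS sites outside promoter windows: the exonic,
#' intronic and intergenic categories combined.  Input order is preserved.
#'
#' @param annotated_sites An `annotated_sites` object or a data.frame with a
#'   `category` column.
#' @return The non-promoter rows.
#' @export
define_enhancers <- function(annotated_sites) {
  df <- if (inherits(annotated_sites, "annotated_sites")) annotated_sites$sites
        else as.data.frame(annotated_sites)
  if (!"category" %in% names(df)) stop("sites must carry a `category` column")
  out <- df[df$category != "promoter", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair enhancers with genes by TSS proximity
#'
#' Emits one link for every (enhancer, gene) pair whose TSS lies within
#' `max_dist` bp (inclusive) of the nearer site border; a TSS inside the
#' site has distance 0.  One enhancer may link several genes and one gene
#' several enhancers.
#'
#' @param enhancers Data.frame with `chrom`, `start`, `end`, optionally
#'   `site_id`, `category` and a signed intensity column
#'   (`delta_norm_maxd` or `intensity`).
#' @param genome A `dhs_genome` with at least one gene.
#' @param max_dist Maximum border-to-TSS distance in bp (inclusive).
#' @return Data.frame of class `enhancer_gene_links` with `site_id`,
#'   coordinates, `category`, `gene_id`, `distance`, `intensity`.
#' @export
link_enhancers_to_genes <- function(enhancers, genome, max_dist = 50000) {
  validate_genome(genome)
  if (nrow(genome$genes) == 0) stop("genome has no genes to link")
  check_scalar_number(max_dist, "max_dist", lower = 0)
  enh <- as.data.frame(enhancers)
  empty <- data.frame(site_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      category = character(), gene_id = character(),
                      distance = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enhancer_gene_links", "data.frame")
  if (nrow(enh) == 0) return(empty)
  if (is.null(enh$site_id)) enh$site_id <- sprintf("site_%05d",
                                                   seq_len(nrow(enh)))
  intensity <- enh$intensity %||% enh$delta_norm_maxd %||%
    rep(NA_real_, nrow(enh))
  tss <- gene_tss(genome)
  levs <- union(names(genome$chroms), unique(enh$chrom))
  tss_gr <- GenomicRanges::GRanges(factor(genome$genes$chrom, levels = levs),
                                   IRanges::IRanges(tss + 1, tss + 1))
  # Candidate pairs: TSS within the site widened by max_dist, then the exact
  # border distance decides.
  widened <- GenomicRanges::GRanges(
    factor(enh$chrom, levels = levs),
    IRanges::IRanges(pmax(1, enh$start + 1 - max_dist), enh$end + max_dist))
  hits <- GenomicRanges::findOverlaps(widened, tss_gr)
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  t0 <- tss[genome$genes$gene_id[g]]
  dist <- pmax(0, enh$start[q] - t0, t0 - (enh$end[q] - 1))
  keep <- dist <= max_dist
  out <- data.frame(site_id = enh$site_id[q][keep],
                    chrom = enh$chrom[q][keep],
                    start = enh$start[q][keep],
                    end = enh$end[q][keep],
                    category = (enh$category %||%
                                  rep(NA_character_, nrow(enh)))[q][keep],
                    gene_id = genome$genes$gene_id[g][keep],
                    distance = unname(dist[keep]),
                    intensity = intensity[q][keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("enhancer_gene_links", "data.frame")
  out
}

#' Collapse enhancer-gene links to one intensity per gene
#'
#' Converts per-link signed MaxD differences into one intensity per gene:
#' by default the signed value of the link with the largest absolute
#' intensity (`mode = "max_abs"`); `mode = "sum"` totals the signed
#' intensities instead.
#'
#' @param links An `enhancer_gene_links` data.frame.
#' @param mode `"max_abs"` (default) or `"sum"`.
#' @return Data.frame with `gene_id`, `intensity`, `n_links`, sorted by
#'   `gene_id`.
#' @export
gene_intensity_table <- function(links, mode = c("max_abs", "sum")) {
  mode <- match.arg(mode)
  links <- as.data.frame(links)
  if (nrow(links) == 0) {
    return(data.frame(gene_id = character(), intensity = numeric(),
                      n_links = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(links, links$gene_id), function(s) {
    val <- if (mode == "max_abs") {
      s$intensity[which.max(abs(s$intensity))]
    } else {
      sum(s$intensity)
    }
    data.frame(gene_id = s$gene_id[1], intensity = val,
               n_links = nrow(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation of linked genes
#'
#' One-sided hypergeometric over-representation test of a query gene list
#' against a background universe, for every set in a GMT-style collection
#' (sets are intersected with the background first), with
#' Benjamini-Hochberg correction across sets.  This open enrichment step
#' replaces proprietary pathway knowledge-base annotation.
#'
#' @param query_genes Character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes Character vector, the gene universe.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return Data.frame with `set_name`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p_value`, `bh_fdr`, sorted by increasing p (ties
#'   by set name).
#' @examples
#' bg <- sprintf("g%02d", 1:20)
#' enrich_gene_sets(bg[1:5], bg, list(s = bg[2:6]))$p_value # 76/15504
#' @export
enrich_gene_sets <- function(query_genes, background_genes, collection) {
  background_genes <- unique(background_genes)
  query_genes <- unique(query_genes)
  if (length(background_genes) == 0) stop("empty background")
  if (!all(query_genes %in% background_genes)) {
    stop("query genes must be a subset of the background")
  }
  if (length(collection) == 0 || is.null(names(collection))) {
    stop("`collection` must be a named list of gene sets")
  }
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background_genes)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Overlay gene intensities with expression ratios
#'
#' Joins the per-gene intensity table with log2 expression ratios at a
#' matched condition/time point.  Genes missing from the expression data are
#' kept and flagged, not dropped.
#'
#' @param gene_table Data.frame with `gene_id` (e.g. from
#'   [gene_intensity_table()]).
#' @param expression_ratios Data.frame with `gene_id` and one or more ratio
#'   columns, or a ratio matrix with gene rownames.
#' @param ratio_col Name of the ratio column to carry over (default: the
#'   first non-`gene_id` column).
#' @return `gene_table` plus `log2_ratio` and logical `in_expression`.
#' @export
overlay_expression <- function(gene_table, expression_ratios,
                               ratio_col = NULL) {
  gene_table <- as.data.frame(gene_table)
  if (is.matrix(expression_ratios)) {
    expression_ratios <- data.frame(gene_id = rownames(expression_ratios),
                                    expression_ratios, check.names = FALSE,
                                    stringsAsFactors = FALSE)
  }
  expression_ratios <- as.data.frame(expression_ratios)
  stopifnot("gene_id" %in% names(gene_table),
            "gene_id" %in% names(expression_ratios))
  ratio_col <- ratio_col %||% setdiff(names(expression_ratios), "gene_id")[1]
  if (is.na(ratio_col) || !ratio_col %in% names(expression_ratios)) {
    stop("no ratio column found in `expression_ratios`")
  }
  if (length(intersect(gene_table$gene_id, expression_ratios$gene_id)) == 0 &&
      nrow(gene_table) > 0) {
    stop(paste0("no shared genes between intensity table and expression; ",
                "check that both use the same gene-id namespace"))
  }
  idx <- match(gene_table$gene_id, expression_ratios$gene_id)
  out <- gene_table
  out$log2_ratio <- expression_ratios[[ratio_col]][idx]
  out$in_expression <- !is.na(idx)
  out
}
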