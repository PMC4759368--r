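#' Run the enhancer-signature linkage pipeline on a fixture
#'
#' Executes the full analysis chain for one condition pair: replicate
#' concordance per condition, pairwise comparison, annotation of the sites
#' unique to the second condition, promoter exclusion to obtain enhancers,
#' enhancer-to-gene pairing by TSS distance, collapse to per-gene signed
#' intensities, and gene-set over-representation of the linked genes
#' against all genes in the genome.
#'
#' @param fixture A `dhs_fixture` (or any list with `genome`, `hotspots`,
#'   `gene_sets` of the same shape).
#' @param cond_a,cond_b Condition labels to compare; sites unique to
#'   `cond_b` drive the linkage.
#' @param alpha Significance level for the MaxD difference test.
#' @param max_dist Enhancer-to-TSS pairing distance in bp.
#' @return List of class `dhs_linkage_run` with `rc` (the two
#'   replicate-concordant sets), `comparison`, `annotated`, `enhancers`,
#'   `links`, `gene_table` and `enrichment`.
#' @export
run_linkage_pipeline <- function(fixture, cond_a = "B39d1",
                                 cond_b = "OIMd1", alpha = 0.05,
                                 max_dist = 50000) {
  stopifnot(all(c(cond_a, cond_b) %in% names(fixture$hotspots)))
  rc_a <- replicate_concordant(fixture$hotspots[[cond_a]][[1]],
                               fixture$hotspots[[cond_a]][[2]])
  rc_b <- replicate_concordant(fixture$hotspots[[cond_b]][[1]],
                               fixture$hotspots[[cond_b]][[2]])
  cmp <- compare_two(rc_a, rc_b, alpha = alpha)
  uniq_b <- cmp$sites[cmp$sites$status == "unique_b", , drop = FALSE]
  ann <- annotate_all(uniq_b, fixture$genome)
  enh <- define_enhancers(ann)
  links <- link_enhancers_to_genes(enh, fixture$genome, max_dist = max_dist)
  gene_table <- gene_intensity_table(links)
  enrichment <- if (length(fixture$gene_sets) > 0 && nrow(gene_table) > 0) {
    enrich_gene_sets(gene_table$gene_id, fixture$genome$genes$gene_id,
                     fixture$gene_sets)
  } else {
    NULL
  }
  structure(list(rc = list(a = rc_a, b = rc_b), comparison = cmp,
                 annotated = ann, enhancers = enh, links = links,
                 gene_table = gene_table, enrichment = enrichment,
                 cond_a = cond_a, cond_b = cond_b),
            class = "dhs_linkage_run")
}

#' @export
print.dhs_linkage_run <- function(x, ...) {
  cat(sprintf("<dhs_linkage_run> %s vs %s\n", x$cond_a, x$cond_b))
  cat(sprintf("  %d sites unique to %s, %d enhancers, %d links, %d genes\n",
              sum(x$comparison$sites$status == "unique_b"), x$cond_b,
              nrow(x$enhancers), nrow(x$links), nrow(x$gene_table)))
  if (!is.null(x$enrichment)) {
    cat("  top set:", x$enrichment$set_name[1],
        sprintf("(p = %.3g)\n", x$enrichment$p_value[1]))
  }
  invisible(x)
}
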