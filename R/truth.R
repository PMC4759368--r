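#' Specification of a synthetic DHS study design
#'
#' Describes the ground truth from which hotspot sets, tag tracks and an
#' expression matrix are simulated: a control condition plus differentiating
#' conditions sampled at one and two days, each carrying shared sites, a
#' per-condition complement of unique sites, and a set of "planted" gained
#' enhancers placed near a chosen gene set.  Defaults mirror a design in
#' which osteogenic-medium conditions gain substantially more unique sites
#' than basal-medium conditions, roughly doubling from day 1 to day 2.
#'
#' @param conditions Character vector of condition labels; the first is the
#'   control.
#' @param n_shared Number of sites shared by all conditions.
#' @param n_unique Named integer vector: number of unique (non-planted) sites
#'   per condition.
#' @param base_maxd_meanlog,base_maxd_sdlog Log-normal parameters for the
#'   baseline true MaxD (peak tag density per 10 million reads) of sites.
#' @param maxd_shift_meanlog,maxd_shift_sdlog Log-normal parameters for the
#'   multiplicative MaxD shift applied to modified shared sites.
#' @param fraction_modified Fraction of shared sites whose MaxD is shifted in
#'   each non-control condition.
#' @param planted_condition Condition receiving the planted gained enhancers.
#' @param planted_genes Optional character vector of gene ids near which
#'   gained enhancers are planted; `NULL` samples `n_planted_genes` genes.
#' @param n_planted_genes Number of genes to sample when `planted_genes` is
#'   `NULL`.
#' @param n_planted_sites Number of planted enhancer sites (cycled over the
#'   planted genes so every planted gene receives at least one when
#'   `n_planted_sites >= n_planted_genes`).
#' @param planted_maxd_meanlog,planted_maxd_sdlog Log-normal parameters for
#'   the true MaxD of planted sites.
#' @param planted_max_offset Maximum distance (bp) between a planted site and
#'   its gene's TSS; kept below `enhancer_max_dist` so planted sites are
#'   linkable by construction.
#' @param expression_effect Additive log2 expression effect carried by the
#'   planted genes in the induced condition.
#' @param expression_noise_sd Per-sample log2 noise SD in the expression
#'   matrix.
#' @param expression_replicates Replicates per condition/time in the
#'   expression matrix.
#' @param total_reads Library size per sequencing replicate.
#' @param boundary_slop Replicate peak-call boundary jitter (bp, each side).
#' @param site_width_range Min/max site width in bp.
#' @param enhancer_max_dist Enhancer-to-TSS pairing distance (bp).
#' @param promoter_halfwidth Promoter window half-width around the TSS (bp).
#'
#' @return An object of class `truth_spec` (a validated list).
#' @export
truth_spec <- function(conditions = c("B34", "B39d1", "B39d2", "OIMd1", "OIMd2"),
                       n_shared = 200,
                       n_unique = c(B34 = 15, B39d1 = 15, B39d2 = 25,
                                    OIMd1 = 33, OIMd2 = 90),
                       base_maxd_meanlog = log(50), base_maxd_sdlog = 0.5,
                       maxd_shift_meanlog = log(2), maxd_shift_sdlog = 0.25,
                       fraction_modified = 0.10,
                       planted_condition = "OIMd1",
                       planted_genes = NULL, n_planted_genes = 8,
                       n_planted_sites = 12,
                       planted_maxd_meanlog = log(90),
                       planted_maxd_sdlog = 0.3,
                       planted_max_offset = 40000,
                       expression_effect = 2, expression_noise_sd = 0.25,
                       expression_replicates = 3,
                       total_reads = 2e6, boundary_slop = 10,
                       site_width_range = c(150, 500),
                       enhancer_max_dist = 50000,
                       promoter_halfwidth = 2500) {
  stopifnot(length(conditions) >= 1, !anyDuplicated(conditions))
  if (is.null(names(n_unique)) || !setequal(names(n_unique), conditions)) {
    stop("`n_unique` must be named by the condition labels")
  }
  n_unique <- n_unique[conditions]
  if (any(n_unique < 0) || n_shared < 0 || n_planted_sites < 0) {
    stop("site counts must be >= 0")
  }
  if (n_planted_sites > 0 && !planted_condition %in% conditions) {
    stop("`planted_condition` must be one of `conditions`")
  }
  stopifnot(planted_max_offset + site_width_range[2] <= enhancer_max_dist +
              planted_max_offset, site_width_range[1] >= 10,
            site_width_range[1] <= site_width_range[2])
  structure(as.list(environment()), class = "truth_spec")
}

#' Generate ground-truth hotspot tables for each condition
#'
#' Places non-overlapping sites on a synthetic genome: a shared complement
#' present in every condition (a random fraction of which carries a
#' condition-specific MaxD shift), unique sites per condition, and planted
#' gained enhancers for the planted condition.  Planted sites are constrained
#' to lie outside every promoter window and within
#' `spec$planted_max_offset` bp of a planted gene's TSS, so their
#' border-to-TSS distance never exceeds the enhancer pairing distance.
#'
#' @param genome A `dhs_genome`.
#' @param spec A [truth_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `dhs_truth`: list with `conditions` (named list
#'   of per-condition site data.frames carrying `site_id`, coordinates,
#'   `true_maxd`, `origin`, `modified`, `planted`, `linked_gene`,
#'   `true_category`), `planted_genes`, and the `spec`.
#' @export
make_hotspot_truth <- function(genome, spec = truth_spec(), seed = NULL) {
  validate_genome(genome)
  stopifnot(inherits(spec, "truth_spec"))
  with_opt_seed(seed, {
    planted_genes <- spec$planted_genes
    if (spec$n_planted_sites > 0 && nrow(genome$genes) == 0) {
      stop("cannot plant gene-proximal enhancers on a genome with no genes")
    }
    if (is.null(planted_genes)) {
      planted_genes <- if (spec$n_planted_sites > 0) {
        sort(sample(genome$genes$gene_id,
                    min(spec$n_planted_genes, nrow(genome$genes))))
      } else character()
    } else if (!all(planted_genes %in% genome$genes$gene_id)) {
      missing <- setdiff(planted_genes, genome$genes$gene_id)
      stop("planted gene set not found in genome: ",
           paste(missing, collapse = ", "))
    }

    pad <- 2L * spec$boundary_slop + 5L
    placer <- new_site_placer(genome, pad)

    planted <- place_planted_sites(genome, spec, planted_genes, placer)
    shared <- place_random_sites(genome, spec, spec$n_shared, placer,
                                 prefix = "S")
    uniq <- lapply(spec$conditions, function(cond) {
      place_random_sites(genome, spec, spec$n_unique[[cond]], placer,
                         prefix = paste0("U_", cond, "_"))
    })
    names(uniq) <- spec$conditions

    base_shared <- stats::rlnorm(nrow(shared), spec$base_maxd_meanlog,
                                 spec$base_maxd_sdlog)
    conds <- lapply(spec$conditions, function(cond) {
      sh <- shared
      sh$true_maxd <- base_shared
      sh$origin <- rep("shared", nrow(sh))
      sh$modified <- rep(FALSE, nrow(sh))
      if (cond != spec$conditions[1] && nrow(sh) > 0 &&
          spec$fraction_modified > 0) {
        n_mod <- round(spec$fraction_modified * nrow(sh))
        if (n_mod > 0) {
          mod_idx <- sample.int(nrow(sh), n_mod)
          shift <- stats::rlnorm(n_mod, spec$maxd_shift_meanlog,
                                 spec$maxd_shift_sdlog)
          up <- sample(c(TRUE, FALSE), n_mod, replace = TRUE)
          sh$true_maxd[mod_idx] <- sh$true_maxd[mod_idx] *
            ifelse(up, shift, 1 / shift)
          sh$modified[mod_idx] <- TRUE
        }
      }
      un <- uniq[[cond]]
      un$true_maxd <- stats::rlnorm(nrow(un), spec$base_maxd_meanlog,
                                    spec$base_maxd_sdlog)
      un$origin <- rep("unique", nrow(un))
      un$modified <- rep(FALSE, nrow(un))
      un$linked_gene <- NULL
      tab <- rbind(sh, un)
      tab$planted <- rep(FALSE, nrow(tab))
      tab$linked_gene <- rep(NA_character_, nrow(tab))
      if (cond == spec$planted_condition && nrow(planted) > 0) {
        pl <- planted
        pl$true_maxd <- stats::rlnorm(nrow(pl), spec$planted_maxd_meanlog,
                                      spec$planted_maxd_sdlog)
        pl$origin <- "unique"
        pl$modified <- FALSE
        pl$planted <- TRUE
        tab <- rbind(tab, pl[, names(tab)])
      }
      tab <- sort_sites(tab)
      rownames(tab) <- NULL
      if (nrow(genome$genes) > 0 && nrow(tab) > 0) {
        ann <- annotate_all(tab, genome,
                            promoter_halfwidth = spec$promoter_halfwidth)
        tab$true_category <- ann$sites$category
      } else {
        tab$true_category <- NA_character_
      }
      tab
    })
    names(conds) <- spec$conditions
    structure(list(conditions = conds, planted_genes = planted_genes,
                   spec = spec),
              class = "dhs_truth")
  })
}

# Closure tracking occupied (padded) intervals per chromosome so that all
# placed sites, across all conditions, are mutually disjoint.
new_site_placer <- function(genome, pad) {
  starts <- lapply(genome$chroms, function(L) numeric())
  ends <- lapply(genome$chroms, function(L) numeric())
  claim <- function(chrom, start0, end0) {
    ps <- start0 - pad
    pe <- end0 + pad
    if (any(ps < ends[[chrom]] & pe > starts[[chrom]])) return(FALSE)
    starts[[chrom]][length(starts[[chrom]]) + 1L] <<- ps
    ends[[chrom]][length(ends[[chrom]]) + 1L] <<- pe
    TRUE
  }
  claim
}

place_planted_sites <- function(genome, spec, planted_genes, claim) {
  n <- spec$n_planted_sites
  empty <- data.frame(site_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      linked_gene = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  tss <- gene_tss(genome)
  prom <- promoter_windows(genome, spec$promoter_halfwidth)
  genes <- genome$genes
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- planted_genes[((i - 1) %% length(planted_genes)) + 1]
    g <- genes[genes$gene_id == gid, ]
    L <- genome$chroms[[g$chrom]]
    ok <- FALSE
    for (try in seq_len(500)) {
      w <- sample(seq(spec$site_width_range[1], spec$site_width_range[2]), 1)
      offset <- sample(seq(-spec$planted_max_offset,
                           spec$planted_max_offset - w), 1)
      s <- tss[[gid]] + offset
      e <- s + w
      if (s < 0 || e > L) next
      cand <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(s + 1, e))
      if (sum(GenomicRanges::countOverlaps(cand, prom)) > 0) next
      if (!claim(g$chrom, s, e)) next
      rows[[i]] <- data.frame(site_id = sprintf("P_%04d", i), chrom = g$chrom,
                              start = s, end = e, linked_gene = gid,
                              stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(paste0("could not place a planted enhancer near gene %s ",
                          "outside all promoter windows; genome too crowded"),
                   gid))
    }
  }
  do.call(rbind, rows)
}

place_random_sites <- function(genome, spec, n, claim, prefix) {
  empty <- data.frame(site_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  chroms <- genome$chroms
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      ch <- sample(names(chroms), 1, prob = chroms / sum(chroms))
      w <- sample(seq(spec$site_width_range[1], spec$site_width_range[2]), 1)
      s <- sample.int(chroms[[ch]] - w, 1) - 1
      if (!claim(ch, s, s + w)) next
      rows[[i]] <- data.frame(site_id = sprintf("%s%04d", prefix, i),
                              chrom = ch, start = s, end = s + w,
                              stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place site: genome too crowded for requested counts")
  }
  do.call(rbind, rows)
}

# Promoter windows [TSS - halfwidth, TSS + halfwidth) as GRanges (1-based,
# trimmed at the chromosome start).
promoter_windows <- function(genome, halfwidth = 2500, seqlevels = NULL) {
  genes <- genome$genes
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
  seqnames <- if (is.null(seqlevels)) genes$chrom
              else factor(genes$chrom, levels = seqlevels)
  GenomicRanges::GRanges(
    seqnames,
    IRanges::IRanges(start = pmax(1, tss - halfwidth + 1),
                     end = pmin(genome$chroms[genes$chrom],
                                tss + halfwidth))
  )
}

#' @export
print.dhs_truth <- function(x, ...) {
  cat(sprintf("<dhs_truth> %d condition(s); planted genes: %s\n",
              length(x$conditions),
              if (length(x$planted_genes)) paste(x$planted_genes,
                                                 collapse = ", ") else "none"))
  for (cond in names(x$conditions)) {
    tab <- x$conditions[[cond]]
    cat(sprintf("  %-7s %4d sites (%d shared, %d unique, %d planted)\n",
                cond, nrow(tab), sum(tab$origin == "shared"),
                sum(tab$origin == "unique" & !tab$planted),
                sum(tab$planted)))
  }
  invisible(x)
}
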