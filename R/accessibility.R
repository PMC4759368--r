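#' Depth-normalize maximal tag densities
#'
#' Scales raw per-bp peak tag counts (MaxD) to a common depth of 10 million
#' reads so that values are comparable across libraries.
#'
#' @param raw_maxd Non-negative integer vector of raw peak tag counts.
#' @param total_reads Library size (> 0).
#' @return Numeric vector `raw_maxd * 1e7 / total_reads`.
#' @examples
#' normalize_maxd(12, 5e6) # 24
#' @export
normalize_maxd <- function(raw_maxd, total_reads) {
  if (any(total_reads <= 0)) stop("`total_reads` must be > 0")
  if (any(raw_maxd < 0)) stop("`raw_maxd` must be >= 0")
  raw_maxd * 1e7 / total_reads
}

#' Construct a hotspot set
#'
#' A hotspot set is one sample's DHS peak calls: 0-based half-open intervals
#' with the raw peak tag count (`raw_maxd`), the library size, and the
#' depth-normalized density `norm_maxd = raw_maxd * 1e7 / total_reads`.
#'
#' @param sites Data.frame with columns `chrom`, `start`, `end`, `raw_maxd`
#'   and optionally `site_id` (generated if absent) and `peak` (0-based
#'   position of the peak bp).
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"B34"`, `"OIMd1"`).
#' @param total_reads Library size (> 0).
#' @return An object of class `hotspot_set`.
#' @export
hotspot_set <- function(sites, sample_id, condition, total_reads) {
  check_scalar_number(total_reads, "total_reads", lower = 1)
  sites <- as.data.frame(sites)
  req <- c("chrom", "start", "end", "raw_maxd")
  if (!all(req %in% names(sites))) {
    stop("`sites` must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(sites) > 0) {
    if (any(sites$start >= sites$end)) stop("site with start >= end")
    if (any(sites$raw_maxd < 0)) stop("negative raw_maxd")
  }
  if (is.null(sites$site_id)) {
    sites$site_id <- sprintf("%s_%05d", sample_id, seq_len(nrow(sites)))
  }
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in hotspot set")
  if (is.null(sites$peak)) sites$peak <- interval_mid0(sites$start, sites$end)
  sites <- sort_sites(sites)
  rownames(sites) <- NULL
  sites$norm_maxd <- normalize_maxd(sites$raw_maxd, total_reads)
  structure(list(sites = sites, sample_id = sample_id, condition = condition,
                 total_reads = total_reads),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<%s> %s (%s): %d sites, %g reads\n",
              class(x)[1], x$sample_id, x$condition, nrow(x$sites),
              sum(x$total_reads)))
  invisible(x)
}

# Per-site counts and pooled depth used by the differential test.
site_counts <- function(x) UseMethod("site_counts")

#' @export
site_counts.hotspot_set <- function(x) {
  list(count = x$sites$raw_maxd, depth = x$total_reads)
}

#' @export
site_counts.rc_set <- function(x) {
  list(count = x$sites$raw_maxd_1 + x$sites$raw_maxd_2,
       depth = sum(x$total_reads))
}

#' Replicate-concordant hotspot set
#'
#' Intersects two biological replicates of the same condition: only sites
#' supported by both replicates (>= 1 bp overlap under half-open semantics)
#' are retained, each concordant site being the union of the overlapping
#' replicate intervals.  The concordant normalized MaxD is the mean of the
#' two replicates' normalized values; the raw replicate counts are carried
#' along for downstream significance testing.
#'
#' @param set_rep1,set_rep2 [hotspot_set()] objects from the same condition.
#' @return An object of class `rc_set` whose `sites` carry `raw_maxd_1`,
#'   `raw_maxd_2`, `norm_maxd` and `peak`; `total_reads` is the named
#'   length-2 vector of replicate library sizes.
#' @export
replicate_concordant <- function(set_rep1, set_rep2) {
  stopifnot(inherits(set_rep1, "hotspot_set"), inherits(set_rep2, "hotspot_set"))
  if (!identical(set_rep1$condition, set_rep2$condition)) {
    stop(sprintf("replicates come from different conditions: '%s' vs '%s'",
                 set_rep1$condition, set_rep2$condition))
  }
  levs <- union(unique(set_rep1$sites$chrom), unique(set_rep2$sites$chrom))
  g1 <- as_granges0(set_rep1$sites, seqlevels = levs)
  g2 <- as_granges0(set_rep2$sites, seqlevels = levs)
  ov <- GenomicRanges::findOverlaps(g1, g2)
  cond <- set_rep1$condition
  reads <- c(rep1 = unname(set_rep1$total_reads),
             rep2 = unname(set_rep2$total_reads))
  if (length(ov) == 0) {
    sites <- data.frame(site_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        raw_maxd_1 = numeric(), raw_maxd_2 = numeric(),
                        peak = numeric(), norm_maxd = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    i1 <- unique(S4Vectors::queryHits(ov))
    i2 <- unique(S4Vectors::subjectHits(ov))
    involved <- rbind(set_rep1$sites[i1, c("chrom", "start", "end")],
                      set_rep2$sites[i2, c("chrom", "start", "end")])
    merged <- GenomicRanges::reduce(as_granges0(involved), min.gapwidth = 0L)
    m1 <- GenomicRanges::findOverlaps(merged, g1)
    m2 <- GenomicRanges::findOverlaps(merged, g2)
    max_by <- function(hits, values, n) {
      out <- numeric(n)
      agg <- tapply(values[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), max)
      out[as.integer(names(agg))] <- agg
      out
    }
    n <- length(merged)
    raw1 <- max_by(m1, set_rep1$sites$raw_maxd, n)
    raw2 <- max_by(m2, set_rep2$sites$raw_maxd, n)
    # Peak position taken from each replicate's deepest contributing site.
    pk <- function(hits, sites, n) {
      out <- rep(NA_real_, n)
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      for (grp in split(seq_along(q), q)) {
        j <- s[grp][which.max(sites$raw_maxd[s[grp]])]
        out[q[grp[1]]] <- sites$peak[j]
      }
      out
    }
    peak1 <- pk(m1, set_rep1$sites, n)
    peak2 <- pk(m2, set_rep2$sites, n)
    sites <- data.frame(
      site_id = sprintf("%s_rc_%05d", cond, seq_len(n)),
      chrom = as.character(GenomicRanges::seqnames(merged)),
      start = GenomicRanges::start(merged) - 1,
      end = GenomicRanges::end(merged),
      raw_maxd_1 = raw1, raw_maxd_2 = raw2,
      peak = ifelse(raw1 >= raw2, peak1, peak2),
      stringsAsFactors = FALSE
    )
    sites$norm_maxd <- (normalize_maxd(raw1, reads[["rep1"]]) +
                          normalize_maxd(raw2, reads[["rep2"]])) / 2
    sites <- sort_sites(sites)
    rownames(sites) <- NULL
  }
  structure(list(sites = sites,
                 sample_id = paste(set_rep1$sample_id, set_rep2$sample_id,
                                   sep = "+"),
                 condition = cond, total_reads = reads),
            class = c("rc_set", "hotspot_set"))
}

#' Exact conditional test for a MaxD difference
#'
#' Tests whether the peak tag counts of a site differ between two libraries
#' beyond what their sequencing depths explain.  Conditional on the total
#' `n = count_a + count_b`, `count_a` is Binomial(n, depth_a / (depth_a +
#' depth_b)) under the null of equal underlying density; the two-sided exact
#' binomial p-value (minimum-likelihood method, as in [stats::binom.test()])
#' is returned.  `n = 0` yields p = 1.
#'
#' @param count_a,count_b Non-negative integer peak counts (vectorized).
#' @param depth_a,depth_b Library sizes (> 0).
#' @param alpha Significance level for the `significant` flag.
#' @return Data.frame with `p_value` and `significant`.
#' @examples
#' maxd_difference_test(30, 1e7, 0, 1e7)$p_value # 2 * 0.5^30
#' @export
maxd_difference_test <- function(count_a, depth_a, count_b, depth_b,
                                 alpha = 0.05) {
  if (any(depth_a <= 0) || any(depth_b <= 0)) stop("depths must be > 0")
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be >= 0")
  m <- max(length(count_a), length(count_b))
  count_a <- rep_len(as.numeric(count_a), m)
  count_b <- rep_len(as.numeric(count_b), m)
  pr <- rep_len(depth_a / (depth_a + depth_b), m)
  n <- count_a + count_b
  p <- rep(1, m)
  idx <- which(n > 0)
  if (length(idx) > 0) {
    p[idx] <- vapply(idx, function(i) {
      stats::binom.test(count_a[i], n[i], pr[i])$p.value
    }, numeric(1))
  }
  data.frame(p_value = p, significant = p < alpha)
}

# ---------------------------------------------------------------------------
# Venn partitions

# membership: data.frame(set, site_id, region); counts over region labels.
new_venn_partition <- function(membership, n_sets) {
  regions <- venn_region_names(n_sets)
  membership$region <- factor(membership$region, levels = regions)
  counts <- table(membership$region)
  structure(list(n_sets = n_sets, membership = membership,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "venn_partition")
}

venn_region_names <- function(n_sets) {
  if (n_sets == 2) c("a_only", "b_only", "ab")
  else c("a_only", "b_only", "c_only", "ab", "ac", "bc", "abc")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d sets\n", x$n_sets))
  print(x$counts)
  invisible(x)
}

region_label <- function(in_a, in_b, in_c = NULL) {
  if (is.null(in_c)) {
    ifelse(in_a & in_b, "ab", ifelse(in_a, "a_only", "b_only"))
  } else {
    tag <- paste0(ifelse(in_a, "a", ""), ifelse(in_b, "b", ""),
                  ifelse(in_c, "c", ""))
    ifelse(nchar(tag) == 1, paste0(tag, "_only"), tag)
  }
}

# ---------------------------------------------------------------------------

#' Pairwise comparison of two hotspot sets
#'
#' Partitions two (typically replicate-concordant) hotspot sets into unique
#' and common sites by >= 1 bp interval overlap, and for every common
#' cluster (all mutually overlapping sites merged into one interval spanning
#' their union, counts summed per side) computes the signed difference in
#' depth-normalized MaxD together with an exact conditional binomial
#' p-value.  Unique sites are tested against a zero count on the other side.
#'
#' @param set_a,set_b [hotspot_set()] or `rc_set` objects.
#' @param alpha Significance level; common sites with `p < alpha` are
#'   `common_modified`, the rest `common_unchanged`.
#' @param p_adjust `"none"` (default) or `"BH"` to apply Benjamini-Hochberg
#'   correction across all tested sites before flagging significance.
#' @return An object of class `dhs_comparison`: list with `venn` (a
#'   `venn_partition` assigning every input site of either set to `a_only`,
#'   `b_only` or `ab`) and `sites`, the differential-site table with columns
#'   `chrom`, `start`, `end`, `peak`, per-side counts and normalized MaxD,
#'   `delta_norm_maxd` (b minus a), `p_value`, `status` in
#'   `unique_a`/`unique_b`/`common_modified`/`common_unchanged`, and the
#'   contributing site ids.
#' @export
compare_two <- function(set_a, set_b, alpha = 0.05,
                        p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(set_a, "hotspot_set"), inherits(set_b, "hotspot_set"))
  sa <- set_a$sites
  sb <- set_b$sites
  ca <- site_counts(set_a)
  cb <- site_counts(set_b)
  levs <- union(unique(sa$chrom), unique(sb$chrom))
  ga <- as_granges0(sa, seqlevels = levs)
  gb <- as_granges0(sb, seqlevels = levs)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  in_b <- seq_along(ga) %in% S4Vectors::queryHits(ov)
  in_a <- seq_along(gb) %in% S4Vectors::subjectHits(ov)
  membership <- rbind(
    data.frame(set = "a", site_id = sa$site_id,
               region = region_label(TRUE, in_b),
               stringsAsFactors = FALSE),
    data.frame(set = "b", site_id = sb$site_id,
               region = region_label(in_a, TRUE),
               stringsAsFactors = FALSE)
  )
  venn <- new_venn_partition(membership, 2)

  rows <- list()
  # Common clusters: union intervals over connected overlapping sites.
  if (length(ov) > 0) {
    ia <- unique(S4Vectors::queryHits(ov))
    ib <- unique(S4Vectors::subjectHits(ov))
    involved <- rbind(sa[ia, c("chrom", "start", "end")],
                      sb[ib, c("chrom", "start", "end")])
    merged <- GenomicRanges::reduce(as_granges0(involved), min.gapwidth = 0L)
    ma <- GenomicRanges::findOverlaps(merged, ga)
    mb <- GenomicRanges::findOverlaps(merged, gb)
    sum_by <- function(hits, values, n) {
      out <- numeric(n)
      agg <- tapply(values[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      out[as.integer(names(agg))] <- agg
      out
    }
    ids_by <- function(hits, ids, n) {
      out <- character(n)
      agg <- tapply(ids[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) paste(x, collapse = ","))
      out[as.integer(names(agg))] <- agg
      out
    }
    n <- length(merged)
    cnt_a <- sum_by(ma, ca$count, n)
    cnt_b <- sum_by(mb, cb$count, n)
    pk_a <- sum_by(ma, sa$peak * sa$norm_maxd, n) /
      pmax(sum_by(ma, sa$norm_maxd, n), .Machine$double.eps)
    rows$common <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(merged)),
      start = GenomicRanges::start(merged) - 1,
      end = GenomicRanges::end(merged),
      peak = round(pk_a),
      site_ids_a = ids_by(ma, sa$site_id, n),
      site_ids_b = ids_by(mb, sb$site_id, n),
      count_a = cnt_a, count_b = cnt_b,
      status = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  uniq_row <- function(s, side) {
    if (nrow(s) == 0) return(NULL)
    data.frame(chrom = s$chrom, start = s$start, end = s$end, peak = s$peak,
               site_ids_a = if (side == "a") s$site_id else "",
               site_ids_b = if (side == "b") s$site_id else "",
               count_a = if (side == "a") s$.count else 0,
               count_b = if (side == "b") s$.count else 0,
               status = paste0("unique_", side),
               stringsAsFactors = FALSE)
  }
  sa$.count <- ca$count
  sb$.count <- cb$count
  rows$ua <- uniq_row(sa[!in_b, , drop = FALSE], "a")
  rows$ub <- uniq_row(sb[!in_a, , drop = FALSE], "b")
  diff <- do.call(rbind, rows)
  if (is.null(diff)) {
    diff <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), peak = numeric(),
                       site_ids_a = character(), site_ids_b = character(),
                       count_a = numeric(), count_b = numeric(),
                       status = character(), stringsAsFactors = FALSE)
  }
  diff$norm_maxd_a <- normalize_maxd(diff$count_a, ca$depth)
  diff$norm_maxd_b <- normalize_maxd(diff$count_b, cb$depth)
  diff$delta_norm_maxd <- diff$norm_maxd_b - diff$norm_maxd_a
  tst <- maxd_difference_test(diff$count_a, ca$depth, diff$count_b, cb$depth,
                              alpha = alpha)
  diff$p_value <- tst$p_value
  sig <- if (p_adjust == "BH") {
    stats::p.adjust(diff$p_value, method = "BH") < alpha
  } else {
    diff$p_value < alpha
  }
  common <- is.na(diff$status)
  diff$status[common] <- ifelse(sig[common], "common_modified",
                                "common_unchanged")
  diff <- sort_sites(diff)
  rownames(diff) <- NULL
  structure(list(venn = venn, sites = diff,
                 condition_a = set_a$condition, condition_b = set_b$condition,
                 depth_a = ca$depth, depth_b = cb$depth, alpha = alpha),
            class = "dhs_comparison")
}

#' @export
print.dhs_comparison <- function(x, ...) {
  cat(sprintf("<dhs_comparison> %s vs %s: %d differential rows\n",
              x$condition_a, x$condition_b, nrow(x$sites)))
  print(table(x$sites$status))
  invisible(x)
}

#' Three-way comparison of hotspot sets
#'
#' Assigns every site of each set to exactly one of the seven Venn regions
#' according to which of the other two sets it overlaps (>= 1 bp).
#'
#' @param set_a,set_b,set_c [hotspot_set()] or `rc_set` objects.
#' @return List of class `dhs_comparison3` with `venn` (7-region
#'   `venn_partition`) and `unique` (named list of the per-set unique site
#'   tables).
#' @export
compare_three <- function(set_a, set_b, set_c) {
  sets <- list(a = set_a, b = set_b, c = set_c)
  stopifnot(all(vapply(sets, inherits, logical(1), "hotspot_set")))
  levs <- unique(unlist(lapply(sets, function(s) s$sites$chrom)))
  grs <- lapply(sets, function(s) as_granges0(s$sites, seqlevels = levs))
  hit <- function(x, y) GenomicRanges::countOverlaps(x, y) > 0
  mem <- list()
  for (nm in names(sets)) {
    others <- setdiff(names(sets), nm)
    flags <- list(a = NULL, b = NULL, c = NULL)
    flags[[nm]] <- rep(TRUE, length(grs[[nm]]))
    for (o in others) flags[[o]] <- hit(grs[[nm]], grs[[o]])
    mem[[nm]] <- data.frame(set = nm, site_id = sets[[nm]]$sites$site_id,
                            region = region_label(flags$a, flags$b, flags$c),
                            stringsAsFactors = FALSE)
  }
  membership <- do.call(rbind, mem)
  rownames(membership) <- NULL
  venn <- new_venn_partition(membership, 3)
  uniq <- lapply(names(sets), function(nm) {
    ids <- membership$site_id[membership$set == nm &
                                membership$region == paste0(nm, "_only")]
    s <- sets[[nm]]$sites
    s[s$site_id %in% ids, , drop = FALSE]
  })
  names(uniq) <- vapply(sets, function(s) s$condition, character(1))
  structure(list(venn = venn, unique = uniq,
                 conditions = names(uniq)),
            class = "dhs_comparison3")
}

#' Select the most changed TSS-proximal sites
#'
#' Restricts differential sites to those intersecting `tss_flank` bp either
#' side of any TSS, ranks them by decreasing absolute normalized MaxD
#' change, and returns the top `n` (ties broken by chromosome then start).
#'
#' @param diff_sites Data.frame with `chrom`, `start`, `end` and
#'   `delta_norm_maxd` (e.g. the `sites` table of [compare_two()]).
#' @param genome A `dhs_genome`.
#' @param n Maximum number of sites to return.
#' @param tss_flank Half-width (bp) of the TSS window.
#' @return The selected rows of `diff_sites`, ranked.
#' @export
top_changed_sites <- function(diff_sites, genome, n = 1500,
                              tss_flank = 1000) {
  validate_genome(genome)
  diff_sites <- as.data.frame(diff_sites)
  if (nrow(diff_sites) == 0) return(diff_sites)
  tss <- gene_tss(genome)
  levs <- union(names(genome$chroms), unique(diff_sites$chrom))
  win <- GenomicRanges::GRanges(
    factor(genome$genes$chrom, levels = levs),
    IRanges::IRanges(pmax(1, tss - tss_flank + 1), tss + tss_flank))
  keep <- GenomicRanges::countOverlaps(as_granges0(diff_sites,
                                                   seqlevels = levs),
                                       win) > 0
  sel <- diff_sites[keep, , drop = FALSE]
  ord <- order(-abs(sel$delta_norm_maxd), sel$chrom, sel$start)
  out <- sel[utils::head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export fixed-width windows around site peaks for motif discovery
#'
#' One window per site, centred on the site's peak bp (interval midpoint
#' when no peak is recorded), of exactly `width` bp unless clipping at a
#' chromosome boundary shortens it (such windows are flagged).
#'
#' @param sites Data.frame with `chrom`, `start`, `end`, optionally `peak`
#'   and `site_id`.
#' @param genome A `dhs_genome` (for chromosome bounds).
#' @param width Window width in bp; must be a positive even number.
#' @return Data.frame with `site_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
export_motif_windows <- function(sites, genome, width = 200) {
  validate_genome(genome)
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0) stop("`sites` is empty")
  check_scalar_number(width, "width", lower = 2)
  if (width %% 2 != 0) stop("`width` must be even")
  if (!all(sites$chrom %in% names(genome$chroms))) {
    stop("site on unknown chromosome: ",
         paste(setdiff(unique(sites$chrom), names(genome$chroms)),
               collapse = ", "))
  }
  centre <- if (!is.null(sites$peak) && !anyNA(sites$peak)) {
    sites$peak
  } else {
    interval_mid0(sites$start, sites$end)
  }
  half <- width / 2
  s <- centre - half
  e <- centre + half
  lens <- genome$chroms[sites$chrom]
  clipped <- s < 0 | e > lens
  out <- data.frame(
    site_id = sites$site_id %||% sprintf("site_%05d", seq_len(nrow(sites))),
    chrom = sites$chrom,
    start = pmax(0, s),
    end = pmin(lens, e),
    clipped = unname(clipped),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
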