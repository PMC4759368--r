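#' Simulate per-bp tag pileups and replicate peak calls for one condition
#'
#' Given a ground-truth site table, draws per-bp cut counts inside each site
#' from a Poisson whose mean follows a triangular profile peaking at the site
#' centre, with the peak mean equal to `true_maxd * total_reads / 1e7`
#' (so that the raw maximal density is calibrated to the stated per-10M
#' value).  The remaining library mass is scattered uniformly as background
#' so the track total is approximately `total_reads` up to Poisson error.
#' Each replicate is an independent realization; its peak calls reproduce the
#' true intervals with boundaries jittered by at most `slop` bp.
#'
#' @param truth_sites Data.frame with `site_id`, `chrom`, `start`, `end`,
#'   `true_maxd` (0-based half-open coordinates); typically one element of
#'   [make_hotspot_truth()]'s `conditions`.
#' @param chroms Named numeric vector of chromosome lengths (bp).
#' @param total_reads Library size per replicate (> 0).
#' @param condition Condition label stored in the returned sets.
#' @param seed Optional integer seed.
#' @param slop Maximum boundary jitter (bp) of replicate peak calls.
#' @param n_replicates Number of replicates to simulate.
#' @param build_track If `TRUE`, also return the replicate-1 pileup as a
#'   run-length encoded bedGraph-style data.frame (zero runs omitted).
#' @param edge_frac Ratio of the Poisson mean at a site edge to its peak.
#'
#' @return List with `replicates` (list of [hotspot_set()] objects, one per
#'   replicate, whose sites carry `raw_maxd` and the 0-based `peak` position)
#'   and `track` (data.frame `chrom`,`start`,`end`,`count`, or `NULL`).
#' @export
simulate_tags <- function(truth_sites, chroms, total_reads, condition = "cond",
                          seed = NULL, slop = 10, n_replicates = 2,
                          build_track = TRUE, edge_frac = 0.3) {
  check_scalar_number(total_reads, "total_reads", lower = 1)
  stopifnot(is.numeric(chroms), !is.null(names(chroms)), all(chroms > 0))
  sites <- sort_sites(as.data.frame(truth_sites))
  if (nrow(sites) > 0 && !all(sites$chrom %in% names(chroms))) {
    stop("truth site on unknown chromosome")
  }
  with_opt_seed(seed, {
    depth_scale <- total_reads / 1e7
    lambdas <- lapply(seq_len(nrow(sites)), function(i) {
      w <- sites$end[i] - sites$start[i]
      peak <- sites$true_maxd[i] * depth_scale
      rel <- 1 - abs(seq_len(w) - (w + 1) / 2) / ((w + 1) / 2)
      peak * (edge_frac + (1 - edge_frac) * rel)
    })
    site_mass <- sum(vapply(lambdas, sum, numeric(1)))
    bg_lambda_total <- max(0, total_reads - site_mass)

    track <- NULL
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      pile <- lapply(chroms, function(L) integer(L))
      for (i in seq_len(nrow(sites))) {
        idx <- (sites$start[i] + 1):sites$end[i]
        pile[[sites$chrom[i]]][idx] <- pile[[sites$chrom[i]]][idx] +
          stats::rpois(length(idx), lambdas[[i]])
      }
      n_bg <- stats::rpois(1, bg_lambda_total)
      if (n_bg > 0) {
        per_chrom <- as.vector(stats::rmultinom(1, n_bg, chroms / sum(chroms)))
        for (k in seq_along(chroms)) {
          if (per_chrom[k] == 0) next
          pos <- sample.int(chroms[[k]], per_chrom[k], replace = TRUE)
          pile[[k]] <- pile[[k]] + tabulate(pos, nbins = chroms[[k]])
        }
      }
      # Replicate peak calls: true intervals with jittered boundaries.
      call <- sites[, c("site_id", "chrom", "start", "end"), drop = FALSE]
      if (nrow(call) > 0) {
        call$start <- pmax(0, call$start + sample(-slop:slop, nrow(call),
                                                  replace = TRUE))
        call$end <- pmin(chroms[call$chrom],
                         call$end + sample(-slop:slop, nrow(call),
                                           replace = TRUE))
        bad <- call$end - call$start < 10
        call$start[bad] <- sites$start[bad]
        call$end[bad] <- sites$end[bad]
        raw <- integer(nrow(call))
        peak <- numeric(nrow(call))
        for (i in seq_len(nrow(call))) {
          v <- pile[[call$chrom[i]]][(call$start[i] + 1):call$end[i]]
          raw[i] <- max(v)
          peak[i] <- call$start[i] + which.max(v) - 1
        }
        call$raw_maxd <- raw
        call$peak <- peak
      } else {
        call$raw_maxd <- integer(0)
        call$peak <- numeric(0)
      }
      reps[[r]] <- hotspot_set(call, sample_id = sprintf("%s_rep%d",
                                                         condition, r),
                               condition = condition,
                               total_reads = total_reads)
      if (r == 1 && build_track) track <- pileup_to_track(pile)
    }
    list(replicates = reps, track = track)
  })
}

# Run-length encode per-chromosome pileups into a bedGraph-style data.frame
# (0-based half-open, zero-count runs omitted).
pileup_to_track <- function(pile) {
  out <- lapply(names(pile), function(ch) {
    r <- rle(pile[[ch]])
    ends <- cumsum(r$lengths)
    keep <- r$values > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = (ends - r$lengths)[keep],
               end = ends[keep], count = r$values[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR titration-of-digestion table
#'
#' Generates Cq values for sensitive and resistant benchmark sites across a
#' DNase concentration series.  At digestion fraction `f` the surviving
#' intact template is `1 - f`, so
#' `Cq(u) = cq0 - log_efficiency(1 - f(u)) + Gaussian(0, sd_noise)`.
#' Every site receives an undigested (`dnase_units = 0`) row with fraction 0.
#'
#' @param true_fractions Named numeric vector mapping DNase concentration
#'   (units per 1e6 nuclei, the names) to the true digested fraction at
#'   sensitive sites; fractions must lie in `[0, 1)`.
#' @param efficiency Amplification efficiency per cycle, in `(1, 2]`.
#' @param cq0 Undigested (baseline) Cq.
#' @param sd_noise Gaussian Cq noise SD (0 for exact round-trips).
#' @param n_sensitive,n_resistant Number of sensitive / resistant primer
#'   sites.
#' @param n_replicates qPCR replicates per site and concentration.
#' @param resistant_leak Digested fraction of resistant sites at the highest
#'   concentration (scaled linearly in concentration; default 0).
#' @param seed Optional integer seed.
#'
#' @return A `titration_table` data.frame with columns `site_id`,
#'   `site_class` (`sensitive`/`resistant`), `dnase_units`, `replicate`,
#'   `cq`, plus the generating `true_fraction`.
#' @export
simulate_titration <- function(true_fractions, efficiency = 2, cq0 = 20,
                               sd_noise = 0.15, n_sensitive = 2,
                               n_resistant = 2, n_replicates = 3,
                               resistant_leak = 0, seed = NULL) {
  if (is.null(names(true_fractions))) {
    stop("`true_fractions` must be named by DNase concentration")
  }
  units <- as.numeric(names(true_fractions))
  fr <- as.numeric(true_fractions)
  if (any(!is.finite(units)) || any(units < 0)) {
    stop("concentrations must be non-negative numbers")
  }
  if (any(fr >= 1)) stop("fraction 1 leaves no intact template: Cq undefined")
  if (any(fr < 0)) stop("fractions must lie in [0, 1)")
  check_scalar_number(efficiency, "efficiency")
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  if (!0 %in% units) {
    units <- c(0, units)
    fr <- c(0, fr)
  }
  fr[units == 0] <- 0
  with_opt_seed(seed, {
    sites <- data.frame(
      site_id = c(sprintf("sens%d", seq_len(n_sensitive)),
                  sprintf("res%d", seq_len(n_resistant))),
      site_class = rep(c("sensitive", "resistant"),
                       c(n_sensitive, n_resistant)),
      stringsAsFactors = FALSE
    )
    umax <- max(units, 1)
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        u_idx = seq_along(units),
                        s_idx = seq_len(nrow(sites)))
    f <- ifelse(sites$site_class[grid$s_idx] == "sensitive",
                fr[grid$u_idx],
                resistant_leak * units[grid$u_idx] / umax)
    cq <- cq0 - log(1 - f, base = efficiency) +
      stats::rnorm(nrow(grid), 0, sd_noise)
    out <- data.frame(site_id = sites$site_id[grid$s_idx],
                      site_class = sites$site_class[grid$s_idx],
                      dnase_units = units[grid$u_idx],
                      replicate = grid$replicate,
                      cq = cq,
                      true_fraction = f,
                      stringsAsFactors = FALSE)
    out <- out[order(out$site_id, out$dnase_units, out$replicate), ]
    rownames(out) <- NULL
    class(out) <- c("titration_table", "data.frame")
    out
  })
}

#' Simulate an expression matrix with planted effects
#'
#' Builds a genes-by-samples intensity matrix over a differentiation time
#' course (control at time 0; basal and induced media at days 1 and 2, each
#' with replicates).  Per-gene baselines are log-normal; planted genes carry
#' an additive log2 effect in the induced-condition samples; all other
#' variation is Gaussian noise on the log2 scale.
#'
#' @param genome A `dhs_genome` providing the gene universe.
#' @param truth A `dhs_truth` providing `planted_genes` (or a character
#'   vector of gene ids).
#' @param n_replicates Replicates per condition/time point (>= 1).
#' @param effect Additive log2 shift for planted genes in induced samples.
#' @param noise_sd Log2 noise SD per sample.
#' @param induced_condition Condition label receiving the effect.
#' @param design Data.frame with columns `condition` and `time` defining the
#'   sampled condition/time points.
#' @param seed Optional integer seed.
#' @return An [expr_matrix()] object.
#' @export
simulate_expression <- function(genome, truth, n_replicates = 3, effect = 2,
                                noise_sd = 0.25, induced_condition = "OIM",
                                design = data.frame(
                                  condition = c("B34", "B39", "B39",
                                                "OIM", "OIM"),
                                  time = c(0, 1, 2, 1, 2)),
                                seed = NULL) {
  validate_genome(genome)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  planted <- if (inherits(truth, "dhs_truth")) truth$planted_genes else truth
  genes <- genome$genes$gene_id
  if (length(genes) == 0) stop("genome has no genes to express")
  with_opt_seed(seed, {
    samples <- design[rep(seq_len(nrow(design)), each = n_replicates), ,
                      drop = FALSE]
    samples$replicate <- rep(seq_len(n_replicates), nrow(design))
    samples$sample_id <- sprintf("%s_t%g_r%d", samples$condition,
                                 samples$time, samples$replicate)
    rownames(samples) <- NULL
    base <- stats::rnorm(length(genes), mean = 7, sd = 1)
    log2v <- matrix(base, nrow = length(genes), ncol = nrow(samples))
    is_planted <- genes %in% planted
    induced <- samples$condition == induced_condition
    log2v[is_planted, induced] <- log2v[is_planted, induced] + effect
    log2v <- log2v + matrix(stats::rnorm(length(log2v), 0, noise_sd),
                            nrow = nrow(log2v))
    values <- 2^log2v
    dimnames(values) <- list(genes, samples$sample_id)
    expr_matrix(values, samples[, c("sample_id", "condition", "time",
                                    "replicate")])
  })
}
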