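#' Fraction of DNA digested from a Cq pair
#'
#' Converts undigested and digested qPCR quantification cycles into the
#' digested fraction, normalizing to the undigested control:
#' `fraction = 1 - efficiency^(cq_undigested - cq_digested)`, clamped to
#' `[0, 1]`.  A missing (`NA`) digested Cq encodes "no amplification" and
#' maps to fraction 1.  Results carry a `flags` attribute (one string per
#' element, `""` when clean): `"negative dCq"` when the digested sample
#' amplified earlier than the control (clamped to 0) and
#' `"no amplification"` for the `NA` sentinel.
#'
#' @param cq_undigested,cq_digested Cq values (vectorized); `cq_digested`
#'   may be `NA` for no amplification.
#' @param efficiency Amplification efficiency per cycle, in `(1, 2]`.
#' @return Numeric vector of fractions in `[0, 1]` with a `flags` attribute.
#' @examples
#' fraction_digested(20, 22, 2) # 0.75
#' @export
fraction_digested <- function(cq_undigested, cq_digested, efficiency = 2) {
  check_scalar_number(efficiency, "efficiency")
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  m <- max(length(cq_undigested), length(cq_digested))
  cq_undigested <- rep_len(cq_undigested, m)
  cq_digested <- rep_len(cq_digested, m)
  if (anyNA(cq_undigested)) stop("undigested Cq must be finite")
  raw <- 1 - efficiency^(cq_undigested - cq_digested)
  flags <- rep("", m)
  flags[!is.na(raw) & raw < 0] <- "negative dCq"
  no_amp <- is.na(cq_digested)
  raw[no_amp] <- 1
  flags[no_amp] <- "no amplification"
  out <- pmin(1, pmax(0, raw))
  attr(out, "flags") <- flags
  out
}

#' Titration curves from a Cq table
#'
#' For each primer site, averages replicate Cq values per DNase
#' concentration, transforms the mean against the site's undigested mean
#' (`dnase_units = 0`) into a digested fraction, and propagates the
#' replicate spread through the transform numerically (SD of the
#' per-replicate fractions).
#'
#' @param table A `titration_table` data.frame (`site_id`, `site_class`,
#'   `dnase_units`, `replicate`, `cq`); every site needs a
#'   `dnase_units = 0` row.
#' @param efficiency Amplification efficiency in `(1, 2]`.
#' @return Data.frame of class `titration_curves` with `site_id`,
#'   `site_class`, `dnase_units`, `fraction`, `sd`.
#' @export
titration_curves <- function(table, efficiency = 2) {
  table <- as.data.frame(table)
  req <- c("site_id", "site_class", "dnase_units", "replicate", "cq")
  if (!all(req %in% names(table))) {
    stop("titration table must have columns: ", paste(req, collapse = ", "))
  }
  out <- lapply(split(table, table$site_id), function(s) {
    und <- s$cq[s$dnase_units == 0]
    if (length(und) == 0) {
      stop(sprintf("site '%s' has no undigested (dnase_units = 0) row",
                   s$site_id[1]))
    }
    cq0 <- mean(und)
    pts <- lapply(split(s, s$dnase_units), function(p) {
      f_mean <- as.numeric(fraction_digested(cq0, mean(p$cq), efficiency))
      f_rep <- as.numeric(fraction_digested(cq0, p$cq, efficiency))
      data.frame(site_id = p$site_id[1], site_class = p$site_class[1],
                 dnase_units = p$dnase_units[1], fraction = f_mean,
                 sd = if (length(f_rep) > 1) stats::sd(f_rep) else 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pts)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$site_id, out$dnase_units), ]
  rownames(out) <- NULL
  class(out) <- c("titration_curves", "data.frame")
  out
}

#' Select the sequencing replica from titration curves
#'
#' Averages the digested fraction over sensitive sites at each DNase
#' concentration and selects the smallest concentration whose mean
#' sensitive-site fraction falls inside `window` while the mean
#' resistant-site fraction stays at or below `resistant_max` (choosing the
#' gentlest digestion minimizes over-digestion artifacts).  When no
#' concentration qualifies, `selected_units` is `NA` and a flag is raised.
#'
#' @param curves A `titration_curves` data.frame (needs >= 1 sensitive
#'   site).
#' @param window Length-2 numeric, the target digestion window (default the
#'   70--80% optimum).
#' @param resistant_max Maximum tolerated mean fraction at resistant sites.
#' @return List of class `replica_selection`: `selected_units`, `window`,
#'   `resistant_max`, the per-concentration `summary` table, and `flags`.
#' @export
select_replica <- function(curves, window = c(0.70, 0.80),
                           resistant_max = 0.10) {
  curves <- as.data.frame(curves)
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (nrow(curves) == 0) stop("empty titration curves")
  sens <- curves[curves$site_class == "sensitive", ]
  if (nrow(sens) == 0) stop("need at least one sensitive-site curve")
  res <- curves[curves$site_class == "resistant", ]
  units <- sort(unique(curves$dnase_units))
  units <- units[units > 0]
  summary <- data.frame(
    dnase_units = units,
    sensitive_mean = vapply(units, function(u) {
      mean(sens$fraction[sens$dnase_units == u])
    }, numeric(1)),
    resistant_mean = vapply(units, function(u) {
      if (nrow(res) == 0) 0 else mean(res$fraction[res$dnase_units == u])
    }, numeric(1))
  )
  summary$in_window <- summary$sensitive_mean >= window[1] &
    summary$sensitive_mean <= window[2] &
    summary$resistant_mean <= resistant_max
  flags <- character()
  if (any(summary$resistant_mean > resistant_max)) {
    flags <- c(flags, "resistant-site digestion above threshold at some units")
  }
  if (any(summary$in_window)) {
    selected <- min(summary$dnase_units[summary$in_window])
  } else {
    selected <- NA_real_
    flags <- c(flags, "no concentration in window")
  }
  structure(list(selected_units = selected, window = window,
                 resistant_max = resistant_max, summary = summary,
                 flags = flags),
            class = "replica_selection")
}

#' @export
print.replica_selection <- function(x, ...) {
  cat(sprintf("<replica_selection> selected: %s (window %.0f-%.0f%%)\n",
              if (is.na(x$selected_units)) "none"
              else paste0(x$selected_units, "U"),
              100 * x$window[1], 100 * x$window[2]))
  print(x$summary)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
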