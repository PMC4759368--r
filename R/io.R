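# Readers and writers for the plain-text formats the pipeline consumes and
# emits.  All writers produce deterministic bytes for a given input; readers
# for BED/bedGraph go through rtracklayer and convert back to the package's
# 0-based half-open data.frames.

#' Read and write BED6 hotspot files
#'
#' The score column holds the raw MaxD and the name column the site id.
#'
#' @param sites Data.frame with `chrom`, `start`, `end`, `site_id`,
#'   `raw_maxd`.
#' @param path File path.
#' @return `read_bed6()`: data.frame with those columns.
#' @export
write_bed6 <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = as.integer(sites$start),
                   end = as.integer(sites$end), name = sites$site_id,
                   score = sites$raw_maxd, strand = ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             site_id = gr$name,
             raw_maxd = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Read and write gene models as BED12
#'
#' @param genome A `dhs_genome` (for `write_genes_bed12()`).
#' @param path File path.
#' @param chroms Named numeric vector of chromosome lengths, used to rebuild
#'   the `dhs_genome` on reading (e.g. from [read_chrom_sizes()]).
#' @return `read_genes_bed12()`: a `dhs_genome`.
#' @export
write_genes_bed12 <- function(genome, path) {
  validate_genome(genome)
  g <- genome$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    ex <- genome$exons[genome$exons$gene_id == g$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(g$chrom[i], format_int(g$tx_start[i]), format_int(g$tx_end[i]),
          g$gene_id[i], 0L, g$strand[i],
          format_int(g$tx_start[i]), format_int(g$tx_end[i]), "0",
          nrow(ex),
          paste0(paste(format_int(ex$end - ex$start), collapse = ","), ","),
          paste0(paste(format_int(ex$start - g$tx_start[i]), collapse = ","),
                 ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

format_int <- function(x) format(as.integer(round(x)), scientific = FALSE,
                                 trim = TRUE)

#' @rdname write_genes_bed12
#' @export
read_genes_bed12 <- function(path, chroms) {
  gr <- rtracklayer::import(path, format = "bed")
  genes <- data.frame(gene_id = gr$name,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      tx_start = GenomicRanges::start(gr) - 1,
                      tx_end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  blocks <- gr$blocks
  exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    data.frame(gene_id = genes$gene_id[i],
               start = genes$tx_start[i] + IRanges::start(b) - 1,
               end = genes$tx_start[i] + IRanges::end(b),
               stringsAsFactors = FALSE)
  }))
  new_dhs_genome(chroms, genes, exons %||% empty_exon_table())
}

#' Read and write chromosome sizes
#'
#' Two-column tab-separated `chrom<TAB>length`, no header.
#' @param chroms Named numeric vector of lengths.
#' @param path File path.
#' @return `read_chrom_sizes()`: named numeric vector.
#' @export
write_chrom_sizes <- function(chroms, path) {
  writeLines(paste(names(chroms), format_int(chroms), sep = "\t"), path)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Read and write bedGraph tag tracks
#'
#' @param track Data.frame `chrom`, `start`, `end`, `count` (0-based
#'   half-open).
#' @param path File path.
#' @return `read_bedgraph()`: a track data.frame.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(chrom = track$chrom, start = as.integer(track$start),
                   end = as.integer(track$end), count = track$count)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             count = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Read and write GMT gene-set collections
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param description Optional per-set description (recycled).
#' @return `read_gmt()`: named list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  if (length(sets) == 0 || is.null(names(sets))) {
    stop("`sets` must be a non-empty named list")
  }
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read and write qPCR titration tables
#'
#' Tab-separated with header: `site_id`, `site_class`, `dnase_units`,
#' `replicate`, `cq` (empty `cq` encodes no amplification).
#' @param table A titration data.frame.
#' @param path File path.
#' @return `read_titration()`: a `titration_table` data.frame.
#' @export
write_titration <- function(table, path) {
  keep <- intersect(c("site_id", "site_class", "dnase_units", "replicate",
                      "cq"), names(table))
  data.table::fwrite(as.data.frame(table)[, keep], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("titration_table", "data.frame")
  out
}

#' Read and write expression matrices
#'
#' Tab-separated, `gene_id` first column, then one column per sample named
#' `<condition>_t<time>_r<replicate>`.
#' @param matrix An [expr_matrix()].
#' @param path File path.
#' @return `read_expression()`: an `expr_matrix`.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  samples <- parse_sample_names(colnames(values))
  expr_matrix(values, samples)
}

# Parse sample names of the form <condition>_t<time>_r<replicate>.
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(.+)_t([0-9.]+)_r([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("cannot parse sample name(s): ", paste(x[bad], collapse = ", "),
         " (expected <condition>_t<time>_r<replicate>)")
  }
  data.frame(sample_id = x,
             condition = vapply(m, `[`, character(1), 2),
             time = as.numeric(vapply(m, `[`, character(1), 3)),
             replicate = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}
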