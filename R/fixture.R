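#' Build a complete synthetic study fixture
#'
#' Assembles everything the pipeline consumes, with known ground truth: a
#' synthetic genome with gene models, per-condition ground-truth hotspot
#' tables, two simulated sequencing replicates (peak calls + tag track) per
#' condition, a qPCR titration-of-digestion table, an expression matrix with
#' planted effects, and a GMT collection holding the planted gene set plus
#' size-matched decoy sets.
#'
#' @param spec A [truth_spec()] describing the study design.
#' @param seed Integer seed; the entire fixture is a deterministic function
#'   of `(spec, seed, genome parameters)`.
#' @param n_chroms,chrom_length,n_genes Genome parameters passed to
#'   [make_genome()].
#' @param conditions Optional subset of `spec$conditions` to simulate
#'   sequencing data for (the truth is always generated for all conditions).
#' @param tracks If `FALSE`, skip building per-bp tag tracks (faster when
#'   only peak calls are needed).
#' @param n_decoy_sets Number of decoy gene sets in the GMT collection.
#' @param titration_fractions Named vector of true digested fractions per
#'   DNase concentration for the titration table.
#' @param titration_noise_sd Cq noise SD of the titration table.
#'
#' @return Object of class `dhs_fixture`: list with `genome`, `truth`,
#'   `hotspots` (condition -> list of replicate [hotspot_set()]s), `tracks`
#'   (condition -> bedGraph data.frame or `NULL`), `titration`,
#'   `expression`, `gene_sets`, `planted_set_name`, `spec`, `seed`.
#' @export
make_fixture <- function(spec = truth_spec(), seed = 1,
                         n_chroms = 2, chrom_length = 5e6, n_genes = 200,
                         conditions = NULL, tracks = TRUE,
                         n_decoy_sets = 20,
                         titration_fractions = c(`0` = 0, `5` = 0.06,
                                                 `10` = 0.18, `20` = 0.44,
                                                 `40` = 0.73, `80` = 0.90),
                         titration_noise_sd = 0.15) {
  stopifnot(inherits(spec, "truth_spec"))
  conditions <- conditions %||% spec$conditions
  stopifnot(all(conditions %in% spec$conditions))
  withr::with_seed(as.integer(seed), {
    genome <- make_genome(n_chroms = n_chroms, chrom_length = chrom_length,
                          n_genes = n_genes)
    truth <- make_hotspot_truth(genome, spec)
    hotspots <- list()
    track_list <- list()
    for (cond in conditions) {
      sim <- simulate_tags(truth$conditions[[cond]], genome$chroms,
                           total_reads = spec$total_reads, condition = cond,
                           slop = spec$boundary_slop, build_track = tracks)
      hotspots[[cond]] <- sim$replicates
      track_list[[cond]] <- sim$track
    }
    titration <- simulate_titration(titration_fractions,
                                    sd_noise = titration_noise_sd)
    expression <- simulate_expression(genome, truth,
                                      n_replicates = spec$expression_replicates,
                                      effect = spec$expression_effect,
                                      noise_sd = spec$expression_noise_sd)
    gene_sets <- make_gene_sets(genome, truth$planted_genes, n_decoy_sets)
    structure(list(genome = genome, truth = truth, hotspots = hotspots,
                   tracks = track_list, titration = titration,
                   expression = expression, gene_sets = gene_sets,
                   planted_set_name = "osteogenic_program",
                   spec = spec, seed = as.integer(seed)),
              class = "dhs_fixture")
  })
}

# Planted set plus size-matched decoys drawn uniformly from the non-planted
# genes.
make_gene_sets <- function(genome, planted_genes, n_decoy_sets) {
  sets <- list()
  if (length(planted_genes) > 0) {
    sets[["osteogenic_program"]] <- planted_genes
    pool <- setdiff(genome$genes$gene_id, planted_genes)
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy_%02d", i)]] <-
        sort(sample(pool, min(length(planted_genes), length(pool))))
    }
  }
  sets
}

#' @export
print.dhs_fixture <- function(x, ...) {
  cat(sprintf("<dhs_fixture> seed %d; conditions: %s\n", x$seed,
              paste(names(x$hotspots), collapse = ", ")))
  print(x$genome)
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits the fixture as plain-text files: `chrom.sizes`, `genes.bed`
#' (BED12), `hotspots_<cond>_rep<k>.bed` (BED6, score = raw MaxD, name =
#' site id), `tags_<cond>.bedGraph`, `meta.tsv` (library sizes),
#' `titration.tsv`, `expression.tsv`, `sets.gmt` and `truth.json`.  Output
#' is byte-identical for identical fixtures.
#'
#' @param fixture A `dhs_fixture`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the written file paths (the manifest).
#' @export
write_fixture <- function(fixture, outdir) {
  stopifnot(inherits(fixture, "dhs_fixture"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      stop("cannot create output directory: ", outdir)
    }
  }
  p <- function(f) file.path(outdir, f)
  manifest <- character()
  add <- function(path) manifest <<- c(manifest, path)

  add(write_chrom_sizes(fixture$genome$chroms, p("chrom.sizes")))
  add(write_genes_bed12(fixture$genome, p("genes.bed")))
  meta <- list()
  for (cond in names(fixture$hotspots)) {
    for (k in seq_along(fixture$hotspots[[cond]])) {
      hs <- fixture$hotspots[[cond]][[k]]
      add(write_bed6(hs$sites, p(sprintf("hotspots_%s_rep%d.bed", cond, k))))
      meta[[length(meta) + 1]] <- data.frame(
        sample_id = hs$sample_id, condition = cond, replicate = k,
        total_reads = hs$total_reads, stringsAsFactors = FALSE)
    }
    if (!is.null(fixture$tracks[[cond]])) {
      add(write_bedgraph(fixture$tracks[[cond]],
                         p(sprintf("tags_%s.bedGraph", cond))))
    }
  }
  meta <- do.call(rbind, meta)
  data.table::fwrite(meta, p("meta.tsv"), sep = "\t", quote = FALSE)
  add(p("meta.tsv"))
  add(write_titration(fixture$titration, p("titration.tsv")))
  add(write_expression(fixture$expression, p("expression.tsv")))
  if (length(fixture$gene_sets) > 0) {
    add(write_gmt(fixture$gene_sets, p("sets.gmt")))
  }
  truth_out <- list(
    planted_genes = fixture$truth$planted_genes,
    planted_set_name = fixture$planted_set_name,
    seed = fixture$seed,
    conditions = fixture$truth$conditions
  )
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  add(p("truth.json"))
  manifest
}

#' Read a fixture back from disk
#'
#' Reconstructs the in-memory objects written by [write_fixture()] (tag
#' tracks included when present).
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `genome`, `hotspots`, `tracks`, `titration`,
#'   `expression`, `gene_sets`, `truth` (the deserialized truth record).
#' @export
read_fixture <- function(dir) {
  chroms <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  genome <- read_genes_bed12(file.path(dir, "genes.bed"), chroms)
  meta <- as.data.frame(data.table::fread(file.path(dir, "meta.tsv")))
  hotspots <- list()
  for (i in seq_len(nrow(meta))) {
    cond <- meta$condition[i]
    bed <- file.path(dir, sprintf("hotspots_%s_rep%d.bed", cond,
                                  meta$replicate[i]))
    sites <- read_bed6(bed)
    hotspots[[cond]][[meta$replicate[i]]] <-
      hotspot_set(sites, sample_id = meta$sample_id[i], condition = cond,
                  total_reads = meta$total_reads[i])
  }
  tracks <- list()
  for (cond in unique(meta$condition)) {
    path <- file.path(dir, sprintf("tags_%s.bedGraph", cond))
    if (file.exists(path)) tracks[[cond]] <- read_bedgraph(path)
  }
  gmt_path <- file.path(dir, "sets.gmt")
  list(genome = genome,
       hotspots = hotspots,
       tracks = tracks,
       titration = read_titration(file.path(dir, "titration.tsv")),
       expression = read_expression(file.path(dir, "expression.tsv")),
       gene_sets = if (file.exists(gmt_path)) read_gmt(gmt_path) else list(),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
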