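# End-to-end orchestration: simulate (or load) -> align -> dedup ->
# gene grouping & longest-contig reference -> splice catalogue ->
# quantify -> differential screening, with every artifact written as
# plain text and reproducible bit-for-bit given the config.

#' Pipeline configuration
#'
#' Collects the thresholds the method fixes (identity 0.99, splice gap
#' 50 bp, coordinate tolerance 5 bp, DE cutoffs p < 0.05 / FDR < 0.01 /
#' 2-fold) together with input paths or simulation settings.
#'
#' @param outdir artifact directory (created if missing).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_genes number of simulated genes (ignored when `reads_fasta`
#'   and `contigs_fasta` are supplied).
#' @param reads_fasta,contigs_fasta optional paths to real inputs; when
#'   given, simulation is skipped.
#' @param alignments_psl optional pre-computed long-read-vs-contig PSL
#'   (e.g. from BLAT/minimap2), bypassing the internal aligner.
#' @param min_identity qualifying identity threshold.
#' @param min_gap splice-gap threshold (bp, exclusive).
#' @param round_bp gap-endpoint clustering tolerance (bp).
#' @param dedup a [dedup_params()] object.
#' @param group_mode gene grouping mode (see [group_genes()]).
#' @param p_cutoff,fdr_cutoff,min_fold DE screening cutoffs.
#' @param focal_condition condition for the tissue-specific intersection.
#' @param read_len,depth short-read simulation settings.
#' @param long_read_error,full_length_frac,dup_rate long-read simulation
#'   settings.
#' @param fold_changes optional planted fold changes (see
#'   [sim_short_reads()]).
#' @return a list of class `iso_pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 13L, n_genes = 50L,
                            reads_fasta = NULL, contigs_fasta = NULL,
                            alignments_psl = NULL,
                            min_identity = 0.99, min_gap = 50L,
                            round_bp = 5L, dedup = dedup_params(),
                            group_mode = "components",
                            p_cutoff = 0.05, fdr_cutoff = 0.01,
                            min_fold = 2, focal_condition = "root",
                            read_len = 75L, depth = 5000L,
                            long_read_error = 0, full_length_frac = 1,
                            dup_rate = 0.15, fold_changes = NULL) {
  abort_if(min_identity <= 0 || min_identity > 1,
           "min_identity must be in (0, 1]")
  abort_if(min_gap < 0 || round_bp < 0, "thresholds must be >= 0")
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 reads_fasta = reads_fasta, contigs_fasta = contigs_fasta,
                 alignments_psl = alignments_psl,
                 min_identity = min_identity, min_gap = as.integer(min_gap),
                 round_bp = as.integer(round_bp), dedup = dedup,
                 group_mode = group_mode, p_cutoff = p_cutoff,
                 fdr_cutoff = fdr_cutoff, min_fold = min_fold,
                 focal_condition = focal_condition,
                 read_len = as.integer(read_len), depth = as.integer(depth),
                 long_read_error = long_read_error,
                 full_length_frac = full_length_frac, dup_rate = dup_rate,
                 fold_changes = fold_changes),
            class = "iso_pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a [pipeline_config()] object.
#' @param path JSON file path.
#' @return `path` (write) / the config (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$dedup <- unclass(x$dedup)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dd <- x$dedup
  x$dedup <- NULL
  if (!is.null(x$fold_changes)) {
    x$fold_changes <- tibble::as_tibble(x$fold_changes)
  }
  cfg <- do.call(pipeline_config, x)
  cfg$dedup <- do.call(dedup_params, dd)
  cfg
}

# derive stage seeds from the master seed, keeping within 32-bit range
stage_seed <- function(seed, k) {
  (as.integer(seed) * 101L + k * 7919L) %% 2000000011L
}

write_tsv_stable <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                        ~ fmt_num(.x)))
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                        ~ vapply(.x, paste,
                                                 character(1),
                                                 collapse = ",")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages (in order): simulate (unless real inputs are configured);
#' all-vs-all long-read alignment and duplicate removal; long-read vs
#' contig alignment (internal aligner, or a supplied PSL); gene grouping
#' and longest-contig reference selection; splice cataloguing; short-read
#' quantification; differential screening against the focal condition.
#' All outputs under `config$outdir` are plain text and bit-for-bit
#' reproducible for a fixed config.
#'
#' @param config a [pipeline_config()] object.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every intermediate result: `models`,
#'   `long_reads`, `drclr`, `dedup_log`, `contigs`, `alignments`,
#'   `groups`, `reference`, `catalog`, `summary`, `report`, `expr`,
#'   `de`, `specific_up`, `specific_down`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  simulated <- is.null(config$reads_fasta)

  # -- inputs ---------------------------------------------------------
  models <- NULL
  if (simulated) {
    say("simulate: %d genes (seed %d)", config$n_genes, config$seed)
    models <- sim_genes(config$n_genes, seed = stage_seed(config$seed, 1L))
    lr <- sim_long_reads(models, error_rate = config$long_read_error,
                         full_length_frac = config$full_length_frac,
                         dup_rate = config$dup_rate,
                         seed = stage_seed(config$seed, 2L))
    long_reads <- lr$reads
    ct <- sim_contigs(models, seed = stage_seed(config$seed, 3L))
    contigs <- ct$contigs
    write_fasta(long_reads, out("long_reads.fasta"))
    write_fasta(contigs, out("contigs.fasta"))
  } else {
    abort_if(!file.exists(config$reads_fasta),
             "missing input file: %s", config$reads_fasta)
    abort_if(is.null(config$contigs_fasta) ||
               !file.exists(config$contigs_fasta),
             "missing input file: %s",
             config$contigs_fasta %||% "<contigs_fasta unset>")
    long_reads <- read_fasta(config$reads_fasta, role = "long_read")
    contigs <- read_fasta(config$contigs_fasta, role = "contig")
    lr <- ct <- NULL
  }

  # -- dedup ----------------------------------------------------------
  say("dedup: all-vs-all alignment of %d long reads", nrow(long_reads))
  self_aln <- align_all(long_reads, long_reads, align_params(),
                        min_identity = 0.9, exclude_self = TRUE)
  dd <- remove_duplicates(long_reads, self_aln, config$dedup)
  drclr <- dd$retained
  write_fasta(drclr, out("drclr.fasta"))
  write_tsv_stable(dd$log, out("dedup_log.tsv"))
  say("dedup: %d -> %d reads", nrow(long_reads), nrow(drclr))

  # -- mapfind --------------------------------------------------------
  if (!is.null(config$alignments_psl)) {
    aln <- read_psl(config$alignments_psl)
    aln <- aln[aln$query_id %in% drclr$id, ]
  } else {
    say("align: %d DRCLR reads vs %d contigs", nrow(drclr), nrow(contigs))
    aln <- align_all(drclr, contigs, align_params(), min_identity = 0.5)
  }
  qual <- aln[qualifies(aln, config$min_identity), ]
  groups <- group_genes(qual, contigs, drclr, mode = config$group_mode)
  groups <- select_longest_contig(groups, aln, contigs, drclr,
                                  min_identity = config$min_identity)
  reference <- build_reference(groups, contigs)
  say("mapfind: %d genes, %d resolved", nrow(groups), nrow(reference))
  ref_fa <- reference
  names(ref_fa)[names(ref_fa) == "ref_id"] <- "fasta_id"
  write_fasta(tibble::tibble(id = ref_fa$fasta_id, seq = ref_fa$seq,
                             length = ref_fa$length, role = "contig"),
              out("lrd.fasta"))
  report <- mapping_report(aln, drclr, contigs,
                           min_identity = config$min_identity)
  write_tsv_stable(report$read_identity, out("map_identity.tsv"))
  write_tsv_stable(report$contigs, out("map_partition.tsv"))

  # -- splicing -------------------------------------------------------
  catalog <- catalog_splicing(groups, reference, aln,
                              min_gap = config$min_gap,
                              round_bp = config$round_bp,
                              min_identity = config$min_identity)
  summary <- summarize_catalog(catalog)
  say("splice: %d isoform classes over %d genes", nrow(catalog),
      summary$n_genes)
  write_tsv_stable(tibble::as_tibble(catalog)[,
      c("gene_id", "contig_id", "signature", "n_events", "support")],
      out("catalog.tsv"))
  write_tsv_stable(summary$histogram, out("isoform_histogram.tsv"))
  events <- extract_gaps(catalog_alignments(catalog, groups, reference,
                                            aln, config$min_identity),
                         min_gap = config$min_gap)
  bed <- tibble::tibble(chrom = events$target_id, start = events$t_start,
                        end = events$t_end,
                        name = paste0(events$query_id, ":", events$kind))
  write_tsv_stable(bed, out("events.bed"))

  # -- quantify + DE --------------------------------------------------
  expr <- de <- specific_up <- specific_down <- NULL
  if (simulated) {
    design <- sim_design()
    sr <- sim_short_reads(models, design, read_len = config$read_len,
                          depth = config$depth,
                          fold_changes = config$fold_changes,
                          seed = stage_seed(config$seed, 4L))
    say("quantify: %d samples x %d reads", length(sr$samples),
        config$depth)
    iso_ref <- isoform_reference(catalog, drclr)
    expr <- quantify_samples(sr$samples, iso_ref)
    write_tsv_stable(expr, out("expression.tsv"))
    others <- setdiff(unique(design$condition), config$focal_condition)
    de <- de_screen(expr, design, cond_a = others[1],
                    cond_b = config$focal_condition,
                    p_cutoff = config$p_cutoff,
                    fdr_cutoff = config$fdr_cutoff,
                    min_fold = config$min_fold)
    write_tsv_stable(de, out("de.tsv"))
    specific_up <- tissue_specific(expr, design, config$focal_condition,
                                   "up", p_cutoff = config$p_cutoff,
                                   fdr_cutoff = config$fdr_cutoff,
                                   min_fold = config$min_fold)
    specific_down <- tissue_specific(expr, design, config$focal_condition,
                                     "down", p_cutoff = config$p_cutoff,
                                     fdr_cutoff = config$fdr_cutoff,
                                     min_fold = config$min_fold)
    writeLines(specific_up$isoforms, out("root_specific_up.txt"))
    writeLines(specific_down$isoforms, out("root_specific_down.txt"))
  }

  # -- run log (thresholds only; no timestamps, for determinism) ------
  log_lines <- c(
    sprintf("seed=%d", config$seed),
    sprintf("n_genes=%s", if (simulated) config$n_genes else "external"),
    sprintf("min_identity=%g", config$min_identity),
    sprintf("min_gap=%d", config$min_gap),
    sprintf("round_bp=%d", config$round_bp),
    sprintf("dedup_min_similarity=%g", config$dedup$min_similarity),
    sprintf("group_mode=%s", config$group_mode),
    sprintf("de_cutoffs=p<%g,fdr<%g,fold>=%g", config$p_cutoff,
            config$fdr_cutoff, config$min_fold),
    sprintf("reads_in=%d", nrow(long_reads)),
    sprintf("drclr=%d", nrow(drclr)),
    sprintf("genes_resolved=%d", nrow(reference)),
    sprintf("isoform_classes=%d", nrow(catalog)))
  con <- file(out("run.log"), "wb"); writeLines(log_lines, con); close(con)

  invisible(list(models = models,
                 read_manifest = if (simulated) lr$manifest,
                 contig_roster = if (simulated) ct$roster,
                 long_reads = long_reads, drclr = drclr,
                 dedup_log = dd$log, contigs = contigs, alignments = aln,
                 groups = groups, reference = reference, catalog = catalog,
                 summary = summary, report = report, expr = expr, de = de,
                 specific_up = specific_up, specific_down = specific_down,
                 config = config))
}

# Alignments of supporting reads to their gene's longest contig, for
# event export.
catalog_alignments <- function(catalog, groups, reference, alignments,
                               min_identity) {
  aln <- best_per_pair(alignments)
  aln <- aln[qualifies(aln, min_identity), ]
  keep <- logical(nrow(aln))
  ref_contigs <- reference$contig_id
  for (i in seq_len(nrow(aln))) {
    keep[i] <- aln$target_id[i] %in% ref_contigs
  }
  aln[keep, ]
}

#' One representative long read per isoform class
#'
#' The quantification reference: the first (smallest-id) supporting read
#' of each catalogued isoform class, labelled
#' `gene_id|signature-rank|read_id`.
#'
#' @param catalog an [catalog_splicing()] result.
#' @param drclr the deduplicated long-read sequence tibble.
#' @return a tibble with `ref_id`, `gene_id`, `signature`, `read_id`,
#'   `seq`.
#' @export
isoform_reference <- function(catalog, drclr) {
  rseq <- setNames(drclr$seq, drclr$id)
  cat_tbl <- tibble::as_tibble(catalog)
  cat_tbl <- dplyr::mutate(
    dplyr::group_by(cat_tbl, .data$gene_id),
    rank = dplyr::row_number(), .keep = "all")
  cat_tbl <- dplyr::ungroup(cat_tbl)
  # prefer the longest supporting read (most complete representative)
  rep_read <- vapply(cat_tbl$read_ids, function(ids) {
    ids[order(-nchar(rseq[ids]), ids)][1]
  }, character(1))
  tibble::tibble(
    ref_id = paste0(cat_tbl$gene_id, "|c", cat_tbl$rank, "|", rep_read),
    gene_id = cat_tbl$gene_id, signature = cat_tbl$signature,
    read_id = rep_read, seq = unname(rseq[rep_read]))
}
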