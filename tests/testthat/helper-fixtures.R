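# Shared (lazily computed, cached) simulation fixtures.  Expensive
# end-to-end objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

# 50 exon-structured genes with true/false contigs -- the main study set
fx_models <- function() fixture("models", sim_genes(50, seed = 13))

fx_contigs <- function() fixture("contigs",
  sim_contigs(fx_models(), include_false = TRUE, seed = 13))

# error-free, full-length long reads over the study set
fx_reads0 <- function() fixture("reads0",
  sim_long_reads(fx_models(), error_rate = 0, full_length_frac = 1,
                 dup_rate = 0, seed = 13))

# long-read vs contig alignments for the clean study set
fx_aln0 <- function() fixture("aln0",
  align_all(fx_reads0()$reads, fx_contigs()$contigs, align_params(),
            min_identity = 0.5))

# resolved gene groups for the clean study set
fx_groups0 <- function() fixture("groups0", {
  aln <- fx_aln0()
  qual <- aln[qualifies(aln, 0.99), ]
  groups <- group_genes(qual, fx_contigs()$contigs, fx_reads0()$reads,
                        mode = "components")
  select_longest_contig(groups, aln, fx_contigs()$contigs,
                        fx_reads0()$reads, min_identity = 0.99)
})

# 200-read dedup study set with planted duplicates (smaller gene panel so
# the all-vs-all alignment stays quick)
fx_dedup_input <- function() fixture("dedup_input", {
  models <- sim_genes(18, n_isoform_range = c(1, 3), seed = 11)
  lr <- sim_long_reads(models, per_isoform_depth = 5, error_rate = 0,
                       full_length_frac = 1, dup_rate = 0.35, seed = 11)
  # top up or trim to exactly 200 reads, keeping duplicate pairs intact
  reads <- head(lr$reads, 200)
  manifest <- lr$manifest[lr$manifest$read_id %in% reads$id, ]
  manifest$duplicate_of[!(manifest$duplicate_of %in% reads$id)] <-
    NA_character_
  aln <- align_all(reads, reads, align_params(), min_identity = 0.9,
                   exclude_self = TRUE)
  list(reads = reads, manifest = manifest, alignments = aln)
})

# full pipeline run on the default 50-gene configuration
fx_pipeline <- function() fixture("pipeline", {
  outdir <- file.path(tempdir(), "isomapr-pipe-fixture")
  cfg <- pipeline_config(outdir = outdir, seed = 13)
  run_pipeline(cfg, quiet = TRUE)
})

# brute-force application of the containment rule with the same retention
# order -- the dedup oracle
oracle_dedup <- function(reads, alignments, params = dedup_params()) {
  aln <- alignments |>
    dplyr::group_by(query_id, target_id) |>
    dplyr::slice_max(matches, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  len <- stats::setNames(reads$length, reads$id)
  ord <- reads$id[order(-reads$length, reads$id)]
  retained <- character(0)
  removed <- character(0)
  for (b in ord) {
    is_dup <- FALSE
    for (a in retained) {
      hit <- aln[aln$query_id == b & aln$target_id == a, ]
      if (nrow(hit) == 1 &&
          len[[a]] > len[[b]] &&
          hit$q_start <= params$max_overhang &&
          (hit$q_size - hit$q_end) <= params$max_overhang &&
          hit$matches / len[[b]] > params$min_similarity &&
          (hit$q_num_insert + hit$t_num_insert) <= params$max_gap_openings) {
        is_dup <- TRUE
        break
      }
    }
    if (is_dup) removed <- c(removed, b) else retained <- c(retained, b)
  }
  list(retained = sort(retained), removed = sort(removed))
}
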