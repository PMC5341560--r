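# Gene grouping, qualifying identity, longest-contig selection.

test_that("the qualifying threshold is >= 0.99 with the boundary included", {
  hit <- tibble::tibble(matches = 999L, q_size = 1000L)
  expect_true(qualifies(hit, 0.99))
  hit$matches <- 990L
  expect_true(qualifies(hit, 0.99))
  hit$matches <- 989L
  expect_false(qualifies(hit, 0.99))
})

test_that("components grouping recovers the planted genes exactly", {
  models <- sim_genes(5, seed = 3)
  contigs <- sim_contigs(models, include_false = FALSE, seed = 3)
  reads <- sim_long_reads(models, per_isoform_depth = 2, seed = 3)
  aln <- align_all(reads$reads, contigs$contigs, min_identity = 0.5)
  qual <- aln[qualifies(aln, 0.99), ]
  groups <- group_genes(qual, contigs$contigs, reads$reads, "components")
  # reads and contigs of one planted gene always co-occur in one group
  read_gene <- setNames(reads$manifest$gene_id, reads$manifest$read_id)
  contig_gene <- setNames(contigs$roster$gene_id, contigs$roster$contig_id)
  mapped <- groups[groups$n_reads > 0, ]
  expect_equal(nrow(mapped), 5L)
  for (i in seq_len(nrow(mapped))) {
    genes_here <- unique(c(read_gene[mapped$read_ids[[i]]],
                           contig_gene[mapped$contig_ids[[i]]]))
    expect_length(genes_here, 1)
  }
})

test_that("a contig aligning to nothing forms a read-free singleton group", {
  contigs <- as_seq_tbl(c(TRINITY_DN1_c0_g1_i1 = rand_seq(300)), "contig")
  reads <- as_seq_tbl(c(LR1 = rand_seq(250)))
  groups <- group_genes(empty_alignments(), contigs, reads, "components")
  solo <- groups[vapply(groups$contig_ids, length, 1L) == 1, ]
  expect_equal(solo$n_reads[1], 0L)
})

test_that("trinity_names grouping joins isoform-suffixed contigs", {
  contigs <- as_seq_tbl(c(TRINITY_DN5_c0_g1_i1 = rand_seq(300),
                          TRINITY_DN5_c0_g1_i2 = rand_seq(280),
                          TRINITY_DN6_c0_g1_i1 = rand_seq(260)), "contig")
  reads <- as_seq_tbl(c(LR1 = rand_seq(200)))
  groups <- group_genes(empty_alignments(), contigs, reads, "trinity_names")
  expect_equal(sort(vapply(groups$contig_ids, length, 1L),
                    decreasing = TRUE)[1:2], c(2L, 1L))
  expect_error(group_genes(empty_alignments(), contigs, reads, "nope"))
})

test_that("selection matches a brute-force enumeration of the candidate rule", {
  groups <- fx_groups0()
  aln <- fx_aln0()
  contigs <- fx_contigs()$contigs
  reads <- fx_reads0()$reads
  clen <- setNames(contigs$length, contigs$id)
  rlen <- setNames(reads$length, reads$id)
  # brute force: per gene, all (contig, read) pairs
  best <- aln |>
    dplyr::group_by(query_id, target_id) |>
    dplyr::slice_max(matches, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  for (i in seq_len(nrow(groups))) {
    read_ids <- groups$read_ids[[i]]
    contig_ids <- groups$contig_ids[[i]]
    if (length(read_ids) == 0) {
      expect_true(is.na(groups$longest_contig_id[i]))
      next
    }
    sub <- best[best$query_id %in% read_ids &
                  best$target_id %in% contig_ids &
                  best$matches / best$q_size >= 0.99, ]
    if (nrow(sub) == 0) {
      expect_true(is.na(groups$longest_contig_id[i]))
      next
    }
    max_read <- max(rlen[unique(sub$query_id)])
    cand <- unique(sub$target_id)
    cand <- cand[clen[cand] >= max_read * 0.99]
    want <- if (length(cand) == 0) NA_character_ else
      cand[order(-clen[cand], cand)][1]
    expect_equal(groups$longest_contig_id[i], want)
  }
})

test_that("the planted all-exon contig is selected for every gene at zero error", {
  groups <- fx_groups0()
  roster <- fx_contigs()$roster
  longest <- setNames(roster$contig_id[roster$label == "longest"],
                      roster$gene_id[roster$label == "longest"])
  read_gene <- setNames(fx_reads0()$manifest$gene_id,
                        fx_reads0()$manifest$read_id)
  mapped <- groups[groups$n_reads > 0, ]
  expect_equal(nrow(mapped), 50L)
  for (i in seq_len(nrow(mapped))) {
    gene <- unname(read_gene[mapped$read_ids[[i]][1]])
    expect_equal(mapped$longest_contig_id[i], unname(longest[gene]))
  }
})

test_that("a chimera is never selected as the reference even when longest", {
  # trinity_names grouping puts each chimera inside its host gene's group
  aln <- fx_aln0()
  qual <- aln[qualifies(aln, 0.99), ]
  contigs <- fx_contigs()$contigs
  roster <- fx_contigs()$roster
  reads <- fx_reads0()$reads
  groups <- group_genes(qual, contigs, reads, "trinity_names")
  groups <- select_longest_contig(groups, aln, contigs, reads, 0.99)
  chimeras <- roster$contig_id[roster$label == "chimera"]
  expect_gte(length(chimeras), 5)
  host_longest <- setNames(roster$length[roster$label == "longest"],
                           roster$gene_id[roster$label == "longest"])
  chim_hosts <- roster$gene_id[roster$label == "chimera"]
  # the fixture really plants chimeras longer than the host's true contig
  expect_true(any(roster$length[roster$label == "chimera"] >
                    host_longest[chim_hosts]))
  expect_false(any(groups$longest_contig_id %in% chimeras))
})

test_that("selection is invariant under permutation of alignment order", {
  aln <- fx_aln0()
  contigs <- fx_contigs()$contigs
  reads <- fx_reads0()$reads
  qual <- aln[qualifies(aln, 0.99), ]
  g1 <- group_genes(qual, contigs, reads, "components")
  sel1 <- select_longest_contig(g1, aln, contigs, reads, 0.99)
  set.seed(99)
  perm <- sample(nrow(aln))
  sel2 <- select_longest_contig(g1, aln[perm, ], contigs, reads, 0.99)
  expect_equal(sel1$longest_contig_id, sel2$longest_contig_id)
})

test_that("raising min_identity never adds candidates", {
  groups <- fx_groups0()
  aln <- fx_aln0()
  contigs <- fx_contigs()$contigs
  reads <- fx_reads0()$reads
  strict <- select_longest_contig(groups[, 1:5], aln, contigs, reads, 0.999)
  loose <- select_longest_contig(groups[, 1:5], aln, contigs, reads, 0.95)
  resolved_strict <- !is.na(strict$longest_contig_id)
  resolved_loose <- !is.na(loose$longest_contig_id)
  expect_true(all(resolved_loose[resolved_strict]))
})

test_that("build_reference emits one longest contig per resolved gene", {
  groups <- fx_groups0()
  ref <- build_reference(groups, fx_contigs()$contigs)
  expect_equal(nrow(ref), sum(!is.na(groups$longest_contig_id)))
  expect_false(any(duplicated(ref$contig_id)))
  expect_true(all(grepl("\\|", ref$ref_id)))
  # function A restated: reference length >= every mapped read in its gene
  rlen <- setNames(fx_reads0()$reads$length, fx_reads0()$reads$id)
  for (i in seq_len(nrow(ref))) {
    g <- groups[groups$gene_id == ref$gene_id[i], ]
    expect_gte(ref$length[i], max(rlen[g$read_ids[[1]]]))
  }
  # empty groups -> empty reference
  empty <- groups[0, ]
  expect_equal(nrow(build_reference(empty, fx_contigs()$contigs)), 0L)
})

test_that("mapping report bins conserve read counts and flag unmapped contigs", {
  aln <- fx_aln0()
  reads <- fx_reads0()$reads
  contigs <- fx_contigs()$contigs
  rep <- mapping_report(aln, reads, contigs)
  expect_equal(sum(rep$read_identity$n), sum(rep$reads$mapped))
  expect_equal(sum(rep$contigs$n), nrow(contigs))
  # zero-error reads: every mapped read sits in the top identity bin
  expect_equal(rep$read_identity$n[nrow(rep$read_identity)],
               sum(rep$reads$mapped))
})

test_that("error-bearing reads shift identity mass below the top bin", {
  models <- sim_genes(4, seed = 5)
  noisy <- sim_long_reads(models, per_isoform_depth = 3, error_rate = 0.02,
                          seed = 5)
  contigs <- sim_contigs(models, include_false = FALSE, seed = 5)
  aln <- align_all(noisy$reads, contigs$contigs, min_identity = 0.5)
  rep <- mapping_report(aln, noisy$reads, contigs$contigs)
  top <- rep$read_identity$n[nrow(rep$read_identity)]
  expect_lt(top, sum(rep$reads$mapped) / 2)
})
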